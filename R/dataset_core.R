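#' Construct a material dataset
#'
#' A `material_dataset` holds one row per material: a fixed vector of base
#' features (synthesis conditions, animal-experiment conditions, physical
#' properties), one or more repeated measurements of the response (bone
#' formation rate, in percent), and optionally per-material spectra (FT-IR
#' and/or XRD traces) and grayscale images (SEM-like).
#'
#' @param samples list of samples; each a list with elements `material_id`
#'   (character scalar), `base_features` (named numeric vector, same names
#'   across all samples) and `measurements` (numeric vector, length >= 1).
#' @param spectra optional named list (by material id); each element a list
#'   with components `ftir` and/or `xrd`, each a list with numeric vectors
#'   `axis` (strictly increasing) and `intensity` (same length).
#' @param images optional named list (by material id) of numeric grayscale
#'   matrices in `[0, 1]`.
#' @return an object of class `material_dataset`.
#' @export
material_dataset <- function(samples, spectra = NULL, images = NULL) {
  if (length(samples) == 0L) {
    ds <- structure(
      list(samples = list(), spectra = NULL, images = NULL,
           feature_names = character(0)),
      class = "material_dataset")
    return(ds)
  }
  ids <- vapply(samples, function(s) as.character(s$material_id), character(1))
  if (anyDuplicated(ids)) {
    bv_stop("bonevar_consistency_error", "material ids must be unique")
  }
  fn <- names(samples[[1L]]$base_features)
  for (s in samples) {
    if (!identical(names(s$base_features), fn)) {
      bv_stop("bonevar_consistency_error",
              "base feature names differ between materials")
    }
    if (length(s$measurements) < 1L || !is_finite_num(s$measurements)) {
      bv_stop("bonevar_input_error",
              "material '%s': measurements must be non-empty and finite",
              s$material_id)
    }
    if (!is_finite_num(unname(s$base_features))) {
      bv_stop("bonevar_input_error",
              "material '%s': base features must be finite", s$material_id)
    }
  }
  if (!is.null(spectra)) {
    for (id in names(spectra)) {
      for (block in names(spectra[[id]])) {
        tr <- spectra[[id]][[block]]
        if (length(tr$axis) != length(tr$intensity) ||
            any(diff(tr$axis) <= 0)) {
          bv_stop("bonevar_consistency_error",
                  "spectrum %s/%s: axis must be strictly increasing and match intensity length",
                  id, block)
        }
      }
    }
  }
  structure(
    list(samples = samples, spectra = spectra, images = images,
         feature_names = fn),
    class = "material_dataset")
}

#' @export
print.material_dataset <- function(x, ...) {
  cat(sprintf("<material_dataset> %d materials, %d base features\n",
              length(x$samples), length(x$feature_names)))
  n_meas <- vapply(x$samples, function(s) length(s$measurements), integer(1))
  if (length(n_meas)) {
    cat(sprintf("  measurements per material: %d-%d (total %d)\n",
                min(n_meas), max(n_meas), sum(n_meas)))
  }
  cat(sprintf("  spectra: %s; images: %s\n",
              if (is.null(x$spectra)) "none" else
                paste(sort(unique(unlist(lapply(x$spectra, names)))), collapse = "+"),
              if (is.null(x$images)) "none" else "yes"))
  invisible(x)
}

#' @export
length.material_dataset <- function(x) length(x$samples)

material_ids <- function(dataset) {
  vapply(dataset$samples, function(s) as.character(s$material_id), character(1))
}

#' Load a material dataset from disk
#'
#' Reads the long-format layout written by [write_dataset()]: one delimited
#' table with columns `material_id`, `measurement`, plus feature columns
#' that are constant within each material; optional two-column spectrum
#' files named `<material_id>_ftir.csv` / `<material_id>_xrd.csv`; optional
#' grayscale PNG images named `<material_id>.png`.
#'
#' @param path path to the main CSV table.
#' @param spectra_dir optional directory of per-material spectrum files.
#' @param image_dir optional directory of per-material grayscale PNGs.
#' @return a [material_dataset()].
#' @export
load_dataset <- function(path, spectra_dir = NULL, image_dir = NULL) {
  if (!file.exists(path)) bv_stop("bonevar_input_error", "file not found: %s", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  required <- c("material_id", "measurement")
  if (!all(required %in% names(tab))) {
    bv_stop("bonevar_format_error",
            "table must contain columns: %s", paste(required, collapse = ", "))
  }
  feat_cols <- setdiff(names(tab), required)
  ids <- unique(as.character(tab$material_id))
  samples <- lapply(ids, function(id) {
    rows <- tab[tab$material_id == id, , drop = FALSE]
    feats <- rows[, feat_cols, drop = FALSE]
    if (nrow(unique(feats)) != 1L) {
      bv_stop("bonevar_consistency_error",
              "feature values vary within material '%s'", id)
    }
    list(material_id = id,
         base_features = unlist(feats[1L, , drop = TRUE]),
         measurements = as.numeric(rows$measurement))
  })
  spectra <- NULL
  if (!is.null(spectra_dir)) {
    spectra <- list()
    for (id in ids) {
      blocks <- list()
      for (block in c("ftir", "xrd")) {
        f <- file.path(spectra_dir, paste0(id, "_", block, ".csv"))
        if (file.exists(f)) {
          sp <- utils::read.csv(f)
          blocks[[block]] <- list(axis = sp[[1L]], intensity = sp[[2L]])
        }
      }
      if (length(blocks)) spectra[[id]] <- blocks
    }
    if (!length(spectra)) spectra <- NULL
  }
  images <- NULL
  if (!is.null(image_dir)) {
    images <- list()
    for (id in ids) {
      f <- file.path(image_dir, paste0(id, ".png"))
      if (file.exists(f)) {
        img <- png::readPNG(f)
        if (length(dim(img)) == 3L) img <- img[, , 1L]
        images[[id]] <- img
      }
    }
    if (!length(images)) images <- NULL
  }
  material_dataset(samples, spectra = spectra, images = images)
}

#' Write a material dataset to disk
#'
#' Inverse of [load_dataset()]; the round trip reproduces ids, features and
#' measurements exactly (images up to 16-bit PNG quantisation).
#'
#' @param dataset a [material_dataset()].
#' @param path output path for the main CSV.
#' @param spectra_dir,image_dir optional output directories (created if
#'   needed) for spectra and images.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, spectra_dir = NULL, image_dir = NULL) {
  rows <- do.call(rbind, lapply(dataset$samples, function(s) {
    data.frame(material_id = s$material_id,
               measurement = s$measurements,
               as.list(s$base_features),
               check.names = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  if (!is.null(spectra_dir) && !is.null(dataset$spectra)) {
    dir.create(spectra_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(dataset$spectra)) {
      for (block in names(dataset$spectra[[id]])) {
        tr <- dataset$spectra[[id]][[block]]
        utils::write.csv(
          data.frame(axis = tr$axis, intensity = tr$intensity),
          file.path(spectra_dir, paste0(id, "_", block, ".csv")),
          row.names = FALSE)
      }
    }
  }
  if (!is.null(image_dir) && !is.null(dataset$images)) {
    dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(dataset$images)) {
      img <- dataset$images[[id]]
      img <- pmin(pmax(img, 0), 1)
      png::writePNG(img, file.path(image_dir, paste0(id, ".png")))
    }
  }
  invisible(path)
}

#' Measurement counts per material
#'
#' @param dataset a [material_dataset()].
#' @return named integer vector, material id -> number of repeated
#'   measurements; the histogram of these counts is the experiment-count
#'   histogram of the dataset.
#' @export
summarize_measurements <- function(dataset) {
  if (length(dataset$samples) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  stats::setNames(
    vapply(dataset$samples, function(s) length(s$measurements), integer(1)),
    material_ids(dataset))
}

#' Feature-block combinations A-H
#'
#' The eight combinations of the three optional feature blocks (FT-IR band
#' intensities, XRD band intensities, SEM-image LBP histogram). Base
#' features are always included. Label A uses no optional block; H uses all
#' three.
#'
#' @param label one of `"A".."H"`.
#' @return object of class `method_combo` with logical fields `use_ftir`,
#'   `use_xrd`, `use_sem`.
#' @export
method_combo <- function(label) {
  tab <- combo_table()
  label <- toupper(as.character(label))
  row <- tab[tab$label == label, ]
  if (nrow(row) != 1L) {
    bv_stop("bonevar_input_error", "combo label must be one of A-H, got '%s'", label)
  }
  structure(list(label = row$label, use_ftir = row$use_ftir,
                 use_xrd = row$use_xrd, use_sem = row$use_sem),
            class = "method_combo")
}

#' @rdname method_combo
#' @export
combo_table <- function() {
  data.frame(
    label = LETTERS[1:8],
    use_ftir = c(FALSE, TRUE,  FALSE, FALSE, TRUE,  TRUE,  FALSE, TRUE),
    use_xrd  = c(FALSE, FALSE, TRUE,  FALSE, TRUE,  FALSE, TRUE,  TRUE),
    use_sem  = c(FALSE, FALSE, FALSE, TRUE,  FALSE, TRUE,  TRUE,  TRUE),
    stringsAsFactors = FALSE)
}

#' Assemble the model matrix for one feature combination
#'
#' Builds the explanatory-variable table `X` shared by every sub-dataset:
#' base features always, then FT-IR band intensities (ascending by
#' wavenumber), then XRD band intensities (ascending by angle), then the
#' 256 LBP histogram bins, for whichever blocks the combo switches on.
#' Materials missing a switched-on image contribute `NA` LBP columns, to be
#' completed with [impute_missing()].
#'
#' @param dataset a [material_dataset()].
#' @param combo a [method_combo()].
#' @param ftir_bands,xrd_bands [band_list()] configurations for the two
#'   spectral blocks (required when the corresponding block is switched on).
#' @param lbp_normalize logical; normalise LBP histograms to sum to 1.
#' @return object of class `feature_table`: list with `material_ids`,
#'   numeric `matrix` (rows = materials) and `column_names`.
#' @export
assemble_feature_matrix <- function(dataset, combo,
                                    ftir_bands = NULL, xrd_bands = NULL,
                                    lbp_normalize = TRUE) {
  stopifnot(inherits(combo, "method_combo"))
  ids <- material_ids(dataset)
  base <- do.call(rbind, lapply(dataset$samples, function(s) unname(s$base_features)))
  colnames(base) <- dataset$feature_names
  blocks <- list(base = base)

  grab_spectrum <- function(id, block) {
    tr <- dataset$spectra[[id]][[block]]
    if (is.null(tr)) {
      bv_stop("bonevar_missing_block_error",
              "combo %s requires %s spectra but material '%s' has none",
              combo$label, toupper(block), id)
    }
    tr
  }
  if (combo$use_ftir) {
    if (is.null(dataset$spectra) || is.null(ftir_bands)) {
      bv_stop("bonevar_missing_block_error",
              "combo %s requires FT-IR spectra and an FT-IR band list", combo$label)
    }
    fb <- band_list(sort(ftir_bands$positions), ftir_bands$window)
    m <- t(vapply(ids, function(id) {
      tr <- grab_spectrum(id, "ftir")
      select_band_intensities(tr$axis, tr$intensity, fb)
    }, numeric(length(fb$positions))))
    colnames(m) <- sprintf("ftir_%g", fb$positions)
    blocks$ftir <- m
  }
  if (combo$use_xrd) {
    if (is.null(dataset$spectra) || is.null(xrd_bands)) {
      bv_stop("bonevar_missing_block_error",
              "combo %s requires XRD spectra and an XRD band list", combo$label)
    }
    xb <- band_list(sort(xrd_bands$positions), xrd_bands$window)
    m <- t(vapply(ids, function(id) {
      tr <- grab_spectrum(id, "xrd")
      select_band_intensities(tr$axis, tr$intensity, xb)
    }, numeric(length(xb$positions))))
    colnames(m) <- sprintf("xrd_%g", xb$positions)
    blocks$xrd <- m
  }
  if (combo$use_sem) {
    if (is.null(dataset$images)) {
      bv_stop("bonevar_missing_block_error",
              "combo %s requires SEM images but the dataset has none", combo$label)
    }
    m <- t(vapply(ids, function(id) {
      img <- dataset$images[[id]]
      if (is.null(img)) return(rep(NA_real_, 256L))
      lbp_histogram(compute_lbp_codes(img), normalize = lbp_normalize)
    }, numeric(256L)))
    colnames(m) <- sprintf("lbp_%03d", 0:255)
    blocks$sem <- m
  }
  mat <- do.call(cbind, blocks)
  rownames(mat) <- ids
  feature_table(ids, mat)
}

#' @rdname assemble_feature_matrix
#' @param matrix numeric matrix with one row per material.
#' @export
feature_table <- function(material_ids, matrix) {
  stopifnot(nrow(matrix) == length(material_ids))
  structure(list(material_ids = material_ids,
                 matrix = matrix,
                 column_names = colnames(matrix)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d materials x %d features (%d NA cells)\n",
              nrow(x$matrix), ncol(x$matrix), sum(is.na(x$matrix))))
  invisible(x)
}
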