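#' Run the variability-prediction pipeline over feature combinations
#'
#' For each requested combination A-H: assemble features, build the
#' sub-dataset ensemble, and evaluate predicted against measured
#' distributions. Returns one `method_evaluation` per combination plus a
#' comparison table (combo label, block flags, aggregate `D_JS`,
#' r-squared) sorted in label order.
#'
#' @param dataset a [material_dataset()].
#' @param combos character vector of combo labels (subset of `"A".."H"`).
#' @param zoo a [model_zoo()].
#' @param n_subdatasets,inner_folds,outer_folds,seed ensemble settings;
#'   see [predict_ensemble()]. Per-combo seeds derive from `seed` so runs
#'   are reproducible end to end.
#' @param ftir_bands,xrd_bands band lists for the spectral blocks.
#' @param grid a [divergence_grid()].
#' @return object of class `pipeline_result`: list `evaluations` (by
#'   label), data frame `comparison`, the `predictions`, and a `manifest`
#'   echoing the run settings.
#' @export
run_pipeline <- function(dataset, combos = LETTERS[1:8], zoo = model_zoo(),
                         n_subdatasets = 100L, inner_folds = 5L,
                         outer_folds = 10L, seed = 1L,
                         ftir_bands = NULL, xrd_bands = NULL,
                         grid = divergence_grid()) {
  combos <- toupper(combos)
  evaluations <- list(); predictions <- list()
  for (lab in combos) {
    combo <- method_combo(lab)
    pred <- predict_ensemble(dataset, combo, zoo,
                             n_subdatasets = n_subdatasets,
                             inner_folds = inner_folds,
                             outer_folds = outer_folds,
                             seed = derive_seed(seed, match(lab, LETTERS)),
                             ftir_bands = ftir_bands, xrd_bands = xrd_bands)
    evaluations[[lab]] <- evaluate_method(dataset, pred, combo, grid = grid)
    predictions[[lab]] <- pred
  }
  flags <- combo_table()
  comparison <- do.call(rbind, lapply(combos, function(lab) {
    f <- flags[flags$label == lab, ]
    data.frame(combo = lab, use_ftir = f$use_ftir, use_xrd = f$use_xrd,
               use_sem = f$use_sem,
               d_js = evaluations[[lab]]$aggregate_d_js,
               r_squared = evaluations[[lab]]$r_squared)
  }))
  structure(list(
    evaluations = evaluations, comparison = comparison,
    predictions = predictions,
    manifest = list(combos = combos, n_subdatasets = n_subdatasets,
                    inner_folds = inner_folds, outer_folds = outer_folds,
                    seed = seed, zoo_methods = names(zoo),
                    package_version = as.character(utils::packageVersion("bonevar")))),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$comparison, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Writes, per combo, the per-material table
#' (`report_<combo>_materials.csv`) and the estimate matrix
#' (`estimates_<combo>.csv`, rows = materials, columns = sub-datasets);
#' plus the comparison table (`comparison.csv`), the chosen-method log and
#' a YAML manifest of the run settings.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  for (lab in names(result$evaluations)) {
    utils::write.csv(result$evaluations[[lab]]$per_material,
                     file.path(dir, sprintf("report_%s_materials.csv", lab)),
                     row.names = FALSE)
    utils::write.csv(data.frame(material_id = rownames(result$predictions[[lab]]$estimates),
                                result$predictions[[lab]]$estimates,
                                check.names = FALSE),
                     file.path(dir, sprintf("estimates_%s.csv", lab)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(result$predictions[[lab]]$chosen_methods),
                     file.path(dir, sprintf("chosen_methods_%s.csv", lab)),
                     row.names = FALSE)
  }
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Diagnostic figures for one evaluated combination
#'
#' Three ggplot objects: (i) measured-mean vs predicted-mean scatter with
#' dispersion rectangles (width = measured spread, height = predicted
#' spread; squares indicate well-predicted variability) and the identity
#' diagonal; (ii) per-material strip plot of measured values and ensemble
#' estimates side by side; (iii) per-material `D_JS` bar chart.
#'
#' @param dataset a [material_dataset()].
#' @param prediction the `ensemble_prediction` for the combo.
#' @param evaluation the matching `method_evaluation`.
#' @param multiplier rectangle side length in SD units.
#' @return named list of ggplot objects `scatter`, `strips`, `divergence`.
#' @export
make_figures <- function(dataset, prediction, evaluation, multiplier = 2) {
  if (nrow(evaluation$per_material) == 0L) {
    bv_stop("bonevar_input_error", "empty evaluation report")
  }
  rect <- rectangle_summary(dataset, prediction, multiplier = multiplier)
  p_scatter <- ggplot2::ggplot(rect, ggplot2::aes(x = .data$mean_x, y = .data$mean_y)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$mean_x - .data$width / 2,
                                    xmax = .data$mean_x + .data$width / 2,
                                    ymin = .data$mean_y - .data$height / 2,
                                    ymax = .data$mean_y + .data$height / 2),
                       fill = NA, colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Measured bone formation rate, mean (%)",
                  y = "Predicted bone formation rate, mean (%)",
                  title = sprintf("Combo %s: means with dispersion rectangles",
                                  evaluation$combo_label)) +
    ggplot2::theme_bw()

  ids <- material_ids(dataset)
  meas <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(material_id = ids[i], kind = "measured",
               value = dataset$samples[[i]]$measurements)
  }))
  est <- data.frame(
    material_id = rep(rownames(prediction$estimates), ncol(prediction$estimates)),
    kind = "estimated",
    value = as.vector(prediction$estimates))
  both <- rbind(meas, est)
  both$material_id <- factor(both$material_id, levels = ids)
  p_strips <- ggplot2::ggplot(both, ggplot2::aes(x = .data$material_id,
                                                 y = .data$value,
                                                 colour = .data$kind)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6),
                        size = 0.5, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(measured = "black", estimated = "#2166ac")) +
    ggplot2::labs(x = "Material", y = "Bone formation rate (%)", colour = NULL,
                  title = sprintf("Combo %s: measured and estimated values",
                                  evaluation$combo_label)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))

  pm <- evaluation$per_material
  pm$material_id <- factor(pm$material_id, levels = ids)
  p_bars <- ggplot2::ggplot(pm, ggplot2::aes(x = .data$material_id, y = .data$d_js)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Material", y = "JS divergence (nats)",
                  title = sprintf("Combo %s: per-material JS divergence",
                                  evaluation$combo_label)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))

  list(scatter = p_scatter, strips = p_strips, divergence = p_bars)
}

#' Save the figures of [make_figures()] as PNG files
#'
#' @inheritParams make_figures
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
save_figures <- function(dataset, prediction, evaluation, dir, multiplier = 2) {
  figs <- make_figures(dataset, prediction, evaluation, multiplier = multiplier)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(figs)) {
    path <- file.path(dir, sprintf("fig_%s_%s.png", evaluation$combo_label, nm))
    ggplot2::ggsave(path, figs[[nm]], width = 7, height = 5, dpi = 150)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @importFrom ggplot2 .data
NULL
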