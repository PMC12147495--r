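#' Spectral band list
#'
#' A set of axis positions (wavenumbers in cm^-1 for FT-IR, 2-theta degrees
#' for XRD) at which band intensities are read off a spectrum, with a
#' half-width `window` in axis units. Typical positions are the
#' characteristic bands of the crystalline phases present (e.g.
#' hydroxyapatite and beta-TCP); they are configuration, not constants.
#'
#' @param positions numeric vector of band positions (finite).
#' @param window non-negative half-width; `0` means "intensity at the
#'   nearest axis point".
#' @export
band_list <- function(positions, window = 0) {
  if (!is_finite_num(positions) || length(positions) == 0L) {
    bv_stop("bonevar_input_error", "band positions must be finite and non-empty")
  }
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) || window < 0) {
    bv_stop("bonevar_input_error", "window must be a single non-negative number")
  }
  structure(list(positions = as.numeric(positions), window = as.numeric(window)),
            class = "band_list")
}

#' Band intensities from one spectrum
#'
#' For each band position, the mean intensity over axis points within
#' `position +/- window`; with `window = 0`, the intensity at the nearest
#' axis point.
#'
#' @param axis strictly increasing numeric vector.
#' @param intensity numeric vector, same length as `axis`.
#' @param bands a [band_list()].
#' @return numeric vector, one intensity per band.
#' @export
select_band_intensities <- function(axis, intensity, bands) {
  stopifnot(inherits(bands, "band_list"))
  if (length(axis) != length(intensity) || any(diff(axis) <= 0)) {
    bv_stop("bonevar_input_error",
            "axis must be strictly increasing and match intensity length")
  }
  w <- bands$window
  vapply(bands$positions, function(p) {
    if (p < min(axis) - w || p > max(axis) + w) {
      bv_stop("bonevar_out_of_range_error",
              "band position %g outside spectrum range [%g, %g] (window %g)",
              p, min(axis), max(axis), w)
    }
    if (w == 0) {
      intensity[which.min(abs(axis - p))]
    } else {
      sel <- abs(axis - p) <= w
      if (!any(sel)) {
        bv_stop("bonevar_out_of_range_error",
                "no axis point within %g of band position %g", w, p)
      }
      mean(intensity[sel])
    }
  }, numeric(1))
}

#' Local binary pattern codes of a grayscale image
#'
#' For every interior pixel the eight neighbour-minus-centre luminance
#' differences are binarised (`>= 0` -> 1, `< 0` -> 0) and read clockwise
#' from the top-left neighbour as the most significant bit of an 8-bit
#' code. Codes depend only on relative luminance: adding a constant to the
#' whole image, or any strictly increasing intensity transform, leaves them
#' unchanged. Border pixels are not coded (no padding is invented).
#'
#' @param image numeric grayscale matrix, at least 3x3.
#' @return integer matrix of codes in `[0, 255]`, dimensions
#'   `(nrow - 2) x (ncol - 2)`.
#' @export
compute_lbp_codes <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L) {
    bv_stop("bonevar_size_error", "image must be a matrix of at least 3x3 pixels")
  }
  h <- nrow(image); w <- ncol(image)
  centre <- image[2:(h - 1), 2:(w - 1), drop = FALSE]
  # clockwise from top-left: NW N NE E SE S SW W; NW is the MSB (weight 128)
  offsets <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                  c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  weights <- 2^(7:0)
  codes <- matrix(0L, h - 2L, w - 2L)
  for (k in seq_along(offsets)) {
    dr <- offsets[[k]][1L]; dc <- offsets[[k]][2L]
    nb <- image[(2:(h - 1)) + dr, (2:(w - 1)) + dc, drop = FALSE]
    codes <- codes + as.integer(nb >= centre) * as.integer(weights[k])
  }
  storage.mode(codes) <- "integer"
  codes
}

#' 256-bin LBP histogram
#'
#' @param codes integer matrix from [compute_lbp_codes()].
#' @param normalize logical; if `TRUE` the histogram is divided by the
#'   number of coded pixels and sums to 1, otherwise bins hold raw counts
#'   summing to `(H-2)(W-2)`.
#' @return numeric vector of length 256 (bins for codes 0..255).
#' @export
lbp_histogram <- function(codes, normalize = TRUE) {
  if (length(codes) == 0L) {
    bv_stop("bonevar_size_error", "empty LBP code matrix")
  }
  if (any(codes < 0L) || any(codes > 255L)) {
    bv_stop("bonevar_input_error", "LBP codes must lie in [0, 255]")
  }
  counts <- tabulate(as.integer(codes) + 1L, nbins = 256L)
  if (normalize) counts / length(codes) else as.numeric(counts)
}

#' Impute missing feature-table cells with an iterative Gaussian mixture
#'
#' Missing cells are initialised at their column means; then, repeatedly, a
#' Gaussian mixture with `n_components` components is fitted to the current
#' completed matrix and every missing cell is replaced by its conditional
#' mean given the row's observed cells under that mixture, until the
#' largest per-cell change falls below `tol` or `max_iter` sweeps. Observed
#' cells are never altered. A complete table is returned unchanged.
#'
#' Covariances are ridge-regularised so near-degenerate blocks (e.g.
#' perfectly collinear columns) keep a well-defined conditional mean.
#'
#' @param table a [feature_table()] (NA marks missing cells).
#' @param n_components number of mixture components (must not exceed the
#'   number of complete rows).
#' @param max_iter maximum number of impute/refit sweeps.
#' @param seed integer seed (component initialisation is seeded k-means).
#' @param tol convergence threshold on the largest absolute cell change.
#' @return the completed [feature_table()].
#' @export
impute_missing <- function(table, n_components = 1L, max_iter = 20L,
                           seed = 1L, tol = 1e-4) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$matrix
  miss <- is.na(x)
  if (!any(miss)) return(table)
  if (any(colSums(!miss) == 0L)) {
    bv_stop("bonevar_imputation_error", "a column is entirely missing")
  }
  complete_rows <- sum(rowSums(miss) == 0L)
  if (complete_rows < 1L) {
    bv_stop("bonevar_imputation_error", "at least one complete row is required")
  }
  if (n_components > complete_rows) {
    bv_stop("bonevar_config_error",
            "n_components (%d) exceeds the number of complete rows (%d)",
            n_components, complete_rows)
  }
  # init: column means of observed cells
  for (j in seq_len(ncol(x))) {
    mj <- mean(x[!miss[, j], j])
    x[miss[, j], j] <- mj
  }
  for (iter in seq_len(max_iter)) {
    fit <- gmm_fit(x, k = n_components, seed = seed)
    x_new <- x
    for (i in which(rowSums(miss) > 0L)) {
      obs <- which(!miss[i, ]); mis <- which(miss[i, ])
      x_new[i, mis] <- gmm_conditional_mean(fit, x[i, ], obs, mis)
    }
    delta <- max(abs(x_new[miss] - x[miss]))
    x <- x_new
    if (delta < tol) break
  }
  feature_table(table$material_ids, x)
}

# Compact EM for a full-covariance Gaussian mixture with ridge-regularised
# covariances; deterministic given `seed` (k-means initialisation).
gmm_fit <- function(x, k, seed, ridge = 1e-6, em_iter = 50L) {
  n <- nrow(x); p <- ncol(x)
  col_var <- apply(x, 2, stats::var)
  lambda <- ridge * max(mean(col_var[col_var > 0], na.rm = TRUE), 1e-12)
  reg <- function(sig) sig + diag(lambda, p)
  if (k == 1L) {
    return(list(k = 1L, pi = 1,
                mu = list(colMeans(x)),
                sigma = list(reg(stats::cov(x) * (n - 1) / n))))
  }
  cl <- withr::with_seed(seed, stats::kmeans(x, centers = k, nstart = 5L)$cluster)
  pi_k <- tabulate(cl, k) / n
  mu <- lapply(seq_len(k), function(j) colMeans(x[cl == j, , drop = FALSE]))
  sigma <- lapply(seq_len(k), function(j) {
    xs <- x[cl == j, , drop = FALSE]
    if (nrow(xs) < 2L) reg(diag(col_var, p)) else reg(stats::cov(xs))
  })
  for (it in seq_len(em_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      dmvnorm_log(x, mu[[j]], sigma[[j]]) + log(pi_k[j])
    }, numeric(n))
    m <- apply(logd, 1, max)
    resp <- exp(logd - m)
    resp <- resp / rowSums(resp)
    nk <- colSums(resp)
    pi_new <- nk / n
    mu_new <- lapply(seq_len(k), function(j) colSums(resp[, j] * x) / nk[j])
    sigma_new <- lapply(seq_len(k), function(j) {
      xc <- sweep(x, 2, mu_new[[j]])
      reg(crossprod(xc * sqrt(resp[, j]), xc * sqrt(resp[, j])) / nk[j])
    })
    shift <- max(abs(unlist(mu_new) - unlist(mu)))
    pi_k <- pi_new; mu <- mu_new; sigma <- sigma_new
    if (shift < 1e-8) break
  }
  list(k = k, pi = pi_k, mu = mu, sigma = sigma)
}

dmvnorm_log <- function(x, mu, sigma) {
  p <- length(mu)
  ch <- chol(sigma)
  xc <- sweep(x, 2, mu)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

# Conditional mean of the missing block given the observed block, averaged
# over components with weights proportional to pi_j * phi(x_obs | comp j).
gmm_conditional_mean <- function(fit, row, obs, mis) {
  k <- fit$k
  logw <- numeric(k)
  cond <- matrix(0, k, length(mis))
  for (j in seq_len(k)) {
    mu <- fit$mu[[j]]; sig <- fit$sigma[[j]]
    s_oo <- sig[obs, obs, drop = FALSE]
    s_mo <- sig[mis, obs, drop = FALSE]
    logw[j] <- log(fit$pi[j]) +
      dmvnorm_log(matrix(row[obs], nrow = 1), mu[obs], s_oo)
    cond[j, ] <- mu[mis] +
      as.numeric(s_mo %*% solve(s_oo, row[obs] - mu[obs]))
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  as.numeric(crossprod(w, cond))
}
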