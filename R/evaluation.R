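#' Gaussian summary of a set of values
#'
#' Measured and predicted bone-formation-rate distributions are compared as
#' fitted normals; a `gaussian_summary` is the (mean, SD) pair with
#' bookkeeping about how the SD was obtained.
#'
#' @param mean,sd distribution parameters (`sd > 0`), in % units.
#' @param n number of values summarised.
#' @param sd_substituted `TRUE` when the SD was not estimated from the
#'   values themselves (fallback rule or numerical floor).
#' @export
gaussian_summary <- function(mean, sd, n, sd_substituted = FALSE) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0) {
    bv_stop("bonevar_domain_error", "gaussian summary requires finite mean and sd > 0")
  }
  structure(list(mean = mean, sd = sd, n = as.integer(n),
                 sd_substituted = isTRUE(sd_substituted)),
            class = "gaussian_summary")
}

#' @export
print.gaussian_summary <- function(x, ...) {
  cat(sprintf("N(mean = %.4g, sd = %.4g) from n = %d%s\n", x$mean, x$sd, x$n,
              if (x$sd_substituted) " [sd substituted]" else ""))
  invisible(x)
}

#' Fit a Gaussian to a material's measured values
#'
#' Mean is the arithmetic mean. With three or more measurements the SD is
#' the sample SD (n-1 denominator); with one or two measurements the SD is
#' replaced by `fallback_sd` — the substitution rule for sparsely measured
#' materials (see [compute_fallback_sd()]).
#'
#' @param measurements numeric vector of repeated measurements (non-empty).
#' @param fallback_sd positive SD used when fewer than three measurements
#'   are available.
#' @return a [gaussian_summary()].
#' @export
fit_gaussian_measured <- function(measurements, fallback_sd = NULL) {
  if (length(measurements) == 0L || !is_finite_num(measurements)) {
    bv_stop("bonevar_input_error", "measurements must be non-empty and finite")
  }
  m <- mean(measurements)
  if (length(measurements) >= 3L) {
    s <- stats::sd(measurements)
    if (s == 0) {
      bv_stop("bonevar_degenerate_distribution_error",
              "three or more identical measurements give a zero-SD distribution")
    }
    gaussian_summary(m, s, length(measurements), sd_substituted = FALSE)
  } else {
    if (is.null(fallback_sd) || !is.finite(fallback_sd) || fallback_sd <= 0) {
      bv_stop("bonevar_input_error",
              "a positive fallback_sd is required for 1 or 2 measurements")
    }
    gaussian_summary(m, fallback_sd, length(measurements), sd_substituted = TRUE)
  }
}

#' Fallback SD for sparsely measured materials
#'
#' The arithmetic mean of the sample SDs of exactly those materials with
#' three or more measurements; substituted as the measured-distribution SD
#' of materials with one or two measurements.
#'
#' @param dataset a [material_dataset()].
#' @return a positive scalar.
#' @export
compute_fallback_sd <- function(dataset) {
  sds <- vapply(dataset$samples, function(s) {
    if (length(s$measurements) >= 3L) stats::sd(s$measurements) else NA_real_
  }, numeric(1))
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0L) {
    bv_stop("bonevar_fallback_undefined_error",
            "no material has three or more measurements")
  }
  mean(sds)
}

#' Fit a Gaussian to a material's ensemble estimates
#'
#' @param estimates numeric vector of out-of-fold ensemble estimates
#'   (length >= 2).
#' @param sd_floor positive floor applied when the sample SD of the
#'   estimates is numerically zero (flagged via `sd_substituted`).
#' @return a [gaussian_summary()].
#' @export
fit_gaussian_predicted <- function(estimates, sd_floor = 1e-6) {
  if (length(estimates) < 2L || !is_finite_num(estimates)) {
    bv_stop("bonevar_input_error", "at least two finite estimates are required")
  }
  s <- stats::sd(estimates)
  floored <- s < sd_floor
  gaussian_summary(mean(estimates), if (floored) sd_floor else s,
                   length(estimates), sd_substituted = floored)
}

#' Integration grid for divergence quadrature
#'
#' Uniform grid spanning `[min(mu) - span_sd * max(sd), max(mu) +
#' span_sd * max(sd)]` for the pair of Gaussians under comparison.
#'
#' @param n_points number of grid points (trapezoidal rule).
#' @param span_sd half-span in units of the larger SD.
#' @export
divergence_grid <- function(n_points = 20001L, span_sd = 10) {
  stopifnot(n_points >= 3L, span_sd > 0)
  structure(list(n_points = as.integer(n_points), span_sd = span_sd),
            class = "divergence_grid")
}

grid_points <- function(p, q, grid) {
  lo <- min(p$mean, q$mean) - grid$span_sd * max(p$sd, q$sd)
  hi <- max(p$mean, q$mean) + grid$span_sd * max(p$sd, q$sd)
  seq(lo, hi, length.out = grid$n_points)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

# integrand of KL on a fixed grid from log-densities; working in log space
# keeps far tails exact (no underflow clamp on log q). Where the reference
# density p vanishes to double precision the contribution is 0 by
# convention.
kl_integrand <- function(logp, logq) {
  p <- exp(logp)
  out <- p * (logp - logq)
  out[p < 1e-300] <- 0
  out
}

#' Kullback-Leibler divergence between two fitted Gaussians
#'
#' Numerical evaluation of `integral p(x) log(p(x)/q(x)) dx` by the
#' trapezoidal rule, in natural log by default. Densities are handled in
#' log space so well-separated narrow Gaussians do not underflow; small
#' negative quadrature results are clipped to 0.
#'
#' @param p,q [gaussian_summary()] objects (`p` is the reference).
#' @param grid a [divergence_grid()].
#' @param base `"nats"` (natural log, default) or `"bits"` (log base 2).
#' @return a non-negative scalar.
#' @export
kl_divergence <- function(p, q, grid = divergence_grid(), base = c("nats", "bits")) {
  base <- match.arg(base)
  stopifnot(inherits(p, "gaussian_summary"), inherits(q, "gaussian_summary"))
  x <- grid_points(p, q, grid)
  logp <- stats::dnorm(x, p$mean, p$sd, log = TRUE)
  logq <- stats::dnorm(x, q$mean, q$sd, log = TRUE)
  val <- trapz(x, kl_integrand(logp, logq))
  if (base == "bits") val <- val / log(2)
  max(val, 0)
}

#' Jensen-Shannon divergence between two fitted Gaussians
#'
#' `D_JS = (D_KL(p || m) + D_KL(q || m)) / 2` with `m` the pointwise
#' mixture `(p + q)/2` — evaluated as a density on the shared grid, not
#' refitted as a Gaussian. Symmetric in its arguments and bounded by
#' `log 2` (0.6931 nats; 1 bit with `base = "bits"`).
#'
#' @inheritParams kl_divergence
#' @return a scalar in `[0, log 2]` (up to quadrature tolerance).
#' @export
js_divergence <- function(p, q, grid = divergence_grid(), base = c("nats", "bits")) {
  base <- match.arg(base)
  stopifnot(inherits(p, "gaussian_summary"), inherits(q, "gaussian_summary"))
  x <- grid_points(p, q, grid)
  logp <- stats::dnorm(x, p$mean, p$sd, log = TRUE)
  logq <- stats::dnorm(x, q$mean, q$sd, log = TRUE)
  # log m = log((e^logp + e^logq)/2), stabilised log-sum-exp
  mx <- pmax(logp, logq)
  logm <- mx + log(exp(logp - mx) + exp(logq - mx)) - log(2)
  val <- (trapz(x, kl_integrand(logp, logm)) +
          trapz(x, kl_integrand(logq, logm))) / 2
  if (base == "bits") val <- val / log(2)
  max(val, 0)
}

#' Coefficient of determination of the means
#'
#' `1 - sum((m_i - p_i)^2) / sum((m_i - mean(m))^2)` between per-material
#' measured means and predicted means; can be negative when predictions
#' explain less variance than the constant mean.
#'
#' @param measured_means,predicted_means numeric vectors of equal length
#'   (>= 2); measured means must not all be equal.
#' @export
r_squared_of_means <- function(measured_means, predicted_means) {
  if (length(measured_means) != length(predicted_means) ||
      length(measured_means) < 2L) {
    bv_stop("bonevar_input_error", "need two equal-length vectors of means")
  }
  if (stats::var(measured_means) == 0) {
    bv_stop("bonevar_undefined_variance_error", "measured means are all equal")
  }
  r2_score(measured_means, predicted_means)
}

#' Evaluate one feature combination
#'
#' Per material: fit the measured Gaussian (sample SD for three or more
#' measurements, the dataset-level fallback SD otherwise) and the predicted
#' Gaussian (mean/SD of the ensemble estimates), and compute their JS
#' divergence. The aggregate `D_JS` is the arithmetic mean over materials;
#' `r_squared` compares measured and predicted means.
#'
#' @param dataset a [material_dataset()].
#' @param prediction an `ensemble_prediction` covering every material.
#' @param combo the [method_combo()] the prediction was run with (label
#'   echoed in the report).
#' @param grid a [divergence_grid()].
#' @param base log base for the divergences.
#' @return object of class `method_evaluation`: `per_material` data frame
#'   (measured/predicted mean, SD, n, `d_js`), `aggregate_d_js`,
#'   `r_squared`, `combo_label`.
#' @export
evaluate_method <- function(dataset, prediction, combo,
                            grid = divergence_grid(), base = "nats") {
  ids <- material_ids(dataset)
  if (!all(ids %in% rownames(prediction$estimates))) {
    bv_stop("bonevar_input_error", "prediction does not cover every material")
  }
  fb <- compute_fallback_sd(dataset)
  rows <- lapply(seq_along(ids), function(i) {
    meas <- fit_gaussian_measured(dataset$samples[[i]]$measurements, fallback_sd = fb)
    pred <- fit_gaussian_predicted(prediction$estimates[ids[i], ])
    data.frame(material_id = ids[i],
               measured_mean = meas$mean, measured_sd = meas$sd,
               measured_n = meas$n, sd_substituted = meas$sd_substituted,
               predicted_mean = pred$mean, predicted_sd = pred$sd,
               d_js = js_divergence(meas, pred, grid = grid, base = base))
  })
  per_material <- do.call(rbind, rows)
  structure(list(
    combo_label = combo$label,
    per_material = per_material,
    aggregate_d_js = mean(per_material$d_js),
    r_squared = r_squared_of_means(per_material$measured_mean,
                                   per_material$predicted_mean),
    fallback_sd = fb),
    class = "method_evaluation")
}

#' @export
print.method_evaluation <- function(x, ...) {
  cat(sprintf("<method_evaluation> combo %s: D_JS = %.3f, r2 = %.3f (%d materials)\n",
              x$combo_label, x$aggregate_d_js, x$r_squared, nrow(x$per_material)))
  invisible(x)
}

#' Dispersion rectangles for the mean-vs-mean scatter
#'
#' For each material, the rectangle centred at (measured mean, predicted
#' mean) whose width is the measured spread and height the predicted
#' spread (`multiplier * SD` each, 2 SD by default). An aspect ratio
#' (height/width) near 1 — a square — means the predicted variability
#' matches the measured one.
#'
#' @inheritParams evaluate_method
#' @param multiplier spread multiple of the SD used for the side lengths.
#' @return data frame with `mean_x`, `mean_y`, `width`, `height`, `aspect`.
#' @export
rectangle_summary <- function(dataset, prediction, multiplier = 2) {
  ids <- material_ids(dataset)
  fb <- compute_fallback_sd(dataset)
  do.call(rbind, lapply(seq_along(ids), function(i) {
    meas <- fit_gaussian_measured(dataset$samples[[i]]$measurements, fallback_sd = fb)
    pred <- fit_gaussian_predicted(prediction$estimates[ids[i], ])
    data.frame(material_id = ids[i],
               mean_x = meas$mean, mean_y = pred$mean,
               width = multiplier * meas$sd, height = multiplier * pred$sd,
               aspect = pred$sd / meas$sd)
  }))
}
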