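#' Regression model zoo
#'
#' The candidate learners competed per sub-dataset, each with a small
#' hyperparameter grid. Available methods: `ols`, `ridge`, `lasso`,
#' `elastic_net`, `svr_linear`, `svr_rbf`, `gpr`, `tree`, `random_forest`,
#' `xgboost`. Features are standardised with training-fold statistics
#' before every fit, so the linear and kernel methods see comparable
#' scales; grids can be overridden per method.
#'
#' @param methods character vector of method names (subset of the above).
#' @param grids optional named list; per method, a list of named parameter
#'   lists replacing the default grid.
#' @return object of class `model_zoo`.
#' @export
model_zoo <- function(methods = c("ols", "ridge", "lasso", "elastic_net",
                                  "svr_linear", "svr_rbf", "gpr", "tree",
                                  "random_forest", "xgboost"),
                      grids = NULL) {
  learners <- bv_learners()
  unknown <- setdiff(methods, names(learners))
  if (length(unknown)) {
    bv_stop("bonevar_config_error", "unknown method(s): %s",
            paste(unknown, collapse = ", "))
  }
  if (length(methods) == 0L) {
    bv_stop("bonevar_config_error", "model zoo must contain at least one method")
  }
  zoo <- lapply(methods, function(m) {
    l <- learners[[m]]
    if (!is.null(grids[[m]])) l$grid <- grids[[m]]
    l
  })
  names(zoo) <- methods
  structure(zoo, class = "model_zoo")
}

# Exact ridge regression via SVD on the (already standardised, hence
# centred) design: coef(lambda) = V diag(d / (d^2 + lambda)) U' (y - ybar).
# One decomposition serves every lambda in the grid, which keeps the inner
# CV loop cheap; handles p > n.
ridge_solve <- function(x, y, lambdas) {
  sv <- svd(x)
  ybar <- mean(y)
  duty <- sv$d * as.numeric(crossprod(sv$u, y - ybar))
  m <- duty / outer(sv$d^2, lambdas, `+`)
  list(beta = sv$v %*% m, intercept = ybar, lambdas = lambdas)
}

ridge_learner <- function(lambdas) {
  lambdas <- sort(lambdas)
  list(
    grid = lapply(lambdas, function(l) list(lambda = l)),
    fit = function(x, y, params, seed) ridge_solve(x, y, params$lambda),
    predict = function(model, x)
      as.numeric(x %*% model$beta + model$intercept),
    path_fit = function(x, y, grid, seed)
      ridge_solve(x, y, vapply(grid, `[[`, numeric(1), "lambda")),
    path_predict = function(model, x, grid)
      x %*% model$beta + rep(model$intercept, each = nrow(x)))
}

# Penalised linear learner over a lambda grid. The whole regularisation
# path is fitted in one glmnet call per fold (`path_*` entries), which the
# inner-CV loop exploits to score every lambda at once.
glmnet_learner <- function(alpha, lambdas) {
  lambdas <- sort(lambdas, decreasing = TRUE)
  list(
    grid = lapply(lambdas, function(l) list(lambda = l, alpha = alpha)),
    fit = function(x, y, params, seed) {
      m <- glmnet::glmnet(x, y, alpha = params$alpha, lambda = lambdas)
      attr(m, "bv_lambda") <- params$lambda
      m
    },
    predict = function(model, x)
      as.numeric(stats::predict(model, x, s = attr(model, "bv_lambda"))),
    path_fit = function(x, y, grid, seed)
      glmnet::glmnet(x, y, alpha = alpha, lambda = lambdas),
    path_predict = function(model, x, grid) {
      pr <- stats::predict(model, x, s = vapply(grid, `[[`, numeric(1), "lambda"))
      matrix(pr, nrow = nrow(x))
    })
}

# Learner registry. Each learner: default grid, fit(x, y, params, seed) and
# predict(model, x); x is already standardised. Optional path_fit /
# path_predict score a whole grid with one fit per fold.
bv_learners <- function() {
  list(
    ols = list(
      grid = list(list()),
      fit = function(x, y, params, seed) {
        df <- data.frame(y = y, x)
        suppressWarnings(stats::lm(y ~ ., data = df))
      },
      predict = function(model, x) {
        suppressWarnings(unname(stats::predict(model, data.frame(x))))
      }),
    ridge = ridge_learner(lambdas = 10^seq(-1, 3, length.out = 5)),
    lasso = glmnet_learner(alpha = 1, lambdas = 10^seq(1, -3, length.out = 5)),
    elastic_net = glmnet_learner(alpha = 0.5, lambdas = 10^seq(1, -3, length.out = 5)),
    svr_linear = list(
      grid = lapply(2^c(-2, 0, 2, 4), function(C) list(cost = C)),
      fit = function(x, y, params, seed)
        e1071::svm(x, y, kernel = "linear", cost = params$cost,
                   epsilon = 0.1, scale = FALSE),
      predict = function(model, x) as.numeric(stats::predict(model, x))),
    svr_rbf = list(
      grid = {
        g <- expand.grid(cost = 2^c(0, 2, 4), gamma = 2^c(-4, -2))
        lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
      },
      fit = function(x, y, params, seed)
        e1071::svm(x, y, kernel = "radial", cost = params$cost,
                   gamma = params$gamma, epsilon = 0.1, scale = FALSE),
      predict = function(model, x) as.numeric(stats::predict(model, x))),
    gpr = list(
      grid = lapply(2^c(-4, -2, 0), function(s) list(sigma = s)),
      fit = function(x, y, params, seed)
        withr::with_seed(seed, kernlab::gausspr(
          x, y, kernel = "rbfdot", kpar = list(sigma = params$sigma),
          scaled = FALSE, var = 0.01)),
      predict = function(model, x) as.numeric(kernlab::predict(model, x))),
    tree = list(
      grid = lapply(c(3L, 5L, 30L), function(d) list(maxdepth = d)),
      fit = function(x, y, params, seed) {
        df <- data.frame(y = y, x)
        rpart::rpart(y ~ ., data = df, method = "anova",
                     control = rpart::rpart.control(
                       maxdepth = params$maxdepth, minsplit = 5L,
                       cp = 0.01, xval = 0L))
      },
      predict = function(model, x) unname(stats::predict(model, data.frame(x)))),
    random_forest = list(
      grid = list(list(num.trees = 200L)),
      fit = function(x, y, params, seed)
        ranger::ranger(x = x, y = y, num.trees = params$num.trees,
                       seed = seed, num.threads = 1L),
      predict = function(model, x)
        stats::predict(model, data = x, num.threads = 1L)$predictions),
    xgboost = list(
      grid = list(list(nrounds = 100L, max_depth = 3L, eta = 0.1)),
      fit = function(x, y, params, seed)
        xgboost::xgboost(x, y, objective = "reg:squarederror",
                         nrounds = params$nrounds,
                         max_depth = params$max_depth,
                         learning_rate = params$eta,
                         verbosity = 0L, nthreads = 1L, seed = seed),
      predict = function(model, x) as.numeric(stats::predict(model, x)))
  )
}

#' Sub-datasets by resampling one measurement per material
#'
#' Each sub-dataset keeps the shared feature table and draws, independently
#' and uniformly, exactly one of each material's repeated measurements as
#' that material's response. Materials with a single measurement therefore
#' carry the same response in every sub-dataset.
#'
#' @param dataset a [material_dataset()].
#' @param n_subdatasets number of sub-datasets (>= 1).
#' @param seed integer seed; draws are deterministic given it.
#' @param feature_table optional shared [feature_table()] attached to every
#'   sub-dataset (required downstream by [double_cross_validate()]).
#' @return list of `sub_dataset` objects, each with `responses` (named
#'   numeric), `chosen_index` (which measurement was drawn) and
#'   `feature_table`.
#' @export
generate_subdatasets <- function(dataset, n_subdatasets, seed,
                                 feature_table = NULL) {
  if (length(dataset$samples) == 0L) {
    bv_stop("bonevar_input_error", "dataset has no materials")
  }
  if (n_subdatasets < 1L) {
    bv_stop("bonevar_input_error", "n_subdatasets must be >= 1")
  }
  ids <- material_ids(dataset)
  counts <- summarize_measurements(dataset)
  idx <- withr::with_seed(seed, {
    vapply(seq_len(n_subdatasets), function(s) {
      vapply(counts, function(n) sample.int(n, 1L), integer(1))
    }, integer(length(ids)))
  })
  idx <- matrix(idx, nrow = length(ids))
  lapply(seq_len(n_subdatasets), function(s) {
    chosen <- idx[, s]
    responses <- vapply(seq_along(ids), function(i) {
      dataset$samples[[i]]$measurements[[chosen[i]]]
    }, numeric(1))
    names(responses) <- ids
    structure(list(feature_table = feature_table,
                   responses = responses,
                   chosen_index = stats::setNames(chosen, ids)),
              class = "sub_dataset")
  })
}

# r2 in coefficient-of-determination form (can be negative)
r2_score <- function(observed, predicted) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

# Inner-CV scores for every grid point of one learner: r2 of pooled
# out-of-fold predictions. One standardisation per fold, shared by all
# grid points; path learners additionally share one fit per fold.
inner_cv_scores <- function(x, y, learner, fold_id, seed) {
  n_grid <- length(learner$grid)
  oof <- matrix(NA_real_, length(y), n_grid)
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    st <- standardize_fit(x[tr, , drop = FALSE])
    xtr <- standardize_apply(x[tr, , drop = FALSE], st)
    xte <- standardize_apply(x[!tr, , drop = FALSE], st)
    if (!is.null(learner$path_fit)) {
      model <- learner$path_fit(xtr, y[tr], learner$grid,
                                seed = derive_seed(seed, f))
      oof[!tr, ] <- learner$path_predict(model, xte, learner$grid)
    } else {
      for (gi in seq_len(n_grid)) {
        model <- learner$fit(xtr, y[tr], learner$grid[[gi]],
                             seed = derive_seed(seed, f))
        oof[!tr, gi] <- learner$predict(model, xte)
      }
    }
  }
  apply(oof, 2, function(p) r2_score(y, p))
}

#' Select the best learner for one sub-dataset and fit it
#'
#' Every method/hyperparameter combination in the zoo is scored by inner
#' cross-validated r-squared (out-of-fold predictions pooled over the inner
#' folds, on features standardised per training fold); the maximiser is
#' refitted on all rows and returned. Ties break towards the first method
#' in zoo order.
#'
#' @param sub a `sub_dataset` with a non-NULL feature table.
#' @param zoo a [model_zoo()].
#' @param inner_folds number of inner CV folds.
#' @param seed integer seed (fold shuffle and stochastic learners).
#' @return object of class `bv_model` with elements `method`, `params`,
#'   `inner_score`, the fitted `fit`, and the standardisation statistics;
#'   use [predict()] with a raw feature matrix.
#' @export
select_and_fit <- function(sub, zoo, inner_folds = 5L, seed = 1L) {
  stopifnot(inherits(sub, "sub_dataset"), inherits(zoo, "model_zoo"))
  if (is.null(sub$feature_table)) {
    bv_stop("bonevar_input_error", "sub-dataset carries no feature table")
  }
  x <- sub$feature_table$matrix
  y <- unname(sub$responses)
  if (nrow(x) < inner_folds) {
    bv_stop("bonevar_fold_error",
            "%d materials cannot be split into %d inner folds", nrow(x), inner_folds)
  }
  if (stats::var(y) == 0) {
    bv_stop("bonevar_degenerate_target_error", "response has zero variance")
  }
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(inner_folds), nrow(x))))
  best <- list(method = names(zoo)[1L], params = zoo[[1L]]$grid[[1L]],
               inner_score = -Inf)
  for (m in names(zoo)) {
    learner <- zoo[[m]]
    scores <- inner_cv_scores(x, y, learner, fold_id,
                              seed = derive_seed(seed, match(m, names(zoo))))
    scores[!is.finite(scores)] <- -Inf
    for (gi in seq_along(scores)) {
      if (scores[gi] > best$inner_score) {
        best <- list(method = m, params = learner$grid[[gi]],
                     inner_score = scores[gi])
      }
    }
  }
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  fit <- zoo[[best$method]]$fit(xs, y, best$params, seed = derive_seed(seed, 0L))
  structure(list(method = best$method, params = best$params,
                 inner_score = best$inner_score, fit = fit, st = st,
                 learner = zoo[[best$method]]),
            class = "bv_model")
}

#' @export
predict.bv_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$matrix else newdata
  object$learner$predict(object$fit, standardize_apply(x, object$st))
}

#' Double (nested) cross-validation over one sub-dataset
#'
#' Materials are shuffled into `outer_folds` folds. For each outer fold,
#' [select_and_fit()] runs on the remaining materials only — so the inner
#' method/hyperparameter selection never sees the held-out rows — and the
#' refitted winner predicts the held-out fold. Every material receives
#' exactly one out-of-fold estimate; one model is fitted per outer fold.
#'
#' @inheritParams select_and_fit
#' @param outer_folds number of outer folds.
#' @return list with `estimates` (named numeric, one per material) and
#'   `chosen_methods` (character, one per outer fold).
#' @export
double_cross_validate <- function(sub, zoo, inner_folds = 5L,
                                  outer_folds = 10L, seed = 1L) {
  stopifnot(inherits(sub, "sub_dataset"))
  n <- length(sub$responses)
  if (n < outer_folds) {
    bv_stop("bonevar_fold_error",
            "%d materials cannot be split into %d outer folds", n, outer_folds)
  }
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(outer_folds), n)))
  estimates <- rep(NA_real_, n)
  names(estimates) <- names(sub$responses)
  chosen <- character(outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- fold_id != f
    sub_tr <- structure(list(
      feature_table = feature_table(
        sub$feature_table$material_ids[tr],
        sub$feature_table$matrix[tr, , drop = FALSE]),
      responses = sub$responses[tr],
      chosen_index = sub$chosen_index[tr]), class = "sub_dataset")
    model <- select_and_fit(sub_tr, zoo, inner_folds = inner_folds,
                            seed = derive_seed(seed, f))
    chosen[f] <- model$method
    estimates[!tr] <- predict(model, sub$feature_table$matrix[!tr, , drop = FALSE])
  }
  list(estimates = estimates, chosen_methods = chosen)
}

#' Ensemble prediction over resampled sub-datasets
#'
#' The full variability-prediction pipeline for one feature combination:
#' assemble the shared feature table (imputing any missing block cells),
#' draw `n_subdatasets` sub-datasets, run [double_cross_validate()] on each
#' with a derived per-sub-dataset seed, and collect, per material, the
#' vector of `n_subdatasets` out-of-fold estimates — the sample from the
#' predictive distribution of that material's response.
#'
#' @param dataset a [material_dataset()].
#' @param combo a [method_combo()].
#' @param zoo a [model_zoo()].
#' @param n_subdatasets number of sub-datasets/models per material.
#' @param inner_folds,outer_folds nested-CV fold counts.
#' @param seed root seed; all sub-dataset draws and fold shuffles derive
#'   from it.
#' @param ftir_bands,xrd_bands,lbp_normalize passed to
#'   [assemble_feature_matrix()].
#' @param impute_components components for [impute_missing()] when the
#'   assembled table has missing cells.
#' @return object of class `ensemble_prediction`: `estimates` matrix
#'   (materials x sub-datasets), `chosen_methods` matrix (sub-datasets x
#'   outer folds), `n_models`, `combo_label`, `feature_table`.
#' @export
predict_ensemble <- function(dataset, combo, zoo,
                             n_subdatasets = 100L, inner_folds = 5L,
                             outer_folds = 10L, seed = 1L,
                             ftir_bands = NULL, xrd_bands = NULL,
                             lbp_normalize = TRUE, impute_components = 1L) {
  ft <- assemble_feature_matrix(dataset, combo, ftir_bands = ftir_bands,
                                xrd_bands = xrd_bands,
                                lbp_normalize = lbp_normalize)
  if (anyNA(ft$matrix)) {
    ft <- impute_missing(ft, n_components = impute_components,
                         seed = derive_seed(seed, 999983L))
  }
  subs <- generate_subdatasets(dataset, n_subdatasets, seed = seed,
                               feature_table = ft)
  ids <- material_ids(dataset)
  estimates <- matrix(NA_real_, length(ids), n_subdatasets,
                      dimnames = list(ids, NULL))
  chosen <- matrix(NA_character_, n_subdatasets, outer_folds)
  for (s in seq_len(n_subdatasets)) {
    dcv <- double_cross_validate(subs[[s]], zoo, inner_folds = inner_folds,
                                 outer_folds = outer_folds,
                                 seed = derive_seed(seed, s))
    estimates[, s] <- dcv$estimates[ids]
    chosen[s, ] <- dcv$chosen_methods
  }
  structure(list(estimates = estimates, chosen_methods = chosen,
                 n_models = n_subdatasets * outer_folds,
                 combo_label = combo$label, feature_table = ft, seed = seed),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> combo %s: %d materials x %d estimates (%d models)\n",
              x$combo_label, nrow(x$estimates), ncol(x$estimates), x$n_models))
  tab <- sort(table(x$chosen_methods), decreasing = TRUE)
  cat("  chosen methods:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
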