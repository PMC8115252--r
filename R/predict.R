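#' Configuration of the amplitude prediction model
#'
#' Settings for the leave-one-out cross-validated linear support vector
#' regression: epsilon-insensitive loss with ridge (L2) regularisation,
#' regularisation strength selected from `c_grid` by an inner leave-one-out
#' grid search minimising mean squared error (ties broken toward the
#' smallest C, i.e. the strongest regularisation).
#'
#' @param epsilon Epsilon-insensitive tube half-width (default 0.1).
#' @param c_grid Ascending vector of positive regularisation strengths
#'   (default `c(0.001, 0.01, 0.1, 1)`).
#' @param standardize_features Z-score features on training-fold statistics
#'   (default TRUE).
#' @param shuffle_mode For permutation tests: `"raw"` shuffles the response
#'   before confound adjustment (the null then preserves the confound
#'   structure); `"adjusted"` shuffles after adjustment.
#' @return List of class `prediction_config`.
#' @export
prediction_config <- function(epsilon = 0.1, c_grid = c(0.001, 0.01, 0.1, 1),
                              standardize_features = TRUE,
                              shuffle_mode = c("raw", "adjusted")) {
  if (length(c_grid) < 1L || any(c_grid <= 0) || is.unsorted(c_grid)) {
    stop("c_grid must be a nonempty ascending vector of positive reals",
         call. = FALSE)
  }
  structure(list(epsilon = epsilon, c_grid = c_grid,
                 standardize_features = standardize_features,
                 shuffle_mode = match.arg(shuffle_mode)),
            class = "prediction_config")
}

# Residualize columns of A on confounds Z (plus intercept) using
# coefficients estimated from training rows only; returns residuals for all
# rows. Z may be NULL/zero-column, in which case adjustment is training-mean
# removal.
residualize_on <- function(A, Z, train_idx) {
  A <- as.matrix(A)
  X <- if (is.null(Z) || ncol(as.matrix(Z)) == 0L) {
    matrix(1, nrow(A), 1)
  } else {
    cbind(1, as.matrix(Z))
  }
  Xt <- X[train_idx, , drop = FALSE]
  if (qr(Xt)$rank < ncol(Xt)) {
    stop("confound matrix is rank deficient on a training fold", call. = FALSE)
  }
  B <- qr.coef(qr(Xt), A[train_idx, , drop = FALSE])
  A - X %*% B
}

#' Cross-validated confound regression
#'
#' For each fold, each feature column and the response are regressed on
#' their confounds (plus intercept) using training rows only; residuals for
#' both training and held-out rows are computed with the training
#' coefficients, so held-out rows never influence the adjustment.
#'
#' @param X n x p feature matrix.
#' @param y Length-n response.
#' @param conf_X Confound matrix for the features (or NULL for mean
#'   removal).
#' @param conf_y Confound matrix for the response (or NULL).
#' @param folds List of held-out index vectors (default: leave-one-out).
#' @return List with one element per fold: `train`, `test` (index vectors),
#'   `X_adj`, `y_adj` (full-length adjusted copies computed with that fold's
#'   training coefficients).
#' @export
cv_confound_regress <- function(X, y, conf_X = NULL, conf_y = NULL,
                                folds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(folds)) folds <- as.list(seq_len(n))
  lapply(folds, function(test_idx) {
    train_idx <- setdiff(seq_len(n), test_idx)
    list(train = train_idx, test = test_idx,
         X_adj = residualize_on(X, conf_X, train_idx),
         y_adj = as.numeric(residualize_on(matrix(y), conf_y, train_idx)))
  })
}

# Fit a linear epsilon-insensitive SVR and return its linear weights.
# With strong regularisation the optimum can have no support vectors (all
# residuals strictly inside the tube at w = 0); any intercept keeping every
# point in the tube is then optimal and we take the midrange.
svr_fit <- function(X, y, cost, epsilon) {
  m <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                  cost = cost, epsilon = epsilon, scale = FALSE,
                  fitted = FALSE)
  if (m$tot.nSV == 0L) {
    return(list(w = rep(0, ncol(X)), b = (min(y) + max(y)) / 2, model = m))
  }
  w <- as.numeric(t(m$coefs) %*% m$SV)
  list(w = w, b = -m$rho, model = m)
}

svr_predict <- function(fit, X) as.numeric(as.matrix(X) %*% fit$w + fit$b)

# Standardize columns of X by training-row statistics; zero-variance
# columns map to 0.
scale_by_train <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  s <- apply(X[train_idx, , drop = FALSE], 2, sd)
  s[s == 0] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, s, `/`), mu = mu, sd = s)
}

# Inner LOO grid search over C on (already adjusted/scaled) training data.
# Returns the MSE-minimising C; ties break to the smallest (grid is
# ascending).
select_c <- function(X, y, config) {
  if (length(config$c_grid) == 1L) return(config$c_grid)
  n <- nrow(X)
  mse <- vapply(config$c_grid, function(C) {
    err <- vapply(seq_len(n), function(i) {
      f <- svr_fit(X[-i, , drop = FALSE], y[-i], C, config$epsilon)
      y[i] - svr_predict(f, X[i, , drop = FALSE])
    }, numeric(1))
    mean(err^2)
  }, numeric(1))
  config$c_grid[which.min(mse)]
}

#' Leave-one-out cross-validated SVR prediction
#'
#' Outer leave-one-out over subjects. Within each training fold the
#' features and response are confound-adjusted with training-only
#' coefficients ([cv_confound_regress()]), features are z-scored on training
#' statistics, the regularisation strength C is chosen by an inner
#' leave-one-out grid search minimising mean squared error, a linear
#' epsilon-insensitive SVR is fitted, and the held-out subject is predicted
#' from its adjusted, training-scaled features.
#'
#' @inheritParams cv_confound_regress
#' @param config A [prediction_config()].
#' @return Object of class `nox_prediction`: tibble `predictions`
#'   (`subject`, `y_adj`, `y_pred`, `fold_c`), `metrics` tibble
#'   (`r2`, `rmse`, `spearman`), and the `config`.
#' @export
loocv_svr <- function(X, y, conf_X = NULL, conf_y = NULL,
                      config = prediction_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  folds <- cv_confound_regress(X, y, conf_X, conf_y)
  y_adj <- numeric(n)
  y_pred <- numeric(n)
  fold_c <- numeric(n)
  for (f in folds) {
    i <- f$test
    Xa <- f$X_adj
    ya <- f$y_adj
    if (sd(ya[f$train]) == 0) {
      stop("adjusted response is constant in a training fold", call. = FALSE)
    }
    if (config$standardize_features) {
      Xa <- scale_by_train(Xa, f$train)$X
    }
    C <- select_c(Xa[f$train, , drop = FALSE], ya[f$train], config)
    fit <- svr_fit(Xa[f$train, , drop = FALSE], ya[f$train], C, config$epsilon)
    y_pred[i] <- svr_predict(fit, Xa[i, , drop = FALSE])
    y_adj[i] <- ya[i]
    fold_c[i] <- C
  }
  subj <- rownames(X) %||% as.character(seq_len(n))
  structure(list(
    predictions = tibble::tibble(subject = subj, y_adj = y_adj,
                                 y_pred = y_pred, fold_c = fold_c),
    metrics = prediction_metrics(y_adj, y_pred),
    config = config), class = "nox_prediction")
}

#' Prediction performance metrics
#'
#' Sums-of-squares coefficient of determination
#' `R^2 = 1 - SSres / SStot` (can be negative and is reported as-is), root
#' mean squared error, and Spearman's rank correlation (average ranks for
#' ties).
#'
#' @param y_obs,y_pred Equal-length numeric vectors; `y_obs` nonconstant.
#' @return Tibble with columns `r2`, `rmse`, `spearman`.
#' @export
prediction_metrics <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (sd(y_obs) == 0) stop("observed response is constant", call. = FALSE)
  ssres <- sum((y_obs - y_pred)^2)
  sstot <- sum((y_obs - mean(y_obs))^2)
  # Spearman is undefined for constant predictions; report NA quietly
  sp <- if (sd(y_pred) == 0) NA_real_ else
    cor(y_obs, y_pred, method = "spearman")
  tibble::tibble(
    r2 = 1 - ssres / sstot,
    rmse = sqrt(mean((y_obs - y_pred)^2)),
    spearman = sp)
}

#' Full-pipeline permutation test of prediction performance
#'
#' Each permutation shuffles the response (by default the raw response,
#' before any confound adjustment) and reruns the entire prediction
#' pipeline — confound regression, scaling, inner grid search, SVR — so the
#' null respects every data-dependent choice. One-tailed Monte-Carlo
#' p-values: larger-is-better for R^2 and Spearman, smaller-is-better for
#' RMSE; `p = (1 + c) / (1 + B)`.
#'
#' @inheritParams loocv_svr
#' @param n_perm Number of permutations B.
#' @param seed Integer seed.
#' @return List of class `nox_perm_prediction` with elements `r2`, `rmse`,
#'   `spearman` (each a `perm_result`) and `observed` (the observed
#'   `nox_prediction`).
#' @export
perm_prediction_test <- function(X, y, conf_X = NULL, conf_y = NULL,
                                 config = prediction_config(),
                                 n_perm = 1000, seed = 1L) {
  obs <- loocv_svr(X, y, conf_X, conf_y, config)
  # "adjusted" mode shuffles the full-sample adjusted response and skips
  # per-permutation re-adjustment; "raw" (default) shuffles the raw response
  # and reruns the entire pipeline including confound regression.
  y_base <- if (config$shuffle_mode == "adjusted") {
    as.numeric(residualize_on(matrix(y), conf_y, seq_along(y)))
  } else y
  cy <- if (config$shuffle_mode == "adjusted") NULL else conf_y
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      res <- loocv_svr(X, sample(y_base), conf_X, cy, config)
      as.numeric(res$metrics[1, c("r2", "rmse", "spearman")])
    }, numeric(3))
  })
  eps <- 1e-12
  mk <- function(name, idx, better_high) {
    stat <- obs$metrics[[name]]
    null <- null_mat[idx, ]
    # a permutation with constant predictions has no Spearman value; count
    # it as exceeding (conservative)
    ge <- if (better_high) null >= stat - eps else null <= stat + eps
    c_exceed <- sum(ge | is.na(ge))
    new_perm_result(stat, null, (1 + c_exceed) / (1 + n_perm), "one",
                    "monte_carlo", n_perm, seed)
  }
  structure(list(r2 = mk("r2", 1, TRUE), rmse = mk("rmse", 2, FALSE),
                 spearman = mk("spearman", 3, TRUE), observed = obs),
            class = "nox_perm_prediction")
}

#' Univariate predictor screens
#'
#' For each feature alone: the confound-adjusted Pearson correlation with
#' the (adjusted) response, and the out-of-fold R^2 of a single-feature
#' LOO-CV SVR.
#'
#' @inheritParams loocv_svr
#' @return Tibble with columns `feature`, `pearson_r`, `single_feature_r2`.
#' @export
univariate_screens <- function(X, y, conf_X = NULL, conf_y = NULL,
                               config = prediction_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  all_idx <- seq_len(n)
  Xa <- residualize_on(X, conf_X, all_idx)
  ya <- as.numeric(residualize_on(matrix(y), conf_y, all_idx))
  nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  purrr::map_dfr(seq_len(ncol(X)), function(j) {
    fit <- loocv_svr(X[, j, drop = FALSE], y, conf_X, conf_y, config)
    tibble::tibble(feature = nm[j],
                   pearson_r = cor(Xa[, j], ya),
                   single_feature_r2 = fit$metrics$r2)
  })
}

#' Apply a trained amplitude prediction model to a new cohort
#'
#' Fits the SVR once on the full training set (confound-adjusted and
#' standardized on the whole training sample, C chosen by leave-one-out grid
#' search), then scores the target cohort. Target features are adjusted
#' either with the target sample's own confound regression
#' (`"within_target"`, the default — predictors and confounds extracted in
#' the same manner as in training) or with the training confound
#' coefficients (`"train_coefs"`).
#'
#' @param train List with `X`, `y`, and optional `conf_X`, `conf_y`.
#' @param new_X Target feature matrix (same columns as `train$X`).
#' @param new_conf_X Target confound matrix (required for
#'   `"within_target"`).
#' @param config A [prediction_config()].
#' @param adjust_mode `"within_target"` or `"train_coefs"`.
#' @return Tibble with columns `subject`, `y_pred`.
#' @export
apply_model <- function(train, new_X, new_conf_X = NULL,
                        config = prediction_config(),
                        adjust_mode = c("within_target", "train_coefs")) {
  adjust_mode <- match.arg(adjust_mode)
  Xtr <- as.matrix(train$X)
  new_X <- as.matrix(new_X)
  if (ncol(new_X) != ncol(Xtr)) {
    stop("feature columns do not align between training and target",
         call. = FALSE)
  }
  n_tr <- nrow(Xtr)
  idx <- seq_len(n_tr)
  Xa <- residualize_on(Xtr, train$conf_X, idx)
  ya <- as.numeric(residualize_on(matrix(train$y), train$conf_y, idx))
  sc <- scale_by_train(Xa, idx)
  Xs <- if (config$standardize_features) sc$X else Xa
  C <- select_c(Xs, ya, config)
  fit <- svr_fit(Xs, ya, C, config$epsilon)
  new_adj <- if (adjust_mode == "within_target") {
    residualize_on(new_X, new_conf_X, seq_len(nrow(new_X)))
  } else {
    Zc <- if (is.null(train$conf_X)) NULL else as.matrix(new_conf_X)
    # reuse training confound coefficients
    Xc <- if (is.null(train$conf_X)) matrix(1, n_tr, 1) else
      cbind(1, as.matrix(train$conf_X))
    B <- qr.coef(qr(Xc), Xtr)
    Xc_new <- if (is.null(train$conf_X)) matrix(1, nrow(new_X), 1) else
      cbind(1, Zc)
    new_X - Xc_new %*% B
  }
  new_s <- if (config$standardize_features) {
    sweep(sweep(new_adj, 2, sc$mu), 2, sc$sd, `/`)
  } else new_adj
  tibble::tibble(
    subject = rownames(new_X) %||% as.character(seq_len(nrow(new_X))),
    y_pred = svr_predict(fit, new_s))
}

#' @export
print.nox_prediction <- function(x, ...) {
  cat(sprintf("LOO-CV SVR prediction over %d subjects\n",
              nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.nox_prediction <- function(x, ...) x$predictions

#' @export
glance.nox_prediction <- function(x, ...) x$metrics

#' @export
tidy.nox_perm_prediction <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$r2), metric = "r2"),
    dplyr::mutate(tidy(x$rmse), metric = "rmse"),
    dplyr::mutate(tidy(x$spearman), metric = "spearman"))[
      , c("metric", "statistic", "p.value", "tails", "convention", "n_perm")]
}

#' Plot out-of-fold predictions against adjusted observations
#'
#' Scatter of predicted versus confound-adjusted observed amplitudes with
#' the identity line along which perfect predictions would lie.
#'
#' @param object A `nox_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nox_prediction <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$y_adj, y = .data$y_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(colour = "#2166ac", size = 2) +
    ggplot2::labs(
      x = "observed amplitude (confound-adjusted)",
      y = "predicted amplitude",
      title = sprintf("Out-of-fold prediction (R² = %.2f)",
                      object$metrics$r2)) +
    ggplot2::theme_minimal()
}
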