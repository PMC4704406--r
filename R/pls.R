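# NIPALS PLS1. X, y already centred/scaled. Returns weights W, x-loadings P,
# y-loadings q and scores T for up to K factors (stopping early if X is
# exhausted). For a single response the per-factor weight is closed-form
# (w = X'y / ||X'y||), so no inner iteration is needed.
.nipals_pls1 <- function(X, y, K) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, K); P <- matrix(0, p, K)
  q <- numeric(K); Tm <- matrix(0, n, K)
  Xd <- X; yd <- y
  k_eff <- 0L
  for (k in seq_len(K)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pk <- crossprod(Xd, t) / tt
    qk <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pk)
    yd <- yd - qk * t
    W[, k] <- w; P[, k] <- pk; q[k] <- qk; Tm[, k] <- t
    k_eff <- k
  }
  list(W = W[, seq_len(k_eff), drop = FALSE],
       P = P[, seq_len(k_eff), drop = FALSE],
       q = q[seq_len(k_eff)],
       scores = Tm[, seq_len(k_eff), drop = FALSE],
       k = k_eff)
}

# Collapsed regression vector on the scaled scale for k factors:
# B_k = W_k (P_k' W_k)^{-1} q_k.
.pls_coef <- function(fit, k) {
  W <- fit$W[, seq_len(k), drop = FALSE]
  P <- fit$P[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$q[seq_len(k)]))
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares with a single response: successive
#' extraction of weight/score/loading triplets with deflation of both
#' blocks. The collapsed coefficient vector on the autoscaled scale is
#' stored alongside the factor-wise decomposition, and the two prediction
#' routes agree to numerical precision.
#'
#' @param X Predictor matrix (raw absorbance rows, or already autoscaled if
#'   `scale = FALSE`).
#' @param y Response vector (original units, or scaled if `scale = FALSE`).
#' @param n_factors Number of latent factors to extract (>= 1).
#' @param scale If `TRUE` (default) X and y are autoscaled internally and
#'   the scaling record stored; set `FALSE` when passing pre-scaled data
#'   (an identity record is stored).
#' @return A `pls_model`: weights, loadings, y-loadings, scores,
#'   coefficients, scaling record, training column names.
#' @export
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X %*% c(1, -1, 0.5) + rnorm(20, 0, .1)
#' m <- fit_pls(X, drop(y), n_factors = 2)
#' head(predict(m, X))
fit_pls <- function(X, y, n_factors, scale = TRUE) {
  if (inherits(X, "absorbance_features")) X <- X$absorbance
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (n_factors < 1 || n_factors != round(n_factors)) {
    stop("n_factors must be a positive integer", call. = FALSE)
  }
  if (scale) {
    sc <- autoscale(X, y)
    Xs <- sc$X; ys <- sc$y; record <- sc$record
  } else {
    Xs <- X; ys <- y
    record <- structure(list(x_center = rep(0, ncol(X)),
                             x_scale = rep(1, ncol(X)),
                             keep = seq_len(ncol(X)), n_input_cols = ncol(X),
                             y_center = 0, y_scale = 1),
                        class = "scaling_record")
  }
  kmax <- min(nrow(Xs) - 1L, ncol(Xs))
  if (n_factors > kmax) {
    stop("n_factors = ", n_factors, " exceeds the achievable maximum ", kmax,
         call. = FALSE)
  }
  fit <- .nipals_pls1(Xs, ys, n_factors)
  if (fit$k < n_factors) {
    stop("X exhausted after ", fit$k, " factor(s); n_factors = ", n_factors,
         " exceeds the achievable maximum ", fit$k, call. = FALSE)
  }
  structure(list(n_factors = as.integer(n_factors),
                 x_weights = fit$W, x_loadings = fit$P, y_loadings = fit$q,
                 scores = fit$scores,
                 coefficients = .pls_coef(fit, n_factors),
                 record = record,
                 columns = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d factor(s), %d predictors\n",
              x$n_factors, length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS calibration model
#'
#' Applies the stored scaling record to new absorbance rows, multiplies by
#' the collapsed coefficient vector and back-transforms to original
#' response units.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix of raw predictor rows (same columns as training) or
#'   an `absorbance_features` object.
#' @param ... Unused.
#' @return Numeric vector of predictions in original response units.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "absorbance_features")) newdata <- newdata$absorbance
  newdata <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$columns)) {
    stop("newdata columns do not match the training wavenumbers",
         call. = FALSE)
  }
  Xs <- scale_features(object$record, newdata)
  unscale_response(object$record, drop(Xs %*% object$coefficients))
}

.make_folds <- function(groups, scheme = c("loso", "kfold"), k = 10,
                        seed = NULL) {
  scheme <- match.arg(scheme)
  ug <- unique(groups)
  if (scheme == "loso") {
    fold_of_group <- stats::setNames(seq_along(ug), ug)
  } else {
    k <- min(k, length(ug))
    if (!is.null(seed)) set.seed(as.integer(seed))
    fold_of_group <- stats::setNames(sample(rep(seq_len(k),
                                                length.out = length(ug))), ug)
  }
  unname(fold_of_group[as.character(groups)])
}

#' Cross-validate a PLS calibration over factor counts
#'
#' Leave-one-sample-out by default: both replicate spectra of a sample leave
#' the training set together, so replicate correlation cannot leak into the
#' validation error. Within every fold the autoscaling parameters are
#' re-estimated on the training rows only. Out-of-fold residuals are
#' reported in original response units for every candidate factor count,
#' together with PRESS(k) and RMSECV(k) = sqrt(PRESS(k)/n).
#'
#' @param X Predictor matrix (raw absorbance rows) or `absorbance_features`.
#' @param y Response vector in original units.
#' @param groups Sample identifier per row; rows sharing a group share a
#'   fold.
#' @param max_factors Largest factor count to evaluate (capped at what the
#'   smallest training fold can support).
#' @param scheme `"loso"` (leave-one-sample-out, default) or `"kfold"`.
#' @param k Number of folds for `scheme = "kfold"`.
#' @param seed Seed for the fold shuffle under `"kfold"`.
#' @return A `cv_trace`: residual matrix (n x K), prediction matrix, fold
#'   assignment, `press` and `rmsecv` vectors, `y`, `groups`.
#' @export
cross_validate <- function(X, y, groups, max_factors = 15,
                           scheme = c("loso", "kfold"), k = 10, seed = NULL) {
  if (inherits(X, "absorbance_features")) X <- X$absorbance
  X <- as.matrix(X); y <- as.numeric(y)
  scheme <- match.arg(scheme)
  if (length(groups) != nrow(X)) {
    stop("groups must cover all rows", call. = FALSE)
  }
  if (max_factors < 1) stop("max_factors must be >= 1", call. = FALSE)
  folds <- .make_folds(groups, scheme, k, seed)
  n <- nrow(X)
  fold_sizes <- table(folds)
  min_train <- n - max(fold_sizes)
  if (length(unique(groups[folds != folds[1]])) < 1 ||
      length(unique(folds)) < 2) {
    stop("cross-validation needs at least 2 folds", call. = FALSE)
  }
  for (f in unique(folds)) {
    if (length(unique(groups[folds != f])) < 2) {
      stop("a fold would leave fewer than 2 training groups", call. = FALSE)
    }
  }
  K <- min(max_factors, min_train - 1L, ncol(X))
  pred <- matrix(NA_real_, n, K)
  for (f in unique(folds)) {
    test <- folds == f
    sc <- suppressWarnings(autoscale(X[!test, , drop = FALSE], y[!test]))
    fit <- .nipals_pls1(sc$X, sc$y, K)
    Xs_test <- scale_features(sc$record, X[test, , drop = FALSE])
    for (kk in seq_len(K)) {
      kf <- min(kk, fit$k)
      b <- .pls_coef(fit, kf)
      pred[test, kk] <- unscale_response(sc$record, drop(Xs_test %*% b))
    }
  }
  resid <- y - pred
  press <- colSums(resid^2)
  structure(list(residuals = resid, predictions = pred, folds = folds,
                 press = press, rmsecv = sqrt(press / n),
                 y = y, groups = groups, scheme = scheme),
            class = "cv_trace")
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("<cv_trace> %d observations, %d folds (%s), factors 1..%d\n",
              length(x$y), length(unique(x$folds)), x$scheme,
              length(x$press)))
  cat("  RMSECV:", paste(sprintf("%.4g", x$rmsecv), collapse = " "), "\n")
  invisible(x)
}

#' Randomization comparison of two models' cross-validated residuals
#'
#' Tests whether two calibration models differ in predictive accuracy, in
#' the spirit of van der Voet: the statistic is the mean difference of
#' paired squared residuals, and its null distribution is generated by
#' random sign flips of those paired differences (each model equally likely
#' to have been the better one on every observation). Two-sided p-value
#' with the add-one (permutation) correction.
#'
#' @param resid_a,resid_b Paired cross-validated residual vectors (same
#'   observations, same order).
#' @param n_perm Number of sign-flip draws (>= 99).
#' @param seed Integer seed; fixed seed gives a deterministic p-value.
#' @return List with `statistic` (observed mean of `resid_a^2 - resid_b^2`),
#'   `p_value`, `n_perm`.
#' @export
randomization_model_comparison <- function(resid_a, resid_b, n_perm = 1000,
                                           seed = 1L) {
  if (length(resid_a) != length(resid_b)) {
    stop("residual vectors must have equal length", call. = FALSE)
  }
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  d <- resid_a^2 - resid_b^2
  n <- length(d)
  t_obs <- mean(d)
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  t_perm <- drop(signs %*% d) / n
  # tolerance keeps ties (e.g. the all-zero case) counted as exceedances
  hits <- sum(abs(t_perm) >= abs(t_obs) - 1e-12 * max(abs(t_obs), 1e-300))
  list(statistic = t_obs, p_value = (1 + hits) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}

#' Choose the factor count by minimum PRESS plus parsimony
#'
#' Finds the factor count minimising PRESS (ties broken toward fewer
#' factors), then scans k = 1 upward and returns the smallest k whose
#' cross-validated residuals are not significantly larger than those of the
#' minimum-PRESS model according to [randomization_model_comparison()].
#'
#' @param trace A `cv_trace` from [cross_validate()].
#' @param alpha Significance level of the comparison (default 0.10).
#' @param n_perm Sign-flip draws per comparison.
#' @param seed Integer seed.
#' @return A `factor_selection`: `k_min_press`, `chosen_k`, `p_values`
#'   (one per candidate k up to `k_min_press`), `alpha`, `n_perm`, `seed`.
#' @export
select_factors <- function(trace, alpha = 0.10, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(trace, "cv_trace"))
  K <- length(trace$press)
  k_star <- which.min(trace$press)
  p_values <- rep(NA_real_, K)
  p_values[k_star] <- 1
  chosen <- k_star
  for (kk in seq_len(k_star)) {
    if (kk == k_star) {
      p_values[kk] <- 1
    } else {
      cmp <- randomization_model_comparison(trace$residuals[, kk],
                                            trace$residuals[, k_star],
                                            n_perm = n_perm,
                                            seed = as.integer(seed) + kk)
      p_values[kk] <- cmp$p_value
    }
    if (p_values[kk] >= alpha) {
      chosen <- kk
      break
    }
  }
  structure(list(k_min_press = as.integer(k_star),
                 chosen_k = as.integer(chosen),
                 p_values = p_values, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "factor_selection")
}

#' @export
print.factor_selection <- function(x, ...) {
  cat(sprintf("<factor_selection> chosen k = %d (min-PRESS k = %d, alpha = %g)\n",
              x$chosen_k, x$k_min_press, x$alpha))
  invisible(x)
}
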