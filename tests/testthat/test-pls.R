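test_that("PLS with one predictor or full rank collapses to least squares", {
  set.seed(1)
  # single scaled column, one factor: slope equals the OLS slope
  x <- drop(scale(rnorm(20)))
  y <- drop(scale(2 * x + rnorm(20, 0, 0.2)))
  m1 <- fit_pls(cbind(x1 = x), y, 1, scale = FALSE)
  expect_equal(unname(m1$coefficients), sum(x * y) / sum(x^2),
               tolerance = 1e-10)
  # full-rank X with as many factors as columns: OLS via normal equations
  X <- matrix(rnorm(40), 10, 4)
  yy <- rnorm(10)
  Xs <- scale(X); ys <- drop(scale(yy))
  m4 <- fit_pls(Xs, ys, 4, scale = FALSE)
  b_ols <- solve(crossprod(Xs), crossprod(Xs, ys))
  expect_equal(drop(Xs %*% m4$coefficients), drop(Xs %*% b_ols),
               tolerance = 1e-8)
})

test_that("NIPALS predictions match the Krylov-subspace oracle", {
  for (seed in 1:20) {
    inst <- scaled_instance(20, 50, seed)
    k <- 1 + (seed %% 5)
    m <- fit_pls(inst$X, inst$y, k, scale = FALSE)
    pred <- drop(inst$X %*% m$coefficients)
    expect_lt(max(abs(pred - oracle_pls_krylov(inst$X, inst$y, k))), 1e-8)
  }
})

test_that("scores are orthogonal and in-sample fit improves with factors", {
  inst <- scaled_instance(30, 40, seed = 5)
  m <- fit_pls(inst$X, inst$y, 8, scale = FALSE)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  rss <- sapply(1:8, function(k) {
    mk <- fit_pls(inst$X, inst$y, k, scale = FALSE)
    sum((inst$y - drop(inst$X %*% mk$coefficients))^2)
  })
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("prediction applies the scaling record and back-transform", {
  set.seed(11)
  X <- matrix(rnorm(60, 10, 2), 20, 3, dimnames = list(NULL, paste0("w", 1:3)))
  y <- 100 + 5 * X[, 1] + rnorm(20)
  m <- fit_pls(X, y, 2)
  # training matrix reproduces in-sample fitted values in original units
  fitted <- predict(m, X)
  expect_equal(length(fitted), 20L)
  expect_gt(cor(fitted, y), 0.9)
  # a row at the column means predicts the response mean
  mu_row <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict(m, mu_row)), mean(y), tolerance = 1e-10)
  # held-out agreement with the oracle, in original units
  Xn <- matrix(rnorm(15, 10, 2), 5, 3, dimnames = list(NULL, colnames(X)))
  sc <- autoscale(X, y)
  o <- oracle_pls_krylov(sc$X, sc$y, 2, scale_features(sc$record, Xn))
  expect_equal(unname(predict(m, Xn)),
               unscale_response(sc$record, o), tolerance = 1e-8)
  bad <- Xn; colnames(bad) <- c("a", "b", "c")
  expect_error(predict(m, bad), "do not match")
  expect_error(fit_pls(X, y, 25), "achievable maximum")
})

test_that("grouped cross-validation learns a noiseless response exactly", {
  set.seed(2)
  n_samp <- 12
  # rank-3 predictor block with a noiseless linear response: three factors
  # suffice for exact out-of-fold prediction
  scores <- matrix(rnorm(2 * n_samp * 3), 2 * n_samp, 3)
  loadings <- matrix(rnorm(3 * 30), 3, 30)
  X <- scores %*% loadings
  groups <- rep(sprintf("S%02d", 1:n_samp), each = 2)
  y <- drop(scores %*% c(1, -2, 0.5))
  tr <- cross_validate(X, y, groups, max_factors = 6)
  expect_lt(min(tr$rmsecv), 1e-8)
  # PRESS(k) = n * RMSECV(k)^2 exactly, replicates share folds
  expect_equal(tr$press, length(y) * tr$rmsecv^2, tolerance = 1e-12)
  expect_true(all(tapply(tr$folds, groups, function(f) length(unique(f))) == 1))
})

test_that("cross-validation on pure noise cannot beat the response spread", {
  ratios <- sapply(1:20, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(30 * 20), 30, 20)
    y <- rnorm(30)
    groups <- sprintf("S%02d", 1:30)
    tr <- cross_validate(X, y, groups, max_factors = 8)
    tr$rmsecv / sd(y)
  })
  # in distribution: mean RMSECV at least the response sd, and more factors
  # only overfit harder
  expect_gt(mean(ratios[1, ]), 0.95)
  expect_gt(mean(ratios[8, ]), mean(ratios[1, ]))
})

test_that("randomization comparison is exact on ties and scale-equivariant", {
  r <- rnorm(40)
  same <- randomization_model_comparison(r, r, n_perm = 199, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- rnorm(40); b <- rnorm(40, 0, 1.3)
  p1 <- randomization_model_comparison(a, b, n_perm = 499, seed = 7)$p_value
  p2 <- randomization_model_comparison(5 * a, 5 * b, n_perm = 499,
                                       seed = 7)$p_value
  expect_identical(p1, p2)
  # two-sided statistic: relabelling the models gives the same p-value
  p3 <- randomization_model_comparison(b, a, n_perm = 499, seed = 7)$p_value
  expect_identical(p1, p3)
  expect_error(randomization_model_comparison(a, b[-1]), "equal length")
  expect_error(randomization_model_comparison(a, b, n_perm = 10), ">= 99")
})

test_that("factor selection returns the fewest statistically equivalent k", {
  fake_trace <- function(res) {
    structure(list(residuals = res, press = colSums(res^2),
                   rmsecv = sqrt(colSums(res^2) / nrow(res))),
              class = "cv_trace")
  }
  set.seed(3)
  n <- 40
  # PRESS minimised at k = 1: parsimony cannot go lower
  res <- cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 1), rnorm(n, 0, 1.5))
  sel <- select_factors(fake_trace(res), n_perm = 199, seed = 2)
  expect_identical(sel$k_min_press, 1L)
  expect_identical(sel$chosen_k, 1L)
  expect_equal(sel$p_values[1], 1)
  # k = 3 is the first candidate indistinguishable from k* = 6: columns 3-5
  # add small perturbations orthogonal to the base residuals, so their PRESS
  # is strictly larger than column 6 but the paired squared differences are
  # centred noise the sign-flip test cannot distinguish
  base <- rnorm(n, 0, 0.2)
  ortho <- function(s) {
    e <- rnorm(n)
    s * residuals(lm(e ~ base)) / sd(e)
  }
  res6 <- cbind(rnorm(n, 0, 3), rnorm(n, 0, 2.5),
                base + ortho(0.01), base + ortho(0.01),
                base + ortho(0.005), base)
  tr6 <- fake_trace(res6)
  sel6 <- select_factors(tr6, alpha = 0.10, n_perm = 499, seed = 4)
  expect_identical(sel6$k_min_press, 6L)
  expect_identical(sel6$chosen_k, 3L)
  # manual scan using the same p-values reproduces the choice
  manual <- which(sel6$p_values >= 0.10)[1]
  expect_identical(sel6$chosen_k, as.integer(manual))
  expect_true(sel6$chosen_k <= sel6$k_min_press)
})
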