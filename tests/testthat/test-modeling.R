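test_that("OLS tier fit recovers exact and closed-form solutions", {
  set.seed(1)
  n <- 60
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 + 1.5 * x$a - 0.5 * x$b
  f <- fit_glm(x, y)
  expect_equal(f$r2_in, 1)
  expect_equal(max(abs(y - f$fitted)), 0, tolerance = 1e-10)

  # orthonormal design (orthogonal to the intercept too): beta = X'y and
  # equal standard errors across predictors
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  colnames(q) <- c("u", "v", "w")
  y2 <- rnorm(n)
  f2 <- fit_glm(q, y2)
  cf <- tidy(f2)
  expect_equal(cf$estimate[-1], as.numeric(crossprod(q, y2)),
               tolerance = 1e-8)
  expect_lt(diff(range(cf$std_error[-1])) /
              mean(cf$std_error[-1]), 1e-6)
})

test_that("intercept-only fit has zero R2 and the definitional AIC", {
  set.seed(2)
  y <- rnorm(40, 10, 3)
  f <- fit_glm(NULL, y)
  expect_equal(f$r2_in, 0)
  n <- length(y)
  expect_equal(f$aic, n * log(var(y) * (n - 1) / n) + 4)
  expect_equal(f$fitted, rep(mean(y), n))
})

test_that("rank-deficient designs are reported with the offending column", {
  x <- data.frame(a = rnorm(30))
  x$b <- 2 * x$a
  expect_error(fit_glm(x, rnorm(30)), "rank-deficient.*b")
  expect_error(fit_glm(data.frame(a = rnorm(3), b = rnorm(3), c = rnorm(3)),
                       rnorm(3)), "n > p")
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  set.seed(3)
  # balanced tertiles: 10 subjects per tertile, 10 folds
  y <- rep(c(1, 10, 20), each = 10)
  folds <- make_folds(y, cv_scheme(n_repetitions = 3, n_folds = 10, seed = 4))
  for (fold in folds) {
    expect_setequal(unique(fold), 1:10)
    for (f in 1:10) {
      expect_equal(sum(fold == f), 3)
      expect_setequal(y[fold == f], c(1, 10, 20))  # one per tertile
    }
  }
  expect_error(make_folds(rnorm(5), cv_scheme(n_folds = 10)), "n_folds")
})

test_that("fold tertile proportions track the cohort within one subject", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(40:240, 1)
    y <- sample(0:60, n, replace = TRUE)
    cv <- cv_scheme(n_repetitions = 2, n_folds = 10, seed = seed)
    tert <- psdstack:::outcome_tertile(y)
    for (fold in make_folds(y, cv)) {
      expect_setequal(which(tabulate(fold) > 0), 1:10)
      expect_equal(sort(unlist(lapply(1:10, function(f) which(fold == f)))),
                   seq_len(n))
      for (f in 1:10) {
        for (tt in 1:3) {
          # count per fold within one subject of the proportional share
          expect_lte(abs(sum(tert[fold == f] == tt) - sum(tert == tt) / 10),
                     1)
        }
      }
    }
  }
})

test_that("LASSO collapses to the null model under an infinite penalty", {
  set.seed(5)
  x <- matrix(rnorm(100 * 8), 100, 8)
  y <- rnorm(100, 5)
  f <- fit_lasso(x, y, lambda = 1e9)
  expect_equal(f$n_predictors, 0)
  expect_equal(f$fitted, rep(mean(y), 100), tolerance = 1e-8)
  expect_equal(f$p_value, 1)
  expect_equal(f$r2_in, 0)
})

test_that("LASSO at zero penalty matches OLS on well-conditioned designs", {
  set.seed(6)
  n <- 200
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, letters[1:5]))
  y <- 1 + x %*% c(1, -2, 0.5, 0, 3) + rnorm(n)
  f_l <- fit_lasso(x, y, lambda = 0)
  f_g <- fit_glm(x, y)
  expect_equal(tidy(f_l)$estimate, tidy(f_g)$estimate, tolerance = 1e-6)
})

test_that("non-negative LASSO never returns a negative coefficient", {
  set.seed(7)
  n <- 150
  x <- matrix(rnorm(n * 10), n, 10)
  y <- x %*% c(2, -2, rep(0, 8)) + rnorm(n)
  f <- fit_lasso(x, y, nonnegative = TRUE, cv = cv_scheme(2, 5, seed = 1))
  expect_true(all(tidy(f)$estimate[-1] >= 0))
  # without the constraint the negative effect is picked up
  f2 <- fit_lasso(x, y, nonnegative = FALSE, cv = cv_scheme(2, 5, seed = 1))
  expect_lt(min(tidy(f2)$estimate[-1]), 0)
})

test_that("LASSO solutions satisfy the KKT conditions at the chosen penalty", {
  set.seed(8)
  n <- 120
  x <- matrix(rnorm(n * 12), n, 12)
  y <- as.numeric(x %*% c(1.5, -1, rep(0, 10)) + rnorm(n))
  f <- fit_lasso(x, y, cv = cv_scheme(2, 5, seed = 2))
  beta <- tidy(f)$estimate[-1]
  # KKT in glmnet's standardised coordinates:
  # |x_j' r| / n = lambda * sd(y)... on the original scale the condition is
  # |x_j_std' r| / n <= lambda, with equality (and matching sign) on the
  # active set
  xs <- scale(x, scale = apply(x, 2, function(v) {
    sqrt(mean((v - mean(v))^2))
  }))
  r <- y - f$fitted
  g <- as.numeric(crossprod(xs, r)) / n
  active <- which(beta != 0)
  expect_true(all(abs(g) <= f$lambda + 1e-6))
  if (length(active)) {
    expect_lt(max(abs(g[active] - f$lambda * sign(beta[active]))), 1e-6)
  }
})

test_that("out-of-sample R2 separates signal from noise and is reproducible", {
  set.seed(9)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4)
  y_signal <- as.numeric(1 + x %*% c(2, -1, 1, 0.5))
  cv <- cv_scheme(3, 10, seed = 7)
  expect_gt(out_of_sample_r2(x, y_signal, cv), 0.99)

  y_noise <- rnorm(n)
  r2_noise <- out_of_sample_r2(x, y_noise, cv)
  expect_lt(r2_noise, 0.05)
  expect_identical(out_of_sample_r2(x, y_noise, cv), r2_noise)
})

test_that("relative probability reproduces worked AIC comparisons", {
  expect_equal(relative_probability(774.91, 722.83), 4.91e-12,
               tolerance = 5e-3)
  expect_equal(relative_probability(771.07, 722.83), 3.35e-11,
               tolerance = 5e-3)
  expect_equal(relative_probability(722.83, 722.83), 1)
  expect_equal(relative_probability(100, 100), 1)
})

test_that("model comparison ranks by AIC and is shift/removal invariant", {
  set.seed(10)
  n <- 80
  x1 <- matrix(rnorm(n * 2), n, 2)
  x2 <- matrix(rnorm(n * 3), n, 3)
  y <- 1 + 2 * x1[, 1] + rnorm(n)
  f1 <- fit_glm(x1, y, name = "informative")
  f2 <- fit_glm(x2, y, name = "noise")
  f1b <- fit_glm(x1, y, name = "informative-copy")

  cmp <- compare_models(list(f1, f1b))
  expect_equal(cmp$delta_aic, c(0, 0))
  expect_equal(cmp$p_vs_best, c(1, 1))

  cmp3 <- compare_models(list(f1, f2, f1b))
  cmp2 <- compare_models(list(f1, f2))
  d3 <- with(as.data.frame(cmp3), aic[model == "noise"] -
               aic[model == "informative"])
  d2 <- with(as.data.frame(cmp2), aic[model == "noise"] -
               aic[model == "informative"])
  expect_equal(d3, d2)
  expect_equal(cmp3$model[1], "informative")

  f_other <- fit_glm(x1[1:40, ], y[1:40], name = "short")
  expect_error(compare_models(list(f1, f_other)), "identical subject set")
})

test_that("AIC comparison depends only on AIC differences", {
  set.seed(11)
  y <- rnorm(50)
  f1 <- fit_glm(matrix(rnorm(50), 50, 1), y, name = "m1")
  f2 <- fit_glm(matrix(rnorm(100), 50, 2), y, name = "m2")
  cmp <- compare_models(list(f1, f2))
  f1$aic <- f1$aic + 37
  f2$aic <- f2$aic + 37
  cmp_shift <- compare_models(list(f1, f2))
  expect_equal(cmp$p_vs_best, cmp_shift$p_vs_best)
  expect_equal(cmp$delta_aic, cmp_shift$delta_aic)
})

test_that("NBS handles empty results, bad thresholds and planted components", {
  set.seed(12)
  n <- 100
  m <- 40
  edge_x <- matrix(pmax(matrix(rnorm(n * m, 0.2, 0.3), n, m), 0), n, m)
  pairs <- t(utils::combn(10, 2))[seq_len(m), ]
  y <- rnorm(n)

  expect_error(nbs_test(edge_x, y, pairs, threshold = -1), "positive")
  expect_warning(nbs_test(edge_x, y, pairs, threshold = 10, n_perm = 50),
                 "coarse")

  r_null <- nbs_test(edge_x, y, pairs, threshold = 1e6, n_perm = 100)
  expect_equal(nrow(r_null$components), 0)
  expect_equal(r_null$p_min, 1)
  expect_equal(r_null$max_component_size, 0)

  # plant a connected 6-edge effect on edges sharing node 1
  planted <- which(pairs[, 1] == 1)[1:6]
  signal <- rnorm(n)
  edge_x2 <- edge_x
  edge_x2[, planted] <- edge_x2[, planted] + 0.25 * signal
  y2 <- signal + 0.5 * rnorm(n)
  r <- nbs_test(edge_x2, y2, pairs, threshold = f_threshold_p(0.01, n),
                n_perm = 300, seed = 3)
  expect_gt(nrow(r$components), 0)
  expect_lt(r$components$p_fwer[which.max(r$components$stat)], 0.05)
  expect_gte(r$fmax, r$threshold)
  expect_true(all(r$components$p_fwer >= 0 & r$components$p_fwer <= 1))
})

test_that("zero-variance edges are excluded from the NBS screen", {
  set.seed(13)
  n <- 60
  edge_x <- cbind(matrix(runif(n * 5), n, 5), 0, 1)
  pairs <- cbind(1:7, 8:14)
  r <- nbs_test(edge_x, rnorm(n), pairs, threshold = 5, n_perm = 100)
  expect_equal(nrow(r$edge_stats), 5)
})
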