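# PGLS, multivariate PGLS, ancestral states and cross-clade ANOVA.

lambda0_transform <- function() {
  # an evo_model_fit shell carrying the star-phylogeny (lambda = 0)
  # correlation structure; pgls() only reads its model and parameter
  tr <- star_tree(4)
  f <- fit_model(tr, setNames(c(1, 2, 4, 8), tr$tip.label), "BM")
  f$model <- "lambda"
  f$param <- 0
  f
}

test_that("PGLS with a star correlation is ordinary least squares", {
  tr <- star_tree(3)
  y <- c(t1 = 2, t2 = 4, t3 = 6)
  x <- c(t1 = 1, t2 = 2, t3 = 3)
  fit <- pgls(tr, y, x, lambda0_transform())
  expect_equal(fit$coefficients$estimate, c(0, 2), tolerance = 1e-10)

  # general case: lambda = 0 on an ultrametric tree equals lm()
  yule <- simulate_yule(40, 1, seed = 8)
  set.seed(9)
  x <- setNames(rnorm(40), yule$tip.label)
  y <- 1.5 - 0.7 * x + setNames(rnorm(40, 0, 0.3), names(x))
  fit0 <- pgls(yule, y, x, lambda0_transform())
  ols <- lm(y ~ x)
  expect_equal(fit0$coefficients$estimate, unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit0$coefficients$se,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-10)
})

test_that("Brownian PGLS slope equals the independent-contrasts regression", {
  for (s in 1:5) {
    tr <- random_tree(10, seed = 40 + s)
    set.seed(50 + s)
    x <- setNames(rnorm(10), tr$tip.label)
    y <- setNames(0.4 * x + rnorm(10, 0, 0.5), tr$tip.label)
    fit <- pgls(tr, y, x, "BM")
    px <- ape::pic(x, tr); py <- ape::pic(y, tr)
    slope_pic <- sum(px * py) / sum(px^2)  # regression through the origin
    expect_equal(fit$coefficients$estimate[2], slope_pic, tolerance = 1e-8)
  }
})

test_that("PGLS slope is invariant to shifting the response", {
  tr <- random_tree(12, seed = 77)
  set.seed(78)
  x <- setNames(rnorm(12), tr$tip.label)
  y <- setNames(-0.3 * x + rnorm(12, 0, 0.4), tr$tip.label)
  f1 <- pgls(tr, y, x, "BM")
  f2 <- pgls(tr, y + 10, x, "BM")
  expect_equal(f1$coefficients$estimate[2], f2$coefficients$estimate[2],
               tolerance = 1e-10)
  expect_equal(f2$coefficients$estimate[1], f1$coefficients$estimate[1] + 10,
               tolerance = 1e-9)
})

test_that("ancestral states follow the conditional-mean formulas", {
  # star tree: root is the arithmetic mean
  tr <- star_tree(3)
  a <- asr_bm(tr, c(t1 = 1, t2 = 2, t3 = 3))
  expect_equal(unname(a$root), 2, tolerance = 1e-10)

  # two tips with branches (1, 3): precision-weighted mean
  tr2 <- parse_newick("(A:1,B:3);")
  a2 <- asr_bm(tr2, c(A = 0, B = 4))
  expect_equal(unname(a2$root), 1, tolerance = 1e-10)
})

test_that("ancestral states agree with an independent GLS implementation", {
  skip_if_not_installed("phytools")
  for (s in 1:3) {
    tr <- random_tree(12, seed = 90 + s)
    set.seed(95 + s)
    x <- setNames(rnorm(12), tr$tip.label)
    mine <- asr_bm(tr, x)$node_estimates
    ref <- phytools::fastAnc(tr, x)
    expect_equal(unname(mine[names(ref)]), unname(as.numeric(ref)),
                 tolerance = 1e-6)
  }
})

test_that("root estimates on ultrametric trees stay within the tip range", {
  for (s in 1:5) {
    yule <- simulate_yule(25, 1, seed = 200 + s)
    x <- drop(simulate_mvbm(yule, matrix(1), 0, seed = 210 + s))
    root <- asr_bm(yule, x)$root
    expect_gte(root, min(x))
    expect_lte(root, max(x))
  }
})

test_that("cross-clade ANOVA matches hand and brute-force sums of squares", {
  res <- class_anova(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(res$F, 1.5, tolerance = 1e-12)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)

  same <- class_anova(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(same$F, 0, tolerance = 1e-12)

  set.seed(5)
  v <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3))
  g <- rep(c("a", "b", "c"), each = 8)
  res3 <- class_anova(v, g)
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - grand)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  f_hand <- (ssb / 2) / (ssw / 21)
  expect_equal(res3$F, f_hand, tolerance = 1e-10)
  expect_equal(nrow(res3$tukey), 3L)
  expect_true(all(res3$tukey$p_adj >= 0 & res3$tukey$p_adj <= 1))

  expect_error(class_anova(c(1, 2, 3), c("a", "a", "b")), "< 2 observations")
})

test_that("multivariate PGLS on a unit-depth star reduces to per-response OLS", {
  tr <- star_tree(25)
  set.seed(61)
  x <- setNames(rnorm(25), tr$tip.label)
  Y <- cbind(a = 1 + 0.5 * x + rnorm(25, 0, 0.4),
             b = -2 + 0.1 * x + rnorm(25, 0, 0.3))
  rownames(Y) <- tr$tip.label
  fit <- mv_pgls(tr, Y, x, estimate_error = FALSE)
  for (k in 1:2) {
    ols <- lm(Y[, k] ~ x)
    expect_equal(unname(fit$B[, k]), unname(coef(ols)), tolerance = 1e-6)
  }
  res <- cbind(lm(Y[, 1] ~ x)$residuals, lm(Y[, 2] ~ x)$residuals)
  expect_equal(unname(fit$R), unname(crossprod(res) / 25), tolerance = 1e-6)
  expect_true(all(abs(fit$correlations) <= 1 + 1e-12))
  expect_equal(unname(diag(fit$correlations)), c(1, 1))
})

test_that("the error-estimating fit beats a dense-likelihood grid and matches it at the optimum", {
  tr <- parse_newick("(((A:1,B:1):1,(C:1.5,D:0.5):0.5):1,E:3);")
  set.seed(71)
  x <- setNames(rnorm(5), tr$tip.label)
  Y <- cbind(p = 0.5 * x + rnorm(5, 0, 0.5), q = -0.2 * x + rnorm(5, 0, 0.5))
  rownames(Y) <- tr$tip.label
  fit <- mv_pgls(tr, Y, x, estimate_error = TRUE)

  C <- vcv_matrix(tr)[tr$tip.label, tr$tip.label]
  X <- cbind(1, x)
  # dense Kronecker likelihood at the fitted (B, R) across a (lambda, e) grid
  ll_dense_opt <- dense_mv_loglik(C, Y, X, fit$B, fit$R,
                                  fit$error_variances, fit$lambda)
  expect_equal(ll_dense_opt, fit$logLik, tolerance = 1e-6)
  grid <- expand.grid(lambda = seq(0, 1, length.out = 50),
                      e = seq(0, 0.5, length.out = 50))
  ll_grid <- mapply(function(l, e) {
    dense_mv_loglik(C, Y, X, fit$B, fit$R, rep(e, 2), l)
  }, grid$lambda, grid$e)
  expect_gte(fit$logLik, max(ll_grid) - 1e-4)
})

test_that("evolutionary correlations recover a known generating correlation", {
  # moderate-size sanity run; the full-scale recovery lives with the
  # acceptance checks
  set.seed(314)
  seeds <- sample.int(1e6, 5)
  rr <- vapply(seeds, function(seed) {
    yule <- simulate_yule(150, 1, seed = seed)
    R <- matrix(c(1, 0.6, 0.6, 1), 2, 2) * 0.02
    E <- simulate_mvbm(yule, R, 0, lambda = 0.9, seed = seed + 1)
    x <- drop(simulate_mvbm(yule, matrix(0.05), 3, lambda = 0.99, seed = seed + 2))
    Y <- cbind(a = 1 - 0.2 * x + E[, 1], b = 0.5 + 0.1 * x + E[, 2])
    rownames(Y) <- rownames(E)
    mv_pgls(yule, Y, x, estimate_error = FALSE)$correlations[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(rr) - 0.6), 0.15)
})
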