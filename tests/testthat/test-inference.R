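test_that("Wald z-tests match direct normal-CDF computation", {
  set.seed(20)
  d <- data.frame(x = factor(rep(c("a", "b", "c"), each = 100)))
  d$y <- rpois(300, exp(1 + 0.3 * (d$x == "b")))
  f <- fit_glmm(y ~ x, d, family = "poisson")
  wt <- wald_table(f)
  expect_equal(wt$z, unname(f$beta / f$se))
  expect_equal(wt$p, unname(2 * pnorm(-abs(f$beta / f$se))))
  expect_true(all(wt$p >= 0 & wt$p <= 1))
  # z = 1.96 corresponds to p ~ 0.05
  expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)
})

test_that("model comparison recovers overdispersion and is null on itself", {
  set.seed(21)
  d <- data.frame(g = factor(rep(1:30, each = 10)))
  u <- rnorm(30, 0, 0.3)
  d$y <- rnbinom(300, size = 0.5, mu = exp(1 + u[as.integer(d$g)]))
  fp <- fit_glmm(y ~ 1 + (1 | g), d, family = "poisson")
  fn <- fit_glmm(y ~ 1 + (1 | g), d, family = "nbinom2")
  cmp <- compare_models(fp, fn)
  expect_lt(cmp$delta_aic, 0)      # NB is the richer, better model
  expect_gt(cmp$chisq, 0)
  expect_equal(cmp$df, 1)
  expect_lt(cmp$p, 1e-6)
  # a model against itself
  self <- compare_models(fn, fn)
  expect_equal(self$chisq, 0)
  expect_equal(self$delta_aic, 0)
  expect_error(compare_models(fp, fit_glmm(y ~ 1, d[1:100, ],
                                           family = "poisson")),
               "different numbers")
})

test_that("the dispersion LRT keeps its size on Poisson data", {
  set.seed(22)
  n_sig <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    d <- data.frame(y = rpois(300, 4))
    fp <- fit_glmm(y ~ 1, d, family = "poisson")
    fn <- fit_glmm(y ~ 1, d, family = "nbinom2")
    if (compare_models(fp, fn)$p < 0.05) n_sig <- n_sig + 1
  }
  # the boundary test is conservative; well over 90% non-significant
  expect_gte(n_rep - n_sig, 0.90 * n_rep)
})

test_that("zero-inflation diagnostics are calibrated and directional", {
  set.seed(23)
  d <- data.frame(x = factor(rep(c("a", "b"), each = 400)))
  d$y <- rnbinom(800, size = 1, mu = exp(0.3 + 0.4 * (d$x == "b")))
  f <- fit_glmm(y ~ x, d, family = "nbinom2")
  ok <- zero_inflation_check(f, n_sims = 199, seed = 1)
  expect_gt(ok$ratio, 0.85)
  expect_lt(ok$ratio, 1.15)
  expect_gt(ok$p, 0.05)
  # 30% structural zeros against a Poisson fit (which cannot absorb them
  # through its dispersion): excess zeros must be detected
  d2 <- data.frame(y = rpois(800, 5))
  d2$y[sample(800, 240)] <- 0L
  f2 <- fit_glmm(y ~ 1, d2, family = "poisson")
  bad <- zero_inflation_check(f2, n_sims = 199, seed = 1)
  expect_gt(bad$ratio, 1)
  expect_lt(bad$p, 0.05)
  # all-positive data under a model that predicts zeros
  d3 <- data.frame(y = rpois(400, 1) + 1L)
  f3 <- fit_glmm(y ~ 1, d3, family = "nbinom2")
  none <- zero_inflation_check(f3, n_sims = 199, seed = 1)
  expect_lt(none$ratio, 1)
  expect_warning(zero_inflation_check(f, n_sims = 50, seed = 1), "coarse")
})

test_that("marginal means equal brute-force grid averaging", {
  set.seed(24)
  d <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v", "w")),
                   rep = 1:40)
  d$y <- rpois(nrow(d), exp(1 + 0.3 * (d$a == "y") - 0.2 * (d$b == "v")))
  f <- fit_glmm(y ~ a + b, d, family = "poisson")
  # intercept-only: single mean = beta0
  f0 <- fit_glmm(y ~ 1, d, family = "poisson")
  mm0 <- marginal_means(f0)
  expect_equal(mm0$emmean, unname(f0$beta[1]))
  # margins over b equal the average of cell predictions (linearity)
  mm <- marginal_means(f, keep = "a")
  grid <- expand.grid(a = factor(c("x", "y"), c("x", "y")),
                      b = factor(c("u", "v", "w"), c("u", "v", "w")))
  Xg <- model.matrix(~ a + b, grid)
  pred <- as.vector(Xg %*% f$beta)
  for (lv in c("x", "y")) {
    expect_equal(mm$emmean[mm$a == lv], mean(pred[grid$a == lv]),
                 tolerance = 1e-10)
  }
  # covariance propagation: L V L'
  L <- attr(mm, "L")
  expect_equal(attr(mm, "vcov"), L %*% f$vcov_beta %*% t(L),
               tolerance = 1e-12)
  expect_error(marginal_means(f, keep = "nope"), "not in the model")
})

test_that("Holm adjustment equals the brute-force step-down oracle", {
  holm_oracle <- function(p) {
    # sequential rejection: sort, multiply by (m - i + 1), enforce monotone
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 0
    for (i in seq_len(m)) {
      running <- max(running, (m - i + 1) * p[o[i]])
      adj[o[i]] <- min(1, running)
    }
    adj
  }
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  set.seed(25)
  for (r in 1:60) {
    p <- round(runif(sample(1:6, 1)), 3)
    expect_equal(holm_adjust(p), holm_oracle(p))
  }
})

test_that("proportion tests follow the expected-count rule", {
  eq <- proportion_test(10, 50, 10, 50)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_equal(eq$method, "chisq")
  # textbook Sigma (O-E)^2 / E oracle on a 2x2 table
  tab <- matrix(c(14, 51, 4, 87), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq_oracle <- sum((tab - E)^2 / E)
  got <- proportion_test(14, 65, 4, 91)
  expect_equal(got$statistic, chisq_oracle, tolerance = 1e-10)
  expect_equal(chisq_oracle, 10.92, tolerance = 0.01)
  # small expected counts force Fisher
  fis <- proportion_test(1, 10, 0, 10)
  expect_equal(fis$method, "fisher")
  expect_true(any(fis$expected < 5))
  expect_equal(fis$p, fisher.test(matrix(c(1, 9, 0, 10), 2,
                                         byrow = TRUE))$p.value)
  expect_error(proportion_test(1, 0, 1, 10), "positive")
  expect_error(proportion_test(11, 10, 1, 10), "between 0")
})
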