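test_that("dip statistic matches closed-form cases and stays in bounds", {
  expect_equal(dip_statistic(rep(c(0, 1), each = 50)), 0.25, tolerance = 1e-9)
  expect_equal(dip_statistic(1:10), 1 / 20, tolerance = 1e-9)
  expect_equal(dip_statistic(rep(3, 10)), 1 / 20)
  expect_error(dip_statistic(1:3), "n >= 4")
  expect_error(dip_statistic(c(1, 2, 3, NA)), "finite")
  set.seed(4)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    x <- switch(sample(3, 1), rnorm(n), round(runif(n), 1), rexp(n))
    d <- dip_statistic(x)
    expect_gte(d, 1 / (2 * n) - 1e-12)
    expect_lte(d, 0.25 + 1e-12)
  }
})

test_that("dip statistic agrees with the brute-force unimodal-CDF oracle", {
  skip_if_not_installed("quadprog")
  expect_equal(oracle_dip(rep(c(0, 1), each = 4)), 0.25, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    x <- switch(sample(4, 1),
                rnorm(n), round(rnorm(n), 1), runif(n), sample(0:2, n, TRUE))
    if (length(unique(x)) == 1) next
    expect_equal(dip_statistic(x), oracle_dip(x), tolerance = 1e-6,
                 label = paste("dip of", paste(round(x, 4), collapse = ",")))
  }
})

test_that("dip test gives small p for bimodal data and validates n_boot", {
  x <- rep(c(0, 1), each = 50)
  r <- dip_test(x, n_boot = 1999, seed = 1)
  expect_lte(r$p, 0.001)
  expect_error(dip_test(x, n_boot = 0), "n_boot")
  # same seed reproduces the p-value exactly
  r2 <- dip_test(x, n_boot = 199, seed = 7)
  r3 <- dip_test(x, n_boot = 199, seed = 7)
  expect_identical(r2$p, r3$p)
})

test_that("k = 1 mixture fit is the closed-form normal MLE", {
  set.seed(2)
  x <- rnorm(200, 5, 2)
  f <- fit_mixture(x, 1)
  expect_equal(f$means, mean(x))
  expect_equal(f$variances, mean((x - mean(x))^2))
  expect_equal(f$logL, sum(dnorm(x, mean(x), sqrt(f$variances), log = TRUE)))
  expect_equal(f$n_params, 2L)
})

test_that("EM is monotone, weights stay on the simplex, duplication doubles logL", {
  set.seed(3)
  x <- c(rnorm(150, 0, 1), rnorm(150, 6, 1))
  f <- fit_mixture(x, 2, seed = 1, n_restarts = 5)
  expect_true(all(diff(f$logl_trace) > -1e-7))
  expect_equal(sum(f$weights), 1, tolerance = 1e-9)
  expect_true(all(f$variances >= 1e-4))
  expect_true(f$converged)
  f2 <- fit_mixture(c(x, x), 2, seed = 1, n_restarts = 5)
  expect_equal(f2$means, f$means, tolerance = 1e-4)
  expect_equal(f2$logL, 2 * f$logL, tolerance = 1e-5 * abs(f$logL))
  expect_error(fit_mixture(rnorm(2), 3), "at least k")
})

test_that("mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  set.seed(9)
  x <- c(rnorm(300, 0, 0.5), rnorm(300, 4, 0.8))
  f <- fit_mixture(x, 2, seed = 1)
  m <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(f$means), sort(as.numeric(m$parameters$mean)),
               tolerance = 0.02)
  expect_equal(f$logL, m$loglik, tolerance = 1e-3 * abs(m$loglik))
})

test_that("model comparison reproduces AIC arithmetic and the chi-square tail", {
  f_small <- structure(list(k = 2L, logL = -1177.5, n_params = 5L,
                            n_obs = 576L, converged = TRUE),
                       class = "mixture_fit")
  f_big <- structure(list(k = 3L, logL = -1177.5, n_params = 8L,
                          n_obs = 576L, converged = TRUE),
                     class = "mixture_fit")
  cmp <- compare_mixtures(f_small, f_big)
  expect_equal(cmp$aic_small, 2365.0)
  expect_equal(cmp$lrt_stat, 0)
  expect_equal(cmp$p_lrt, 1)
  f_big$logL <- -1167.5
  cmp2 <- compare_mixtures(f_small, f_big)
  expect_equal(cmp2$lrt_stat, 20)
  expect_equal(cmp2$df, 3L)
  expect_equal(cmp2$p_lrt, chisq3_sf(20), tolerance = 1e-12)
  f_bad <- f_big; f_bad$k <- 4L
  expect_error(compare_mixtures(f_small, f_bad), "nested")
})

test_that("modes are sorted component means; collisions and non-convergence flagged", {
  f <- structure(list(k = 3L, means = c(2.6, 7.8, 5.5), converged = TRUE),
                 class = "mixture_fit")
  expect_equal(as.numeric(mixture_modes(f)), c(7.8, 5.5, 2.6))
  f1 <- structure(list(k = 1L, means = 6.1, converged = TRUE),
                  class = "mixture_fit")
  expect_equal(as.numeric(mixture_modes(f1)), 6.1)
  fc <- structure(list(k = 2L, means = c(3, 3), converged = TRUE),
                  class = "mixture_fit")
  expect_warning(mc <- mixture_modes(fc), "share the same mean")
  expect_true(attr(mc, "collision"))
  fu <- structure(list(k = 2L, means = c(1, 2), converged = FALSE),
                  class = "mixture_fit")
  expect_warning(mixture_modes(fu), "converge")
})
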