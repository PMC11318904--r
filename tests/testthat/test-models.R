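test_that("zscore standardizes to mean 0 and sample sd 1", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- withr::with_seed(1, rnorm(20, 5, 3))
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(rep(2, 5)), class = "phylograd_domain_error")
  expect_error(zscore(1), class = "phylograd_domain_error")
})

test_that("fit_ols_ml matches the closed-form normal-equations oracle", {
  dat <- withr::with_seed(42, {
    x1 <- rnorm(15); x2 <- rnorm(15)
    tibble::tibble(x1 = x1, x2 = x2, y = 1 + 2 * x1 - x2 + rnorm(15, 0, 0.5))
  })
  fit <- fit_ols_ml(dat, "y", c("x1", "x2"))
  X <- cbind(1, dat$x1, dat$x2)
  beta <- solve(crossprod(X), crossprod(X, dat$y))
  expect_equal(unname(coef(fit$fit)), drop(beta), tolerance = 1e-9)
  rss <- sum((dat$y - X %*% beta)^2)
  expect_equal(fit$rss, rss, tolerance = 1e-9)
  # Gaussian ML log-likelihood with variance RSS/n, and k counts sigma^2
  n <- 15
  expect_equal(fit$loglik, -(n / 2) * (log(2 * pi) + log(rss / n) + 1),
    tolerance = 1e-9)
  expect_equal(fit$k, 4)
})

test_that("degenerate designs are rejected", {
  dat <- tibble::tibble(x = 1:6, x2 = 2 * (1:6), y = (1:6) * 3)
  expect_error(fit_ols_ml(dat, "y", c("x", "x2")), class = "phylograd_domain_error")
  expect_error(fit_ols_ml(dat, "y", "x"), class = "phylograd_domain_error") # RSS ~ 0
})

test_that("aicc follows the closed form and weights normalize", {
  fit <- list(loglik = -13.688, n = 8, k = 2)
  expect_equal(aicc(fit), 2 * 13.688 + 4 + 12 / 5, tolerance = 1e-9)
  expect_error(aicc(list(loglik = 0, n = 4, k = 3)), class = "phylograd_domain_error")

  # two models at delta 0 and 2: closed-form weights
  w1 <- 1 / (1 + exp(-1))
  dat <- mt_wilhelm_sites()
  rk <- rank_models(dat, "nri", c("plant_richness_z", "predator_abundance_z",
    "temperature_z"))
  expect_equal(sum(rk$weight), 1, tolerance = 1e-12)
  expect_equal(rk$delta_aicc[1], 0)
  expect_equal(nrow(rk), 8)
  d2 <- c(0, 2)
  expect_equal(exp(-d2 / 2)[1] / sum(exp(-d2 / 2)), w1, tolerance = 1e-12)
})

test_that("AICc ranking is invariant to predictor scaling", {
  dat <- mt_wilhelm_sites()
  rk1 <- rank_models(dat, "nti", c("plant_richness_z", "temperature_z"))
  dat2 <- dat
  dat2$plant_richness_z <- dat2$plant_richness_z * 1000
  dat2$temperature_z <- dat2$temperature_z / 37
  rk2 <- rank_models(dat2, "nti", c("plant_richness_z", "temperature_z"))
  expect_equal(rk1$model, rk2$model)
  expect_equal(rk1$aicc, rk2$aicc, tolerance = 1e-9)
})

test_that("quadratic fits detect curvature and are basis-invariant", {
  dat <- tibble::tibble(x = seq(-3, 3, length.out = 12))
  dat$y_exact <- dat$x^2
  p <- fit_poly2(dat, "y_exact", "x")
  expect_true(p$perfect)
  expect_lt(p$rss, 1e-10)

  dat$y <- withr::with_seed(3, dat$x^2 + rnorm(12, 0, 0.5))
  p2 <- fit_poly2(dat, "y", "x")
  expect_lt(p2$quadratic_p, 0.001)
  raw <- summary(lm(y ~ x + I(x^2), dat))$coefficients
  expect_equal(p2$quadratic_p, raw["I(x^2)", 4], tolerance = 1e-9)
})

test_that("quadratic p-values are uniform under the null", {
  ps <- withr::with_seed(11, vapply(1:400, function(i) {
    dat <- tibble::tibble(x = rnorm(12), y = rnorm(12))
    fit_poly2(dat, "y", "x")$quadratic_p
  }, 1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pearson_test recovers exact and degenerate correlations", {
  dat <- tibble::tibble(x = 1:10, y = 1:10, yr = 10:1)
  expect_equal(pearson_test(dat, "x", "y")$r, 1)
  expect_equal(pearson_test(dat, "x", "yr")$r, -1)
  expect_error(pearson_test(tibble::tibble(x = 1:5, y = rep(1, 5)), "x", "y"),
    class = "phylograd_domain_error")
})

test_that("mantel attains the maximal statistic on identical matrices", {
  d <- withr::with_seed(5, random_distance_matrix(8))
  m <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p_value, 1 / 100)
})

test_that("mantel agrees with the reference implementation and is seed-stable", {
  skip_if_not_installed("vegan")
  d1 <- withr::with_seed(6, random_distance_matrix(10))
  d2 <- withr::with_seed(7, random_distance_matrix(10))
  m <- mantel_test(d1, d2, n_perm = 999, seed = 42)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(m$r, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(m$p_value, ref$signif, tolerance = 0.06)
  expect_identical(m, mantel_test(d1, d2, n_perm = 999, seed = 42))
})

test_that("mantel rejects mismatched labels", {
  d1 <- random_distance_matrix(5)
  d2 <- random_distance_matrix(5, labels = paste0("z", 1:5))
  expect_error(mantel_test(d1, d2), class = "phylograd_validation_error")
})

test_that("independent random matrices rarely look significant", {
  res <- withr::with_seed(31, vapply(1:50, function(i) {
    mantel_test(random_distance_matrix(9), random_distance_matrix(9),
      n_perm = 199)$p_value
  }, 1))
  expect_gte(mean(res > 0.05), 0.86)
})
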