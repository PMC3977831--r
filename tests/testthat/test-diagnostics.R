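test_that("deviance matches hand-computed values and vanishes for saturated fits", {
  # D = 0 iff the prediction equals k/n at every block: build counts that
  # sit exactly on the curve
  p <- psy_params(0.5, 0.2, lam = 0, gamma = 0.5)
  x <- c(0.3, 0.5, 0.7)
  prob <- psy_predict(p, x)
  n <- c(1000, 1000, 1000)
  k <- round(prob * n)
  # adjust prediction to the realized proportions via direct term evaluation
  terms <- jointpsy:::deviance_terms(k, n, k / n)
  expect_equal(sum(terms), 0)

  # hand values, 0*log(0) = 0 convention
  expect_equal(jointpsy:::deviance_terms(15, 20, 0.5),
               2 * (15 * log(1.5) + 5 * log(0.5)), tolerance = 1e-9)
  expect_equal(jointpsy:::deviance_terms(20, 20, 0.9),
               2 * 20 * log(1 / 0.9), tolerance = 1e-9)
})

test_that("deviance report decomposes additively with signed residuals", {
  d <- block_data(c(0.2, 0.5, 0.8), k = c(12, 16, 18), n = rep(20, 3))
  p <- psy_params(0.5, 0.2, 0.02, 0.5)
  rep1 <- psy_deviance(d, p)
  expect_gte(rep1$deviance, 0)
  # total deviance equals the sum of squared residuals
  expect_equal(sum(rep1$residuals^2), rep1$deviance)
  # residual sign follows the direction of misfit
  prob <- psy_predict(p, d$intensity)
  expect_equal(sign(rep1$residuals), sign(d$k / d$n - prob))
  # additivity over conditions
  d2 <- block_data(c(0.1, 0.5, 0.9), k = c(9, 15, 20), n = rep(20, 3))
  expect_equal(deviance_sum(list(rep1, psy_deviance(d2, p))),
               rep1$deviance + psy_deviance(d2, p)$deviance)
})

test_that("overlap statistic reproduces its anchor values", {
  expect_identical(overlap_stat(c(1, 3), c(1, 3)), 1)
  expect_identical(overlap_stat(c(1, 2), c(2, 3)), 0)
  # diverging distributions approach -1 from above
  d <- 10^(2:6)
  vals <- vapply(d, function(di) overlap_stat(c(0, 1), c(di, di + 1)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > -1))
  expect_equal(vals[length(vals)], -1, tolerance = 1e-5)
})

test_that("overlap is symmetric, affine-invariant, monotone under separation", {
  a <- c(0.3, 1.1); b <- c(0.7, 2.5)
  expect_equal(overlap_stat(a, b), overlap_stat(b, a))
  for (sc in c(0.1, 3, 100)) for (sh in c(-5, 0, 2)) {
    expect_equal(overlap_stat(sc * a + sh, sc * b + sh), overlap_stat(a, b))
  }
  # identical interval always scores 1
  for (iv in list(c(0, 1), c(-3, -3), c(2.5, 7))) {
    expect_equal(overlap_stat(iv, iv), 1)
  }
  # translating B away never increases the score
  shifts <- seq(0, 10, by = 0.5)
  sc <- vapply(shifts, function(s) overlap_stat(a, b + s), numeric(1))
  expect_true(all(diff(sc) <= 0))
  expect_error(overlap_stat(c(2, 1), c(0, 1)), "q1 <= q3")
})

test_that("posterior overlap matches direct quartile computation and is symmetric", {
  set.seed(8)
  xa <- runif(4000)          # quartiles near 0.25, 0.75
  xb <- runif(4000) + 10     # near 10.25, 10.75
  got <- posterior_overlap(xa, xb)
  direct <- overlap_stat(unname(quantile(xa, c(.25, .75), type = 7)),
                         unname(quantile(xb, c(.25, .75), type = 7)))
  expect_equal(got, direct)
  expect_lt(got, 0)
  # closed-form uniform quartiles: (0.75 - 10.25)/(10.75 - 0.25)
  expect_equal(got, (0.75 - 10.25) / (10.75 - 0.25), tolerance = 0.02)
  expect_equal(posterior_overlap(xb, xa), got)
  expect_equal(posterior_overlap(xa, xa), 1)
  expect_error(posterior_overlap(c(1, 2, 3), xa), "at least 4 draws")
})

test_that("posterior correlation handles exact, anti- and null dependence", {
  f <- quiet(sir_sample(fixed_data(), config = sir_config(2000, 500), seed = 2))
  expect_equal(posterior_correlation(f, "w", "w"), 1)
  mirrored <- f
  mirrored$draws <- cbind(f$draws, neg = -f$draws[, "w"] + 3)
  expect_equal(posterior_correlation(mirrored, "w", "neg"), -1)
  # independent draws: |r| < 0.1 in at least 95% of seeds
  n_ok <- sum(vapply(1:40, function(s) {
    set.seed(s)
    abs(cor(rnorm(2000), rnorm(2000))) < 0.1
  }, logical(1)))
  expect_gte(n_ok, 0.95 * 40)
  bad <- f
  bad$draws <- cbind(f$draws, const = rep(1, nrow(f$draws)))
  expect_error(posterior_correlation(bad, "w", "const"), "zero variance")
})
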