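# The generic SIR core is validated against conjugate closed forms
# (Beta-binomial) and the prior-recovery property, the Gamma ML summary
# against known Gamma samples and an independent fitter.

test_that("SIR recovers the prior under a flat likelihood (KS test)", {
  post <- sir(log_lik = function(th) rep(0, length(th)),
              propose = function(n) rnorm(n, 1, 2),
              n_proposals = 25000, n_final = 2000, seed = 42)
  ks <- suppressWarnings(ks.test(post$draws, pnorm, 1, 2))
  expect_gt(ks$p.value, 0.01)
  # constant likelihood c: marginal-likelihood estimate is log c exactly
  post_c <- sir(log_lik = function(th) rep(log(0.3), length(th)),
                propose = function(n) runif(n),
                n_proposals = 1000, n_final = 100, seed = 1)
  expect_equal(marginal_loglik(post_c), log(0.3))
})

test_that("SIR matches the Beta-binomial conjugate oracle", {
  # Beta(1,1) prior, binomial k = 7, n = 10: posterior is Beta(8, 4) with
  # mean 8/12; marginal likelihood is choose(10,7) * B(8,4)
  k <- 7; n <- 10
  post <- sir(log_lik = function(p) dbinom(k, n, p, log = TRUE),
              propose = function(m) runif(m),
              n_proposals = 25000, n_final = 2000, seed = 7)
  mc_se <- sd(post$draws) / sqrt(post$ess)
  expect_lt(abs(mean(post$draws) - 8 / 12), 3 * mc_se)

  logZ_true <- lchoose(n, k) + lbeta(k + 1, n - k + 1)
  # MC standard error of the logZ estimate from the weight variance
  w <- exp(post$proposal_log_weights)
  se_logZ <- sd(w) / (mean(w) * sqrt(length(w)))
  expect_lt(abs(marginal_loglik(post) - logZ_true), 3 * se_logZ)
})

test_that("resampling stays on the proposal support with weights proportional to likelihood", {
  d <- fixed_data()
  fit <- quiet(sir_sample(d, config = sir_config(2000, 500), seed = 3))
  # every final draw is one of the proposals: w draws live on a finite set
  # of proposal values, so each must have been proposed (checked via the
  # importance weights: resampled values must carry positive weight)
  expect_true(all(is.finite(fit$draws)))
  expect_equal(nrow(fit$draws), 500)
  # proposals are prior draws, so log weight = log likelihood
  theta <- local({
    set.seed(3)
    jointpsy:::prior_sample(fit$prior, 2000)
  })
  expect_equal(fit$proposal_log_weights,
               jointpsy:::psy_loglik_matrix(theta, 0.5, d))
  # normalized importance weights sum to one
  w <- exp(fit$proposal_log_weights - max(fit$proposal_log_weights))
  expect_equal(sum(w / sum(w)), 1)
})

test_that("degenerate weights raise, low ESS warns", {
  expect_error(sir(log_lik = function(th) rep(-Inf, length(th)),
                   propose = function(n) runif(n),
                   n_proposals = 100, n_final = 10, seed = 1),
               "all importance weights are zero")
  expect_warning(
    sir(log_lik = function(th) ifelse(seq_along(th) == 1, 0, -1e6),
        propose = function(n) runif(n),
        n_proposals = 100, n_final = 10, seed = 1, ess_floor = 5),
    "degenerate")
})

test_that("doubling the proposal count shrinks marginal-likelihood variance", {
  k <- 7; n <- 10
  est <- function(n_prop, seed) {
    marginal_loglik(sir(log_lik = function(p) dbinom(k, n, p, log = TRUE),
                        propose = function(m) runif(m),
                        n_proposals = n_prop, n_final = 10, seed = seed))
  }
  v1 <- var(vapply(1:50, function(s) est(500, s), numeric(1)))
  v2 <- var(vapply(1:50, function(s) est(1000, 100 + s), numeric(1)))
  expect_gt(v2 / v1, 0.3)
  expect_lt(v2 / v1, 0.8)
})

test_that("posterior concentrates as trial counts grow", {
  gen <- default_gen()
  iqr_w <- function(mult, seed) {
    sch <- sampling_scheme(c(0.15, 0.35, 0.45, 0.55, 0.65, 0.85),
                           rep(50 * mult, 6))
    d <- generate_dataset(gen, sch, seed = seed)
    f <- quiet(sir_sample(d, config = test_config(), seed = seed + 1))
    IQR(f$draws[, "w"])
  }
  small <- vapply(1:20, function(s) iqr_w(1, 10 * s), numeric(1))
  big <- vapply(1:20, function(s) iqr_w(2, 1000 + 10 * s), numeric(1))
  expect_lte(mean(big), mean(small))
})

test_that("Gamma ML summary recovers known shapes and matches an independent fitter", {
  set.seed(5)
  x <- rgamma(2000, shape = 3, rate = 2)
  g <- fit_gamma_summary(x, "w")
  expect_gt(g$shape, 2.7); expect_lt(g$shape, 3.3)
  expect_gt(g$rate, 1.8); expect_lt(g$rate, 2.2)
  # fitted mean equals the sample mean to within 1%
  expect_lt(abs(g$shape / g$rate - mean(x)) / mean(x), 0.01)
  # exponential draws are Gamma(1, 1)
  set.seed(6)
  e <- fit_gamma_summary(rexp(2000), "w")
  expect_lt(abs(e$shape - 1), 0.1)
  # cross-check against MASS::fitdistr on the same draws
  ref <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_equal(g$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(g$rate, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("Gamma summary rejects degenerate or invalid input", {
  expect_error(fit_gamma_summary(rep(2, 100)), "degenerate")
  expect_error(fit_gamma_summary(c(-1, rexp(99))), "positive")
  expect_error(fit_gamma_summary(rexp(5)), "at least 10")
})
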