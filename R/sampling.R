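# Posterior estimation by sampling-importance-resampling (SIR) and
# parametric Gamma summaries of marginal posteriors.

#' Prior specification for a psychometric fit
#'
#' Per-parameter parametric priors. The threshold \code{m} gets a Gaussian
#' prior, the width \code{w} a Gamma prior (positive support), and the lapse
#' rate \code{lam} a Beta prior truncated to a small interval near zero.
#'
#' @param m_mean,m_sd Mean and standard deviation of the Gaussian prior on
#'   the threshold, in intensity units.
#' @param w_shape,w_rate Shape and rate of the Gamma prior on the width.
#' @param lam_shape1,lam_shape2 Beta shape parameters for the lapse-rate
#'   prior.
#' @param lam_upper Upper truncation bound for the lapse rate.
#' @return An object of class \code{"prior_spec"}.
#' @seealso \code{\link{default_prior}} for data-driven defaults.
#' @export
prior_spec <- function(m_mean, m_sd, w_shape, w_rate,
                       lam_shape1 = 2, lam_shape2 = 20, lam_upper = 0.1) {
  stopifnot(is.finite(m_mean), m_sd > 0, w_shape > 0, w_rate > 0,
            lam_shape1 > 0, lam_shape2 > 0, lam_upper > 0, lam_upper <= 1)
  structure(list(m = list(dist = "norm", mean = m_mean, sd = m_sd),
                 w = list(dist = "gamma", shape = w_shape, rate = w_rate),
                 lam = list(dist = "beta_trunc", shape1 = lam_shape1,
                            shape2 = lam_shape2, upper = lam_upper)),
            class = "prior_spec")
}

#' Weakly informative default prior from the tested intensities
#'
#' Centres the threshold prior at the midrange of the tested intensities
#' with a standard deviation equal to the intensity range; gives the width a
#' Gamma(2, rate) prior with mean equal to half the intensity range; and the
#' lapse rate a Beta(2, 20) prior truncated to \code{[0, 0.1]}.
#'
#' @param data A \code{\link{block_data}} object (its intensities set the
#'   scale), or a numeric vector of intensities.
#' @return A \code{\link{prior_spec}}.
#' @export
default_prior <- function(data) {
  x <- if (inherits(data, "block_data")) data$intensity else as.numeric(data)
  rng <- range(x)
  span <- diff(rng)
  if (span <= 0) stop("intensities must span a nonzero range", call. = FALSE)
  prior_spec(m_mean = mean(rng), m_sd = span,
             w_shape = 2, w_rate = 2 / (span / 2))
}

# Draw n parameter proposals (matrix with columns m, w, lam) from a prior.
prior_sample <- function(prior, n) {
  m <- stats::rnorm(n, prior$m$mean, prior$m$sd)
  w <- stats::rgamma(n, shape = prior$w$shape, rate = prior$w$rate)
  lp <- prior$lam
  u <- stats::runif(n) * stats::pbeta(lp$upper, lp$shape1, lp$shape2)
  lam <- stats::qbeta(u, lp$shape1, lp$shape2)
  cbind(m = m, w = w, lam = lam)
}

#' Sampler settings
#'
#' @param n_proposals Number of proposal samples drawn from the prior.
#' @param n_final Number of resampled posterior draws.
#' @param ess_floor Effective-sample-size floor below which a fit is flagged
#'   degenerate (with a warning).
#' @return A list of class \code{"sir_config"}.
#' @export
sir_config <- function(n_proposals = 25000, n_final = 2000, ess_floor = 50) {
  stopifnot(n_proposals >= n_final, n_final >= 1)
  structure(list(n_proposals = as.integer(n_proposals),
                 n_final = as.integer(n_final),
                 ess_floor = ess_floor),
            class = "sir_config")
}

#' Generic sampling-importance-resampling
#'
#' Draws proposals, weights them by a log-likelihood, and resamples with
#' replacement with probabilities proportional to the importance weights.
#' When proposals come from the prior, the importance weight of a proposal
#' is its likelihood, and the log of the mean likelihood over proposals is a
#' consistent estimate of the log marginal likelihood of the data.
#'
#' @param log_lik Function taking the proposal matrix (or vector) and
#'   returning a vector of log-likelihoods.
#' @param propose Function taking a count and returning that many proposals
#'   (rows of a matrix, or a vector).
#' @param n_proposals,n_final Proposal and final draw counts.
#' @param seed Optional integer seed.
#' @param ess_floor Effective-sample-size floor for the degeneracy warning.
#' @param proposals_from_prior Logical flag recorded in the result; the
#'   marginal-likelihood estimate is only valid when \code{TRUE}.
#' @return A list of class \code{"sir_posterior"} with elements
#'   \code{draws}, \code{proposal_log_weights}, \code{marginal_loglik},
#'   \code{ess}, \code{degenerate}, \code{n_proposals}, \code{n_final},
#'   \code{seed}, \code{proposals_from_prior}.
#' @export
sir <- function(log_lik, propose, n_proposals, n_final, seed = NULL,
                ess_floor = 0, proposals_from_prior = TRUE) {
  stopifnot(n_proposals >= n_final, n_final >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- propose(n_proposals)
  logw <- log_lik(theta)
  if (length(logw) != n_proposals)
    stop("log_lik must return one value per proposal", call. = FALSE)
  logw[is.na(logw)] <- -Inf
  if (all(logw == -Inf))
    stop("all importance weights are zero: likelihood vanishes on every proposal",
         call. = FALSE)
  M <- max(logw)
  wr <- exp(logw - M)
  p <- wr / sum(wr)
  ess <- 1 / sum(p^2)
  degenerate <- ess < ess_floor
  if (degenerate)
    warning(sprintf("effective sample size %.1f below floor %g: posterior flagged degenerate",
                    ess, ess_floor), call. = FALSE)
  idx <- sample.int(n_proposals, n_final, replace = TRUE, prob = p)
  draws <- if (is.matrix(theta)) theta[idx, , drop = FALSE] else theta[idx]
  structure(list(draws = draws,
                 proposal_log_weights = logw,
                 marginal_loglik = M + log(mean(wr)),
                 ess = ess,
                 degenerate = degenerate,
                 n_proposals = as.integer(n_proposals),
                 n_final = as.integer(n_final),
                 seed = seed,
                 proposals_from_prior = isTRUE(proposals_from_prior)),
            class = "sir_posterior")
}

#' Fit a psychometric function to one condition by SIR
#'
#' Proposals are drawn from the prior, so each proposal's importance weight
#' is its binomial likelihood; \code{n_final} draws are resampled with
#' replacement proportionally to the weights.
#'
#' @param data A \code{\link{block_data}} object.
#' @param prior A \code{\link{prior_spec}}; defaults to
#'   \code{default_prior(data)}.
#' @param gamma Fixed guess rate (lower asymptote), e.g. 0.5 for 2AFC.
#' @param config A \code{\link{sir_config}}.
#' @param seed Optional integer seed.
#' @return A \code{"sir_posterior"} whose \code{draws} matrix has columns
#'   \code{m}, \code{w}, \code{lam}; also carries \code{gamma},
#'   \code{prior}, and the condition label.
#' @examples
#' d <- block_data(c(0.2, 0.4, 0.5, 0.6, 0.8),
#'                 k = c(26, 32, 38, 45, 49), n = rep(50, 5))
#' fit <- sir_sample(d, config = sir_config(2000, 200), seed = 1)
#' apply(fit$draws, 2, stats::median)
#' @export
sir_sample <- function(data, prior = default_prior(data), gamma = 0.5,
                       config = sir_config(), seed = NULL) {
  validate_block_data(data)
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  post <- sir(log_lik = function(theta) psy_loglik_matrix(theta, gamma, data),
              propose = function(n) prior_sample(prior, n),
              n_proposals = config$n_proposals, n_final = config$n_final,
              seed = seed, ess_floor = config$ess_floor,
              proposals_from_prior = TRUE)
  post$gamma <- gamma
  post$prior <- prior
  post$condition <- attr(data, "condition")
  post
}

#' @export
print.sir_posterior <- function(x, ...) {
  cat(sprintf("SIR posterior (%d proposals -> %d draws), ESS %.1f%s\n",
              x$n_proposals, x$n_final, x$ess,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  if (is.matrix(x$draws)) {
    q <- apply(x$draws, 2, stats::quantile, c(0.25, 0.5, 0.75))
    print(round(q, 4))
  }
  invisible(x)
}

#' Log marginal likelihood from a SIR posterior
#'
#' The log of the mean proposal likelihood. Valid (a consistent estimator of
#' \code{log p(data)}) only when the proposals were drawn from the prior.
#'
#' @param post A \code{"sir_posterior"}.
#' @return Scalar log marginal likelihood estimate.
#' @export
marginal_loglik <- function(post) {
  stopifnot(inherits(post, "sir_posterior"))
  if (!isTRUE(post$proposals_from_prior))
    stop("marginal likelihood estimate requires proposals drawn from the prior",
         call. = FALSE)
  post$marginal_loglik
}

#' Maximum-likelihood Gamma summary of posterior draws
#'
#' Fits a Gamma distribution to one-parameter posterior draws by maximum
#' likelihood (Newton iteration on the shape via the digamma function,
#' moment-matched start, tolerance 1e-8). Used to carry a marginal
#' posterior, in parametric form, into the next round of inference.
#'
#' @param x Numeric vector of at least 10 strictly positive draws with
#'   nonzero variance.
#' @param parameter_name Label for the summarised parameter.
#' @return An object of class \code{"gamma_summary"} with fields
#'   \code{shape}, \code{rate}, \code{parameter_name}.
#' @examples
#' set.seed(1)
#' fit_gamma_summary(rgamma(2000, shape = 3, rate = 2), "w")
#' @export
fit_gamma_summary <- function(x, parameter_name = "w") {
  x <- as.numeric(x)
  if (length(x) < 10) stop("need at least 10 draws", call. = FALSE)
  if (any(x <= 0)) stop("Gamma summary requires strictly positive draws", call. = FALSE)
  mx <- mean(x)
  v <- stats::var(x)
  if (!is.finite(v) || v < 1e-12 * mx^2)
    stop("draws are (near-)degenerate: variance too small for a Gamma fit",
         call. = FALSE)
  s <- log(mx) - mean(log(x))   # always > 0 by Jensen for non-degenerate x
  a <- mx^2 / v                  # moment-matching start
  for (i in 1:100) {
    g <- log(a) - digamma(a) - s
    step <- g / (1 / a - trigamma(a))
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-8 * (1 + abs(a))) { a <- a_new; break }
    a <- a_new
  }
  structure(list(shape = a, rate = a / mx, parameter_name = parameter_name),
            class = "gamma_summary")
}

#' @export
print.gamma_summary <- function(x, ...) {
  cat(sprintf("Gamma summary of '%s': shape = %.4g, rate = %.4g (mean %.4g)\n",
              x$parameter_name, x$shape, x$rate, x$shape / x$rate))
  invisible(x)
}

# Derive reproducible child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}
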