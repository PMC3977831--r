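# Model selection between the isolated models and the joint model:
# posterior model probabilities under a model prior (flat by default),
# equivalent to a Bayes-factor decision.

#' Posterior model probabilities from log marginal likelihoods
#'
#' Given log marginal likelihoods of the isolated and joint models and a
#' prior probability for the isolated model, returns the posterior model
#' probabilities. With a flat model prior the decision is equivalent to one
#' based on the Bayes factor.
#'
#' @param log_marglik_isolated,log_marglik_joint Log marginal likelihoods.
#' @param prior_isolated Prior probability of the isolated model (0.5 =
#'   flat).
#' @return Named list with \code{p_isolated} and \code{p_joint} (summing to
#'   1).
#' @export
model_posterior <- function(log_marglik_isolated, log_marglik_joint,
                            prior_isolated = 0.5) {
  stopifnot(prior_isolated > 0, prior_isolated < 1)
  a <- log(prior_isolated) + log_marglik_isolated
  b <- log(1 - prior_isolated) + log_marglik_joint
  M <- max(a, b)
  pi_iso <- exp(a - M) / (exp(a - M) + exp(b - M))
  list(p_isolated = pi_iso, p_joint = 1 - pi_iso)
}

#' Compare the isolated and joint models
#'
#' Estimates the marginal likelihood of the isolated model (product over
#' conditions of per-condition marginal likelihoods under the original
#' priors) and of the joint model (chain factorisation: the first condition
#' under its original prior, each subsequent condition with the shared
#' parameter's prior replaced by the product of the Gamma summaries of the
#' previously processed conditions' posteriors). Because the processing
#' order should not matter in theory but does affect a finite Monte Carlo
#' estimate, the joint log marginal likelihood is averaged over the forward
#' and reverse orders. Posterior model probabilities follow from
#' \code{\link{model_posterior}}.
#'
#' @param datasets List of at least 2 \code{\link{block_data}} objects.
#' @param shared Shared parameter name (\code{"w"} or \code{"lam"}).
#' @param gamma Fixed guess rate.
#' @param priors Optional per-condition \code{\link{prior_spec}} list.
#' @param config A \code{\link{sir_config}}.
#' @param seed Master seed.
#' @param prior_isolated Prior probability of the isolated model.
#' @return Object of class \code{"model_comparison"}: \code{p_isolated},
#'   \code{p_joint}, \code{log_marglik_isolated}, \code{log_marglik_joint},
#'   \code{method} (\code{"analytic-stationary"}), \code{degenerate}
#'   (TRUE if any underlying SIR fit was flagged degenerate), and
#'   \code{isolated_fits} (the per-condition round-1 posteriors, for
#'   diagnostics such as posterior correlations).
#' @export
compare_models <- function(datasets, shared = "w", gamma = 0.5, priors = NULL,
                           config = sir_config(), seed = NULL,
                           prior_isolated = 0.5) {
  n <- length(datasets)
  stopifnot(n >= 2)
  if (is.null(priors)) priors <- lapply(datasets, default_prior)
  seeds <- derive_seeds(seed, n + 2L * n)

  iso <- vector("list", n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    iso[[i]] <- withCallingHandlers(
      sir_sample(datasets[[i]], prior = priors[[i]], gamma = gamma,
                 config = config, seed = seeds[[i]]),
      warning = function(w) invokeRestart("muffleWarning"))
    degenerate <- degenerate || isTRUE(iso[[i]]$degenerate)
  }
  logZ_iso <- sum(vapply(iso, marginal_loglik, numeric(1)))

  # joint-model marginal likelihood for one processing order
  chain_logZ <- function(ord, seed_offset) {
    logZ <- 0
    summaries <- list()
    for (pos in seq_along(ord)) {
      i <- ord[pos]
      if (pos == 1) {
        # reuse the isolated fit: same prior, same estimator
        logZ <- logZ + marginal_loglik(iso[[i]])
        summaries <- list(fit_gamma_summary(iso[[i]]$draws[, shared], shared))
      } else {
        prod_prior <- gamma_product_prior(summaries)
        prior2 <- prior_with_shared(priors[[i]], shared, prod_prior)
        d <- datasets[[i]]
        fit <- withCallingHandlers(
          sir(log_lik = function(theta) psy_loglik_matrix(theta, gamma, d),
              propose = function(k) prior_sample_any(prior2, k),
              n_proposals = config$n_proposals, n_final = config$n_final,
              seed = seeds[[seed_offset + pos]], ess_floor = config$ess_floor),
          warning = function(w) invokeRestart("muffleWarning"))
        degenerate <<- degenerate || isTRUE(fit$degenerate)
        logZ <- logZ + marginal_loglik(fit)
        summaries <- c(summaries,
                       list(fit_gamma_summary(fit$draws[, shared], shared)))
      }
    }
    logZ
  }
  logZ_fwd <- chain_logZ(seq_len(n), n)
  logZ_rev <- chain_logZ(rev(seq_len(n)), 2L * n)
  logZ_joint <- (logZ_fwd + logZ_rev) / 2

  p <- model_posterior(logZ_iso, logZ_joint, prior_isolated)
  structure(list(p_isolated = p$p_isolated, p_joint = p$p_joint,
                 log_marglik_isolated = logZ_iso,
                 log_marglik_joint = logZ_joint,
                 method = "analytic-stationary",
                 degenerate = degenerate,
                 prior_isolated = prior_isolated,
                 isolated_fits = iso,
                 seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model comparison (%s):\n", x$method))
  cat(sprintf("  p(isolated | data) = %.4f   log Z = %.3f\n",
              x$p_isolated, x$log_marglik_isolated))
  cat(sprintf("  p(joint | data)    = %.4f   log Z = %.3f\n",
              x$p_joint, x$log_marglik_joint))
  verdict <- if (x$p_joint >= x$p_isolated)
    "the data support a shared parameter (joint model)"
  else "the data support condition-specific parameters (isolated models)"
  cat("  verdict:", verdict, "\n")
  if (isTRUE(x$degenerate))
    cat("  NOTE: at least one underlying fit was flagged degenerate;",
        "treat this comparison as low-confidence\n")
  invisible(x)
}

#' Two-state chain over the model indicator
#'
#' Simulates a collapsed Gibbs chain over the model indicator
#' (\code{isolated} vs \code{joint}): with parameters marginalised out the
#' full conditional of the indicator is the analytic posterior, so the
#' chain's stationary indicator frequency converges to
#' \code{\link{model_posterior}}'s value. Provided as a stochastic
#' cross-check of the analytic probabilities.
#'
#' @param comparison A \code{"model_comparison"}, or a list with
#'   \code{log_marglik_isolated}, \code{log_marglik_joint},
#'   \code{prior_isolated}.
#' @param n_sweeps Number of sweeps.
#' @param seed Optional seed.
#' @return List with \code{p_isolated_chain} (indicator frequency),
#'   \code{n_sweeps}, and \code{method = "gibbs-chain"}.
#' @export
model_posterior_chain <- function(comparison, n_sweeps = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pi0 <- if (!is.null(comparison$prior_isolated)) comparison$prior_isolated else 0.5
  p <- model_posterior(comparison$log_marglik_isolated,
                       comparison$log_marglik_joint, pi0)$p_isolated
  ind <- integer(n_sweeps)
  state <- 1L  # start in the isolated model
  for (s in seq_len(n_sweeps)) {
    state <- stats::rbinom(1, 1, p)  # collapsed full conditional
    ind[s] <- state
  }
  list(p_isolated_chain = mean(ind), n_sweeps = n_sweeps,
       method = "gibbs-chain")
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score, ties counted one half — the normalised rank-sum
#' statistic, a measure of separability between two score distributions.
#'
#' @param scores_pos,scores_neg Nonempty numeric vectors.
#' @return AUC in \code{[0, 1]}.
#' @examples
#' auc(c(3, 1), c(2, 0))  # 0.75
#' @export
auc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("both score vectors must be nonempty", call. = FALSE)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  n1 <- length(scores_pos)
  n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
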