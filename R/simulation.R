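# Synthetic-data generation and the two evaluation experiments:
# robustness to posterior parameter correlation, and model-selection
# sensitivity to a true width difference.

#' Sampling scheme for a simulated condition
#'
#' Six stimulus intensities and per-block trial counts. A valid scheme
#' covers the generating function's lower asymptote, rising part, and upper
#' asymptote: at least one block with \eqn{\Psi < \gamma + 0.1(1-\gamma-\lambda)},
#' one in the central rise, and one with \eqn{\Psi > 1-\lambda-0.1(1-\gamma-\lambda)}.
#'
#' @param intensities Numeric vector of stimulus intensities (typically 6).
#' @param trials_per_block Integer trial counts in \code{[20, 200]}, one per
#'   block (recycled if scalar).
#' @return List of class \code{"sampling_scheme"}.
#' @export
sampling_scheme <- function(intensities, trials_per_block) {
  trials <- rep_len(as.integer(trials_per_block), length(intensities))
  stopifnot(all(is.finite(intensities)), all(trials >= 1))
  structure(list(intensities = as.numeric(intensities),
                 trials_per_block = trials),
            class = "sampling_scheme")
}

# Does a set of intensities cover asymptotes and rising part of gen?
scheme_covers <- function(gen, intensities) {
  psi <- psy_predict(gen, intensities)
  span <- 1 - gen$gamma - gen$lam
  lo <- gen$gamma + 0.1 * span
  hi <- 1 - gen$lam - 0.1 * span
  any(psi < lo) && any(psi > lo & psi < hi) && any(psi > hi)
}

# Random scheme: 6 intensities uniform on `range`, trial counts uniform on
# trials_range, rejection-resampled until the coverage invariant holds.
random_scheme <- function(gen, n_levels = 6, range = c(0, 1),
                          trials_range = c(20, 200), max_tries = 1000) {
  for (t in seq_len(max_tries)) {
    x <- stats::runif(n_levels, range[1], range[2])
    if (scheme_covers(gen, x)) {
      ntr <- sample(seq(trials_range[1], trials_range[2]), n_levels,
                    replace = TRUE)
      return(sampling_scheme(sort(x), ntr))
    }
  }
  stop("could not draw a sampling scheme covering both asymptotes and the ",
       "rising part in ", max_tries, " tries: widen the intensity range or ",
       "check the generating parameters", call. = FALSE)
}

#' Generate a synthetic condition from a known psychometric function
#'
#' Draws \code{k ~ Binomial(n, Psi(x))} per block. With
#' \code{scheme = "random"}, six intensities are drawn uniformly on
#' \code{range} and rejection-resampled until they cover the lower
#' asymptote, the rising part and the upper asymptote of the generating
#' function, and trial counts are drawn uniformly from
#' \code{trials_range} — emulating randomly placed blocks of 20 to 200
#' trials.
#'
#' @param gen Generating \code{\link{psy_params}}.
#' @param scheme A \code{\link{sampling_scheme}} or \code{"random"}.
#' @param seed Optional integer seed (bitwise-reproducible datasets).
#' @param condition Condition label.
#' @param range,trials_range,max_tries Controls for random schemes.
#' @return A \code{\link{block_data}} object.
#' @examples
#' gen <- psy_params(0.5, 0.2, 0.02, 0.5)
#' generate_dataset(gen, seed = 1)
#' @export
generate_dataset <- function(gen, scheme = "random", seed = NULL,
                             condition = "simulated", range = c(0, 1),
                             trials_range = c(20, 200), max_tries = 1000) {
  validate_psy_params(gen)
  if (!is.null(seed)) set.seed(seed)
  if (identical(scheme, "random"))
    scheme <- random_scheme(gen, range = range, trials_range = trials_range,
                            max_tries = max_tries)
  stopifnot(inherits(scheme, "sampling_scheme"))
  p <- psy_predict(gen, scheme$intensities)
  k <- stats::rbinom(length(p), scheme$trials_per_block, p)
  block_data(scheme$intensities, k, scheme$trials_per_block,
             condition = condition)
}

#' Correlation-robustness sweep
#'
#' Generates pairs of conditions from the same psychometric function
#' (so the joint model is correct by design), fits each pair in isolation
#' and jointly, and records goodness-of-fit and posterior overlap together
#' with the posterior width–lapse correlations. Used to check that (a)
#' neither deviance nor overlap trends with the correlation magnitude and
#' (b) joint fitting shifts the overlap distribution towards larger values
#' without inflating deviance.
#'
#' @param n_pairs Number of simulated pairs.
#' @param gen Generating \code{\link{psy_params}}.
#' @param config A \code{\link{sir_config}} (reduced sizes are adequate:
#'   effects are medians over pairs).
#' @param seed Master seed; pair \code{i} uses a seed derived from it, so
#'   every record is reproducible from its own seed.
#' @param ... Passed to \code{\link{generate_dataset}}.
#' @return A \code{data.frame} of class \code{"sweep_result"} with one row
#'   per pair: \code{r1}, \code{r2} (round-1 posterior w–lam correlations),
#'   \code{d_sum_iso}, \code{d_sum_joint} (summed deviance at the posterior
#'   mean), \code{overlap_iso}, \code{overlap_joint}, \code{total_trials},
#'   \code{seed}.
#' @export
correlation_sweep <- function(n_pairs, gen = psy_params(0.5, 0.2, 0.02, 0.5),
                              config = sir_config(5000, 500), seed = NULL,
                              ...) {
  seeds <- derive_seeds(seed, max(n_pairs, 1L))
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    rows[[i]] <- tryCatch(
      sweep_pair(gen, gen, seeds[[i]], config, ...),
      error = function(e) {
        warning("pair ", i, " failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(r1 = numeric(0), r2 = numeric(0),
                      d_sum_iso = numeric(0), d_sum_joint = numeric(0),
                      overlap_iso = numeric(0), overlap_joint = numeric(0),
                      total_trials = numeric(0), seed = numeric(0))
  class(out) <- c("sweep_result", "data.frame")
  out
}

# Fit one simulated pair and measure everything the sweeps record.
sweep_pair <- function(gen1, gen2, seed, config, ...) {
  sub <- derive_seeds(seed, 3L)
  d1 <- generate_dataset(gen1, seed = sub[[1]], condition = "sim1", ...)
  d2 <- generate_dataset(gen2, seed = sub[[2]], condition = "sim2", ...)
  fit <- withCallingHandlers(
    joint_fit(list(d1, d2), config = config, seed = sub[[3]],
              gamma = gen1$gamma),
    warning = function(w) invokeRestart("muffleWarning"))
  dev_at_mean <- function(post, data) {
    mu <- colMeans(post$draws)
    psy_deviance(data, psy_params(mu["m"], mu["w"], mu["lam"], gen1$gamma))
  }
  d_iso <- deviance_sum(list(dev_at_mean(fit$isolated[[1]], d1),
                             dev_at_mean(fit$isolated[[2]], d2)))
  d_joint <- deviance_sum(list(dev_at_mean(fit$joint[[1]], d1),
                               dev_at_mean(fit$joint[[2]], d2)))
  data.frame(r1 = fit$correlations[[1]]["w", "lam"],
             r2 = fit$correlations[[2]]["w", "lam"],
             d_sum_iso = d_iso, d_sum_joint = d_joint,
             overlap_iso = posterior_overlap(fit$isolated[[1]],
                                             fit$isolated[[2]], "w"),
             overlap_joint = posterior_overlap(fit$joint[[1]],
                                               fit$joint[[2]], "w"),
             total_trials = sum(d1$n) + sum(d2$n),
             seed = if (is.null(seed)) NA_real_ else seed)
}

#' Width-difference model-selection sweep
#'
#' Generates pairs of conditions whose generating widths differ by
#' \code{delta_w}, runs isolated-vs-joint model selection on each pair, and
#' summarises, per \code{delta_w}, the distribution of the isolated models'
#' posterior probability and its AUC separability against the
#' \code{delta_w = 0} reference. Pairs with large posterior width–lapse
#' correlation (poorly constrained fits) can be filtered before the
#' summaries, as such schemes would not be tolerated in a real experiment.
#'
#' @param delta_w_grid Width differences; must include 0 (the reference).
#' @param n_pairs_per_delta Pairs per grid value.
#' @param gen Generating parameters of the first condition; the second uses
#'   \code{w + delta_w}.
#' @param config A \code{\link{sir_config}}.
#' @param seed Master seed.
#' @param cor_filter Keep only pairs with both \code{|r| <} this value in
#'   the summaries (default 0.5); \code{Inf} disables filtering.
#' @param ... Passed to \code{\link{generate_dataset}}.
#' @return List of class \code{"delta_w_sweep"}: \code{records} (one row
#'   per pair: \code{delta_w}, \code{p_isolated}, \code{r1}, \code{r2},
#'   \code{total_trials}, \code{seed}), \code{auc} (per \code{delta_w > 0}:
#'   AUC vs the reference, computed on filtered records), and
#'   \code{cor_filter}.
#' @export
delta_w_sweep <- function(delta_w_grid = c(0, 0.1, 0.2),
                          n_pairs_per_delta = 50,
                          gen = psy_params(0.5, 0.2, 0.02, 0.5),
                          config = sir_config(5000, 500), seed = NULL,
                          cor_filter = 0.5, ...) {
  if (!any(delta_w_grid == 0))
    stop("delta_w_grid must include 0 as the reference condition", call. = FALSE)
  seeds <- derive_seeds(seed, length(delta_w_grid) * n_pairs_per_delta)
  rows <- list()
  idx <- 0L
  for (dw in delta_w_grid) {
    gen2 <- psy_params(gen$m, gen$w + dw, gen$lam, gen$gamma)
    for (j in seq_len(n_pairs_per_delta)) {
      idx <- idx + 1L
      s <- seeds[[idx]]
      row <- tryCatch({
        sub <- derive_seeds(s, 3L)
        d1 <- generate_dataset(gen, seed = sub[[1]], condition = "sim1", ...)
        d2 <- generate_dataset(gen2, seed = sub[[2]], condition = "sim2", ...)
        cmp <- compare_models(list(d1, d2), gamma = gen$gamma,
                              config = config, seed = sub[[3]])
        data.frame(delta_w = dw, p_isolated = cmp$p_isolated,
                   r1 = posterior_correlation(cmp$isolated_fits[[1]]),
                   r2 = posterior_correlation(cmp$isolated_fits[[2]]),
                   total_trials = sum(d1$n) + sum(d2$n),
                   seed = if (is.null(s)) NA_real_ else s)
      }, error = function(e) {
        warning("pair failed (delta_w = ", dw, "): ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      rows[[idx]] <- row
    }
  }
  rec <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  keep <- rec[abs(rec$r1) < cor_filter & abs(rec$r2) < cor_filter, ]
  ref <- keep$p_isolated[keep$delta_w == 0]
  pos_dw <- setdiff(unique(keep$delta_w), 0)
  auc_tab <- data.frame(
    delta_w = pos_dw,
    auc = vapply(pos_dw, function(dw)
      auc(keep$p_isolated[keep$delta_w == dw], ref), numeric(1)))
  structure(list(records = rec, auc = auc_tab, cor_filter = cor_filter),
            class = "delta_w_sweep")
}

#' @export
print.delta_w_sweep <- function(x, ...) {
  med <- stats::aggregate(p_isolated ~ delta_w, data = x$records, median)
  cat("width-difference sweep (|r| filter:", x$cor_filter, ")\n")
  cat("median p(isolated) per delta_w:\n")
  print(med, row.names = FALSE)
  cat("AUC vs delta_w = 0:\n")
  print(x$auc, row.names = FALSE)
  invisible(x)
}
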