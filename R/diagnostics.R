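# Goodness-of-fit (binomial deviance) and the quartile-based overlap
# statistic for comparing posterior distributions.

#' Binomial deviance of a psychometric fit
#'
#' Deviance of a condition's blocks under given parameters:
#' \deqn{D = 2 \sum_j [k_j \ln(k_j / (n_j p_j)) +
#'   (n_j - k_j) \ln((n_j - k_j) / (n_j (1 - p_j)))]}
#' with \eqn{p_j} the model prediction at block \eqn{j} and the convention
#' \eqn{0 \ln 0 = 0}. Signed deviance residuals are
#' \eqn{\mathrm{sign}(k/n - p) \sqrt{d_j}}.
#'
#' @param data A \code{\link{block_data}} object.
#' @param params A \code{\link{psy_params}} object.
#' @return Object of class \code{"deviance_report"}: list with
#'   \code{residuals} (signed, one per block), \code{deviance} (total
#'   \eqn{D \ge 0}), \code{condition}.
#' @examples
#' d <- block_data(c(0.3, 0.5, 0.7), k = c(28, 38, 46), n = rep(50, 3))
#' psy_deviance(d, psy_params(0.5, 0.2, 0.02, 0.5))
#' @export
psy_deviance <- function(data, params) {
  validate_block_data(data)
  p <- psy_predict(params, data$intensity)
  d <- deviance_terms(data$k, data$n, p)
  res <- sign(data$k / data$n - p) * sqrt(pmax(d, 0))
  structure(list(residuals = res, deviance = sum(d),
                 condition = attr(data, "condition")),
            class = "deviance_report")
}

# per-block deviance contributions, 0*log(0) = 0 convention;
# p = 0 or 1 with contradicting counts yields Inf
deviance_terms <- function(k, n, p) {
  t1 <- ifelse(k > 0, k * log(k / (n * p)), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log((n - k) / (n * (1 - p))), 0)
  2 * (t1 + t2)
}

#' @export
print.deviance_report <- function(x, ...) {
  cat(sprintf("deviance D = %.4f over %d blocks (%s)\n",
              x$deviance, length(x$residuals), x$condition))
  invisible(x)
}

#' Summed deviance over conditions
#'
#' Deviance is additive over blocks and over conditions; this sums the
#' per-condition deviances of a list of fits.
#'
#' @param reports List of \code{"deviance_report"} objects.
#' @return Scalar summed deviance.
#' @export
deviance_sum <- function(reports) {
  sum(vapply(reports, function(r) r$deviance, numeric(1)))
}

#' Quartile-based overlap statistic
#'
#' An index of agreement between two distributions computed from their
#' first and third quartiles:
#' \deqn{q = \frac{\min(Q^A_3, Q^B_3) - \max(Q^A_1, Q^B_1)}
#'              {\max(Q^A_3, Q^B_3) - \min(Q^A_1, Q^B_1)}}
#' It equals 1 when both quartile pairs coincide, is positive when the
#' interquartile ranges partly overlap, 0 when one interquartile range
#' starts exactly where the other ends, and decreases towards a limit of
#' \eqn{-1} as the distributions are moved arbitrarily far apart.
#'
#' @param a,b Length-2 numeric vectors \code{c(q1, q3)} giving the first and
#'   third quartile of each distribution.
#' @return Scalar overlap score in \code{(-1, 1]}.
#' @examples
#' overlap_stat(c(1, 3), c(1, 3))  # 1: coinciding quartiles
#' overlap_stat(c(1, 2), c(2, 3))  # 0: abutting interquartile ranges
#' overlap_stat(c(0, 1), c(1e6, 1e6 + 1))  # close to -1
#' @export
overlap_stat <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2, all(is.finite(c(a, b))))
  if (a[1] > a[2] || b[1] > b[2])
    stop("each quartile pair must satisfy q1 <= q3", call. = FALSE)
  denom <- max(a[2], b[2]) - min(a[1], b[1])
  if (denom == 0) return(1)  # all four quartiles coincide in a point
  (min(a[2], b[2]) - max(a[1], b[1])) / denom
}

#' Overlap of two posterior marginals
#'
#' Extracts the first and third quartiles (linear interpolation of order
#' statistics, quantile type 7) of the named parameter's draws in two
#' posteriors and evaluates \code{\link{overlap_stat}}.
#'
#' @param a,b \code{"sir_posterior"} objects (or plain draw vectors).
#' @param param Parameter name, a column of the draw matrices.
#' @return Scalar overlap score.
#' @export
posterior_overlap <- function(a, b, param = "w") {
  qa <- marginal_quartiles(a, param)
  qb <- marginal_quartiles(b, param)
  overlap_stat(qa, qb)
}

marginal_quartiles <- function(post, param) {
  x <- marginal_draws(post, param)
  if (length(x) < 4) stop("need at least 4 draws to estimate quartiles", call. = FALSE)
  unname(stats::quantile(x, c(0.25, 0.75), type = 7))
}

marginal_draws <- function(post, param) {
  if (inherits(post, "sir_posterior")) {
    if (!is.matrix(post$draws) || !(param %in% colnames(post$draws)))
      stop("posterior has no parameter '", param, "'", call. = FALSE)
    post$draws[, param]
  } else as.numeric(post)
}

#' Posterior correlation between two parameters
#'
#' Pearson correlation of the two marginal draw vectors of one posterior;
#' used to check the a-posteriori-independence assumption behind joint
#' inference (typically between width and lapse rate).
#'
#' @param post A \code{"sir_posterior"}.
#' @param p1,p2 Parameter names.
#' @return Correlation in \code{[-1, 1]}.
#' @export
posterior_correlation <- function(post, p1 = "w", p2 = "lam") {
  x <- marginal_draws(post, p1)
  y <- marginal_draws(post, p2)
  if (length(x) < 3) stop("need at least 3 draws", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a marginal: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}
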