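# Psychometric function core: parameter container, sigmoid, likelihood.

# Scaling constant making `w` the exact 10%-90% rise interval of the
# logistic core: F(m + w/2) = 0.9 and F(m - w/2) = 0.1.
Z_WIDTH <- 2 * log(9)

#' Psychometric function parameters
#'
#' Container for the parameters of a psychometric (dose-rate) function with
#' asymptotes: threshold \code{m}, width \code{w}, lapse rate \code{lam} and
#' guess rate \code{gamma}.
#'
#' @param m Threshold: stimulus intensity at which performance is halfway
#'   between the lower asymptote \code{gamma} and the upper asymptote
#'   \code{1 - lam}.
#' @param w Width: the range of intensities over which the function rises
#'   from 10\% above the lower asymptote to 10\% below the upper asymptote.
#'   Inversely related to slope; must be strictly positive.
#' @param lam Lapse rate: shortfall of the upper asymptote below 1, i.e. the
#'   probability of an error even at maximal intensity. In \code{[0, 1)}.
#' @param gamma Guess rate: the lower asymptote, fixed by the experimental
#'   design (0.5 for a two-alternative forced-choice task). In \code{[0, 1)}.
#'
#' @return An object of class \code{"psy_params"}.
#' @examples
#' p <- psy_params(m = 0.5, w = 0.2, lam = 0.02, gamma = 0.5)
#' psy_predict(p, c(0.3, 0.5, 0.7))
#' @export
psy_params <- function(m, w, lam = 0, gamma = 0.5) {
  p <- structure(list(m = as.numeric(m), w = as.numeric(w),
                      lam = as.numeric(lam), gamma = as.numeric(gamma)),
                 class = "psy_params")
  validate_psy_params(p)
  p
}

validate_psy_params <- function(p) {
  for (f in c("m", "w", "lam", "gamma")) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (p$w <= 0) stop("width 'w' must be strictly positive", call. = FALSE)
  if (p$lam < 0 || p$lam >= 1) stop("lapse rate 'lam' must lie in [0, 1)", call. = FALSE)
  if (p$gamma < 0 || p$gamma >= 1) stop("guess rate 'gamma' must lie in [0, 1)", call. = FALSE)
  if (p$gamma + p$lam >= 1)
    stop("'gamma' + 'lam' must be < 1 (asymptotes must not cross)", call. = FALSE)
  invisible(p)
}

#' @export
print.psy_params <- function(x, ...) {
  cat(sprintf("psychometric parameters: m = %g, w = %g, lam = %g, gamma = %g\n",
              x$m, x$w, x$lam, x$gamma))
  invisible(x)
}

# logistic core scaled so that w is the 10%-90% rise interval
psy_sigmoid <- function(x, m, w) {
  stats::plogis(Z_WIDTH * (x - m) / w)
}

#' Evaluate the psychometric function
#'
#' Computes the probability of a correct response at the given stimulus
#' intensities: \code{gamma + (1 - gamma - lam) * F(x; m, w)} where \code{F}
#' is a logistic sigmoid scaled so that \code{w} spans the rise from
#' \code{F = 0.1} to \code{F = 0.9}.
#'
#' @param params A \code{\link{psy_params}} object.
#' @param x Numeric vector of stimulus intensities.
#' @return Vector of success probabilities in \code{[gamma, 1 - lam]}.
#' @export
psy_predict <- function(params, x) {
  validate_psy_params(params)
  params$gamma + (1 - params$gamma - params$lam) * psy_sigmoid(x, params$m, params$w)
}

# Vectorised over parameter draws: m, w, lam vectors, x a vector of
# intensities; returns a length(m) x length(x) matrix of probabilities.
psy_predict_matrix <- function(m, w, lam, gamma, x) {
  eta <- (matrix(x, nrow = length(m), ncol = length(x), byrow = TRUE) - m) / w
  gamma + (1 - gamma - lam) * stats::plogis(Z_WIDTH * eta)
}

#' Block data for one experimental condition
#'
#' A condition's data are blocks of binomial counts: at each stimulus
#' intensity, \code{k} correct responses out of \code{n} trials.
#'
#' @param intensity Numeric vector of stimulus intensities (finite).
#' @param k Integer vector of correct-response counts, \code{0 <= k <= n}.
#' @param n Integer vector of trial counts, \code{n >= 1}.
#' @param condition Label for the condition.
#' @return An object of class \code{"block_data"}: a data frame with columns
#'   \code{intensity}, \code{k}, \code{n} and attribute \code{condition}.
#' @examples
#' block_data(c(0.2, 0.5, 0.8), k = c(21, 32, 45), n = c(50, 50, 50))
#' @export
block_data <- function(intensity, k, n, condition = "condition") {
  d <- data.frame(intensity = as.numeric(intensity),
                  k = as.numeric(k), n = as.numeric(n))
  attr(d, "condition") <- as.character(condition)
  class(d) <- c("block_data", "data.frame")
  validate_block_data(d)
  d
}

validate_block_data <- function(d) {
  if (nrow(d) < 3L)
    stop("a condition needs at least 3 blocks", call. = FALSE)
  if (any(!is.finite(d$intensity)))
    stop("intensities must be finite", call. = FALSE)
  bad <- which(d$n < 1 | d$k < 0 | d$k > d$n | d$n != round(d$n) | d$k != round(d$k))
  if (length(bad))
    stop("invalid counts in row(s) ", paste(bad, collapse = ", "),
         ": need integer 0 <= k <= n with n >= 1", call. = FALSE)
  invisible(d)
}

#' Binomial log-likelihood of a psychometric fit
#'
#' Sum over blocks of the binomial log probability of \code{k} successes in
#' \code{n} trials with success probability \code{psy_predict(params, x)}.
#' Returns \code{-Inf} (never an error) when a block's predicted probability
#' is exactly 0 or 1 but its counts contradict it.
#'
#' @param params A \code{\link{psy_params}} object.
#' @param data A \code{\link{block_data}} object.
#' @return Scalar log-likelihood.
#' @export
psy_loglik <- function(params, data) {
  validate_block_data(data)
  p <- psy_predict(params, data$intensity)
  sum(stats::dbinom(data$k, data$n, p, log = TRUE))
}

# Vectorised log-likelihood over parameter draws (columns m, w, lam).
psy_loglik_matrix <- function(theta, gamma, data) {
  P <- psy_predict_matrix(theta[, "m"], theta[, "w"], theta[, "lam"], gamma,
                          data$intensity)
  ll <- matrix(0, nrow(P), ncol(P))
  for (j in seq_along(data$intensity)) {
    ll[, j] <- stats::dbinom(data$k[j], data$n[j], P[, j], log = TRUE)
  }
  rowSums(ll)
}
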