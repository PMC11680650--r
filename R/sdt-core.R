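#' Hit and false-alarm rates from sensitivity and criterion
#'
#' Maps latent Gaussian signal-detection parameters to response rates.  The
#' signal distribution is centred at \code{+d/2} with standard deviation
#' \code{sigma_s}; the noise distribution at \code{-d/2} with standard
#' deviation \code{sigma_n} (conventionally fixed at 1).  The criterion
#' \code{c} is the deviation of the response threshold from the midpoint
#' between the two means, so
#' \deqn{\theta^h = \Phi[(d/2 - c)/\sigma_s], \quad
#'       \theta^f = \Phi[(-d/2 - c)/\sigma_n].}
#'
#' @param d numeric vector of sensitivities (z-units; may be negative).
#' @param c numeric vector of criteria (z-units).
#' @param sigma_s signal standard deviation(s), positive; recycled against
#'   \code{d}.
#' @param sigma_n noise standard deviation, positive (default 1).
#' @return data.frame with columns \code{theta_h}, \code{theta_f}, both
#'   strictly inside (0, 1).
#' @seealso [paramsFromRates()] for the exact inverse.
#' @export
ratesFromParams <- function(d, c, sigma_s = 1, sigma_n = 1) {
  stopifnot(is.numeric(d), is.numeric(c), length(d) == length(c))
  if (any(!is.finite(sigma_s)) || any(sigma_s <= 0))
    stop("'sigma_s' must be positive")
  if (any(!is.finite(sigma_n)) || any(sigma_n <= 0))
    stop("'sigma_n' must be positive")
  data.frame(theta_h = stats::pnorm((0.5 * d - c) / sigma_s),
             theta_f = stats::pnorm((-0.5 * d - c) / sigma_n))
}

#' Sensitivity and criterion from hit and false-alarm rates
#'
#' Exact inverse of [ratesFromParams()] for matching scales:
#' \deqn{d = \sigma_s z(\theta^h) - \sigma_n z(\theta^f), \quad
#'       c = -\tfrac{1}{2}[\sigma_s z(\theta^h) + \sigma_n z(\theta^f)]}
#' where \eqn{z} is the standard-normal quantile function.  Rates of exactly
#' 0 or 1 are rejected rather than corrected: the edge-stabilising rate
#' correction lives in [zrateMoments()] so the policy has one documented home.
#'
#' @param theta_h,theta_f numeric vectors of rates, strictly in (0, 1).
#' @inheritParams ratesFromParams
#' @return data.frame with columns \code{d}, \code{c}.
#' @export
paramsFromRates <- function(theta_h, theta_f, sigma_s = 1, sigma_n = 1) {
  stopifnot(length(theta_h) == length(theta_f))
  if (any(theta_h <= 0 | theta_h >= 1 | theta_f <= 0 | theta_f >= 1))
    stop("rates must lie strictly inside (0, 1); no edge correction is applied here")
  if (any(sigma_s <= 0) || any(sigma_n <= 0))
    stop("scales must be positive")
  zh <- stats::qnorm(theta_h)
  zf <- stats::qnorm(theta_f)
  data.frame(d = sigma_s * zh - sigma_n * zf,
             c = -0.5 * (sigma_s * zh + sigma_n * zf))
}

#' Population-parameter container
#'
#' Bundles the five population parameters of the unequal-variance model:
#' mean sensitivity \code{mu_d}, mean criterion \code{mu_c}, their population
#' standard deviations \code{sigma_d} and \code{sigma_c} (reciprocal square
#' roots of the precisions \eqn{\lambda_d, \lambda_c}), and the signal
#' standard deviation \code{sigma_s}.  The noise SD is the fixed unit of the
#' latent axis, \code{sigma_n = 1}.
#'
#' @param mu_d,mu_c population means of sensitivity and criterion.
#' @param sigma_d,sigma_c positive population SDs.
#' @param sigma_s positive signal SD (1 recovers the equal-variance model).
#' @return object of class \code{"populationParams"}.
#' @export
populationParams <- function(mu_d, mu_c, sigma_d, sigma_c, sigma_s = 1) {
  stopifnot(is.finite(mu_d), is.finite(mu_c))
  if (sigma_d < 0 || sigma_c < 0)
    stop("'sigma_d' and 'sigma_c' must be non-negative")
  if (!is.finite(sigma_s) || sigma_s <= 0)
    stop("'sigma_s' must be positive")
  structure(list(mu_d = mu_d, mu_c = mu_c, sigma_d = sigma_d,
                 sigma_c = sigma_c, sigma_s = sigma_s, sigma_n = 1),
            class = "populationParams")
}

#' @export
print.populationParams <- function(x, ...) {
  cat("Population parameters (noise SD fixed at 1):\n")
  print(round(unlist(x[c("mu_d", "mu_c", "sigma_d", "sigma_c", "sigma_s")]), 4))
  invisible(x)
}

#' Moment summary of z-transformed rates
#'
#' Container for the first and second moments of the bivariate distribution
#' of \eqn{(z(\theta^h), z(\theta^f))} across participants — the five
#' observable quantities that identify the five population parameters.
#'
#' @param mean_zh,mean_zf means of the z-transformed hit / false-alarm rates.
#' @param var_zh,var_zf their variances (non-negative).
#' @param cov_zhzf their covariance; must satisfy
#'   \code{cov_zhzf^2 <= var_zh * var_zf}.
#' @param n number of participants the moments were computed from
#'   (\code{NA} for model-implied moments).
#' @return object of class \code{"momentSummary"}.
#' @export
momentSummary <- function(mean_zh, mean_zf, var_zh, var_zf, cov_zhzf, n = NA_integer_) {
  if (var_zh < 0 || var_zf < 0)
    stop("variances must be non-negative")
  if (cov_zhzf^2 > var_zh * var_zf * (1 + 1e-8))
    stop("covariance inconsistent with variances (|correlation| > 1)")
  if (!is.na(n) && n < 2) stop("'n' must be at least 2")
  structure(list(mean_zh = mean_zh, mean_zf = mean_zf, var_zh = var_zh,
                 var_zf = var_zf, cov_zhzf = cov_zhzf, n = n),
            class = "momentSummary")
}

#' @export
print.momentSummary <- function(x, ...) {
  cat("Moments of z-transformed (hit, false-alarm) rates",
      if (is.na(x$n)) "(model-implied)" else sprintf("(n = %d)", x$n), "\n")
  print(round(unlist(x[c("mean_zh", "mean_zf", "var_zh", "var_zf", "cov_zhzf")]), 4))
  invisible(x)
}

#' Model-implied moments of z-transformed rates
#'
#' Under the hierarchical unequal-variance model with independent normal
#' sensitivity and criterion, the z-transformed hit and false-alarm rates are
#' bivariate normal with
#' \deqn{E[z^h] = (\mu_d/2 - \mu_c)/\sigma_s, \quad E[z^f] = -\mu_d/2 - \mu_c,}
#' \deqn{Var[z^h] = (\sigma_c^2 + \sigma_d^2/4)/\sigma_s^2, \quad
#'       Var[z^f] = \sigma_c^2 + \sigma_d^2/4,}
#' \deqn{Cov[z^h, z^f] = (\sigma_c^2 - \sigma_d^2/4)/\sigma_s.}
#' The ratio \eqn{Var[z^f]/Var[z^h] = \sigma_s^2} is what makes the signal
#' SD identifiable from binary data at the population level.
#'
#' @param pop a [populationParams()] object.
#' @return a [momentSummary()] with \code{n = NA}.
#' @export
momentMap <- function(pop) {
  stopifnot(inherits(pop, "populationParams"))
  v <- pop$sigma_c^2 + pop$sigma_d^2 / 4       # Var of z(theta_f)
  momentSummary(
    mean_zh  = (pop$mu_d / 2 - pop$mu_c) / pop$sigma_s,
    mean_zf  = -pop$mu_d / 2 - pop$mu_c,
    var_zh   = v / pop$sigma_s^2,
    var_zf   = v,
    cov_zhzf = (pop$sigma_c^2 - pop$sigma_d^2 / 4) / pop$sigma_s)
}

#' Closed-form moment estimator of the population parameters
#'
#' Inverts [momentMap()]: given (empirical or model-implied) moments of the
#' z-transformed rates, recovers the five population parameters,
#' \deqn{\sigma_s = \sqrt{Var[z^f]/Var[z^h]},}
#' \deqn{\sigma_c^2 = (Var[z^f] + \sigma_s Cov)/2, \quad
#'       \sigma_d^2 = 2 (Var[z^f] - \sigma_s Cov),}
#' \deqn{\mu_d = \sigma_s E[z^h] - E[z^f], \quad
#'       \mu_c = -(\sigma_s E[z^h] + E[z^f])/2.}
#' \code{momentEstimate(momentMap(p))} is the identity.  With sampling noise
#' the implied variances can turn non-positive, in which case an error
#' reports the offending quantity.
#'
#' @param m a [momentSummary()].
#' @return a [populationParams()] object.
#' @export
momentEstimate <- function(m) {
  stopifnot(inherits(m, "momentSummary"))
  if (m$var_zh <= 0) stop("moment estimation failed: var_zh = ", m$var_zh,
                          " is not positive")
  sigma_s <- sqrt(m$var_zf / m$var_zh)
  sc2 <- (m$var_zf + sigma_s * m$cov_zhzf) / 2
  sd2 <- 2 * (m$var_zf - sigma_s * m$cov_zhzf)
  if (sc2 < 0) stop("moment estimation failed: implied sigma_c^2 = ", sc2)
  if (sd2 < 0) stop("moment estimation failed: implied sigma_d^2 = ", sd2)
  populationParams(mu_d = sigma_s * m$mean_zh - m$mean_zf,
                   mu_c = -0.5 * (sigma_s * m$mean_zh + m$mean_zf),
                   sigma_d = sqrt(sd2), sigma_c = sqrt(sc2),
                   sigma_s = sigma_s)
}

#' Empirical moments of z-transformed rates from count data
#'
#' Computes observed hit/false-alarm rates, applies the edge-stabilising
#' correction \eqn{(h + 1/2)/(s + 1)} (and likewise for false alarms) so the
#' z-transform stays finite when a participant scores 0 or the maximum, and
#' returns unbiased (n-1 denominator) sample moments.  The Bayesian models
#' need no such correction (the rates are latent there); this preprocessing
#' exists for the closed-form [momentEstimate()].
#'
#' @param counts a counts data.frame (see [validateCounts()]).
#' @param edge_correct apply the (h + 0.5)/(s + 1) correction (default TRUE).
#'   With \code{FALSE}, boundary rates raise an error.
#' @return a [momentSummary()] with \code{n} set.
#' @export
zrateMoments <- function(counts, edge_correct = TRUE) {
  counts <- validateCounts(counts)
  if (nrow(counts) < 2) stop("need at least 2 participants")
  if (edge_correct) {
    th <- (counts$hits + 0.5) / (counts$signal_trials + 1)
    tf <- (counts$false_alarms + 0.5) / (counts$noise_trials + 1)
  } else {
    th <- counts$hits / counts$signal_trials
    tf <- counts$false_alarms / counts$noise_trials
    if (any(th <= 0 | th >= 1 | tf <= 0 | tf >= 1))
      stop("boundary rates present; use edge_correct = TRUE")
  }
  zh <- stats::qnorm(th)
  zf <- stats::qnorm(tf)
  momentSummary(mean_zh = mean(zh), mean_zf = mean(zf),
                var_zh = stats::var(zh), var_zf = stats::var(zf),
                cov_zhzf = stats::cov(zh, zf), n = nrow(counts))
}

#' z-ROC line implied by population parameters
#'
#' In z-coordinates the unequal-variance ROC is the line
#' \eqn{z(\theta^h) = z(\theta^f)/\sigma_s + \mu_d/\sigma_s}: slope
#' \eqn{1/\sigma_s}, y-intercept \eqn{\mu_d/\sigma_s}, x-intercept
#' \eqn{-\mu_d}.  A slope below 1 indicates a signal distribution wider than
#' the noise distribution.
#'
#' @param mu_d population mean sensitivity.
#' @param sigma_s positive signal SD.
#' @return named numeric vector \code{c(slope, intercept, x_intercept)}.
#' @export
zrocLine <- function(mu_d, sigma_s) {
  if (!is.finite(sigma_s) || sigma_s <= 0) stop("'sigma_s' must be positive")
  c(slope = 1 / sigma_s, intercept = mu_d / sigma_s, x_intercept = -mu_d)
}

#' ROC curve in probability coordinates
#'
#' Maps the z-ROC line back through the Gaussian CDF:
#' \eqn{\theta^h = \Phi[(z(\theta^f) + \mu_d)/\sigma_s]}, evaluated on a
#' grid of false-alarm rates.
#'
#' @inheritParams zrocLine
#' @param theta_f grid of false-alarm rates, strictly in (0, 1).
#' @return data.frame with columns \code{theta_f}, \code{theta_h}, monotone
#'   nondecreasing in \code{theta_f}.
#' @export
rocCurve <- function(mu_d, sigma_s, theta_f = seq(0.001, 0.999, length.out = 199)) {
  if (!is.finite(sigma_s) || sigma_s <= 0) stop("'sigma_s' must be positive")
  if (any(theta_f <= 0 | theta_f >= 1))
    stop("'theta_f' grid must lie strictly inside (0, 1)")
  data.frame(theta_f = theta_f,
             theta_h = stats::pnorm((stats::qnorm(theta_f) + mu_d) / sigma_s))
}

#' Area under the ROC curve
#'
#' For Gaussian signal/noise distributions separated by \code{mu_d} with SDs
#' \code{sigma_s} and 1, the area under the ROC is
#' \eqn{\Phi(\mu_d/\sqrt{1 + \sigma_s^2})} — the probability that a random
#' signal-trial strength exceeds a random noise-trial strength.
#'
#' @inheritParams zrocLine
#' @return scalar in (0, 1).
#' @export
sdtAUC <- function(mu_d, sigma_s) {
  if (!is.finite(sigma_s) || sigma_s <= 0) stop("'sigma_s' must be positive")
  stats::pnorm(mu_d / sqrt(1 + sigma_s^2))
}
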