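# Model specification and joint log-posterior for the hierarchical
# signal-detection variants.  All densities are computed on the log scale;
# out-of-support states evaluate to -Inf rather than erroring.

# Rates implied by extreme latent states can underflow to exactly 0/1; the
# likelihood clamps them to keep early MCMC iterations finite.  The bound is
# far below any probability the data can resolve, so it introduces no
# measurable bias.
.RATE_EPS <- 1e-12

#' Specify a hierarchical signal-detection model
#'
#' Three variants are supported:
#' \describe{
#'   \item{huvsd}{unequal variance: five population parameters
#'     (\eqn{\mu_d, \mu_c, \lambda_d, \lambda_c, \sigma_s}), precisions with
#'     gamma(0.5, 0.5) priors, signal variance \eqn{\sigma_s^2} with a
#'     normal(1, 2) prior truncated to \eqn{(0, \infty)} by default.}
#'   \item{hevsd}{equal variance (\eqn{\sigma_s = 1} fixed), four population
#'     parameters; precision prior defaults to gamma(0.5, 0.5) for
#'     comparability with huvsd (gamma(0.1, 0.1) selectable).}
#'   \item{hevsd_expanded}{linearly expanded equal-variance model:
#'     \eqn{d_i = \mu_d + \xi_d \delta^d_i} with auxiliary scale factors
#'     \eqn{\xi_d, \xi_c \sim} beta(1, 1) and precision priors
#'     gamma(0.1, 0.1) on the deviations' precisions.}
#' }
#' The population-mean priors are normal with mean 0 and variance
#' \code{mu_prior_var} (default 1000, i.e. precision 0.001 in BUGS
#' convention — a weakly informative prior).
#'
#' @param variant model variant.
#' @param prior_sigma_s prior family for the signal variance
#'   \eqn{\sigma_s^2} (huvsd only): truncated normal (default),
#'   gamma(0.5, 0.5), or uniform(0, 5).
#' @param truncnorm_spread whether the truncated-normal prior's second
#'   parameter 2 is a variance (default) or an SD.
#' @param precision_prior length-2 shape/rate for the gamma priors on
#'   \eqn{\lambda_d, \lambda_c}; \code{NULL} uses the variant default.
#' @param mu_prior_var variance of the normal priors on \eqn{\mu_d, \mu_c}.
#' @return object of class \code{"modelSpec"}.
#' @export
modelSpec <- function(variant = c("huvsd", "hevsd", "hevsd_expanded"),
                      prior_sigma_s = c("truncnorm", "gamma", "uniform"),
                      truncnorm_spread = c("variance", "sd"),
                      precision_prior = NULL,
                      mu_prior_var = 1000) {
  variant <- match.arg(variant)
  prior_sigma_s <- match.arg(prior_sigma_s)
  truncnorm_spread <- match.arg(truncnorm_spread)
  if (is.null(precision_prior))
    precision_prior <- if (variant == "hevsd_expanded") c(0.1, 0.1) else c(0.5, 0.5)
  stopifnot(length(precision_prior) == 2, all(precision_prior > 0),
            mu_prior_var > 0)
  structure(list(variant = variant,
                 prior_sigma_s = prior_sigma_s,
                 truncnorm_sd = if (truncnorm_spread == "variance") sqrt(2) else 2,
                 precision_prior = precision_prior,
                 mu_prior_var = mu_prior_var),
            class = "modelSpec")
}

#' @export
print.modelSpec <- function(x, ...) {
  cat("Hierarchical SDT model:", x$variant, "\n")
  cat(sprintf("  mu priors: N(0, %g); precision priors: gamma(%g, %g)\n",
              x$mu_prior_var, x$precision_prior[1], x$precision_prior[2]))
  if (x$variant == "huvsd")
    cat("  sigma_s^2 prior:", x$prior_sigma_s,
        if (x$prior_sigma_s == "truncnorm")
          sprintf("N(1, sd = %.3f) I(0, Inf)", x$truncnorm_sd) else "", "\n")
  invisible(x)
}

#' Construct a latent state for density evaluation
#'
#' Bundles the per-participant parameters (\code{d}, \code{c}) with the
#' population-level parameters.  Precisions \eqn{\lambda} are the
#' authoritative representation; SDs are derived views.  For the expanded
#' equal-variance variant, supply \code{xi_d}, \code{xi_c},
#' \code{delta_d}, \code{delta_c}; \code{d} and \code{c} are then derived as
#' \eqn{\mu + \xi \delta} and must not be supplied separately.
#'
#' @param d,c numeric vectors of per-participant sensitivity / criterion.
#' @param mu_d,mu_c population means.
#' @param lambda_d,lambda_c positive precisions of the population normals.
#' @param sigma_s signal SD (must be 1 for equal-variance variants).
#' @param xi_d,xi_c,delta_d,delta_c expanded-parameterisation components.
#' @return object of class \code{"latentState"}.
#' @export
latentState <- function(d = NULL, c = NULL, mu_d, mu_c, lambda_d, lambda_c,
                        sigma_s = 1, xi_d = NULL, xi_c = NULL,
                        delta_d = NULL, delta_c = NULL) {
  expanded <- !is.null(xi_d)
  if (expanded) {
    stopifnot(!is.null(xi_c), !is.null(delta_d), !is.null(delta_c),
              is.null(d), is.null(c),
              length(delta_d) == length(delta_c))
    d <- mu_d + xi_d * delta_d
    c <- mu_c + xi_c * delta_c
  }
  stopifnot(is.numeric(d), is.numeric(c), length(d) == length(c))
  structure(list(d = d, c = c, mu_d = mu_d, mu_c = mu_c,
                 lambda_d = lambda_d, lambda_c = lambda_c, sigma_s = sigma_s,
                 xi_d = xi_d, xi_c = xi_c,
                 delta_d = delta_d, delta_c = delta_c,
                 expanded = expanded),
            class = "latentState")
}

# clamped response probabilities for a state
.stateRates <- function(state) {
  th <- stats::pnorm((0.5 * state$d - state$c) / state$sigma_s)
  tf <- stats::pnorm(-0.5 * state$d - state$c)
  list(theta_h = pmin(pmax(th, .RATE_EPS), 1 - .RATE_EPS),
       theta_f = pmin(pmax(tf, .RATE_EPS), 1 - .RATE_EPS))
}

#' Binomial log-likelihood of a latent state
#'
#' Each participant contributes two independent binomial terms: hits out of
#' signal trials at rate \eqn{\theta^h_i} and false alarms out of noise
#' trials at rate \eqn{\theta^f_i}, with the rates computed from
#' \eqn{(d_i, c_i, \sigma_s)} via the Gaussian model.  Rates are clamped to
#' \eqn{[10^{-12}, 1 - 10^{-12}]} so the value is finite for any valid state.
#'
#' @param counts counts data.frame (see [validateCounts()]).
#' @param state a [latentState()] whose vectors match \code{nrow(counts)}.
#' @return scalar log-likelihood.
#' @export
logLikelihood <- function(counts, state) {
  counts <- validateCounts(counts, allow_zero_trials = TRUE)
  if (length(state$d) != nrow(counts))
    stop("state dimension (", length(state$d),
         ") does not match participant count (", nrow(counts), ")")
  r <- .stateRates(state)
  sum(stats::dbinom(counts$hits, counts$signal_trials, r$theta_h, log = TRUE)) +
    sum(stats::dbinom(counts$false_alarms, counts$noise_trials, r$theta_f,
                      log = TRUE))
}

# log density of the sigma_s^2 prior evaluated through sigma_s, including
# the change-of-variables Jacobian d(sigma_s^2)/d(sigma_s) = 2 sigma_s.
# The truncation normalising constant is a parameter-free additive constant
# and is omitted.
.logPriorSigmaS <- function(sigma_s, spec) {
  if (!is.finite(sigma_s) || sigma_s <= 0) return(-Inf)
  s2 <- sigma_s^2
  base <- switch(spec$prior_sigma_s,
    truncnorm = stats::dnorm(s2, mean = 1, sd = spec$truncnorm_sd, log = TRUE),
    gamma     = stats::dgamma(s2, shape = 0.5, rate = 0.5, log = TRUE),
    uniform   = stats::dunif(s2, 0, 5, log = TRUE))
  base + log(2 * sigma_s)
}

#' Joint log-prior of a latent state
#'
#' Sums the population-normal log-densities of the individual parameters,
#' the hyperpriors on the population means and precisions, and (for the
#' unequal-variance variant) the signal-variance prior evaluated through
#' \eqn{\sigma_s} with its change-of-variables Jacobian.  Out-of-support
#' states return \code{-Inf}.
#'
#' @inheritParams logLikelihood
#' @param spec a [modelSpec()].
#' @return scalar log-prior (possibly \code{-Inf}).
#' @export
logPrior <- function(state, spec) {
  stopifnot(inherits(state, "latentState"), inherits(spec, "modelSpec"))
  if (spec$variant == "huvsd") {
    if (state$sigma_s <= 0 || !is.finite(state$sigma_s)) return(-Inf)
  } else if (state$sigma_s != 1) {
    stop("equal-variance variants require sigma_s = 1")
  }
  if (state$lambda_d <= 0 || state$lambda_c <= 0) return(-Inf)
  a <- spec$precision_prior[1]; b <- spec$precision_prior[2]
  mu_sd <- sqrt(spec$mu_prior_var)
  lp <- stats::dnorm(state$mu_d, 0, mu_sd, log = TRUE) +
        stats::dnorm(state$mu_c, 0, mu_sd, log = TRUE) +
        stats::dgamma(state$lambda_d, shape = a, rate = b, log = TRUE) +
        stats::dgamma(state$lambda_c, shape = a, rate = b, log = TRUE)
  if (spec$variant == "hevsd_expanded") {
    if (!state$expanded)
      stop("hevsd_expanded requires xi/delta components in the state")
    if (state$xi_d <= 0 || state$xi_d >= 1 || state$xi_c <= 0 || state$xi_c >= 1)
      return(-Inf)                                   # beta(1,1) support
    lp <- lp +
      sum(stats::dnorm(state$delta_d, 0, 1 / sqrt(state$lambda_d), log = TRUE)) +
      sum(stats::dnorm(state$delta_c, 0, 1 / sqrt(state$lambda_c), log = TRUE))
  } else {
    lp <- lp +
      sum(stats::dnorm(state$d, state$mu_d, 1 / sqrt(state$lambda_d), log = TRUE)) +
      sum(stats::dnorm(state$c, state$mu_c, 1 / sqrt(state$lambda_c), log = TRUE))
    if (spec$variant == "huvsd")
      lp <- lp + .logPriorSigmaS(state$sigma_s, spec)
  }
  lp
}

#' Joint log-posterior (unnormalised)
#'
#' Sum of [logLikelihood()] and [logPrior()]; \code{-Inf} propagates from
#' out-of-support states.
#'
#' @inheritParams logLikelihood
#' @inheritParams logPrior
#' @return scalar log-posterior density (up to the model evidence).
#' @export
logPosterior <- function(counts, state, spec) {
  lp <- logPrior(state, spec)
  if (!is.finite(lp)) return(lp)
  lp + logLikelihood(counts, state)
}
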