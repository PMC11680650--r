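# Metropolis-within-Gibbs posterior sampler for the hierarchical
# signal-detection models, plus convergence diagnostics and information
# criteria.  The conjugate hyperparameter blocks (mu | d, lambda and
# lambda | d, mu) are updated by exact Gibbs draws; the per-participant
# (d_i, c_i) pairs by a vectorised joint random-walk Metropolis step with
# per-participant adaptive scales; sigma_s by a scalar adaptive random walk.
# Adaptation (Robbins-Monro on the log proposal scale, targets 0.23 for the
# bivariate block and 0.44 for scalars) runs during burn-in only, so the
# retained draws come from a fixed-kernel chain.

#' Sampler configuration
#'
#' @param chains number of chains (at least 2, default 4).
#' @param iterations total iterations per chain (default 10000).
#' @param burn_in iterations discarded from the start of each chain
#'   (default 4000; must be below \code{iterations}).  Applications with
#'   well-behaved data often need far less (e.g. 1000).
#' @param seed master seed; per-chain streams are spawned from it, so a fit
#'   is bit-reproducible given the same data, spec and config.
#' @param thin keep every \code{thin}-th post-burn-in draw (default 1).
#' @return object of class \code{"samplerConfig"}.
#' @export
samplerConfig <- function(chains = 4, iterations = 10000, burn_in = 4000,
                          seed = 1, thin = 1) {
  if (chains < 2) stop("'chains' must be at least 2 (diagnostics need them)")
  if (burn_in >= iterations) stop("'burn_in' must be below 'iterations'")
  if (burn_in < 0 || thin < 1) stop("invalid 'burn_in' or 'thin'")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 seed = as.integer(seed), thin = as.integer(thin)),
            class = "samplerConfig")
}

.clampRate <- function(p) pmin(pmax(p, .RATE_EPS), 1 - .RATE_EPS)

# Conjugate posterior for a population mean: d_i ~ N(mu, 1/lambda) iid,
# mu ~ N(0, v0).  Returns the posterior mean and precision of mu.
.muPosterior <- function(x, lambda, mu_prior_var) {
  prec <- 1 / mu_prior_var + length(x) * lambda
  list(mean = lambda * sum(x) / prec, precision = prec)
}

# Conjugate posterior for a population precision: x_i ~ N(mu, 1/lambda) iid,
# lambda ~ gamma(shape, rate).  Returns the posterior shape and rate.
.lambdaPosterior <- function(x, mu, shape, rate) {
  list(shape = shape + length(x) / 2,
       rate  = rate + 0.5 * sum((x - mu)^2))
}

# One chain for the huvsd / plain hevsd variants.
.runChainPlain <- function(h, f, s, nn, spec, cfg, seed) {
  set.seed(seed)
  n <- length(h)
  a <- spec$precision_prior[1]; b <- spec$precision_prior[2]
  v0 <- spec$mu_prior_var
  uvsd <- spec$variant == "huvsd"

  # initial values: individual parameters from edge-corrected empirical
  # rates at sigma_s = 1; precisions drawn from their priors (random,
  # overdispersed starts that make the between-chain diagnostic meaningful)
  pr <- paramsFromRates((h + 0.5) / (s + 1), (f + 0.5) / (nn + 1), 1, 1)
  d <- pr$d; c <- pr$c
  mu_d <- mean(d); mu_c <- mean(c)
  lambda_d <- stats::rgamma(1, a, rate = b)
  lambda_c <- stats::rgamma(1, a, rate = b)
  sigma_s <- 1

  llh <- stats::dbinom(h, s, .clampRate(stats::pnorm((0.5 * d - c) / sigma_s)),
                       log = TRUE)
  llf <- stats::dbinom(f, nn, .clampRate(stats::pnorm(-0.5 * d - c)),
                       log = TRUE)

  ls_dc <- rep(log(0.25), n)      # log proposal SD per participant
  ls_sig <- log(0.1)
  ls_scale <- log(0.1)
  ls_shift <- c(log(0.1), log(0.1))   # translation moves for (mu_d, mu_c)
  kept <- seq.int(cfg$burn_in + cfg$thin, cfg$iterations, by = cfg$thin)
  npar <- 5L + 2L * n
  draws <- matrix(NA_real_, length(kept), npar)
  row <- 0L
  acc_dc_post <- 0; acc_sig_post <- 0; acc_scale_post <- 0; n_post <- 0L

  for (t in seq_len(cfg$iterations)) {
    # --- joint random-walk on (d_i, c_i), vectorised across participants
    sc <- exp(ls_dc)
    dp <- d + sc * stats::rnorm(n)
    cp <- c + sc * stats::rnorm(n)
    llhp <- stats::dbinom(h, s,
             .clampRate(stats::pnorm((0.5 * dp - cp) / sigma_s)), log = TRUE)
    llfp <- stats::dbinom(f, nn,
             .clampRate(stats::pnorm(-0.5 * dp - cp)), log = TRUE)
    sd_d <- 1 / sqrt(lambda_d); sd_c <- 1 / sqrt(lambda_c)
    logr <- (llhp + llfp - llh - llf) +
      stats::dnorm(dp, mu_d, sd_d, log = TRUE) -
      stats::dnorm(d,  mu_d, sd_d, log = TRUE) +
      stats::dnorm(cp, mu_c, sd_c, log = TRUE) -
      stats::dnorm(c,  mu_c, sd_c, log = TRUE)
    acc <- log(stats::runif(n)) < logr
    if (any(acc)) {
      d[acc] <- dp[acc]; c[acc] <- cp[acc]
      llh[acc] <- llhp[acc]; llf[acc] <- llfp[acc]
    }

    # --- scalar random walk on sigma_s (unequal-variance model only)
    acc_s <- FALSE
    if (uvsd) {
      sp <- sigma_s + exp(ls_sig) * stats::rnorm(1)
      lp_prop <- .logPriorSigmaS(sp, spec)
      if (is.finite(lp_prop)) {
        llh_prop <- stats::dbinom(h, s,
          .clampRate(stats::pnorm((0.5 * d - c) / sp)), log = TRUE)
        logr_s <- sum(llh_prop) - sum(llh) +
          lp_prop - .logPriorSigmaS(sigma_s, spec)
        if (log(stats::runif(1)) < logr_s) {
          sigma_s <- sp; llh <- llh_prop; acc_s <- TRUE
        }
      }
    }

    # --- likelihood-invariant rescale move along the (sigma_s, d, c) ridge:
    # propose sigma_s' and remap every (d_i, c_i) so the implied rates are
    # unchanged (d' = sigma_s' z_h - z_f, c' = -(sigma_s' z_h + z_f)/2 with
    # z_h = (d/2 - c)/sigma_s, z_f = -d/2 - c).  The likelihood cancels
    # exactly; the MH ratio is the prior ratio times the Jacobian
    # (sigma_s'/sigma_s)^n of the per-participant linear remap.
    # The move is likelihood-free (only prior densities enter), so it is
    # cheap; it is repeated a few times per sweep to beat the serial
    # dependence between sigma_s and the individual parameters.
    acc_r <- 0
    if (uvsd) {
      for (rep_r in 1:3) {
        sp <- sigma_s + exp(ls_scale) * stats::rnorm(1)
        lp_prop <- .logPriorSigmaS(sp, spec)
        if (is.finite(lp_prop)) {
          zh <- (0.5 * d - c) / sigma_s
          zf <- -0.5 * d - c
          dp <- sp * zh - zf
          cp <- -0.5 * (sp * zh + zf)
          sd_d <- 1 / sqrt(lambda_d); sd_c <- 1 / sqrt(lambda_c)
          logr_r <- sum(stats::dnorm(dp, mu_d, sd_d, log = TRUE) -
                        stats::dnorm(d,  mu_d, sd_d, log = TRUE) +
                        stats::dnorm(cp, mu_c, sd_c, log = TRUE) -
                        stats::dnorm(c,  mu_c, sd_c, log = TRUE)) +
            lp_prop - .logPriorSigmaS(sigma_s, spec) + n * log(sp / sigma_s)
          if (log(stats::runif(1)) < logr_r) {
            sigma_s <- sp; d <- dp; c <- cp; acc_r <- acc_r + 1
          }
        }
      }
      acc_r <- acc_r / 3
    }

    # --- joint translation moves: shift mu_d and every d_i (then mu_c and
    # every c_i) by the same amount.  The population prior of the
    # individuals depends only on the differences d_i - mu_d, so the MH
    # ratio reduces to the likelihood ratio times the mu hyperprior ratio.
    # These moves traverse the hierarchical funnel that per-participant
    # random walks cannot (essential when the data carry little or no
    # information and the chain must mix over the prior).
    eps <- exp(ls_shift[1]) * stats::rnorm(1)
    dp <- d + eps
    llhp <- stats::dbinom(h, s,
             .clampRate(stats::pnorm((0.5 * dp - c) / sigma_s)), log = TRUE)
    llfp <- stats::dbinom(f, nn,
             .clampRate(stats::pnorm(-0.5 * dp - c)), log = TRUE)
    logr_t <- sum(llhp + llfp - llh - llf) +
      stats::dnorm(mu_d + eps, 0, sqrt(v0), log = TRUE) -
      stats::dnorm(mu_d, 0, sqrt(v0), log = TRUE)
    acc_td <- log(stats::runif(1)) < logr_t
    if (acc_td) { d <- dp; mu_d <- mu_d + eps; llh <- llhp; llf <- llfp }

    eps <- exp(ls_shift[2]) * stats::rnorm(1)
    cp <- c + eps
    llhp <- stats::dbinom(h, s,
             .clampRate(stats::pnorm((0.5 * d - cp) / sigma_s)), log = TRUE)
    llfp <- stats::dbinom(f, nn,
             .clampRate(stats::pnorm(-0.5 * d - cp)), log = TRUE)
    logr_t <- sum(llhp + llfp - llh - llf) +
      stats::dnorm(mu_c + eps, 0, sqrt(v0), log = TRUE) -
      stats::dnorm(mu_c, 0, sqrt(v0), log = TRUE)
    acc_tc <- log(stats::runif(1)) < logr_t
    if (acc_tc) { c <- cp; mu_c <- mu_c + eps; llh <- llhp; llf <- llfp }

    # --- exact Gibbs draws for the conjugate hyperparameters
    post <- .muPosterior(d, lambda_d, v0)
    mu_d <- stats::rnorm(1, post$mean, 1 / sqrt(post$precision))
    post <- .muPosterior(c, lambda_c, v0)
    mu_c <- stats::rnorm(1, post$mean, 1 / sqrt(post$precision))
    post <- .lambdaPosterior(d, mu_d, a, b)
    lambda_d <- stats::rgamma(1, post$shape, rate = post$rate)
    post <- .lambdaPosterior(c, mu_c, a, b)
    lambda_c <- stats::rgamma(1, post$shape, rate = post$rate)

    if (t <= cfg$burn_in) {
      g <- t^(-0.6)
      ls_dc <- ls_dc + g * (as.numeric(acc) - 0.23)
      if (uvsd) {
        ls_sig <- ls_sig + g * (as.numeric(acc_s) - 0.44)
        ls_scale <- ls_scale + g * (as.numeric(acc_r) - 0.44)
      }
      ls_shift <- ls_shift + g * (as.numeric(c(acc_td, acc_tc)) - 0.44)
    } else {
      n_post <- n_post + 1L
      acc_dc_post <- acc_dc_post + mean(acc)
      acc_sig_post <- acc_sig_post + as.numeric(acc_s)
      acc_scale_post <- acc_scale_post + as.numeric(acc_r)
      if ((t - cfg$burn_in) %% cfg$thin == 0L) {
        row <- row + 1L
        draws[row, ] <- c(mu_d, mu_c, lambda_d, lambda_c, sigma_s, d, c)
      }
    }
  }
  list(draws = draws,
       accept = c(dc = acc_dc_post / n_post,
                  sigma_s = if (uvsd) acc_sig_post / n_post else NA_real_,
                  rescale = if (uvsd) acc_scale_post / n_post else NA_real_))
}

# One chain for the linearly expanded hEVSD variant:
# d_i = mu_d + xi_d * delta_d_i, xi ~ beta(1, 1), delta ~ N(0, 1/lambda).
# mu and xi enter the likelihood directly, so they move by scalar Metropolis;
# the lambdas stay conjugate given the deltas.
.runChainExpanded <- function(h, f, s, nn, spec, cfg, seed) {
  set.seed(seed)
  n <- length(h)
  a <- spec$precision_prior[1]; b <- spec$precision_prior[2]
  v0 <- spec$mu_prior_var

  pr <- paramsFromRates((h + 0.5) / (s + 1), (f + 0.5) / (nn + 1), 1, 1)
  mu_d <- mean(pr$d); mu_c <- mean(pr$c)
  xi_d <- stats::runif(1, 0.2, 0.8); xi_c <- stats::runif(1, 0.2, 0.8)
  delta_d <- (pr$d - mu_d) / xi_d
  delta_c <- (pr$c - mu_c) / xi_c
  lambda_d <- stats::rgamma(1, a, rate = b)
  lambda_c <- stats::rgamma(1, a, rate = b)

  loglik_vec <- function(dd, cc) {
    stats::dbinom(h, s, .clampRate(stats::pnorm(0.5 * dd - cc)), log = TRUE) +
      stats::dbinom(f, nn, .clampRate(stats::pnorm(-0.5 * dd - cc)), log = TRUE)
  }
  d <- mu_d + xi_d * delta_d
  c <- mu_c + xi_c * delta_c
  ll <- loglik_vec(d, c)

  ls_del <- rep(log(0.5), n)
  ls_sc <- c(mu_d = log(0.1), mu_c = log(0.1), xi_d = log(0.1), xi_c = log(0.1))
  kept <- seq.int(cfg$burn_in + cfg$thin, cfg$iterations, by = cfg$thin)
  draws <- matrix(NA_real_, length(kept), 7L + 2L * n)
  row <- 0L; acc_del_post <- 0; n_post <- 0L

  scalar_step <- function(name, cur, logr_fun) {
    prop <- cur + exp(ls_sc[[name]]) * stats::rnorm(1)
    out <- logr_fun(prop)
    if (is.finite(out$logr) && log(stats::runif(1)) < out$logr)
      list(value = prop, extra = out, accepted = TRUE)
    else list(value = cur, extra = NULL, accepted = FALSE)
  }

  for (t in seq_len(cfg$iterations)) {
    # deltas, jointly per participant
    sc <- exp(ls_del)
    ddp <- delta_d + sc * stats::rnorm(n)
    dcp <- delta_c + sc * stats::rnorm(n)
    dp <- mu_d + xi_d * ddp; cp <- mu_c + xi_c * dcp
    llp <- loglik_vec(dp, cp)
    sd_d <- 1 / sqrt(lambda_d); sd_c <- 1 / sqrt(lambda_c)
    logr <- (llp - ll) +
      stats::dnorm(ddp, 0, sd_d, log = TRUE) - stats::dnorm(delta_d, 0, sd_d, log = TRUE) +
      stats::dnorm(dcp, 0, sd_c, log = TRUE) - stats::dnorm(delta_c, 0, sd_c, log = TRUE)
    acc <- log(stats::runif(n)) < logr
    delta_d[acc] <- ddp[acc]; delta_c[acc] <- dcp[acc]
    d[acc] <- dp[acc]; c[acc] <- cp[acc]; ll[acc] <- llp[acc]

    # population means (enter the likelihood through d_i, c_i)
    st <- scalar_step("mu_d", mu_d, function(m) {
      dn <- m + xi_d * delta_d; lln <- loglik_vec(dn, c)
      list(logr = sum(lln) - sum(ll) +
             stats::dnorm(m, 0, sqrt(v0), log = TRUE) -
             stats::dnorm(mu_d, 0, sqrt(v0), log = TRUE),
           d = dn, ll = lln)
    })
    acc_mu_d <- st$accepted
    if (st$accepted) { mu_d <- st$value; d <- st$extra$d; ll <- st$extra$ll }
    st <- scalar_step("mu_c", mu_c, function(m) {
      cn <- m + xi_c * delta_c; lln <- loglik_vec(d, cn)
      list(logr = sum(lln) - sum(ll) +
             stats::dnorm(m, 0, sqrt(v0), log = TRUE) -
             stats::dnorm(mu_c, 0, sqrt(v0), log = TRUE),
           c = cn, ll = lln)
    })
    acc_mu_c <- st$accepted
    if (st$accepted) { mu_c <- st$value; c <- st$extra$c; ll <- st$extra$ll }

    # auxiliary scales, beta(1, 1) support (flat log-prior on (0, 1))
    st <- scalar_step("xi_d", xi_d, function(x) {
      if (x <= 0 || x >= 1) return(list(logr = -Inf))
      dn <- mu_d + x * delta_d; lln <- loglik_vec(dn, c)
      list(logr = sum(lln) - sum(ll), d = dn, ll = lln)
    })
    acc_xi_d <- st$accepted
    if (st$accepted) { xi_d <- st$value; d <- st$extra$d; ll <- st$extra$ll }
    st <- scalar_step("xi_c", xi_c, function(x) {
      if (x <= 0 || x >= 1) return(list(logr = -Inf))
      cn <- mu_c + x * delta_c; lln <- loglik_vec(d, cn)
      list(logr = sum(lln) - sum(ll), c = cn, ll = lln)
    })
    acc_xi_c <- st$accepted
    if (st$accepted) { xi_c <- st$value; c <- st$extra$c; ll <- st$extra$ll }

    post <- .lambdaPosterior(delta_d, 0, a, b)
    lambda_d <- stats::rgamma(1, post$shape, rate = post$rate)
    post <- .lambdaPosterior(delta_c, 0, a, b)
    lambda_c <- stats::rgamma(1, post$shape, rate = post$rate)

    if (t <= cfg$burn_in) {
      g <- t^(-0.6)
      ls_del <- ls_del + g * (as.numeric(acc) - 0.23)
      ls_sc <- ls_sc + g * (as.numeric(c(acc_mu_d, acc_mu_c,
                                         acc_xi_d, acc_xi_c)) - 0.44)
    } else {
      n_post <- n_post + 1L
      acc_del_post <- acc_del_post + mean(acc)
      if ((t - cfg$burn_in) %% cfg$thin == 0L) {
        row <- row + 1L
        draws[row, ] <- c(mu_d, mu_c, lambda_d, lambda_c, 1, d, c, xi_d, xi_c)
      }
    }
  }
  list(draws = draws, accept = c(dc = acc_del_post / n_post,
                                 sigma_s = NA_real_, rescale = NA_real_))
}

#' Fit a hierarchical signal-detection model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler: exact Gibbs draws for the
#' conjugate population means and precisions, vectorised joint random-walk
#' updates for the per-participant \eqn{(d_i, c_i)} pairs, and a scalar
#' adaptive random walk for \eqn{\sigma_s}.  Proposal scales adapt during
#' burn-in only (Robbins-Monro toward 0.23 / 0.44 acceptance) and are frozen
#' afterwards.  Chains use independent seeds spawned from the master seed;
#' precisions are initialised by random draws from their priors so the
#' between-chain diagnostic starts from dispersed points.
#'
#' @param counts counts data.frame (see [validateCounts()]); rows with zero
#'   trials are tolerated and contribute no likelihood (useful for
#'   prior-recovery checks).
#' @param spec a [modelSpec()].
#' @param config a [samplerConfig()].
#' @return an object of class \code{"sdtFit"}: a list with the draws array
#'   (\code{iteration x chain x parameter}, population parameters first,
#'   then \code{d[i]} and \code{c[i]}), acceptance rates, and the inputs.
#' @export
fitSDT <- function(counts, spec = modelSpec(), config = samplerConfig()) {
  counts <- validateCounts(counts, allow_zero_trials = TRUE)
  stopifnot(inherits(spec, "modelSpec"), inherits(config, "samplerConfig"))
  n <- nrow(counts)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$chains)
  runner <- if (spec$variant == "hevsd_expanded") .runChainExpanded else .runChainPlain
  t0 <- proc.time()[["elapsed"]]
  chains <- lapply(chain_seeds, function(sd)
    runner(counts$hits, counts$false_alarms, counts$signal_trials,
           counts$noise_trials, spec, config, sd))
  elapsed <- proc.time()[["elapsed"]] - t0

  par_names <- c("mu_d", "mu_c", "lambda_d", "lambda_c", "sigma_s",
                 paste0("d[", seq_len(n), "]"), paste0("c[", seq_len(n), "]"))
  if (spec$variant == "hevsd_expanded")
    par_names <- c(par_names, "xi_d", "xi_c")
  kept <- nrow(chains[[1]]$draws)
  draws <- array(NA_real_, c(kept, config$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]$draws
  if (any(!is.finite(draws)))
    stop("sampler produced non-finite draws")  # should be unreachable

  structure(list(draws = draws, counts = counts, spec = spec, config = config,
                 accept = do.call(rbind, lapply(chains, `[[`, "accept")),
                 elapsed = elapsed),
            class = "sdtFit")
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Computes the split-\eqn{\hat R} statistic: each chain is halved, and the
#' between/within variance ratio of the resulting 2m sequences is reported.
#' Values near 1 indicate convergence; 1.01 is the conventional cutoff used
#' throughout the package's simulation reports.  Chains that are all
#' identical and constant report 1 by convention.
#'
#' @param draws matrix (\code{iteration x chain}) or 3-d array
#'   (\code{iteration x chain x parameter}).
#' @return scalar, or a named vector per parameter for array input.
#' @export
gelmanRhat <- function(draws) {
  if (is.array(draws) && length(dim(draws)) == 3) {
    res <- apply(draws, 3, gelmanRhat)
    return(res)
  }
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("at least 2 chains are required")
  if (nrow(draws) < 10) stop("at least 10 post-burn-in draws are required")
  half <- floor(nrow(draws) / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(split); n <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# flattened draws (all chains stacked) for a fit
.flatDraws <- function(fit) {
  dm <- dim(fit$draws)
  matrix(aperm(fit$draws, c(1, 2, 3)), dm[1] * dm[2], dm[3],
         dimnames = list(NULL, dimnames(fit$draws)[[3]]))
}

# total log-likelihood at one (d, c, sigma_s) point
.loglikAt <- function(counts, d, c, sigma_s) {
  th <- .clampRate(stats::pnorm((0.5 * d - c) / sigma_s))
  tf <- .clampRate(stats::pnorm(-0.5 * d - c))
  sum(stats::dbinom(counts$hits, counts$signal_trials, th, log = TRUE)) +
    sum(stats::dbinom(counts$false_alarms, counts$noise_trials, tf, log = TRUE))
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D} with deviance \eqn{D = -2 \log L},
#' \eqn{\bar D} the posterior mean deviance over the saved draws, and
#' \eqn{p_D = \bar D - D(\hat\theta)} evaluated at the posterior means of
#' the likelihood-level parameters \eqn{(d_i, c_i, \sigma_s)} — the focus
#' matching the binomial likelihood.
#'
#' @param fit an [fitSDT()] result.
#' @return scalar DIC; attributes \code{Dbar} and \code{pD} carry the parts.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "sdtFit"))
  flat <- .flatDraws(fit)
  n <- nrow(fit$counts)
  d_idx <- 5L + seq_len(n); c_idx <- 5L + n + seq_len(n)
  dev <- vapply(seq_len(nrow(flat)), function(j)
    -2 * .loglikAt(fit$counts, flat[j, d_idx], flat[j, c_idx],
                   flat[j, "sigma_s"]), numeric(1))
  Dbar <- mean(dev)
  Dhat <- -2 * .loglikAt(fit$counts, colMeans(flat[, d_idx, drop = FALSE]),
                         colMeans(flat[, c_idx, drop = FALSE]),
                         mean(flat[, "sigma_s"]))
  pD <- Dbar - Dhat
  structure(Dbar + pD, Dbar = Dbar, pD = pD)
}

.logMeanExp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' \eqn{WAIC = -2 (lppd - p_{WAIC})}, computed pointwise at the grain at
#' which the likelihood factorises exactly: one signal-trial term and one
#' noise-trial term per participant.  \eqn{p_{WAIC}} is the sum of pointwise
#' posterior variances of the log-likelihood.
#'
#' @param fit an [fitSDT()] result with at least 2 saved draws.
#' @return scalar WAIC; attributes \code{lppd} and \code{p_waic}.
#' @export
waic <- function(fit) {
  stopifnot(inherits(fit, "sdtFit"))
  flat <- .flatDraws(fit)
  if (nrow(flat) < 2) stop("at least 2 draws are required")
  n <- nrow(fit$counts)
  sig <- flat[, "sigma_s"]
  lppd <- 0; p_waic <- 0
  for (i in seq_len(n)) {
    di <- flat[, 5L + i]; ci <- flat[, 5L + n + i]
    ll_h <- stats::dbinom(fit$counts$hits[i], fit$counts$signal_trials[i],
                          .clampRate(stats::pnorm((0.5 * di - ci) / sig)),
                          log = TRUE)
    ll_f <- stats::dbinom(fit$counts$false_alarms[i], fit$counts$noise_trials[i],
                          .clampRate(stats::pnorm(-0.5 * di - ci)), log = TRUE)
    lppd <- lppd + .logMeanExp(ll_h) + .logMeanExp(ll_f)
    p_waic <- p_waic + stats::var(ll_h) + stats::var(ll_f)
  }
  structure(-2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Posterior summary table
#'
#' Mean, SD, central 95\% credible interval, median, split-\eqn{\hat R} and
#' effective sample size per parameter.  Derived population SDs
#' \eqn{\sigma_d = \lambda_d^{-1/2}}, \eqn{\sigma_c = \lambda_c^{-1/2}} are
#' appended as extra rows (computed draw-wise).  By default only
#' population-level parameters are summarised; \code{pars = "all"} includes
#' every \code{d[i]} and \code{c[i]} (ESS computation across thousands of
#' individual parameters is the slow part).
#'
#' @param object an [fitSDT()] result.
#' @param pars \code{"population"} (default), \code{"all"}, or a character
#'   vector of parameter names.
#' @param ... unused.
#' @return data.frame with one row per parameter.
#' @export
summary.sdtFit <- function(object, pars = "population", ...) {
  pop <- c("mu_d", "mu_c", "lambda_d", "lambda_c",
           if (object$spec$variant == "huvsd") "sigma_s",
           if (object$spec$variant == "hevsd_expanded") c("xi_d", "xi_c"))
  names_all <- dimnames(object$draws)[[3]]
  sel <- if (identical(pars, "population")) pop
         else if (identical(pars, "all")) names_all
         else intersect(pars, names_all)
  sub <- object$draws[, , sel, drop = FALSE]

  # derived SD views of the precisions
  derived <- list()
  if (all(c("lambda_d", "lambda_c") %in% sel)) {
    derived$sigma_d <- 1 / sqrt(sub[, , "lambda_d"])
    derived$sigma_c <- 1 / sqrt(sub[, , "lambda_c"])
  }
  stat_row <- function(x2d) {   # iteration x chain
    v <- as.vector(x2d)
    ess <- tryCatch(
      sum(coda::effectiveSize(coda::as.mcmc.list(
        lapply(seq_len(ncol(x2d)), function(ch) coda::mcmc(x2d[, ch]))))),
      error = function(e) NA_real_)
    c(mean = mean(v), sd = stats::sd(v),
      `2.5%` = unname(stats::quantile(v, 0.025)),
      `50%` = unname(stats::quantile(v, 0.5)),
      `97.5%` = unname(stats::quantile(v, 0.975)),
      rhat = gelmanRhat(x2d), ess = ess)
  }
  rows <- lapply(sel, function(p) stat_row(sub[, , p]))
  rows <- c(rows, lapply(derived, stat_row))
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(parameter = c(sel, names(derived)), out)
  rownames(out) <- NULL
  out
}

#' @export
print.sdtFit <- function(x, ...) {
  cat(sprintf("Hierarchical SDT fit (%s): %d participants, %d chains x %d iterations (burn-in %d, thin %d)\n",
              x$spec$variant, nrow(x$counts), x$config$chains,
              x$config$iterations, x$config$burn_in, x$config$thin))
  s <- summary(x)
  print(cbind(s["parameter"], round(s[-1], 3)))
  cat(sprintf("Mean acceptance: (d,c) block %.2f", mean(x$accept[, "dc"])))
  if (x$spec$variant == "huvsd")
    cat(sprintf(", sigma_s %.2f", mean(x$accept[, "sigma_s"])))
  cat(sprintf("; elapsed %.1fs\n", x$elapsed))
  invisible(x)
}

#' Posterior means of the population parameters
#'
#' @param object an [fitSDT()] result.
#' @param ... unused.
#' @return named numeric vector (\code{mu_d}, \code{mu_c}, \code{sigma_d},
#'   \code{sigma_c}, \code{sigma_s}).
#' @export
coef.sdtFit <- function(object, ...) {
  flat <- .flatDraws(object)
  c(mu_d = mean(flat[, "mu_d"]), mu_c = mean(flat[, "mu_c"]),
    sigma_d = mean(1 / sqrt(flat[, "lambda_d"])),
    sigma_c = mean(1 / sqrt(flat[, "lambda_c"])),
    sigma_s = mean(flat[, "sigma_s"]))
}

#' Posterior means of the individual parameters
#'
#' @param fit an [fitSDT()] result.
#' @return data.frame with \code{participant_id}, \code{d}, \code{c}.
#' @export
individualMeans <- function(fit) {
  stopifnot(inherits(fit, "sdtFit"))
  flat <- .flatDraws(fit)
  n <- nrow(fit$counts)
  data.frame(participant_id = fit$counts$participant_id,
             d = colMeans(flat[, 5L + seq_len(n), drop = FALSE]),
             c = colMeans(flat[, 5L + n + seq_len(n), drop = FALSE]))
}

#' Export posterior draws as a long table
#'
#' @param fit an [fitSDT()] result.
#' @param pars parameter names to include (default: population level).
#' @return data.frame with columns \code{chain}, \code{iteration},
#'   \code{parameter}, \code{value}.
#' @export
drawsTable <- function(fit, pars = c("mu_d", "mu_c", "lambda_d", "lambda_c",
                                     "sigma_s")) {
  stopifnot(inherits(fit, "sdtFit"))
  pars <- intersect(pars, dimnames(fit$draws)[[3]])
  dm <- dim(fit$draws)
  do.call(rbind, lapply(pars, function(p)
    data.frame(chain = rep(seq_len(dm[2]), each = dm[1]),
               iteration = rep(seq_len(dm[1]), dm[2]),
               parameter = p,
               value = as.vector(fit$draws[, , p]))))
}
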