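# Synthetic-data generator implementing the model's generative process and
# its controlled violations (heterogeneous signal SD, correlated latent
# parameters).  Every simulation experiment in the package runs on data
# produced here.

#' Simulation configuration
#'
#' Describes one synthetic study: the generating population, sample size,
#' trial counts, and optional violations of the model assumptions.
#'
#' With \code{sigma_s_heterogeneity}, each participant gets an individual
#' signal SD \eqn{\sigma_{s,i} \sim N(\sigma_s, 2\sigma_s^4/n)} truncated to
#' positive values by rejection — the spread matched to the standard error
#' of a sample variance at sample size \eqn{n}, so the violation stays
#' within what the data could resolve.  \code{rho_dc} correlates sensitivity
#' and criterion (the model assumes 0); \code{rho_ds} / \code{rho_cs}
#' correlate them with \eqn{\sigma_{s,i}} (require heterogeneity).
#'
#' @param pop a [populationParams()] object.
#' @param n_participants number of participants (>= 1).
#' @param signal_trials,noise_trials trials per participant (>= 1).
#' @param seed RNG seed for [simulateSDT()].
#' @param sigma_s_heterogeneity draw per-participant signal SDs (default
#'   FALSE).
#' @param rho_dc,rho_ds,rho_cs latent correlations in [-1, 1] (defaults 0).
#' @return object of class \code{"simConfig"}.
#' @export
simConfig <- function(pop, n_participants, signal_trials, noise_trials,
                      seed = 1, sigma_s_heterogeneity = FALSE,
                      rho_dc = 0, rho_ds = 0, rho_cs = 0) {
  stopifnot(inherits(pop, "populationParams"),
            n_participants >= 1, signal_trials >= 1, noise_trials >= 1)
  if (any(abs(c(rho_dc, rho_ds, rho_cs)) > 1))
    stop("correlations must lie in [-1, 1]")
  if (!sigma_s_heterogeneity && (rho_ds != 0 || rho_cs != 0))
    stop("rho_ds / rho_cs require sigma_s_heterogeneity = TRUE")
  R <- matrix(c(1, rho_dc, rho_ds,
                rho_dc, 1, rho_cs,
                rho_ds, rho_cs, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("correlation structure is not positive semi-definite")
  structure(list(pop = pop, n_participants = as.integer(n_participants),
                 signal_trials = as.integer(signal_trials),
                 noise_trials = as.integer(noise_trials),
                 seed = as.integer(seed),
                 sigma_s_heterogeneity = sigma_s_heterogeneity,
                 rho_dc = rho_dc, rho_ds = rho_ds, rho_cs = rho_cs),
            class = "simConfig")
}

# draw n rows from N(mu, diag(s) R diag(s)) allowing zero scales
.rmvn <- function(n, mu, s, R) {
  active <- s > 0
  X <- matrix(rep(mu, each = n), n, length(mu))
  if (any(active)) {
    Ra <- R[active, active, drop = FALSE]
    L <- tryCatch(chol(Ra), error = function(e)
      stop("invalid covariance structure: ", conditionMessage(e)))
    Z <- matrix(stats::rnorm(n * sum(active)), n) %*% L
    X[, active] <- X[, active] +
      Z * rep(s[active], each = n)
  }
  X
}

#' Generate a synthetic yes/no detection dataset
#'
#' Draws per-participant \eqn{(d_i, c_i)} (and, under heterogeneity,
#' \eqn{\sigma_{s,i}}) from the configured multivariate normal, maps them to
#' hit and false-alarm probabilities through the Gaussian model, and draws
#' binomial response counts.  No edge correction is applied: participants
#' with 0 or maximal counts are retained verbatim, and downstream consumers
#' must cope.
#'
#' @param cfg a [simConfig()].
#' @return object of class \code{"sdtSim"}: list with \code{counts} (a
#'   counts data.frame), \code{truth} (per-participant \code{d}, \code{c},
#'   \code{sigma_s}) and the generating \code{config}.
#' @export
simulateSDT <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  p <- cfg$pop
  n <- cfg$n_participants
  sd_sig <- if (cfg$sigma_s_heterogeneity)
    sqrt(2 * p$sigma_s^4 / n) else 0
  mu <- c(p$mu_d, p$mu_c, p$sigma_s)
  s <- c(p$sigma_d, p$sigma_c, sd_sig)
  R <- matrix(c(1, cfg$rho_dc, cfg$rho_ds,
                cfg$rho_dc, 1, cfg$rho_cs,
                cfg$rho_ds, cfg$rho_cs, 1), 3, 3)
  X <- .rmvn(n, mu, s, R)
  # truncate sigma_{s,i} at zero by rejection (negligible at the regimes of
  # interest, but keeps the rates well defined)
  bad <- which(X[, 3] <= 0)
  guard <- 0L
  while (length(bad)) {
    X[bad, ] <- .rmvn(length(bad), mu, s, R)
    bad <- bad[X[bad, 3] <= 0]
    if ((guard <- guard + 1L) > 1000L)
      stop("rejection sampling for positive sigma_s,i failed to terminate")
  }
  d <- X[, 1]; c_ <- X[, 2]; sig_i <- X[, 3]
  theta_h <- stats::pnorm((0.5 * d - c_) / sig_i)
  theta_f <- stats::pnorm(-0.5 * d - c_)
  counts <- data.frame(
    participant_id = seq_len(n),
    hits = stats::rbinom(n, cfg$signal_trials, theta_h),
    false_alarms = stats::rbinom(n, cfg$noise_trials, theta_f),
    signal_trials = cfg$signal_trials,
    noise_trials = cfg$noise_trials)
  structure(list(counts = counts,
                 truth = data.frame(participant_id = seq_len(n),
                                    d = d, c = c_, sigma_s = sig_i),
                 config = cfg),
            class = "sdtSim")
}

#' @export
print.sdtSim <- function(x, ...) {
  cat(sprintf("Synthetic SDT dataset: %d participants, %d + %d trials (seed %d)\n",
              x$config$n_participants, x$config$signal_trials,
              x$config$noise_trials, x$config$seed))
  print(x$config$pop)
  invisible(x)
}

#' Ladder of progressively smaller synthetic datasets
#'
#' Generates one dataset per \code{(n, k)} level — the classic design halves
#' both participants and trials from 512 down to 16.  Trials split evenly
#' into signal and noise; the heterogeneity spread of \eqn{\sigma_{s,i}} is
#' re-scaled to each level's \eqn{n} automatically.  Level \code{i} uses
#' seed \code{cfg$seed + i - 1}, so a single-level ladder reproduces
#' [simulateSDT()] at the base seed exactly.
#'
#' @param cfg base [simConfig()] (its n and trial numbers are overridden
#'   per level).
#' @param levels matrix-like or list of \code{(n, k)} pairs; default the
#'   six halvings 512, 256, ..., 16.
#' @return list of \code{"sdtSim"} objects, one per level, named "n=..,k=..".
#' @export
simulateLadder <- function(cfg, levels = lapply(2^(9:4), function(x) c(x, x))) {
  stopifnot(inherits(cfg, "simConfig"), length(levels) >= 1)
  out <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    lev <- levels[[i]]
    n <- lev[1]; k <- lev[2]
    cfg_i <- simConfig(cfg$pop, n_participants = n,
                       signal_trials = ceiling(k / 2),
                       noise_trials = floor(k / 2),
                       seed = cfg$seed + i - 1L,
                       sigma_s_heterogeneity = cfg$sigma_s_heterogeneity,
                       rho_dc = cfg$rho_dc, rho_ds = cfg$rho_ds,
                       rho_cs = cfg$rho_cs)
    out[[i]] <- simulateSDT(cfg_i)
  }
  names(out) <- vapply(levels, function(l) sprintf("n=%d,k=%d", l[1], l[2]), "")
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Produces \code{counts.csv}, \code{truth.csv} and a \code{config.txt}
#' key-value sidecar in \code{dir}.
#'
#' @param sim an \code{"sdtSim"} object.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeSim <- function(sim, dir) {
  stopifnot(inherits(sim, "sdtSim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(sim$counts, file.path(dir, "counts.csv"))
  utils::write.table(sim$truth, file.path(dir, "truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  cfg <- sim$config
  keys <- c(mu_d = cfg$pop$mu_d, mu_c = cfg$pop$mu_c,
            sigma_d = cfg$pop$sigma_d, sigma_c = cfg$pop$sigma_c,
            sigma_s = cfg$pop$sigma_s,
            n_participants = cfg$n_participants,
            signal_trials = cfg$signal_trials,
            noise_trials = cfg$noise_trials, seed = cfg$seed,
            sigma_s_heterogeneity = as.numeric(cfg$sigma_s_heterogeneity),
            rho_dc = cfg$rho_dc, rho_ds = cfg$rho_ds, rho_cs = cfg$rho_cs)
  writeLines(paste(names(keys), keys, sep = " = "),
             file.path(dir, "config.txt"))
  invisible(dir)
}
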