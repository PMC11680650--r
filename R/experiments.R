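# Simulation-study runners: parameter recovery, misspecification bias,
# robustness to assumption violations, and fitting of external count tables
# with model comparison.

# population summary rows against the generating truth
.populationReport <- function(fit, pop) {
  s <- summary(fit)
  rows <- data.frame(parameter = s$parameter, mean = s$mean, sd = s$sd,
                     lower = s$`2.5%`, upper = s$`97.5%`,
                     rhat = s$rhat, ess = s$ess)
  truth_map <- c(mu_d = pop$mu_d, mu_c = pop$mu_c,
                 lambda_d = 1 / pop$sigma_d^2, lambda_c = 1 / pop$sigma_c^2,
                 sigma_s = pop$sigma_s, sigma_d = pop$sigma_d,
                 sigma_c = pop$sigma_c)
  rows$truth <- unname(truth_map[rows$parameter])
  rows$covered <- !is.na(rows$truth) & rows$lower <= rows$truth &
    rows$truth <= rows$upper
  rows
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic dataset from a known population, fits the requested
#' model, and reports population-parameter recovery (posterior mean, SD,
#' 95\% credible interval, coverage of the generating value) together with
#' the Pearson correlations \code{r_d}, \code{r_c} between posterior-mean
#' and generating individual parameters.  A degenerate zero-variance truth
#' (\code{sigma_d = sigma_c = 0}) leaves the correlations \code{NA} and is
#' recorded in the report.
#'
#' @param cfg a [simConfig()] describing the generating population.
#' @param sampler a [samplerConfig()].
#' @param spec a [modelSpec()] (default hUVSD).
#' @param rhat_threshold convergence flag cutoff (default 1.01); exceeding
#'   it flags the report, it is not an error.
#' @param keep_fit retain the full \code{sdtFit} in the report (default
#'   FALSE to keep reports light).
#' @return object of class \code{"recoveryReport"}.
#' @export
runRecovery <- function(cfg, sampler = samplerConfig(), spec = modelSpec(),
                        rhat_threshold = 1.01, keep_fit = FALSE) {
  sim <- simulateSDT(cfg)
  fit <- fitSDT(sim$counts, spec, sampler)
  ind <- individualMeans(fit)
  degenerate <- stats::sd(sim$truth$d) == 0 || stats::sd(sim$truth$c) == 0
  r_d <- if (degenerate) NA_real_ else stats::cor(ind$d, sim$truth$d)
  r_c <- if (degenerate) NA_real_ else stats::cor(ind$c, sim$truth$c)
  population <- .populationReport(fit, cfg$pop)
  all_rhat <- gelmanRhat(fit$draws)
  structure(list(population = population, r_d = r_d, r_c = r_c,
                 degenerate_truth = degenerate,
                 max_rhat = max(all_rhat),
                 converged = max(all_rhat) < rhat_threshold,
                 model = spec$variant, config = cfg, sampler = sampler,
                 fit = if (keep_fit) fit else NULL),
            class = "recoveryReport")
}

#' @export
print.recoveryReport <- function(x, ...) {
  cat(sprintf("Recovery report: %s fit to data from the configured population (n = %d, %d + %d trials)\n",
              x$model, x$config$n_participants, x$config$signal_trials,
              x$config$noise_trials))
  print(cbind(x$population["parameter"],
              round(x$population[c("truth", "mean", "sd", "lower", "upper")], 3),
              x$population["covered"]))
  if (x$degenerate_truth)
    cat("Individual-parameter correlations undefined: zero-variance truth\n")
  else
    cat(sprintf("Individual recovery: r_d = %.3f, r_c = %.3f\n", x$r_d, x$r_c))
  cat(sprintf("Max split-Rhat %.4f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "FLAGGED: not converged"))
  invisible(x)
}

#' Misspecification-bias experiment
#'
#' Fits the equal-variance model to data generated with \eqn{\sigma_s \ne 1}
#' (or any other deliberate mismatch).  With \eqn{\sigma_s > 1} the
#' equal-variance fit underestimates \eqn{\mu_d} and overestimates
#' \eqn{\mu_c} — the criterion shifted by roughly half the sensitivity
#' change — with generating values frequently outside the 95\% credible
#' intervals.
#'
#' @inheritParams runRecovery
#' @param spec model to (mis)fit; default plain hEVSD.
#' @return a \code{"recoveryReport"}.
#' @export
runBias <- function(cfg, sampler = samplerConfig(),
                    spec = modelSpec("hevsd"), rhat_threshold = 1.01,
                    keep_fit = FALSE) {
  runRecovery(cfg, sampler, spec, rhat_threshold, keep_fit)
}

#' Robustness experiments over correlation grids and size ladders
#'
#' Runs one recovery experiment per cell of a violation grid: either a grid
#' of sensitivity-criterion correlations \code{rho_dc} at fixed size, or a
#' ladder of \code{(n, k)} levels (typically with heterogeneous
#' \eqn{\sigma_{s,i}} and/or \code{rho_ds} set in \code{cfg}), for each
#' requested model variant.
#'
#' @param cfg base [simConfig()].
#' @param sampler a [samplerConfig()].
#' @param rho_dc_grid numeric vector of d-c correlations, or \code{NULL}.
#' @param levels list of \code{(n, k)} pairs, or \code{NULL}.  One of
#'   \code{rho_dc_grid} / \code{levels} must be given.
#' @param models character vector of model variants to fit per cell.
#' @param rhat_threshold convergence flag cutoff.
#' @return named list of \code{"recoveryReport"} objects.
#' @export
runRobustness <- function(cfg, sampler = samplerConfig(),
                          rho_dc_grid = NULL, levels = NULL,
                          models = c("huvsd", "hevsd"),
                          rhat_threshold = 1.01) {
  if (is.null(rho_dc_grid) && is.null(levels))
    stop("provide 'rho_dc_grid' and/or 'levels'")
  cells <- list()
  if (!is.null(rho_dc_grid)) {
    for (rho in rho_dc_grid) {
      cfg_i <- simConfig(cfg$pop, cfg$n_participants, cfg$signal_trials,
                         cfg$noise_trials, seed = cfg$seed,
                         sigma_s_heterogeneity = cfg$sigma_s_heterogeneity,
                         rho_dc = rho, rho_ds = cfg$rho_ds, rho_cs = cfg$rho_cs)
      cells[[sprintf("rho_dc=%.1f", rho)]] <- cfg_i
    }
  }
  if (!is.null(levels)) {
    for (i in seq_along(levels)) {
      lev <- levels[[i]]
      cfg_i <- simConfig(cfg$pop, lev[1], ceiling(lev[2] / 2),
                         floor(lev[2] / 2), seed = cfg$seed + i - 1L,
                         sigma_s_heterogeneity = cfg$sigma_s_heterogeneity,
                         rho_dc = cfg$rho_dc, rho_ds = cfg$rho_ds,
                         rho_cs = cfg$rho_cs)
      cells[[sprintf("n=%d,k=%d", lev[1], lev[2])]] <- cfg_i
    }
  }
  out <- list()
  for (cell in names(cells)) {
    for (m in models) {
      out[[paste(m, cell)]] <-
        runRecovery(cells[[cell]], sampler, modelSpec(m), rhat_threshold)
    }
  }
  out
}

#' Fit models to an observed count table and compare them
#'
#' Reads a delimited count table (or takes a counts data.frame directly),
#' fits the requested model variants, and reports posterior summaries, the
#' implied z-ROC line, AUC, and DIC/WAIC per model with pairwise deltas
#' relative to the first model.
#'
#' @param data path to a delimited count table, or a counts data.frame.
#' @param models character vector of model variants (default hUVSD and
#'   hEVSD).
#' @param sampler a [samplerConfig()]; applications typically need a
#'   shorter burn-in than simulation studies (e.g. 1000).
#' @param out_dir if non-NULL, write per-model summary and draws tables and
#'   the comparison report there.
#' @param keep_fits retain the \code{sdtFit} objects in the report.
#' @return object of class \code{"comparisonReport"}.
#' @export
fitDataset <- function(data, models = c("huvsd", "hevsd"),
                       sampler = samplerConfig(burn_in = 1000),
                       out_dir = NULL, keep_fits = FALSE) {
  counts <- if (is.character(data)) readCounts(data) else validateCounts(data)
  per_model <- list()
  for (m in models) {
    fit <- fitSDT(counts, modelSpec(m), sampler)
    est <- coef(fit)
    per_model[[m]] <- list(
      summary = summary(fit),
      coef = est,
      zroc = zrocLine(est[["mu_d"]], est[["sigma_s"]]),
      auc = sdtAUC(est[["mu_d"]], est[["sigma_s"]]),
      dic = dic(fit), waic = waic(fit),
      max_rhat = max(gelmanRhat(fit$draws)),
      fit = if (keep_fits) fit else NULL)
  }
  ic <- data.frame(model = models,
                   dic = vapply(per_model, function(x) as.numeric(x$dic), 0),
                   waic = vapply(per_model, function(x) as.numeric(x$waic), 0))
  ic$delta_dic <- ic$dic - ic$dic[1]
  ic$delta_waic <- ic$waic - ic$waic[1]
  report <- structure(list(models = per_model, ic = ic, n = nrow(counts)),
                      class = "comparisonReport")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in models) {
      utils::write.table(per_model[[m]]$summary,
                         file.path(out_dir, paste0("summary_", m, ".csv")),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
    utils::write.table(ic, file.path(out_dir, "information_criteria.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    writeReport(report, file.path(out_dir, "comparison_report.txt"))
  }
  report
}

#' @export
print.comparisonReport <- function(x, ...) {
  cat(sprintf("Model comparison on %d participants\n", x$n))
  for (m in names(x$models)) {
    pm <- x$models[[m]]
    cat(sprintf("\n%s: AUC %.3f; z-ROC slope %.2f, intercept %.2f; max Rhat %.4f\n",
                m, pm$auc, pm$zroc[["slope"]], pm$zroc[["intercept"]],
                pm$max_rhat))
    print(cbind(pm$summary["parameter"], round(pm$summary[-1], 3)))
  }
  cat("\nInformation criteria:\n")
  print(cbind(x$ic["model"], round(x$ic[-1], 1)))
  invisible(x)
}

#' Serialise a report to text and back
#'
#' Reports round-trip losslessly through a plain-text representation
#' (deparsed at full double precision).  Fits embedded with
#' \code{keep_fit = TRUE} are dropped before writing.
#'
#' @param report a \code{"recoveryReport"} or \code{"comparisonReport"}.
#' @param path output file.
#' @return \code{path} (write) / the restored report object (read).
#' @export
writeReport <- function(report, path) {
  report$fit <- NULL
  if (inherits(report, "comparisonReport"))
    report$models <- lapply(report$models, function(m) { m$fit <- NULL; m })
  writeLines(deparse(report, control = c("all", "digits17")), path)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  eval(parse(path), envir = baseenv())
}
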