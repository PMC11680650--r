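# Shared fixtures and independent oracles for the test suite.

toyCounts <- function() {
  data.frame(participant_id = c("p1", "p2"),
             hits = c(8L, 5L), false_alarms = c(2L, 4L),
             signal_trials = c(10L, 10L), noise_trials = c(10L, 10L))
}

standardPop <- function() populationParams(2.0, -0.5, 0.6, 0.4, 1.5)

randomPop <- function() {
  populationParams(mu_d = stats::runif(1, -1, 3),
                   mu_c = stats::runif(1, -1, 1),
                   sigma_d = stats::runif(1, 0.1, 1),
                   sigma_c = stats::runif(1, 0.1, 1),
                   sigma_s = stats::runif(1, 0.5, 2.5))
}

# Grid-integration posterior means E[d_i | h_i, f_i] and E[c_i | h_i, f_i]
# under KNOWN population parameters: a sampler-free Bayes estimator used as
# an independent oracle for the MCMC individual-level estimates.
gridPosteriorMeans <- function(counts, pop, half_width = 4.5, grid_n = 121) {
  dg <- seq(pop$mu_d - half_width * pop$sigma_d,
            pop$mu_d + half_width * pop$sigma_d, length.out = grid_n)
  cg <- seq(pop$mu_c - half_width * pop$sigma_c,
            pop$mu_c + half_width * pop$sigma_c, length.out = grid_n)
  G <- expand.grid(d = dg, c = cg)
  th <- stats::pnorm((0.5 * G$d - G$c) / pop$sigma_s)
  tf <- stats::pnorm(-0.5 * G$d - G$c)
  pri <- stats::dnorm(G$d, pop$mu_d, pop$sigma_d, log = TRUE) +
         stats::dnorm(G$c, pop$mu_c, pop$sigma_c, log = TRUE)
  n <- nrow(counts)
  dhat <- chat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- stats::dbinom(counts$hits[i], counts$signal_trials[i], th, log = TRUE) +
          stats::dbinom(counts$false_alarms[i], counts$noise_trials[i], tf,
                        log = TRUE) + pri
    w <- exp(ll - max(ll)); w <- w / sum(w)
    dhat[i] <- sum(w * G$d); chat[i] <- sum(w * G$c)
  }
  data.frame(d = dhat, c = chat)
}

# A tiny but real posterior fit reused by several diagnostic tests.
smallFit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateSDT(simConfig(standardPop(), 40, 100, 100, seed = 21))
      cache <<- list(sim = sim,
                     fit = fitSDT(sim$counts, modelSpec("huvsd"),
                                  samplerConfig(chains = 2, iterations = 3000,
                                                burn_in = 1500, seed = 5)))
    }
    cache
  }
})
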