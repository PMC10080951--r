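# ZEST: Bayesian yes/no threshold strategy with a mean-of-posterior stimulus
# rule, as used for perimetric threshold estimation.

#' ZEST strategy configuration
#'
#' Defaults follow standard perimetric practice: uniform prior over the
#' instrument range 0-50 dB on a 0.1 dB grid, Gaussian-CDF likelihood with
#' SD 1 dB and 3% guess/lapse, stimulus = posterior mean rounded to the
#' nearest integer dB, dynamic termination at posterior SD < 1.5 dB.
#'
#' @param prior_range dB range of the uniform prior.
#' @param grid_step posterior grid resolution, dB.
#' @param likelihood_sd Gaussian likelihood SD, dB.
#' @param likelihood_rate guess/lapse rate of the likelihood.
#' @param stop_sd termination criterion on the posterior SD, dB.
#' @param max_trials runaway guard.
#' @return object of class `zest_config`.
#' @export
zest_config <- function(prior_range = c(0, 50), grid_step = 0.1,
                        likelihood_sd = 1, likelihood_rate = 0.03,
                        stop_sd = 1.5, max_trials = 200) {
  structure(list(prior_range = prior_range, grid_step = grid_step,
                 likelihood_sd = likelihood_sd, likelihood_rate = likelihood_rate,
                 stop_sd = stop_sd, max_trials = max_trials),
            class = "zest_config")
}

#' Run one ZEST thread against a simulated observer
#'
#' @param observer a [psychometric_params()] describing the true
#'   frequency-of-seeing curve.
#' @param cfg a [zest_config()].
#' @param seed integer seed for the simulated responses.
#' @return list with `threshold` (posterior mean, dB), `n_trials`, `trace`
#'   (data frame of stimulus, response, posterior mean/SD per trial) and
#'   `runaway` (TRUE if the trial cap was hit before termination).
#' @export
zest_run <- function(observer, cfg = zest_config(), seed = NULL) {
  stopifnot(inherits(observer, "psychometric_params"), inherits(cfg, "zest_config"))
  grid <- seq(cfg$prior_range[1], cfg$prior_range[2], by = cfg$grid_step)
  post <- rep(1 / length(grid), length(grid))
  rate <- cfg$likelihood_rate
  trace <- vector("list", cfg$max_trials)
  with_seed(seed, {
    n <- 0
    repeat {
      pm <- sum(grid * post)
      psd <- sqrt(sum(grid^2 * post) - pm^2)
      if (n > 0 && psd < cfg$stop_sd) break
      if (n >= cfg$max_trials) break
      stim <- round(pm)
      seen <- observe_trial(stim, observer)
      lik <- rate + (1 - 2 * rate) * pnorm((grid - stim) / cfg$likelihood_sd)
      if (!seen) lik <- 1 - lik
      post <- post * lik
      post <- post / sum(post)
      n <- n + 1
      pm2 <- sum(grid * post)
      trace[[n]] <- data.frame(trial = n, stimulus_db = stim, seen = seen,
                               post_mean = pm2,
                               post_sd = sqrt(sum(grid^2 * post) - pm2^2))
    }
    trace <- do.call(rbind, trace[seq_len(n)])
    runaway <- n >= cfg$max_trials && trace$post_sd[n] >= cfg$stop_sd
    if (runaway) warnf("ZEST hit the %d-trial cap before termination", cfg$max_trials)
    list(threshold = sum(grid * post), n_trials = n, trace = trace,
         runaway = runaway)
  })
}
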