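# QUEST+: two-parameter Bayesian adaptive estimation of the
# frequency-of-seeing curve (threshold and spread simultaneously), choosing
# each stimulus to minimize the expected posterior entropy and stopping when
# the joint posterior entropy falls below a criterion.

#' QUEST+ configuration
#'
#' The threshold prior is a Gaussian centered on a seed estimate (from ZEST),
#' SD 4 dB, truncated to +/- 5 dB around its mean; the spread prior is
#' uniform on 1-10 dB in 0.5 dB steps; guess/lapse are fixed at 3%. Entropy
#' is measured in nats over the joint grid; the default stop criterion is
#' 4.5.
#'
#' @param mu_seed center of the threshold prior, dB.
#' @param mu_prior_sd threshold prior SD, dB.
#' @param mu_halfwidth half-width of the threshold domain, dB.
#' @param mu_step threshold grid step, dB.
#' @param sigma_range,sigma_step spread prior domain and step, dB.
#' @param rate fixed guess/lapse rate.
#' @param stop_entropy termination criterion, nats.
#' @param candidates candidate stimulus levels, dB (integer grid).
#' @param max_trials runaway guard.
#' @return object of class `questplus_config`.
#' @export
questplus_config <- function(mu_seed, mu_prior_sd = 4, mu_halfwidth = 5,
                             mu_step = 0.1, sigma_range = c(1, 10),
                             sigma_step = 0.5, rate = 0.03,
                             stop_entropy = 4.5, candidates = 0:50,
                             max_trials = 300) {
  structure(list(mu_seed = mu_seed, mu_prior_sd = mu_prior_sd,
                 mu_halfwidth = mu_halfwidth, mu_step = mu_step,
                 sigma_range = sigma_range, sigma_step = sigma_step,
                 rate = rate, stop_entropy = stop_entropy,
                 candidates = candidates, max_trials = max_trials),
            class = "questplus_config")
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Expected posterior entropy for every candidate, given the current posterior
# and the likelihood matrix P[state, candidate] = P(seen).
questplus_expected_entropy <- function(post, P) {
  M1 <- post * P            # joint (state, candidate) mass for "seen"
  p1 <- colSums(M1)
  M0 <- post * (1 - P)
  p0 <- colSums(M0)
  safe_xlogx <- function(M) {
    M[M <= 0] <- 1  # x log x -> 0
    M * log(M)
  }
  A1 <- -colSums(safe_xlogx(M1))
  A0 <- -colSums(safe_xlogx(M0))
  H1 <- ifelse(p1 > 0, A1 / p1 + log(p1), 0)
  H0 <- ifelse(p0 > 0, A0 / p0 + log(p0), 0)
  p1 * H1 + p0 * H0
}

#' Run a QUEST+ thread against a simulated observer
#'
#' @param observer a [psychometric_params()].
#' @param cfg a [questplus_config()].
#' @param seed integer seed.
#' @return list with `mu_hat`, `sigma_hat` (posterior means), `n_trials`,
#'   `entropy` (final), `trace`, `runaway`.
#' @export
questplus_run <- function(observer, cfg, seed = NULL) {
  stopifnot(inherits(observer, "psychometric_params"),
            inherits(cfg, "questplus_config"))
  mu_grid <- seq(cfg$mu_seed - cfg$mu_halfwidth, cfg$mu_seed + cfg$mu_halfwidth,
                 by = cfg$mu_step)
  sigma_grid <- seq(cfg$sigma_range[1], cfg$sigma_range[2], by = cfg$sigma_step)
  states <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  prior <- dnorm(states$mu, cfg$mu_seed, cfg$mu_prior_sd)
  post <- prior / sum(prior)
  P <- cfg$rate + (1 - 2 * cfg$rate) *
    pnorm((outer(states$mu, cfg$candidates, "-")) / states$sigma)
  trace <- vector("list", cfg$max_trials)
  with_seed(seed, {
    n <- 0
    repeat {
      H <- entropy_nats(post)
      if (H <= cfg$stop_entropy) break
      if (n >= cfg$max_trials) break
      eh <- questplus_expected_entropy(post, P)
      ci <- which.min(eh)
      stim <- cfg$candidates[ci]
      seen <- observe_trial(stim, observer)
      lik <- if (seen) P[, ci] else 1 - P[, ci]
      post <- post * lik
      post <- post / sum(post)
      n <- n + 1
      trace[[n]] <- data.frame(trial = n, stimulus_db = stim, seen = seen,
                               entropy = entropy_nats(post))
    }
    trace <- do.call(rbind, trace[seq_len(n)])
    runaway <- n >= cfg$max_trials && entropy_nats(post) > cfg$stop_entropy
    if (runaway) warnf("QUEST+ hit the %d-trial cap before termination", cfg$max_trials)
    list(mu_hat = sum(states$mu * post), sigma_hat = sum(states$sigma * post),
         n_trials = n, entropy = entropy_nats(post), trace = trace,
         posterior = post, states = states, runaway = runaway)
  })
}
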