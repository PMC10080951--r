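# Method of constant stimuli: level placement and experiment bookkeeping.

#' MOCS stimulus levels from a coarse FOS estimate
#'
#' Places seven levels at the {0.0001, 0.1, 0.3, 0.5, 0.7, 0.9, 0.9999}
#' quantiles of the estimated Gaussian frequency-of-seeing curve, then (i)
#' pushes the two extremes to at least 10 dB above and below the threshold,
#' (ii) spreads inner levels outward minimally so all levels are at least
#' 1 dB apart (the instrument's minimum step), and (iii) rounds to the 1 dB
#' grid preserving order.
#'
#' @param mu_hat estimated 50% threshold, dB.
#' @param sigma_hat estimated spread, dB; must lie in the QUEST+ prior range
#'   [1, 10].
#' @return integer vector of 7 levels, dB, increasing.
#' @examples
#' mocs_design(30, 2)  # 20 27 29 30 31 33 40
#' @export
mocs_design <- function(mu_hat, sigma_hat) {
  if (!is.finite(sigma_hat) || sigma_hat < 1 || sigma_hat > 10) {
    stopf("sigma_hat must be in [1, 10] dB")
  }
  q <- c(0.0001, 0.1, 0.3, 0.5, 0.7, 0.9, 0.9999)
  lv <- mu_hat + sigma_hat * qnorm(q)
  lv[1] <- min(lv[1], mu_hat - 10)
  lv[7] <- max(lv[7], mu_hat + 10)
  for (i in 5:7) lv[i] <- max(lv[i], lv[i - 1] + 1)
  for (i in 3:1) lv[i] <- min(lv[i], lv[i + 1] - 1)
  lv <- round(lv)
  for (i in 5:7) lv[i] <- max(lv[i], lv[i - 1] + 1)
  for (i in 3:1) lv[i] <- min(lv[i], lv[i + 1] - 1)
  as.integer(lv)
}

#' MOCS experiment size
#'
#' @param n_levels levels per condition (default 7).
#' @param n_repeats presentations per level (default 25).
#' @param n_conditions stimulus size/duration combinations (default 4).
#' @param n_locations test locations (default 4).
#' @return total number of presentations (2,800 with the defaults).
#' @export
mocs_trial_count <- function(n_levels = 7, n_repeats = 25, n_conditions = 4,
                             n_locations = 4) {
  n_levels * n_repeats * n_conditions * n_locations
}

#' Simulate a MOCS block for one observer
#'
#' @param levels stimulus levels, dB.
#' @param observer a [psychometric_params()].
#' @param n_repeats presentations per level.
#' @param seed integer seed.
#' @return data frame of trials (`stimulus_db`, `seen`), fully randomized.
#' @export
simulate_mocs <- function(levels, observer, n_repeats = 25, seed = NULL) {
  with_seed(seed, {
    stim <- sample(rep(levels, each = n_repeats))
    data.frame(stimulus_db = stim,
               seen = runif(length(stim)) < p_seen(stim, observer))
  })
}
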