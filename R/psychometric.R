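# Frequency-of-seeing (psychometric) functions for the yes/no perimetric task.

#' Psychometric function parameters
#'
#' The probability of seeing a stimulus of intensity x dB is
#' \eqn{p(x) = \gamma + (1 - \gamma - \lambda)\,\Phi((\mu - x)/\sigma)}:
#' decreasing in x (higher dB = dimmer), with lower asymptote the guess rate
#' and upper asymptote 1 - lapse rate.
#'
#' @param mu 50% threshold, dB.
#' @param sigma spread (inverse slope), dB (> 0).
#' @param lapse_rate,guess_rate rates in [0, 0.5).
#' @return object of class `psychometric_params`.
#' @export
psychometric_params <- function(mu, sigma, lapse_rate = 0, guess_rate = 0) {
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be positive")
  for (r in c(lapse_rate, guess_rate)) {
    if (!is.finite(r) || r < 0 || r >= 0.5) stopf("rates must be in [0, 0.5)")
  }
  structure(list(mu = mu, sigma = sigma, lapse_rate = lapse_rate,
                 guess_rate = guess_rate),
            class = "psychometric_params")
}

#' Probability of seeing
#'
#' @param x stimulus intensity, dB.
#' @param p a [psychometric_params()].
#' @return probability of a "seen" response.
#' @export
p_seen <- function(x, p) {
  stopifnot(inherits(p, "psychometric_params"))
  p$guess_rate + (1 - p$guess_rate - p$lapse_rate) * pnorm((p$mu - x) / p$sigma)
}

# simulate one yes/no response (assumes RNG state is already set)
observe_trial <- function(x, observer) {
  runif(1) < p_seen(x, observer)
}
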