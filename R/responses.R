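# Response-time validity filtering and synthetic observers.

#' Flag false responses
#'
#' A button press is a false response if it occurs less than 180 ms after
#' stimulus onset (faster than human reaction) or within an inter-stimulus
#' pause window. Trials with no response are valid by definition.
#'
#' @param records data frame with column `rt_ms` (response latency from
#'   stimulus onset; NA for no response) and optionally `response_abs_ms`
#'   (absolute response time, for pause checking).
#' @param pauses optional data frame of pause windows with columns
#'   `start_ms`, `end_ms` (absolute time).
#' @param min_latency_ms minimum plausible latency (default 180 ms).
#' @return `records` with a logical `valid` column added.
#' @export
filter_responses <- function(records, pauses = NULL, min_latency_ms = 180) {
  if (!("rt_ms" %in% names(records))) stopf("records need an rt_ms column")
  valid <- is.na(records$rt_ms) | records$rt_ms >= min_latency_ms
  if (!is.null(pauses) && nrow(pauses) > 0) {
    if (!("response_abs_ms" %in% names(records))) {
      stopf("pause filtering needs a response_abs_ms column")
    }
    t_abs <- records$response_abs_ms
    in_pause <- rep(FALSE, nrow(records))
    for (i in seq_len(nrow(pauses))) {
      in_pause <- in_pause |
        (!is.na(t_abs) & t_abs >= pauses$start_ms[i] & t_abs <= pauses$end_ms[i])
    }
    valid <- valid & !in_pause
  }
  records$valid <- valid
  records
}

#' Synthetic observer for a stimulus condition
#'
#' Builds a frequency-of-seeing curve whose threshold is the model's
#' predicted sensitivity for the condition and whose spread follows a
#' log-linear slope-threshold relation (shallower curves at lower
#' sensitivity, the standard signature of multiplicative noise). The default
#' relation constants are in the range reported for perimetric observers.
#'
#' @param params an [st_params()] (with its offset set).
#' @param map an [area_input_map()] for the location.
#' @param area stimulus area, deg2.
#' @param duration_ms stimulus duration, ms.
#' @param slope,intercept constants of log10(sigma) = intercept + slope * mu
#'   (mu in dB).
#' @param lapse_rate,guess_rate observer rates.
#' @param noise_sd optional Gaussian perturbation of the threshold, dB
#'   (test-retest noise); 0 leaves mu exactly at the model prediction.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return a [psychometric_params()].
#' @export
synthetic_observer <- function(params, map, area, duration_ms,
                               slope = -0.035, intercept = 1.42,
                               lapse_rate = 0.01, guess_rate = 0.01,
                               noise_sd = 0, seed = NULL) {
  S <- area_to_input(map, area)
  mu <- 10 * predicted_dls(S, duration_ms, params)
  if (noise_sd > 0) mu <- mu + with_seed(seed, rnorm(1, 0, noise_sd))
  sigma <- 10^(intercept + slope * mu)
  psychometric_params(mu, max(sigma, 0.25), lapse_rate, guess_rate)
}
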