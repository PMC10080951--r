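# The spatiotemporal pooler.
#
# The total spatial input S charges a leaky integrator ("capacitor") whose
# impulse response is h(t) = (S/tau) exp(-t S / tau): unit area, time constant
# tau/S, so larger stimuli integrate faster and the critical duration
# shortens, while longer durations shrink Ricco's area. Convolving h with the
# stimulus step f(t) (duration T) and pooling with a Minkowski exponent k
# gives the closed form
#
#   R = (tau * g(x))^(1/k),  x = S*T/tau,
#   g(x) = int_0^x (1 - e^-u)^k du + (1 - e^-x)^k / k.
#
# Sensitivity readout is DLS = log10(R) + Offset, with contrast entering only
# at this stage (stimuli are modeled at unit Weber contrast). Both the closed
# form and an independent numerical-convolution route are provided.

#' Spatiotemporal pooler parameters
#'
#' @param tau integration constant, input-units x ms (> 0).
#' @param k Minkowski summation exponent (default 4).
#' @param offset vertical offset of the sensitivity readout, log10-DLS units.
#' @return object of class `st_params`.
#' @export
st_params <- function(tau, k = 4, offset = 0) {
  if (!is.finite(tau) || tau <= 0) stopf("tau must be positive")
  if (!is.finite(k) || k < 1) stopf("k must be >= 1")
  structure(list(tau = tau, k = k, offset = offset), class = "st_params")
}

# g(x): the normalized pooled-energy integral. Closed (binomial) form for
# integer k at x >= 0.1; adaptive quadrature otherwise (the binomial sum
# cancels catastrophically for small x).
g_integral <- function(x, k) {
  if (any(x < 0)) stopf("x must be non-negative")
  bterm <- (-expm1(-x))^k / k
  main <- numeric(length(x))
  closed <- (abs(k - round(k)) < 1e-12) & (x >= 0.1)
  if (any(closed)) {
    kk <- round(k)
    j <- seq_len(kk)
    cj <- choose(kk, j) * (-1)^j / j
    xs <- x[closed]
    main[closed] <- xs + colSums(cj * (-expm1(-outer(j, xs))))
  }
  if (any(!closed)) {
    main[!closed] <- vapply(x[!closed], function(xx) {
      if (xx == 0) return(0)
      integrate(function(u) (-expm1(-u))^k, 0, xx,
                rel.tol = 1e-12, abs.tol = 0)$value
    }, numeric(1))
  }
  main + bterm
}

#' Pooled spatiotemporal response
#'
#' @param S total spatial input (> 0), from [spatial_input()] or an
#'   [area_input_map()].
#' @param T_ms stimulus duration, ms (> 0).
#' @param params an [st_params()].
#' @return object of class `summation_result` (a data frame with columns
#'   `S`, `T_ms`, `x` (normalized input S*T/tau), `time_constant` (tau/S, ms)
#'   and `R`). `R` depends on S and T only through their product.
#' @export
pooled_response <- function(S, T_ms, params) {
  stopifnot(inherits(params, "st_params"))
  n <- max(length(S), length(T_ms))
  S <- rep_len(S, n)
  T_ms <- rep_len(T_ms, n)
  if (any(!is.finite(S)) || any(S <= 0)) stopf("S must be positive")
  if (any(!is.finite(T_ms)) || any(T_ms <= 0)) stopf("T_ms must be positive")
  x <- S * T_ms / params$tau
  R <- (params$tau * g_integral(x, params$k))^(1 / params$k)
  structure(data.frame(S = S, T_ms = T_ms, x = x,
                       time_constant = params$tau / S, R = R),
            class = c("summation_result", "data.frame"))
}

#' Pooled response by numerical convolution (independent route)
#'
#' Evaluates the pooler with no use of the closed form: the response
#' waveform r(t) is obtained by numerical convolution of the stimulus step
#' with the integrator kernel (inner quadrature), and the Minkowski pooling
#' integral is evaluated by outer quadrature on (0, Inf). Slow; intended for
#' cross-validation of [pooled_response()].
#'
#' @inheritParams pooled_response
#' @return scalar R.
#' @export
pooled_response_numeric <- function(S, T_ms, params) {
  stopifnot(inherits(params, "st_params"), length(S) == 1, length(T_ms) == 1)
  if (S <= 0 || T_ms <= 0) stopf("S and T_ms must be positive")
  rate <- S / params$tau
  h <- function(u) rate * exp(-rate * u)
  r_of_t <- function(t) {
    vapply(t, function(tt) {
      lo <- max(0, tt - T_ms)
      if (lo >= tt) return(0)
      integrate(h, lo, tt, rel.tol = 1e-11, abs.tol = 0)$value
    }, numeric(1))
  }
  k <- params$k
  tail_end <- T_ms + 50 / rate
  i1 <- integrate(function(t) r_of_t(t)^k, 0, T_ms, rel.tol = 1e-9)$value
  i2 <- integrate(function(t) r_of_t(t)^k, T_ms, tail_end, rel.tol = 1e-9)$value
  (S * (i1 + i2))^(1 / k)
}

#' Predicted differential light sensitivity
#'
#' DLS = log10(R) + Offset, in dB/10 units (multiply by 10 for dB).
#'
#' @inheritParams pooled_response
#' @return numeric vector of predicted DLS.
#' @export
predicted_dls <- function(S, T_ms, params) {
  log10(pooled_response(S, T_ms, params)$R) + params$offset
}

#' Critical normalized input for the slope-0.5 criterion
#'
#' The log-log slope of R against S (at fixed T) is
#' x (1-e^-x)^(k-1) / (k g(x)), decreasing from 1 (complete summation,
#' Ricco/Bloch regime) to 1/k (partial summation). The critical point solves
#' slope = 0.5 (Piper criterion); it exists only for k > 2.
#'
#' @param k summation exponent.
#' @return critical normalized input x_c (2.8822 for k = 4).
#' @export
critical_x <- function(k = 4) {
  if (k <= 2) stopf("slope-0.5 criterion has no solution for k <= 2")
  uniroot(function(x) x * (-expm1(-x))^(k - 1) - (k / 2) * g_integral(x, k),
          c(0.05, 100), tol = 1e-10)$root
}

#' Critical input and critical duration
#'
#' Given the pooler parameters, the critical total input at duration T is
#' S_c = x_c tau / T, and the critical duration at input S is
#' T_c = x_c tau / S; their product S*T is constant at x_c tau.
#'
#' @param params an [st_params()].
#' @param T_ms stimulus duration, ms.
#' @param S total spatial input.
#' @return object of class `critical_point`: list with `x_c`, `S_c`, `T_c`,
#'   `tau`, `k`.
#' @export
critical_input <- function(params, T_ms) {
  stopifnot(inherits(params, "st_params"))
  if (any(T_ms <= 0)) stopf("T_ms must be positive")
  xc <- critical_x(params$k)
  structure(list(x_c = xc, S_c = xc * params$tau / T_ms, T_c = T_ms,
                 tau = params$tau, k = params$k),
            class = "critical_point")
}

#' @rdname critical_input
#' @export
critical_duration <- function(params, S) {
  stopifnot(inherits(params, "st_params"))
  if (any(S <= 0)) stopf("S must be positive")
  xc <- critical_x(params$k)
  structure(list(x_c = xc, S_c = S, T_c = xc * params$tau / S,
                 tau = params$tau, k = params$k),
            class = "critical_point")
}

#' Ricco's area
#'
#' Converts the critical input S_c at duration T back to a stimulus area
#' through the (conventionally blur-free) area-input map.
#'
#' @param params an [st_params()].
#' @param T_ms stimulus duration, ms.
#' @param map an [area_input_map()] for the location's retinal context.
#' @return critical area, deg2.
#' @export
ricco_area <- function(params, T_ms, map) {
  cp <- critical_input(params, T_ms)
  input_to_area(map, cp$S_c)
}

#' Spatial summation curve
#'
#' Predicted DLS across a ladder of stimulus areas at fixed duration.
#' Because R depends on area and duration only through their product (times
#' density), doubling the duration shifts the curve by exactly -log10(2)
#' along log-area.
#'
#' @param params an [st_params()].
#' @param map an [area_input_map()].
#' @param T_ms duration, ms.
#' @param areas areas, deg2 (defaults to the map's ladder).
#' @return data frame with `area`, `S`, `dls`.
#' @export
summation_curve <- function(params, map, T_ms, areas = NULL) {
  if (is.null(areas)) areas <- map$areas
  S <- area_to_input(map, areas)
  data.frame(area = areas, S = S, dls = predicted_dls(S, T_ms, params))
}

#' Fit the spatiotemporal model to threshold data
#'
#' Minimizes the root-mean-squared error (in dB) between observed and
#' predicted sensitivity over (log10 tau, offset) with Nelder-Mead from
#' three deterministic starts, keeping the summation exponent fixed.
#'
#' @param data data frame with columns `duration_ms`, a sensitivity column
#'   (`db` or `dls`), and either `S` (total input) or `area` (deg2, converted
#'   through `map`).
#' @param map an [area_input_map()]; required when `data` has `area` but not
#'   `S`.
#' @param k fixed summation exponent.
#' @return list with `tau`, `offset`, `rmse_db`, `k`, `params` (an
#'   [st_params()]), and `n`.
#' @export
fit_spatiotemporal <- function(data, map = NULL, k = 4) {
  if (!("S" %in% names(data))) {
    if (is.null(map) || !("area" %in% names(data))) {
      stopf("data needs an S column, or an area column plus a map")
    }
    data$S <- area_to_input(map, data$area)
  }
  if (!("db" %in% names(data))) {
    if (!("dls" %in% names(data))) stopf("data needs a db or dls column")
    data$db <- 10 * data$dls
  }
  if (!("duration_ms" %in% names(data))) stopf("data needs a duration_ms column")
  if (nrow(data) < 3) stopf("need at least 3 observations")
  st <- data$S * data$duration_ms
  if (diff(range(st)) < 1e-9 * max(st)) {
    stopf("unidentifiable: all observations share the same S x T product")
  }
  obs_dls <- data$db / 10
  objective <- function(par) {
    params <- st_params(10^par[1], k = k, offset = par[2])
    pred <- predicted_dls(data$S, data$duration_ms, params)
    sqrt(mean((10 * (pred - obs_dls))^2))
  }
  best <- NULL
  for (lt in c(2, 3, 4)) {
    p0 <- st_params(10^lt, k = k)
    off0 <- mean(obs_dls - log10(pooled_response(data$S, data$duration_ms, p0)$R))
    fit <- optim(c(lt, off0), objective, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  params <- st_params(10^best$par[1], k = k, offset = best$par[2])
  list(tau = params$tau, offset = params$offset, rmse_db = best$value,
       k = k, params = params, n = nrow(data))
}

# invert a (possibly noisy) log-log S(area) curve at a single input value by
# local linear interpolation around the crossing
invert_crossing <- function(log_S, log_area, log_Sc) {
  ok <- is.finite(log_S)
  log_S <- log_S[ok]
  log_area <- log_area[ok]
  if (log_Sc < min(log_S) || log_Sc > max(log_S)) {
    stopf("critical input outside the tabulated curve; widen the area ladder")
  }
  i <- max(which(log_S <= log_Sc))
  if (i == length(log_S)) return(10^log_area[i])
  w <- (log_Sc - log_S[i]) / (log_S[i + 1] - log_S[i])
  10^(log_area[i] + w * (log_area[i + 1] - log_area[i]))
}

#' Effect of random RGC loss on Ricco's area
#'
#' Computes per-RGC responses for a ladder of areas once on the intact
#' mosaic, then deletes cells i.i.d. with probability `loss_fraction` over
#' `n_seeds` replicates (deletion only removes summands from Eq. 5) and
#' re-derives Ricco's area from each degraded area-input curve. With signed
#' summation the expected input scales by (1 - loss), so the expected area
#' ratio is 1/(1 - loss).
#'
#' @param context a [retinal_context()].
#' @param params an [st_params()].
#' @param T_ms duration, ms.
#' @param loss_fraction i.i.d. cell deletion probability.
#' @param n_seeds number of degraded replicates.
#' @param seed master seed.
#' @param areas area ladder (must bracket both intact and degraded critical
#'   areas).
#' @return list with `intact_area`, `ratios` (length `n_seeds`),
#'   `mean_ratio`.
#' @export
ricco_loss_ratio <- function(context, params, T_ms, loss_fraction = 0.73,
                             n_seeds = 100, seed = 1,
                             areas = 10^seq(-2, 0.3, by = 0.1)) {
  map <- area_input_map(context, areas = areas, method = "mosaic",
                        blur = FALSE, keep_responses = TRUE)
  Sc <- critical_input(params, T_ms)$S_c
  intact_area <- input_to_area(map, Sc)
  n <- nrow(map$responses)
  ratios <- with_seed(seed, {
    vapply(seq_len(n_seeds), function(i) {
      surv <- runif(n) >= loss_fraction
      S_deg <- colSums(map$responses[surv, , drop = FALSE])
      S_deg[S_deg <= 0] <- NA  # signed sums can dip below 0 at tiny areas
      area_deg <- invert_crossing(log10(S_deg), log10(map$areas), log10(Sc))
      area_deg / intact_area
    }, numeric(1))
  })
  list(intact_area = intact_area, ratios = ratios, mean_ratio = mean(ratios))
}
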