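# Seeded synthetic data emulating the experimental design: model-generated
# thresholds with test-retest noise, and MOCS trial tables from synthetic
# observers.

#' Specification for a synthetic data set
#'
#' Defaults reproduce the experimental design grid: 12 locations on the
#' diagonals ({+-7,+-7}, {+-4,+-4}, {+-1,+-1} deg), Goldmann sizes I-V
#' everywhere at 200 ms, with four additional durations (15, 30, 55, 105 ms)
#' at the {+-7,+-7} ring — 140 independent threshold threads in total. Model
#' truth uses convergence-weighted input with the all-durations integration
#' constant; test-retest noise is Gaussian with SD 1 dB.
#'
#' @param tau,offset,k generating pooler parameters (convergence-weighted
#'   input units).
#' @param density_table retinal density table (see [read_density_table()]).
#' @param sizes Goldmann size labels.
#' @param durations_ms durations tested at the outer ring.
#' @param base_duration_ms duration tested at every location.
#' @param locations data frame with `x_deg`, `y_deg`.
#' @param noise_sd_db test-retest threshold noise, dB.
#' @param fos_slope,fos_intercept slope-threshold relation constants for the
#'   synthetic observers.
#' @param seed master seed; child seeds are derived per stage.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(tau = 3465, offset = 2.36, k = 4,
                         density_table = default_density_table(),
                         sizes = c("I", "II", "III", "IV", "V"),
                         durations_ms = c(15, 30, 55, 105),
                         base_duration_ms = 200,
                         locations = NULL,
                         noise_sd_db = 1,
                         fos_slope = -0.035, fos_intercept = 1.42,
                         seed = 1) {
  if (is.null(locations)) {
    sgn <- expand.grid(sx = c(-1, 1), sy = c(-1, 1))
    locations <- do.call(rbind, lapply(c(7, 4, 1), function(a) {
      data.frame(x_deg = sgn$sx * a, y_deg = sgn$sy * a)
    }))
  }
  structure(list(tau = tau, offset = offset, k = k,
                 density_table = density_table, sizes = sizes,
                 durations_ms = durations_ms,
                 base_duration_ms = base_duration_ms,
                 locations = locations, noise_sd_db = noise_sd_db,
                 fos_slope = fos_slope, fos_intercept = fos_intercept,
                 seed = seed),
            class = "fixture_spec")
}

# convergence-weighted product map for one location from a density table
location_map <- function(density_table, ecc) {
  prof <- convergence_profile(
    density_table[, c("eccentricity_deg", "cone_density_per_deg2")],
    density_table[, c("eccentricity_deg", "rgc_rf_density_per_deg2")]
  )
  ctx <- retinal_context(rgc_density = prof$rgc(ecc),
                         convergence = convergence_ratio(prof, ecc))
  area_input_map(ctx, method = "product")
}

#' Generate a synthetic threshold and trial data set
#'
#' Thresholds are the model's predicted sensitivities (convergence-weighted
#' product mapping) plus Gaussian test-retest noise; the trial table holds
#' MOCS responses from synthetic observers for the four extreme
#' size/duration conditions at the outer ring, mirroring the
#' frequency-of-seeing protocol.
#'
#' @param spec a [fixture_spec()].
#' @return list with `thresholds` (one row per thread) and `trials` (MOCS
#'   trial records), both seeded and reproducible.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  params <- st_params(spec$tau, k = spec$k, offset = spec$offset)
  loc <- spec$locations
  outer_ring <- abs(loc$x_deg) == max(abs(loc$x_deg))
  rows <- list()
  for (i in seq_len(nrow(loc))) {
    ecc <- sqrt(loc$x_deg[i]^2 + loc$y_deg[i]^2)
    map <- location_map(spec$density_table, ecc)
    durs <- if (outer_ring[i]) c(spec$base_duration_ms, spec$durations_ms) else spec$base_duration_ms
    for (sz in spec$sizes) {
      a <- goldmann_area(sz)
      S <- area_to_input(map, a)
      for (T_ms in durs) {
        rows[[length(rows) + 1]] <- data.frame(
          x_deg = loc$x_deg[i], y_deg = loc$y_deg[i],
          eccentricity_deg = ecc, size_label = sz,
          diameter_deg = goldmann_diameter(sz), area_deg2 = a,
          duration_ms = T_ms, S = S,
          db_true = 10 * predicted_dls(S, T_ms, params))
      }
    }
  }
  thr <- do.call(rbind, rows)
  thr$db <- with_seed(child_seed(spec$seed, "thresholds"), {
    thr$db_true + rnorm(nrow(thr), 0, spec$noise_sd_db)
  })
  thr$dls <- thr$db / 10

  # MOCS trials: extreme size/duration combinations at the outer ring
  fos_conditions <- expand.grid(size_label = c("I", "V"),
                                duration_ms = range(c(spec$base_duration_ms,
                                                      spec$durations_ms)),
                                stringsAsFactors = FALSE)
  trial_rows <- list()
  oloc <- loc[outer_ring, , drop = FALSE]
  for (i in seq_len(nrow(oloc))) {
    ecc <- sqrt(oloc$x_deg[i]^2 + oloc$y_deg[i]^2)
    map <- location_map(spec$density_table, ecc)
    for (j in seq_len(nrow(fos_conditions))) {
      sz <- fos_conditions$size_label[j]
      T_ms <- fos_conditions$duration_ms[j]
      obs <- synthetic_observer(params, map, goldmann_area(sz), T_ms,
                                slope = spec$fos_slope,
                                intercept = spec$fos_intercept)
      lv <- mocs_design(round(obs$mu), min(10, max(1, obs$sigma)))
      tr <- simulate_mocs(lv, obs,
                          seed = child_seed(spec$seed, paste("mocs", i, j)))
      tr$x_deg <- oloc$x_deg[i]
      tr$y_deg <- oloc$y_deg[i]
      tr$location <- i
      tr$size_label <- sz
      tr$duration_ms <- T_ms
      tr$mu_true <- obs$mu
      tr$sigma_true <- obs$sigma
      trial_rows[[length(trial_rows) + 1]] <- tr
    }
  }
  list(thresholds = thr, trials = do.call(rbind, trial_rows))
}
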