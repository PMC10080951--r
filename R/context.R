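# Retinal context: everything the model needs to know about one visual-field
# location, and the numeric mapping between stimulus area and total retinal
# input used for Ricco's-area reporting.

#' Retinal context for one visual-field location
#'
#' @param rgc_density parasol-OFF RGC receptive-field density, cells/deg2.
#' @param cone_density cone density, cells/deg2; together with `rgc_density`
#'   it sets the convergence weight (their ratio). Defaults to `rgc_density`
#'   (convergence 1).
#' @param convergence explicit convergence weight; overrides the density
#'   ratio if given.
#' @param optics an [optics_params()] or NULL (no optical blur).
#' @param mode summation mode for Eq. 5: `"signed"` (default) or
#'   `"absolute"`.
#' @param dog_truncate kernel truncation radius in surround SDs.
#' @return object of class `retinal_context`.
#' @export
retinal_context <- function(rgc_density, cone_density = NULL, convergence = NULL,
                            optics = NULL, mode = c("signed", "absolute"),
                            dog_truncate = 4) {
  mode <- match.arg(mode)
  if (!is.finite(rgc_density) || rgc_density <= 0) stopf("rgc_density must be positive")
  if (is.null(convergence)) {
    convergence <- if (is.null(cone_density)) 1 else cone_density / rgc_density
  }
  if (!is.finite(convergence) || convergence <= 0) stopf("convergence must be positive")
  if (!is.null(optics)) stopifnot(inherits(optics, "optics_params"))
  spacing <- hex_spacing(rgc_density)
  structure(list(rgc_density = rgc_density, convergence = convergence,
                 optics = optics, mode = mode, spacing = spacing,
                 dog = dog_params(spacing, truncate = dog_truncate)),
            class = "retinal_context")
}

#' Map between stimulus area and total retinal input
#'
#' Computes the total spatial input S for a ladder of disc areas in a given
#' retinal context, either numerically from the mosaic simulation
#' (`method = "mosaic"`: render the disc, optionally blur it, sample it with
#' the cone mosaic, pool through DoG receptive fields, sum) or analytically
#' (`method = "product"`: S = area x RGC density x convergence, the
#' signed-mode large-mosaic limit). Queries between ladder points are
#' interpolated linearly in log10-log10 space, following the local-linear
#' approximation used for critical-size reporting.
#'
#' @param context a [retinal_context()].
#' @param areas ladder of stimulus areas, deg2 (geometric by default).
#' @param method `"product"` (fast, analytic) or `"mosaic"` (numeric).
#' @param blur apply the context's optics before sampling (mosaic method
#'   only). Defaults to TRUE when the context carries enabled optics.
#'   Ricco's-area reporting conventionally uses blur-free maps.
#' @param keep_responses keep the per-RGC response matrix (mosaic method),
#'   needed for degradation studies.
#' @param phase_seed lattice phase jitter passed to [build_hex_mosaic()].
#' @return object of class `area_input_map`.
#' @export
area_input_map <- function(context,
                           areas = 10^seq(-2.5, 0.5, by = 0.125),
                           method = c("product", "mosaic"),
                           blur = NULL, keep_responses = FALSE,
                           phase_seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(context, "retinal_context"))
  areas <- sort(unique(as.numeric(areas)))
  if (any(areas <= 0)) stopf("areas must be positive")
  if (is.null(blur)) blur <- !is.null(context$optics) && isTRUE(context$optics$enabled)
  if (method == "product") {
    S <- areas * context$rgc_density * context$convergence
    return(structure(list(method = "product", areas = areas, S = S,
                          log_area = log10(areas), log_S = log10(S),
                          context = context, responses = NULL, mosaic = NULL),
                     class = "area_input_map"))
  }
  rmax <- sqrt(max(areas) / pi)
  margin <- 3 * context$dog$sigma_s + 0.5
  mosaic <- build_hex_mosaic(context$rgc_density, 2 * (rmax + margin),
                             phase_seed = phase_seed)
  kern <- dog_lattice_kernel(context$dog, mosaic$spacing)
  reg <- regularize_lattice(mosaic)
  resp <- if (keep_responses) {
    matrix(NA_real_, nrow(mosaic$positions), length(areas))
  } else {
    NULL
  }
  S <- numeric(length(areas))
  for (i in seq_along(areas)) {
    d <- 2 * sqrt(areas[i] / pi)
    pitch <- min(mosaic$spacing / 2, d / 25)
    img_extent <- if (blur) d + 1 else d + 6 * pitch
    img <- make_stimulus_image(d, pitch, extent = img_extent)
    if (blur) img <- blur_stimulus(img, context$optics)
    cv <- cone_response(img, mosaic, outside = 0)
    field <- rgc_responses(cv, mosaic, dog = context$dog,
                           convergence = context$convergence, method = "grid")
    if (keep_responses) resp[, i] <- field$values
    S[i] <- spatial_input(field, mode = context$mode)
  }
  if (any(diff(S) < -1e-9 * max(S))) {
    stopf("area-input curve is not monotone; widen the area ladder")
  }
  # On a discrete mosaic S(area) has plateaus while the disc grows between
  # lattice shells; keep the strictly increasing envelope for the log-log
  # interpolation table (queries on a plateau resolve to its first area).
  keep <- c(TRUE, diff(cummax(S)) > 0)
  structure(list(method = "mosaic", areas = areas, S = S,
                 log_area = log10(areas[keep]), log_S = log10(S[keep]),
                 context = context, responses = resp, mosaic = mosaic),
            class = "area_input_map")
}

# shared log-log interpolation with extrapolation guards (warn beyond 0.3
# log-units, error beyond 1)
loglog_interp <- function(xs, ys, xq, what) {
  lo <- min(xs)
  hi <- max(xs)
  over <- pmax(lo - xq, xq - hi, 0)
  if (any(over > 1)) {
    stopf("%s query %.3g log10-units outside the tabulated range", what, max(over))
  }
  if (any(over > 0.3)) {
    warnf("%s query extrapolated %.2f log10-units beyond the tabulated range", what, max(over))
  }
  n <- length(xs)
  slope_lo <- (ys[2] - ys[1]) / (xs[2] - xs[1])
  slope_hi <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
  out <- approx(xs, ys, xout = pmin(pmax(xq, lo), hi))$y
  out <- out + ifelse(xq < lo, (xq - lo) * slope_lo,
                      ifelse(xq > hi, (xq - hi) * slope_hi, 0))
  out
}

#' Convert stimulus area to total retinal input (and back)
#'
#' @param map an [area_input_map()].
#' @param area stimulus area(s), deg2.
#' @param S total retinal input value(s).
#' @return the mapped quantity.
#' @export
area_to_input <- function(map, area) {
  stopifnot(inherits(map, "area_input_map"))
  if (any(area <= 0)) stopf("area must be positive")
  10^loglog_interp(map$log_area, map$log_S, log10(area), "area")
}

#' @rdname area_to_input
#' @export
input_to_area <- function(map, S) {
  stopifnot(inherits(map, "area_input_map"))
  if (any(S <= 0)) stopf("input must be positive")
  10^loglog_interp(map$log_S, map$log_area, log10(S), "input")
}
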