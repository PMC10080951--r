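# File formats: threshold tables, run configuration.

#' Goldmann stimulus sizes
#'
#' Standard perimetric disc diameters in deg: I = 0.10, II = 0.21,
#' III = 0.43, IV = 0.86, V = 1.72 (each quadrupling in area).
#'
#' @param label character vector of labels ("I".."V", optionally prefixed
#'   "G-").
#' @return diameters (deg) or areas (deg2).
#' @export
goldmann_diameter <- function(label) {
  d <- c(I = 0.10, II = 0.21, III = 0.43, IV = 0.86, V = 1.72)
  key <- toupper(gsub("^G-?", "", label))
  bad <- !(key %in% names(d))
  if (any(bad)) stopf("unknown Goldmann size label: %s", label[bad][1])
  unname(d[key])
}

#' @rdname goldmann_diameter
#' @export
goldmann_area <- function(label) {
  pi * (goldmann_diameter(label) / 2)^2
}

#' Read and write threshold tables
#'
#' Comma-delimited UTF-8 with header. Required columns: `x_deg`, `y_deg`,
#' `duration_ms`, a size column (`diameter_deg` or `size_label`) and a
#' sensitivity column (`db`, or `dls` which is converted to dB on read).
#' Duplicate (location, size, duration, repeat) keys and malformed cells are
#' reported with their row number.
#'
#' @param path file path.
#' @param data data frame of thresholds (for writing).
#' @return data frame with normalized columns (`diameter_deg`, `area_deg2`,
#'   `db`, `dls` all present).
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stopf("threshold table not found: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_deg", "y_deg", "duration_ms")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("threshold table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!("diameter_deg" %in% names(d))) {
    if (!("size_label" %in% names(d))) {
      stopf("threshold table needs diameter_deg or size_label")
    }
    d$diameter_deg <- goldmann_diameter(d$size_label)
  }
  if (!("db" %in% names(d))) {
    if (!("dls" %in% names(d))) stopf("threshold table needs a db or dls column")
    d$db <- 10 * as.numeric(d$dls)
  }
  for (col in c("x_deg", "y_deg", "duration_ms", "diameter_deg", "db")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (any(is.na(v))) {
      stopf("non-numeric value in column %s at row %d", col, which(is.na(v))[1])
    }
    d[[col]] <- v
  }
  rep_col <- if ("repeat_id" %in% names(d)) d$repeat_id else 1
  key <- paste(d$x_deg, d$y_deg, d$diameter_deg, d$duration_ms, rep_col)
  if (anyDuplicated(key)) {
    stopf("duplicate (location, size, duration, repeat) key at row %d",
          which(duplicated(key))[1])
  }
  d$dls <- d$db / 10
  d$area_deg2 <- pi * (d$diameter_deg / 2)^2
  d
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' YAML file with blocks `mosaic` (densities or `density_table` path),
#' `optics`, `model` (`k`, `tau_init`), `strategy` (`zest`, `questplus`,
#' `mocs`), `fixture` and `seed`.
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return `read_run_config`: the configuration list;
#'   `validate_run_config`: character vector of problems (length 0 if ok).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  model <- config$model
  if (!is.null(model$k)) chk(is.numeric(model$k) && model$k >= 1, "model.k must be >= 1")
  if (!is.null(model$tau_init)) {
    chk(is.numeric(model$tau_init) && model$tau_init > 0, "model.tau_init must be > 0")
  }
  mos <- config$mosaic
  for (f in c("rgc_density", "cone_density")) {
    if (!is.null(mos[[f]])) chk(is.numeric(mos[[f]]) && all(mos[[f]] > 0),
                                sprintf("mosaic.%s must be positive", f))
  }
  opt <- config$optics
  if (!is.null(opt$pupil_mm)) {
    chk(is.numeric(opt$pupil_mm) && opt$pupil_mm > 1 && opt$pupil_mm < 9,
        "optics.pupil_mm must be in (1, 9)")
  }
  if (!is.null(opt$pigmentation)) {
    chk(opt$pigmentation %in% c("light", "medium", "dark"),
        "optics.pigmentation must be light/medium/dark")
  }
  for (f in c("lapse_rate", "guess_rate")) {
    v <- config$strategy[[f]]
    if (!is.null(v)) chk(is.numeric(v) && v >= 0 && v < 0.5,
                         sprintf("strategy.%s must be in [0, 0.5)", f))
  }
  fx <- config$fixture
  if (!is.null(fx$noise_sd_db)) {
    chk(is.numeric(fx$noise_sd_db) && fx$noise_sd_db >= 0,
        "fixture.noise_sd_db must be >= 0")
  }
  if (!is.null(config$seed)) {
    chk(is.numeric(config$seed) && config$seed == round(config$seed),
        "seed must be an integer")
  }
  errs
}

#' Default retinal density table
#'
#' Ships with the package: synthetic parasol-OFF RGC receptive-field and
#' cone densities at the three tested eccentricities, chosen to be
#' consistent with published central-field estimates. Replace with
#' subject-specific tables where available.
#'
#' @return data frame (see [read_density_table()]).
#' @export
default_density_table <- function() {
  read_density_table(system.file("extdata", "synthetic_densities.csv",
                                 package = "perisum", mustWork = TRUE))
}
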