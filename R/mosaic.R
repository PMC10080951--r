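# Hexagonal detector mosaics.
#
# A hexagonal lattice is generated from the basis vectors a1 = (s, 0) and
# a2 = (s/2, s*sqrt(3)/2), so every cell position is a linear function of its
# integer (row, col) index. That linearity is what makes the "regularized"
# rectangular view lossless: relative position depends only on the index
# difference, so receptive-field pooling can be done by discrete convolution
# over index space (row pitch s*sqrt(3)/2, column pitch s).

#' Spacing/density identities for hexagonal packing
#'
#' For a hexagonal lattice with center-to-center spacing `s`, the density is
#' \eqn{\rho = 2/(\sqrt{3} s^2)} cells per unit area.
#'
#' @param density cells/deg2.
#' @param spacing deg.
#' @return the complementary quantity.
#' @export
hex_spacing <- function(density) {
  if (any(density <= 0)) stopf("density must be positive")
  sqrt(2 / (sqrt(3) * density))
}

#' @rdname hex_spacing
#' @export
hex_density <- function(spacing) {
  if (any(spacing <= 0)) stopf("spacing must be positive")
  2 / (sqrt(3) * spacing^2)
}

#' Build a hexagonal detector mosaic
#'
#' Generates detector positions on a regular hexagonal lattice covering a
#' centered rectangular extent. By default one cell sits exactly at the
#' origin (the stimulus center); `phase_seed` reproducibly jitters the global
#' lattice phase within one unit cell, which only perturbs edge effects.
#'
#' @param density cells/deg2 (> 0).
#' @param extent numeric length-2, width and height in deg (a scalar is
#'   recycled). Must span at least 7 cells per side.
#' @param phase_seed optional integer; jitters the lattice offset.
#' @return an object of class `hex_mosaic` with elements `positions`
#'   (n x 2 matrix, deg), `index` (n x 2 integer matrix of (row, col) lattice
#'   indices), `spacing`, `density`, `extent`, `offset`, `phase_seed`.
#' @examples
#' m <- build_hex_mosaic(115.47, c(2, 2))
#' m$spacing  # ~0.1 deg
#' @export
build_hex_mosaic <- function(density, extent, phase_seed = NULL) {
  if (length(density) != 1 || !is.finite(density) || density <= 0) {
    stopf("density must be a positive scalar")
  }
  extent <- rep_len(as.numeric(extent), 2)
  if (any(!is.finite(extent)) || any(extent <= 0)) stopf("extent must be positive")
  s <- hex_spacing(density)
  if (min(extent) < 7 * s) {
    stopf("extent (%.3g x %.3g deg) too small: need >= 7 cells per side at spacing %.3g",
          extent[1], extent[2], s)
  }
  offset <- c(0, 0)
  if (!is.null(phase_seed)) {
    offset <- with_seed(phase_seed, c(runif(1, -0.5, 0.5) * s,
                                      runif(1, -0.5, 0.5) * s * sqrt(3) / 2))
  }
  row_pitch <- s * sqrt(3) / 2
  half_w <- extent[1] / 2
  half_h <- extent[2] / 2
  rmax <- floor((half_h - offset[2]) / row_pitch)
  rmin <- ceiling((-half_h - offset[2]) / row_pitch)
  rows <- list()
  for (r in rmin:rmax) {
    x_shift <- offset[1] + r * s / 2
    cmin <- ceiling((-half_w - x_shift) / s)
    cmax <- floor((half_w - x_shift) / s)
    if (cmax < cmin) next
    cc <- cmin:cmax
    rows[[length(rows) + 1]] <- cbind(row = r, col = cc)
  }
  idx <- do.call(rbind, rows)
  pos <- cbind(x = offset[1] + idx[, "col"] * s + idx[, "row"] * s / 2,
               y = offset[2] + idx[, "row"] * row_pitch)
  structure(list(positions = pos, index = idx, spacing = s,
                 density = density, extent = extent, offset = offset,
                 phase_seed = phase_seed, loss_fraction = 0),
            class = "hex_mosaic")
}

#' @export
print.hex_mosaic <- function(x, ...) {
  cat(sprintf("hex_mosaic: %d cells, spacing %.4f deg, density %.1f /deg2, extent %.2f x %.2f deg\n",
              nrow(x$positions), x$spacing, x$density, x$extent[1], x$extent[2]))
  if (x$loss_fraction > 0) {
    cat(sprintf("  degraded: %.0f%% of cells removed\n", 100 * x$loss_fraction))
  }
  invisible(x)
}

#' Regular (anisotropic rectangular) grid view of a hexagonal mosaic
#'
#' Rearranges the mosaic onto a rectangular index grid: rows at pitch
#' spacing * sqrt(3)/2, columns at pitch spacing, with the half-column shift
#' of alternate rows absorbed into the (sheared) column coordinate. The view
#' is a bijection with the position list; convolution on this grid is exactly
#' equivalent to per-cell weighted sums because cell position is linear in the
#' (row, col) index.
#'
#' @param mosaic a `hex_mosaic`.
#' @return list with `grid` (matrix of cell ids, NA where the sheared grid
#'   falls outside the extent), `row_range`, `col_range`, `row_pitch`,
#'   `col_pitch`.
#' @export
regularize_lattice <- function(mosaic) {
  stopifnot(inherits(mosaic, "hex_mosaic"))
  idx <- mosaic$index
  rr <- range(idx[, "row"])
  cr <- range(idx[, "col"])
  grid <- matrix(NA_integer_, nrow = rr[2] - rr[1] + 1, ncol = cr[2] - cr[1] + 1)
  grid[cbind(idx[, "row"] - rr[1] + 1, idx[, "col"] - cr[1] + 1)] <- seq_len(nrow(idx))
  list(grid = grid, row_range = rr, col_range = cr,
       row_pitch = mosaic$spacing * sqrt(3) / 2, col_pitch = mosaic$spacing)
}

#' Randomly degrade a mosaic (simulated RGC loss)
#'
#' Deletes each cell independently with probability `loss_fraction`,
#' emulating diffuse ganglion-cell loss. The lattice geometry of the
#' survivors is unchanged; the `density` field is rescaled by the realized
#' survival fraction.
#'
#' @param mosaic a `hex_mosaic`.
#' @param loss_fraction probability of deletion, in [0, 1).
#' @param seed integer for reproducibility.
#' @return degraded `hex_mosaic`.
#' @export
degrade_mosaic <- function(mosaic, loss_fraction, seed = NULL) {
  stopifnot(inherits(mosaic, "hex_mosaic"))
  if (!is.finite(loss_fraction) || loss_fraction < 0 || loss_fraction >= 1) {
    stopf("loss_fraction must be in [0, 1)")
  }
  if (loss_fraction == 0) return(mosaic)
  n <- nrow(mosaic$positions)
  keep <- with_seed(seed, runif(n) >= loss_fraction)
  out <- mosaic
  out$positions <- mosaic$positions[keep, , drop = FALSE]
  out$index <- mosaic$index[keep, , drop = FALSE]
  out$density <- mosaic$density * mean(keep)
  out$loss_fraction <- loss_fraction
  out
}

#' Cone-to-RGC convergence profile
#'
#' The convergence ratio is the local density of cones over the local density
#' of RGC receptive fields. Each density may be a constant or a table of
#' (eccentricity, density) rows, interpolated linearly in log10-density
#' against eccentricity. Downstream, the ratio multiplies each RGC's
#' contribution to the total retinal input (the scaling-factor route), so no
#' integer-ratio mosaic re-meshing is needed.
#'
#' @param cone_density,rgc_density scalar densities (cells/deg2) or data
#'   frames with columns `eccentricity_deg` and a density column
#'   (`cone_density_per_deg2` / `rgc_rf_density_per_deg2`, or `density`).
#' @return object of class `convergence_profile`.
#' @export
convergence_profile <- function(cone_density, rgc_density) {
  mk <- function(d, col) {
    if (is.numeric(d) && length(d) == 1) {
      if (!is.finite(d) || d <= 0) stopf("density must be positive")
      function(ecc) rep_len(d, length(ecc))
    } else if (is.data.frame(d)) {
      dcol <- intersect(c(col, "density"), names(d))
      if (!("eccentricity_deg" %in% names(d)) || length(dcol) == 0) {
        stopf("density table needs columns eccentricity_deg and %s", col)
      }
      dens <- d[[dcol[1]]]
      ecc0 <- d$eccentricity_deg
      if (any(!is.finite(dens)) || any(dens <= 0)) stopf("densities must be positive")
      function(ecc) {
        tol <- 1e-3 * diff(range(ecc0))
        if (any(ecc < min(ecc0) - tol) || any(ecc > max(ecc0) + tol)) {
          stopf("eccentricity %.3g outside density table range [%.3g, %.3g]",
                ecc[which(ecc < min(ecc0) - tol | ecc > max(ecc0) + tol)][1],
                min(ecc0), max(ecc0))
        }
        ecc <- pmin(pmax(ecc, min(ecc0)), max(ecc0))
        10^approx(ecc0, log10(dens), xout = ecc)$y
      }
    } else {
      stopf("density must be a positive scalar or a table")
    }
  }
  structure(list(cone = mk(cone_density, "cone_density_per_deg2"),
                 rgc = mk(rgc_density, "rgc_rf_density_per_deg2")),
            class = "convergence_profile")
}

#' Convergence ratio at an eccentricity
#'
#' @param profile a `convergence_profile`.
#' @param eccentricity deg from fixation.
#' @return dimensionless ratio cone density / RGC density (>= 1 in the
#'   supported range of human data).
#' @export
convergence_ratio <- function(profile, eccentricity) {
  stopifnot(inherits(profile, "convergence_profile"))
  profile$cone(eccentricity) / profile$rgc(eccentricity)
}

#' Read a retinal density table
#'
#' Delimited text with columns `eccentricity_deg`, `rgc_rf_density_per_deg2`,
#' `cone_density_per_deg2`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_density_table <- function(path) {
  if (!file.exists(path)) stopf("density table not found: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("eccentricity_deg", "rgc_rf_density_per_deg2", "cone_density_per_deg2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("density table missing column(s): %s", paste(miss, collapse = ", "))
  for (col in need) {
    if (!is.numeric(d[[col]])) stopf("non-numeric values in column %s", col)
  }
  d
}
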