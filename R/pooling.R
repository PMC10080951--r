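# Retinal pooling: cone sampling, DoG receptive fields, total spatial input.
#
# RGC receptive fields are difference-of-Gaussians with the classic
# center/surround ratios (surround peak 1% of center, surround SD 6.7x the
# center SD); the center SD is spacing/1.414 so the center radius (where the
# excitatory Gaussian falls to 1/e) equals the intercell spacing. Kernel
# weights are normalized to unit sum over the matched cone lattice, so an RGC
# fully covered by a unit-contrast stimulus responds 1 and the total spatial
# input S equals the number of stimulated RGCs (times the convergence weight).

#' Difference-of-Gaussians receptive-field parameters
#'
#' @param spacing RGC intercell spacing, deg; sets the center SD
#'   (spacing/1.414) and hence the whole filter scale.
#' @param Kc center peak sensitivity (default 1).
#' @param Ks_ratio surround/center peak ratio (default 0.01).
#' @param sigma_s_ratio surround/center SD ratio (default 6.7).
#' @param truncate kernel truncation radius in surround SDs (default 4; the
#'   neglected tail mass is < 1e-3 of the surround).
#' @return object of class `dog_params`.
#' @export
dog_params <- function(spacing, Kc = 1, Ks_ratio = 0.01, sigma_s_ratio = 6.7,
                       truncate = 4) {
  if (!is.finite(spacing) || spacing <= 0) stopf("spacing must be positive")
  sigma_c <- spacing / 1.414
  structure(list(Kc = Kc, Ks = Ks_ratio * Kc, sigma_c = sigma_c,
                 sigma_s = sigma_s_ratio * sigma_c, spacing = spacing,
                 truncate = truncate),
            class = "dog_params")
}

#' Evaluate a DoG profile at radial distances
#'
#' @param d distances, deg.
#' @param dog a `dog_params`.
#' @return unnormalized filter values.
#' @export
dog_value <- function(d, dog) {
  dog$Kc * exp(-d^2 / (2 * dog$sigma_c^2)) -
    dog$Ks * exp(-d^2 / (2 * dog$sigma_s^2))
}

# Lattice offsets (dr, dc) and weights of the DoG kernel on a hexagonal
# lattice with the given spacing, truncated at truncate * sigma_s. `norm` is
# the weight sum: dividing by it makes a fully covered cell respond exactly 1
# on a matched 1:1 cone lattice.
dog_lattice_kernel <- function(dog, spacing) {
  rad <- dog$truncate * dog$sigma_s
  row_pitch <- spacing * sqrt(3) / 2
  kr <- ceiling(rad / row_pitch)
  dr <- -kr:kr
  offs <- list()
  for (r in dr) {
    # sheared column coordinate: x = dc*s + r*s/2
    cmax <- floor((sqrt(max(0, rad^2 - (r * row_pitch)^2)) - r * spacing / 2) / spacing + 1)
    cmin <- ceiling((-sqrt(max(0, rad^2 - (r * row_pitch)^2)) - r * spacing / 2) / spacing - 1)
    if (cmax < cmin) next
    cc <- cmin:cmax
    x <- cc * spacing + r * spacing / 2
    y <- r * row_pitch
    d <- sqrt(x^2 + y^2)
    keep <- d <= rad
    if (!any(keep)) next
    offs[[length(offs) + 1]] <- cbind(dr = r, dc = cc[keep], w = dog_value(d[keep], dog))
  }
  k <- do.call(rbind, offs)
  list(dr = k[, "dr"], dc = k[, "dc"], w = k[, "w"], norm = sum(k[, "w"]))
}

#' Sample a stimulus image with a cone mosaic
#'
#' Each cone reads the image value at its position by bilinear interpolation;
#' the operation is linear in contrast.
#'
#' @param image a `stimulus_image`.
#' @param cones a `hex_mosaic`.
#' @param outside value assigned to cones outside the image footprint; the
#'   default (`NULL`) raises a coverage error. Passing `0` is appropriate
#'   when the image is known to contain all nonzero stimulus flux.
#' @return numeric vector of per-cone values.
#' @export
cone_response <- function(image, cones, outside = NULL) {
  stopifnot(inherits(image, "stimulus_image"), inherits(cones, "hex_mosaic"))
  px <- image$pixels
  x <- cones$positions[, 1]
  y <- cones$positions[, 2]
  inx <- x >= image$x[1] & x <= image$x[length(image$x)]
  iny <- y >= image$y[1] & y <= image$y[length(image$y)]
  inside <- inx & iny
  if (!all(inside) && is.null(outside)) {
    stopf("%d cone(s) fall outside the image footprint", sum(!inside))
  }
  out <- rep(if (is.null(outside)) NA_real_ else outside, length(x))
  if (any(inside)) {
    xs <- (x[inside] - image$x[1]) / image$pitch
    ys <- (y[inside] - image$y[1]) / image$pitch
    ix <- pmin(pmax(floor(xs), 0), length(image$x) - 2)
    iy <- pmin(pmax(floor(ys), 0), length(image$y) - 2)
    fx <- xs - ix
    fy <- ys - iy
    i1 <- cbind(iy + 1, ix + 1)
    v <- px[i1] * (1 - fx) * (1 - fy) +
      px[cbind(iy + 1, ix + 2)] * fx * (1 - fy) +
      px[cbind(iy + 2, ix + 1)] * (1 - fx) * fy +
      px[cbind(iy + 2, ix + 2)] * fx * fy
    out[inside] <- v
  }
  out
}

# "Same"-size 2-D convolution of value grid V with a symmetric kernel given
# as lattice offsets, via zero-padded FFT.
conv2d_lattice <- function(V, kern) {
  kr <- max(abs(kern$dr))
  kc <- max(abs(kern$dc))
  ny <- nrow(V)
  nx <- ncol(V)
  pny <- stats::nextn(ny + 2 * kr, c(2, 3))
  pnx <- stats::nextn(nx + 2 * kc, c(2, 3))
  pv <- matrix(0, pny, pnx)
  pv[seq_len(ny), seq_len(nx)] <- V
  pk <- matrix(0, pny, pnx)
  # place kernel with its center at (1,1), wrapping negative offsets
  rr <- (kern$dr %% pny) + 1
  cc <- (kern$dc %% pnx) + 1
  pk[cbind(rr, cc)] <- pk[cbind(rr, cc)] + kern$w
  out <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / (pny * pnx)
  out[seq_len(ny), seq_len(nx)]
}

#' Pool cone responses into per-RGC responses
#'
#' Each RGC response is the convergence-weighted, DoG-weighted sum of cone
#' values within its receptive field, normalized so that full coverage on a
#' matched 1:1 cone lattice gives 1. Two computation routes are provided:
#' `"grid"` (discrete convolution on the regularized lattice; requires cones
#' and RGCs to share the same lattice) and `"direct"` (per-cell weighted sum
#' over any pair of mosaics). The two agree to numerical precision on shared
#' lattices.
#'
#' @param cone_values per-cone values from [cone_response()].
#' @param cones,rgcs `hex_mosaic` objects.
#' @param dog a `dog_params`; defaults to the standard filter for the RGC
#'   spacing.
#' @param convergence multiplicative cone/RGC convergence weight c (>= 1 in
#'   human data); scales every response.
#' @param method `"auto"`, `"grid"` or `"direct"`.
#' @return object of class `rgc_field`: `values`, `mosaic`, `convergence`.
#' @export
rgc_responses <- function(cone_values, cones, rgcs = cones, dog = NULL,
                          convergence = 1, method = c("auto", "grid", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(cones, "hex_mosaic"), inherits(rgcs, "hex_mosaic"))
  if (length(cone_values) != nrow(cones$positions)) {
    stopf("cone_values length (%d) != number of cones (%d)",
          length(cone_values), nrow(cones$positions))
  }
  if (is.null(dog)) dog <- dog_params(rgcs$spacing)
  if (dog$truncate * dog$sigma_s < 3 * dog$sigma_s) {
    stopf("DoG kernel truncated before 3 surround SDs")
  }
  shared <- isTRUE(all.equal(cones$spacing, rgcs$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(cones$offset, rgcs$offset, tolerance = 1e-12))
  if (method == "auto") method <- if (shared) "grid" else "direct"
  if (method == "grid" && !shared) {
    stopf("grid pooling requires cones and RGCs on the same lattice")
  }
  # normalization is always tied to the RGC's own lattice geometry
  norm <- dog_lattice_kernel(dog, rgcs$spacing)$norm
  if (method == "grid") {
    reg <- regularize_lattice(cones)
    V <- matrix(0, nrow(reg$grid), ncol(reg$grid))
    V[!is.na(reg$grid)] <- cone_values[reg$grid[!is.na(reg$grid)]]
    kern <- dog_lattice_kernel(dog, cones$spacing)
    conv <- conv2d_lattice(V, kern)
    ri <- conv[cbind(rgcs$index[, "row"] - reg$row_range[1] + 1,
                     rgcs$index[, "col"] - reg$col_range[1] + 1)]
  } else {
    rad <- dog$truncate * dog$sigma_s
    cp <- cones$positions
    ri <- numeric(nrow(rgcs$positions))
    chunk <- max(1L, floor(2e6 / nrow(cp)))
    for (start in seq(1, length(ri), by = chunk)) {
      ii <- start:min(start + chunk - 1, length(ri))
      dx <- outer(rgcs$positions[ii, 1], cp[, 1], "-")
      dy <- outer(rgcs$positions[ii, 2], cp[, 2], "-")
      d2 <- dx * dx + dy * dy
      w <- dog_value(sqrt(d2), dog)
      w[d2 > rad^2] <- 0
      ri[ii] <- as.vector(w %*% cone_values)
    }
  }
  structure(list(values = convergence * ri / norm, mosaic = rgcs,
                 convergence = convergence),
            class = "rgc_field")
}

#' Total spatial input S
#'
#' Sums per-RGC responses into the total spatial input of Eq. S = sum(R_i).
#' In signed mode, RGCs with negative response (surround-driven) subtract,
#' interpreted as inhibition of their background activity; signed S is linear
#' in contrast and essentially blur-invariant (flux conservation propagates
#' through linear pooling). Absolute mode sums |R_i| and is retained for the
#' blur-sensitivity contrast.
#'
#' @param field an `rgc_field`.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return scalar S (dimensionless RGC-count units).
#' @export
spatial_input <- function(field, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "rgc_field"))
  if (mode == "signed") sum(field$values) else sum(abs(field$values))
}
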