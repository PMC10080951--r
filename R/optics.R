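# Mean human optical MTF.
#
# The optical front end follows the published mean-observer formulation: the
# square root of the diffraction-limited MTF for the pupil diameter (at 555 nm)
# multiplied by a Lorentzian whose half-width depends on pupil size, which
# together approximate the average human radial MTF. An optional multiplicative
# scatter attenuation models the age- and pigmentation-dependent straylight
# loss; it is frequency-flat, so it rescales total flux rather than reshaping
# the image, and is off by default.

#' Optical parameters
#'
#' @param pupil_mm pupil diameter in mm, in (1, 9).
#' @param age observer age in years (only used by the scatter correction).
#' @param pigmentation iris pigmentation class: `"light"`, `"medium"` or
#'   `"dark"`; lighter irides scatter more.
#' @param wavelength_nm design wavelength, default 555 (photopic peak).
#' @param scatter logical; apply the scatter attenuation (default FALSE).
#' @param enabled logical; when FALSE, downstream blurring is skipped.
#' @return object of class `optics_params`.
#' @export
optics_params <- function(pupil_mm = 3, age = 30,
                          pigmentation = c("medium", "light", "dark"),
                          wavelength_nm = 555, scatter = FALSE, enabled = TRUE) {
  pigmentation <- match.arg(pigmentation)
  if (!is.finite(pupil_mm) || pupil_mm <= 1 || pupil_mm >= 9) {
    stopf("pupil_mm must be in (1, 9)")
  }
  if (!is.finite(age) || age < 0) stopf("age must be non-negative")
  structure(list(pupil_mm = pupil_mm, age = age, pigmentation = pigmentation,
                 wavelength_nm = wavelength_nm, scatter = scatter,
                 enabled = enabled),
            class = "optics_params")
}

#' Incoherent diffraction cutoff frequency
#'
#' cutoff = pupil diameter / wavelength, converted to cycles/deg
#' (pi/180 cycles per degree per cycle per radian). A 3-mm pupil at 555 nm
#' cuts off at ~94.3 cycles/deg.
#'
#' @param params an `optics_params`.
#' @return cycles/deg.
#' @export
diffraction_cutoff <- function(params) {
  (params$pupil_mm * 1e-3) / (params$wavelength_nm * 1e-9) * pi / 180
}

#' Diffraction-limited MTF for a circular pupil
#'
#' \eqn{M(v) = (2/\pi)(\arccos v - v\sqrt{1-v^2})} for \eqn{v = f/f_c < 1},
#' 0 beyond the cutoff \eqn{f_c}.
#'
#' @param freq spatial frequency, cycles/deg (>= 0).
#' @param params an `optics_params`.
#' @return modulation in [0, 1].
#' @export
diffraction_limited_mtf <- function(freq, params) {
  if (any(freq < 0)) stopf("negative spatial frequency")
  v <- pmin(freq / diffraction_cutoff(params), 1)
  (2 / pi) * (acos(v) - v * sqrt(pmax(0, 1 - v^2)))
}

# Lorentzian half-width (cycles/deg) of the mean-observer MTF as a function
# of pupil diameter d in mm.
mtf_lorentzian_halfwidth <- function(pupil_mm) {
  21.95 - 5.512 * pupil_mm + 0.3922 * pupil_mm^2
}

# Straylight fraction: pigmentation baseline scaled by the standard quartic
# age factor (1 + (age/70)^4).
scatter_fraction <- function(params) {
  s0 <- c(light = 0.13, medium = 0.10, dark = 0.08)[[params$pigmentation]]
  min(0.9, s0 * (1 + (params$age / 70)^4))
}

#' Mean human optical MTF
#'
#' sqrt(diffraction-limited MTF) times a pupil-dependent Lorentzian,
#' optionally attenuated by the age/pigmentation scatter factor. Without
#' scatter, MTF(0) = 1; the function is monotone non-increasing in frequency
#' and never exceeds the square root of the diffraction-limited MTF.
#'
#' @inheritParams diffraction_limited_mtf
#' @return modulation in [0, 1].
#' @export
mean_human_mtf <- function(freq, params) {
  if (any(freq < 0)) stopf("negative spatial frequency")
  u1 <- mtf_lorentzian_halfwidth(params$pupil_mm)
  m <- sqrt(diffraction_limited_mtf(freq, params)) / (1 + (freq / u1)^2)
  if (isTRUE(params$scatter)) m <- m * (1 - scatter_fraction(params))
  m
}
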