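#' Sensitivity unit conversions (dB, DLS, Weber contrast)
#'
#' Perimetric sensitivity is conventionally expressed in decibels of
#' attenuation of the maximum stimulus luminance (3,185 cd/m2 on a
#' 10 cd/m2 background), so higher contrast means lower dB. Differential
#' light sensitivity (DLS) is the same quantity in dB/10. Weber contrast at
#' threshold follows \eqn{W_c = 318.5 \times 10^{-DLS}}.
#'
#' @param value numeric vector to convert.
#' @param from,to one of `"db"`, `"dls"`, `"weber"`.
#' @param max_luminance,background luminance constants in cd/m2; the defaults
#'   are the standard bowl-perimeter values (3,185 and 10).
#' @return numeric vector in the `to` unit.
#' @examples
#' dls_convert(1.0, "dls", "weber")  # 31.85
#' dls_convert(25, "db", "dls")      # 2.5
#' @export
dls_convert <- function(value, from = c("db", "dls", "weber"),
                        to = c("dls", "db", "weber"),
                        max_luminance = 3185, background = 10) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (!all(is.finite(value))) stopf("non-finite input to dls_convert()")
  ratio <- max_luminance / background  # 318.5 for the default apparatus
  dls <- switch(from,
    db = value / 10,
    dls = value,
    weber = {
      if (any(value <= 0)) stopf("Weber contrast must be positive")
      log10(ratio / value)
    }
  )
  switch(to,
    dls = dls,
    db = 10 * dls,
    weber = ratio * 10^(-dls)
  )
}
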