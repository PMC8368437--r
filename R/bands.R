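#' Frequency band definitions
#'
#' The analysis decomposes sensor signals into six canonical bands:
#' 1-4, 4-8, 8-12, 12-30, 30-80 and 80-250 Hz. `band_definition()` builds a
#' single validated band; `canonical_bands()` returns the full set.
#'
#' @param name Band label, e.g. `"8-12"`.
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo_hz < hi_hz`.
#' @return `band_definition()`: a `band_definition` object (named list).
#'   `canonical_bands()`: a data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @examples
#' canonical_bands()
#' band_definition("alpha", 8, 12)
#' @export
band_definition <- function(name, lo_hz, hi_hz) {
  if (!is_number(lo_hz) || !is_number(hi_hz) || lo_hz <= 0 || hi_hz <= lo_hz)
    stop_config("invalid band [%s, %s]: need 0 < lo < hi", lo_hz, hi_hz)
  structure(list(name = as.character(name), lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("1-4", "4-8", "8-12", "12-30", "30-80", "80-250"),
    lo_hz = c(1, 4, 8, 12, 30, 80),
    hi_hz = c(4, 8, 12, 30, 80, 250),
    stringsAsFactors = FALSE
  )
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$lo_hz, x$hi_hz))
  invisible(x)
}

as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.numeric(band) && length(band) == 2L)
    return(band_definition(paste0(band[1L], "-", band[2L]), band[1L], band[2L]))
  if (is.list(band) || is.data.frame(band))
    return(band_definition(band$name %||% paste0(band$lo_hz, "-", band$hi_hz),
                           band$lo_hz, band$hi_hz))
  stop_config("cannot interpret band specification")
}
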