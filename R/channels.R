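#' Multispectral channel map
#'
#' The imaging system captures 10 channels per overhead exposure: nine narrow
#' LED bands plus a broad-spectrum white channel used for visualisation and
#' quality control. Channel order here is the page order used when cubes are
#' written to multi-page TIFF.
#'
#' @return A tibble with columns `channel` (1-10), `name`, and `peak_nm`
#'   (mean peak wavelength in nm; `NA` for the broad white channel).
#' @examples
#' msi_channels()
#' @export
msi_channels <- function() {
  tibble::tibble(
    channel = 1:10,
    name = c("blue", "cyan", "green", "amber", "red",
             "deep_red", "far_red", "nir850", "nir940", "white"),
    peak_nm = c(475, 497, 526, 603, 640, 665, 740, 855, 949, NA)
  )
}

#' Names of the nine narrow-band channels, in wavelength order
#' @keywords internal
narrow_band_channels <- function() {
  ch <- msi_channels()
  ch$name[!is.na(ch$peak_nm)]
}

validate_channel_map <- function(ch) {
  stopifnot(nrow(ch) == 10, !anyDuplicated(ch$name))
  wl <- ch$peak_nm[1:9]
  if (any(diff(wl) <= 0)) stop("narrow-band wavelengths must be strictly increasing")
  invisible(ch)
}
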