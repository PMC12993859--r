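#' Construct a multispectral image cube
#'
#' An `msi_cube` is an H x W x 10 numeric array of reflectances in \[0, 1\]
#' with channel names on the third dimension, plus acquisition metadata
#' (days after transplanting and the within-night capture index).
#'
#' @param data numeric array H x W x 10, or H x W x C matching `channels`.
#' @param channels channel names for the third dimension.
#' @param dat days after transplanting of the capture.
#' @param capture 1-based within-night capture index (captures are hourly
#'   from 10 pm; capture 2 corresponds to the 11 pm exposure when a night
#'   has all 8 captures).
#' @return an `msi_cube` object.
#' @export
msi_cube <- function(data, channels = msi_channels()$name, dat = NA_integer_,
                     capture = NA_integer_) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != length(channels)) {
    stop("cube has ", dim(data)[3], " channels but ", length(channels),
         " channel names were given")
  }
  dimnames(data)[[3]] <- channels
  structure(data, class = c("msi_cube", "array"),
            dat = dat, capture = capture)
}

#' @export
print.msi_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<msi_cube %d x %d px, %d channels, DAT %s, capture %s>\n",
              d[1], d[2], d[3], attr(x, "dat"), attr(x, "capture")))
  invisible(x)
}

#' Write / read a cube as a multi-page TIFF
#'
#' One 32-bit float page per channel, in channel-map order. Reflectances are
#' clamped to \[0, 1\] on write (the TIFF writer's float range).
#'
#' @param cube an [msi_cube()].
#' @param path file path ending in `.tif`/`.tiff`.
#' @export
write_msi_tiff <- function(cube, path) {
  pages <- lapply(seq_len(dim(cube)[3]), function(k) {
    pmin(pmax(unclass(cube)[, , k], 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_msi_tiff
#' @param channels,dat,capture metadata to attach (TIFF pages carry none).
#' @export
read_msi_tiff <- function(path, channels = msi_channels()$name,
                          dat = NA_integer_, capture = NA_integer_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  msi_cube(arr, channels = channels, dat = dat, capture = capture)
}

#' Write / read a binary plant mask as 8-bit PNG (0/255)
#' @param mask logical matrix.
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Evaluate a vegetation index over the masked pixels of a cube
#'
#' The formula (a string over channel names, see [vi_registry()]) is
#' evaluated with each channel bound to its full H x W reflectance matrix;
#' pixels outside the mask are set to `NA` in the returned index image.
#' Division by (near-)zero follows the [safe_div()] rule, so every in-mask
#' pixel is finite.
#'
#' @param cube an [msi_cube()].
#' @param mask logical H x W matrix with at least one `TRUE` pixel.
#' @param formula index formula string, e.g. `"nd(nir850, red)"`.
#' @return H x W numeric matrix, `NA` outside the mask.
#' @examples
#' arr <- array(runif(5 * 5 * 10), dim = c(5, 5, 10))
#' cube <- msi_cube(arr)
#' img <- compute_index(cube, matrix(TRUE, 5, 5), "nd(nir850, red)")
#' @export
compute_index <- function(cube, mask, formula) {
  stopifnot(inherits(cube, "msi_cube"), is.logical(mask))
  if (!any(mask)) stop("mask is empty")
  if (!all(dim(mask) == dim(cube)[1:2])) stop("mask dimensions do not match cube")
  chn <- dimnames(cube)[[3]]
  expr <- parse(text = formula)[[1]]
  bad <- setdiff(all.vars(expr), chn)
  if (length(bad)) stop("unknown channel(s) in formula: ", paste(bad, collapse = ", "))
  env <- new.env(parent = baseenv())
  for (nm in chn) assign(nm, unclass(cube)[, , nm], envir = env)
  assign("nd", nd, envir = env)
  assign("rr", rr, envir = env)
  assign("safe_div", safe_div, envir = env)
  img <- eval(expr, envir = env)
  if (!is.matrix(img)) img <- matrix(img, nrow(mask), ncol(mask))
  if (any(!is.finite(img[mask]))) stop("non-finite index values inside mask")
  img[!mask] <- NA_real_
  img
}

#' Summarise an index image over its foliar surface
#'
#' Returns the mean, median and standard deviation over non-`NA` pixels.
#' The SD is the population SD (divisor n), fixed by convention so feature
#' tables are deterministic and comparable across implementations.
#'
#' @param img index image from [compute_index()], or a numeric vector of
#'   in-mask values.
#' @return named numeric vector `c(mean=, median=, std=)`.
#' @export
summarize_index <- function(img) {
  v <- as.numeric(img)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no pixels to summarise")
  m <- mean(v)
  c(mean = m, median = median(v), std = sqrt(mean((v - m)^2)))
}
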