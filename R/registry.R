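#' Safe division for vegetation-index arithmetic
#'
#' Pixels where the denominator magnitude falls below `eps` yield 0 rather
#' than NaN/Inf, so summaries over a foliar surface are always finite.
#'
#' @param num,den numeric vectors or matrices.
#' @param eps magnitude below which a denominator is treated as zero.
#' @export
safe_div <- function(num, den, eps = 1e-9) {
  out <- num / den
  out[abs(den) < eps] <- 0
  out
}

#' Normalized difference of two channels: (a - b) / (a + b)
#' @param a,b reflectance vectors/matrices.
#' @param eps see [safe_div()].
#' @export
nd <- function(a, b, eps = 1e-9) safe_div(a - b, a + b, eps)

#' Simple ratio of two channels: a / b
#' @param a,b reflectance vectors/matrices.
#' @param eps see [safe_div()].
#' @export
rr <- function(a, b, eps = 1e-9) safe_div(a, b, eps)

#' Default vegetation-index registry
#'
#' Five canonical indices identified by name (NDVI, GNDVI, NDRE, NDWI with
#' NIR-940 standing in for shortwave infrared, and GRVI) plus the remaining
#' normalized differences over all pairs of the nine narrow bands. That gives
#' 36 indices; with mean/median/SD summaries per foliar surface the default
#' feature table carries 108 columns, close to the roughly hundred VI-based
#' features the full pipeline was designed around. The registry is plain data
#' (name -> formula string) and can be replaced or extended from YAML with
#' [read_vi_registry()].
#'
#' @param include_generic also include the unnamed narrow-band pair indices
#'   (default TRUE). With FALSE you get only the five canonical indices.
#' @return tibble with columns `name` and `formula`. Formulas are R
#'   expressions over channel names using [nd()], [rr()] and [safe_div()].
#' @examples
#' vi_registry(include_generic = FALSE)
#' @export
vi_registry <- function(include_generic = TRUE) {
  named <- tibble::tibble(
    name = c("NDVI", "GNDVI", "NDRE", "NDWI", "GRVI"),
    formula = c(
      "nd(nir850, red)",
      "nd(nir850, green)",
      "nd(nir850, far_red)",
      "nd(nir850, nir940)",
      "nd(green, red)"
    )
  )
  if (!include_generic) return(named)
  bands <- narrow_band_channels()
  pairs <- utils::combn(bands, 2)
  taken <- list(c("red", "nir850"), c("green", "nir850"),
                c("far_red", "nir850"), c("nir850", "nir940"),
                c("green", "red"))
  gen <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]   # a shorter wavelength than b
    if (any(vapply(taken, function(p) setequal(p, c(a, b)), logical(1)))) return(NULL)
    tibble::tibble(name = paste0("nd_", b, "_", a),
                   formula = paste0("nd(", b, ", ", a, ")"))
  })
  dplyr::bind_rows(named, dplyr::bind_rows(gen))
}

#' Read / write a vegetation-index registry as YAML
#'
#' The YAML file is a flat mapping from index name to formula string, e.g.
#' `NDVI: nd(nir850, red)`.
#'
#' @param path file path.
#' @return `read_vi_registry()` returns a registry tibble;
#'   `write_vi_registry()` returns `path` invisibly.
#' @export
read_vi_registry <- function(path) {
  x <- yaml::read_yaml(path)
  reg <- tibble::tibble(name = names(x), formula = unname(unlist(x)))
  validate_registry(reg)
  reg
}

#' @rdname read_vi_registry
#' @param registry a registry tibble (`name`, `formula`).
#' @export
write_vi_registry <- function(registry, path) {
  validate_registry(registry)
  yaml::write_yaml(as.list(setNames(registry$formula, registry$name)), path)
  invisible(path)
}

#' Check that a registry only references known channels
#' @keywords internal
validate_registry <- function(registry, channels = msi_channels()$name) {
  stopifnot(is.data.frame(registry), all(c("name", "formula") %in% names(registry)))
  if (anyDuplicated(registry$name)) stop("duplicate index names in registry")
  allowed_funs <- c("nd", "rr", "safe_div", "+", "-", "*", "/", "(", "sqrt", "abs")
  for (i in seq_len(nrow(registry))) {
    expr <- tryCatch(parse(text = registry$formula[i])[[1]],
                     error = function(e) stop("unparseable formula for index '",
                                              registry$name[i], "': ", registry$formula[i]))
    vars <- all.vars(expr)
    bad <- setdiff(vars, channels)
    if (length(bad)) {
      stop("index '", registry$name[i], "' references unknown channel(s): ",
           paste(bad, collapse = ", "))
    }
    funs <- setdiff(all.names(expr), vars)
    badf <- setdiff(funs, allowed_funs)
    if (length(badf)) {
      stop("index '", registry$name[i], "' uses disallowed function(s): ",
           paste(badf, collapse = ", "))
    }
  }
  invisible(registry)
}
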