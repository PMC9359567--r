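# Spectral domain: l1 normalization and agglomeration spectra.

#' Construct a spectrum
#'
#' @param values Numeric vector of S channel values.
#' @param wavelengths Wavelength axis (nm), same length.
#' @return Object of class `spectrum` with fields `values` and `wavelengths`.
#' @export
spectrum <- function(values, wavelengths) {
  wavelengths <- wavelength_axis(wavelengths)
  values <- as.numeric(values)
  if (length(values) != length(wavelengths)) {
    stop("spectrum length does not match wavelength axis", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("spectrum values must be finite", call. = FALSE)
  structure(list(values = values, wavelengths = wavelengths), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d channels, %.0f-%.0f nm, range [%.4g, %.4g]\n",
              length(x$values), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$wavelengths, x$values, type = "l",
                 xlab = "wavelength [nm]", ylab = "value", ...)
  invisible(x)
}

#' l1-normalize a spectrum
#'
#' Divides each channel by the sum of absolute channel values, so the
#' normalized spectrum has absolute sum 1. This removes the overall amplitude
#' (illumination / albedo) and keeps only the spectral shape; it is applied
#' mandatorily before embedding.
#'
#' @param spec A `spectrum` or bare numeric vector.
#' @return Same type as the input, l1-normalized.
#' @export
normalize_l1 <- function(spec) {
  v <- if (inherits(spec, "spectrum")) spec$values else as.numeric(spec)
  denom <- sum(abs(v))
  if (!is.finite(denom) || denom == 0) {
    stop("degenerate spectrum: all-zero (empty/dead pixel), cannot l1-normalize",
         call. = FALSE)
  }
  out <- v / denom
  if (inherits(spec, "spectrum")) spectrum(out, spec$wavelengths) else out
}

# linear (column-major) indices of 0-based pixel coords into an (h, w) plane
pixel_lin_index <- function(x, y, h, w) {
  if (any(x < 0 | x >= w | y < 0 | y >= h)) {
    stop("pixel coordinates outside the image", call. = FALSE)
  }
  as.integer(y + 1 + x * h)
}

# spectra of given pixels as an n x S matrix (rows in input order)
pixel_spectra_matrix <- function(cube, x, y) {
  d <- dim(cube$values)
  lin <- pixel_lin_index(x, y, d[1], d[2])
  vm <- matrix(cube$values, d[1] * d[2], d[3])
  vm[lin, , drop = FALSE]
}

# resolve a pixel argument against a cube's mask; pixels: NULL (all mask-true),
# a data.frame with x/y, or an hsi_selection (filtered to cube's time point)
resolve_pixels <- function(cube, pixels = NULL) {
  d <- dim(cube$values)
  if (is.null(pixels)) {
    idx <- which(cube$mask) - 1L
    return(data.frame(x = idx %/% d[1], y = idx %% d[1]))
  }
  if (inherits(pixels, "hsi_selection")) {
    px <- pixels$pixels
    px <- px[as.character(px$time_point) == cube$time_point, c("x", "y"), drop = FALSE]
  } else {
    px <- as.data.frame(pixels)[, c("x", "y"), drop = FALSE]
  }
  if (nrow(px) == 0) return(px)
  keep <- cube$mask[cbind(px$y + 1, px$x + 1)]
  px[keep, , drop = FALSE]
}

#' Agglomeration spectrum over a pixel set
#'
#' Channel-wise summary (mean, max, min or median) of the spectra of a set of
#' masked pixels. With no pixel set given, all mask-true pixels of the cube
#' are used, which yields the per-sample agglomeration spectrum. With
#' `normalized = TRUE` each pixel spectrum is l1-normalized *before*
#' aggregation. All-zero (dead) pixel spectra are excluded with a warning.
#'
#' @param cube An `hsi_cube`.
#' @param pixels Optional pixel set: a data.frame with 0-based `x`, `y`
#'   columns, or an `hsi_selection` (its pixels at this cube's time point are
#'   used). Intersected with the cube mask.
#' @param method Aggregation operator, one of `"mean"`, `"max"`, `"min"`,
#'   `"median"`. Median over an even count is the midpoint of the two central
#'   values.
#' @param normalized Logical; l1-normalize each pixel spectrum first.
#' @return A `spectrum`.
#' @export
agg_spectrum <- function(cube, pixels = NULL,
                         method = c("mean", "max", "min", "median"),
                         normalized = FALSE) {
  stopifnot(inherits(cube, "hsi_cube"))
  method <- match.arg(method)
  px <- resolve_pixels(cube, pixels)
  if (nrow(px) == 0) stop("empty selection: no mask-true pixels to aggregate", call. = FALSE)
  M <- pixel_spectra_matrix(cube, px$x, px$y)
  sums <- rowSums(abs(M))
  if (any(sums == 0)) {
    warning(sum(sums == 0), " degenerate all-zero pixel spectra excluded from aggregation")
    M <- M[sums > 0, , drop = FALSE]
    if (nrow(M) == 0) stop("empty selection: all pixels degenerate", call. = FALSE)
    sums <- sums[sums > 0]
  }
  if (normalized) M <- M / sums
  agg <- switch(method,
    mean = colMeans(M),
    max = apply(M, 2, max),
    min = apply(M, 2, min),
    median = apply(M, 2, stats::median))
  spectrum(agg, cube$wavelengths)
}
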