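# Image domain: representative pseudo grey-value images and display
# transforms (linear [0,255] scaling, brightness, pseudocolor, single channel).

#' Render a pseudo grey-value image from a cube
#'
#' Collapses the spectral dimension per pixel with mean, max, min or median,
#' or extracts the single plane of the channel nearest to `channel_nm`.
#' Non-mask pixels carry `NA` as sentinel and render black.
#'
#' @param cube An `hsi_cube`.
#' @param source One of `"mean"`, `"max"`, `"min"`, `"median"`, `"channel"`.
#' @param channel_nm Wavelength (nm) for `source = "channel"`; must lie within
#'   the axis range.
#' @return Object of class `pseudo_image`: list with `pixels` (h x w numeric,
#'   `NA` off-mask), `mask`, `source`, `channel_nm`, `brightness`, `scaled`
#'   (logical), `color` (logical).
#' @export
render_pseudo <- function(cube, source = c("mean", "max", "min", "median", "channel"),
                          channel_nm = NULL) {
  stopifnot(inherits(cube, "hsi_cube"))
  source <- match.arg(source)
  d <- dim(cube$values)
  vm <- matrix(cube$values, d[1] * d[2], d[3])
  px <- switch(source,
    mean = rowMeans(vm),
    max = apply(vm, 1, max),
    min = apply(vm, 1, min),
    median = apply(vm, 1, stats::median),
    channel = {
      if (is.null(channel_nm)) stop("channel_nm required for source = 'channel'", call. = FALSE)
      if (channel_nm < min(cube$wavelengths) || channel_nm > max(cube$wavelengths)) {
        stop("channel_nm ", channel_nm, " outside the wavelength axis range", call. = FALSE)
      }
      vm[, which.min(abs(cube$wavelengths - channel_nm))]
    })
  img <- matrix(px, d[1], d[2])
  img[!cube$mask] <- NA_real_
  structure(list(pixels = img, mask = cube$mask, source = source,
                 channel_nm = if (source == "channel") channel_nm else NULL,
                 brightness = 1, scaled = FALSE, color = FALSE),
            class = "pseudo_image")
}

#' @export
print.pseudo_image <- function(x, ...) {
  cat(sprintf("<pseudo_image> %s%s, %d x %d px%s%s\n",
              x$source, if (!is.null(x$channel_nm)) sprintf(" (%g nm)", x$channel_nm) else "",
              ncol(if (x$color) x$pixels[, , 1] else x$pixels),
              nrow(if (x$color) x$pixels[, , 1] else x$pixels),
              if (x$scaled) ", scaled [0,255]" else "",
              if (x$color) ", pseudocolor" else ""))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Linearly scale a pseudo image to [0, 255]
#'
#' Affine map of masked pixels so the masked minimum becomes 0 and the masked
#' maximum 255, then round half-up to integers. A constant image maps to all
#' 0 (declared convention). Scaling statistics use mask-true pixels only,
#' otherwise the dark background would dominate the dynamic range.
#'
#' @param img A grey `pseudo_image`.
#' @return The scaled `pseudo_image` (`scaled = TRUE`).
#' @export
scale_to_uint8 <- function(img) {
  stopifnot(inherits(img, "pseudo_image"))
  if (img$color) stop("scale_to_uint8 expects a grey image", call. = FALSE)
  v <- img$pixels[img$mask]
  lo <- min(v); hi <- max(v)
  out <- img$pixels
  if (hi == lo) {
    out[img$mask] <- 0
  } else {
    out[img$mask] <- round_half_up((img$pixels[img$mask] - lo) / (hi - lo) * 255)
  }
  img$pixels <- out
  img$scaled <- TRUE
  img
}

#' Multiply a pseudo image by a brightness factor
#'
#' Values are multiplied by `b` and clipped to [0, 255]. Brightening is used
#' to make dark radiance images legible; `b = 1` is the identity (up to
#' clipping already-scaled values at 255).
#'
#' @param img A `pseudo_image` (grey or color), typically already scaled.
#' @param b Brightness factor, > 0.
#' @return The brightened `pseudo_image`.
#' @export
apply_brightness <- function(img, b) {
  stopifnot(inherits(img, "pseudo_image"))
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b <= 0) {
    stop("brightness b must be a positive number", call. = FALSE)
  }
  img$pixels <- pmin(pmax(img$pixels * b, 0), 255)
  img$brightness <- img$brightness * b
  img
}

# fixed 256-entry spectral-style lookup table (violet -> blue -> cyan ->
# green -> yellow -> orange -> red -> dark red), built once at load time.
# All 256 entries are distinct by construction.
build_spectral_lut <- function() {
  anchors <- c("#4B0082", "#0000CD", "#0080FF", "#00C8C8", "#00B400",
               "#96DC00", "#FFFF00", "#FF9600", "#FF3200", "#8B0000")
  ramp <- grDevices::colorRamp(anchors, space = "rgb")
  lut <- round_half_up(ramp(seq(0, 1, length.out = 256)))
  storage.mode(lut) <- "integer"
  colnames(lut) <- c("r", "g", "b")
  lut
}

.spectral_lut <- build_spectral_lut()

#' The shipped 256-entry spectral lookup table
#'
#' @return Integer matrix 256 x 3 (`r`, `g`, `b` in 0..255); row `i` is the
#'   color of grey level `i - 1`. Deterministic and shipped with the package;
#'   no claim is made of color identity with any specific plotting library's
#'   colormap.
#' @export
spectral_lut <- function() .spectral_lut

#' Map a scaled grey image through the spectral lookup table
#'
#' @param img A grey `pseudo_image` already scaled to [0, 255]
#'   (see [scale_to_uint8()]).
#' @return A color `pseudo_image` whose `pixels` field is an h x w x 3 array
#'   in [0, 255]; non-mask pixels are black.
#' @export
apply_pseudocolor <- function(img) {
  stopifnot(inherits(img, "pseudo_image"))
  if (img$color) stop("image is already pseudocolored", call. = FALSE)
  if (!img$scaled) stop("apply_pseudocolor expects a [0,255]-scaled image", call. = FALSE)
  lut <- .spectral_lut
  g <- round_half_up(pmin(pmax(img$pixels, 0), 255))
  h <- nrow(g); w <- ncol(g)
  out <- array(0, dim = c(h, w, 3))
  on_mask <- which(img$mask)
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[on_mask] <- lut[g[on_mask] + 1L, ch]
    out[, , ch] <- plane
  }
  img$pixels <- out
  img$color <- TRUE
  img
}

#' Write a pseudo image as PNG
#'
#' @param img A `pseudo_image` (grey or color). Grey images should already be
#'   scaled to [0, 255]; `NA` (background) renders black.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_pseudo_png <- function(img, path) {
  stopifnot(inherits(img, "pseudo_image"))
  px <- img$pixels
  px[is.na(px)] <- 0
  px <- pmin(pmax(px / 255, 0), 1)
  png::writePNG(px, target = path)
  invisible(path)
}

#' @export
plot.pseudo_image <- function(x, ...) {
  px <- x$pixels
  px[is.na(px)] <- 0
  if (x$color) {
    rgbm <- grDevices::rgb(px[, , 1] / 255, px[, , 2] / 255, px[, , 3] / 255)
    dim(rgbm) <- dim(px)[1:2]
    ras <- grDevices::as.raster(rgbm)
  } else {
    ras <- grDevices::as.raster(pmin(pmax(px / 255, 0), 1))
  }
  graphics::plot(ras, ...)
  invisible(x)
}
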