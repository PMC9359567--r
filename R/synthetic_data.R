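# Synthetic coral-like HSI time series with known ground truth: locally
# red-shifted pixel subsets and a wrong-mask artifact fixture. Every other
# module is testable against these generators without any external data.

#' Configuration for the synthetic HSI generator
#'
#' Defaults describe the canonical study-like conditions: 64 x 64 images with
#' 40 channels over 380-750 nm, an elliptical coral mask, a 20% sub-population
#' of pixels whose spectra acquire a red-shifting linear tilt of fractional
#' magnitude 0.1 at T2 only, and 2% multiplicative per-channel noise.
#'
#' @param seed Integer RNG seed; the whole series is a deterministic function
#'   of the config.
#' @param w,h,S Image width, height and channel count.
#' @param axis_range Wavelength range in nm (`c(lo, hi)`, S evenly spaced
#'   channels).
#' @param morph Coral color morph, `"white"` or `"orange"`; selects the base
#'   spectrum template.
#' @param shift_fraction Fraction p of masked pixels that shift; exactly
#'   `round(p * |mask|)` pixels are drawn (seeded) and held constant across
#'   all shifted time points.
#' @param shift_magnitude Fractional tilt magnitude delta >= 0: the tilt ramps
#'   linearly from `-delta` at the axis minimum to `+delta` at the maximum
#'   (a red shift: lowered blue, elevated red). Positivity of spectra is
#'   preserved for delta < 1.
#' @param shift_timepoints Subset of time points at which the shifted pixels
#'   carry the tilt (default `"T2"`).
#' @param noise_sd Relative (multiplicative) Gaussian noise sd sigma per
#'   channel; radiance scales with illumination, so noise is modeled
#'   multiplicatively, which also keeps l1-normalized shapes stable.
#' @param mask_shape `"ellipse"` or `"blob"` (ellipse with a seeded sinusoidal
#'   boundary perturbation).
#' @param background_level Background radiance as a fraction of the mean base
#'   spectrum (flat across wavelength).
#' @param sample_id,condition,concentration Cube metadata.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, w = 64L, h = 64L, S = 40L,
                             axis_range = c(380, 750), morph = c("white", "orange"),
                             shift_fraction = 0.2, shift_magnitude = 0.1,
                             shift_timepoints = "T2", noise_sd = 0.02,
                             mask_shape = c("ellipse", "blob"),
                             background_level = 0.05,
                             sample_id = NULL, condition = "control",
                             concentration = 0) {
  morph <- match.arg(morph)
  mask_shape <- match.arg(mask_shape)
  stopifnot(w >= 4, h >= 4, S >= 2,
            shift_fraction >= 0, shift_fraction <= 1,
            is.finite(shift_magnitude), shift_magnitude >= 0,
            is.finite(noise_sd), noise_sd >= 0)
  shift_timepoints <- intersect(TIMEPOINTS, shift_timepoints)
  structure(list(seed = as.integer(seed), w = as.integer(w), h = as.integer(h),
                 S = as.integer(S), axis_range = as.numeric(axis_range),
                 morph = morph, shift_fraction = shift_fraction,
                 shift_magnitude = shift_magnitude,
                 shift_timepoints = shift_timepoints, noise_sd = noise_sd,
                 mask_shape = mask_shape, background_level = background_level,
                 sample_id = sample_id %||% paste0("synthetic-", seed),
                 condition = condition, concentration = concentration),
            class = "synthetic_config")
}

#' Base radiance spectrum of a coral color morph
#'
#' Smooth, strictly positive templates: the white morph is broadband with a
#' mild rise towards long wavelengths; the orange morph adds a pigment hump
#' around 590 nm. Deterministic given morph and axis; no numeric template is
#' taken from any measured spectrum.
#'
#' @param morph `"white"` or `"orange"`.
#' @param wavelengths Wavelength axis in nm.
#' @return A `spectrum`.
#' @export
make_base_spectrum <- function(morph = c("white", "orange"), wavelengths) {
  morph <- match.arg(morph)
  wl <- wavelength_axis(wavelengths)
  base <- 0.55 + 0.35 * stats::plogis((wl - 560) / 80)
  if (morph == "orange") {
    base <- base + 0.35 * exp(-((wl - 590)^2) / (2 * 28^2))
  }
  spectrum(base, wl)
}

# elliptical or blob mask centered in the image; blob perturbs the radius
# with seeded low-order sinusoids (uses the current RNG stream)
make_mask <- function(w, h, shape) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  rx <- 0.4 * w; ry <- 0.4 * h
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  if (shape == "ellipse") {
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  } else {
    amp <- stats::runif(3, 0.05, 0.15)
    phs <- stats::runif(3, 0, 2 * pi)
    theta <- atan2((y - cy) / ry, (x - cx) / rx)
    mod <- 1 + amp[1] * sin(2 * theta + phs[1]) + amp[2] * sin(3 * theta + phs[2]) +
      amp[3] * sin(5 * theta + phs[3])
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= mod^2
  }
}

# red-shift tilt factor per channel: ramps -delta .. +delta across the axis
tilt_factors <- function(wl, delta) {
  if (diff(range(wl)) == 0) return(rep(0, length(wl)))
  delta * (2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1)
}

#' Simulate a coral-like HSI time series with ground truth
#'
#' Per time point, each masked pixel's spectrum is
#' `base * (1 + tau(s)) * (1 + eps)` where the linear tilt `tau` (see
#' [synthetic_config()]) applies only to the shifted pixel subset at the
#' shifted time points and `eps ~ N(0, sigma^2)` i.i.d. per channel.
#' Background pixels get a flat spectrum at `background_level` times the mean
#' base radiance, with the same noise. The shifted subset is drawn once
#' (seeded) and held constant across shifted time points, modeling a
#' persistent local physiological response. With `shift_fraction = 0` all
#' four cubes are draws from one stationary model.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `ts` (an `hsi_timeseries`) and `truth` (class
#'   `hsi_ground_truth`: `shifted_pixels` -- named list per time point of
#'   data frames `x`, `y` -- `mask`, `base_spectrum`, `background_value`,
#'   `config`).
#' @export
simulate_timeseries <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  wl <- seq(cfg$axis_range[1], cfg$axis_range[2], length.out = cfg$S)
  base <- make_base_spectrum(cfg$morph, wl)$values
  bg_val <- cfg$background_level * mean(base)
  mask <- make_mask(cfg$w, cfg$h, cfg$mask_shape)
  n_mask <- sum(mask)
  if (n_mask == 0) stop("generated mask is empty", call. = FALSE)
  n_shift <- round(cfg$shift_fraction * n_mask)
  if (n_shift > 0 && n_mask == 0) stop("shift requested with empty mask", call. = FALSE)
  mask_lin <- which(mask)                       # column-major linear indices
  shift_lin <- if (n_shift > 0) sort(sample(mask_lin, n_shift)) else integer(0)
  tau <- tilt_factors(wl, cfg$shift_magnitude)
  h <- cfg$h; w <- cfg$w; S <- cfg$S
  cubes <- list()
  shifted_pixels <- list()
  for (tp in TIMEPOINTS) {
    vm <- matrix(bg_val, h * w, S)
    vm[mask_lin, ] <- rep(base, each = n_mask)
    if (tp %in% cfg$shift_timepoints && n_shift > 0) {
      vm[shift_lin, ] <- vm[shift_lin, , drop = FALSE] *
        rep(1 + tau, each = n_shift)
    }
    if (cfg$noise_sd > 0) {
      vm <- vm * (1 + matrix(stats::rnorm(h * w * S, 0, cfg$noise_sd), h * w, S))
    }
    vm[vm < 0] <- 0
    cubes[[tp]] <- hsi_cube(array(vm, c(h, w, S)), wl, mask,
                            sample_id = cfg$sample_id, time_point = tp,
                            condition = cfg$condition,
                            concentration = cfg$concentration)
    idx0 <- if (tp %in% cfg$shift_timepoints) shift_lin - 1L else integer(0)
    shifted_pixels[[tp]] <- data.frame(x = idx0 %/% h, y = idx0 %% h)
  }
  truth <- structure(list(shifted_pixels = shifted_pixels, mask = mask,
                          base_spectrum = spectrum(base, wl),
                          background_value = bg_val, config = cfg),
                     class = "hsi_ground_truth")
  list(ts = hsi_timeseries(cubes), truth = truth)
}

# binary dilation of a logical matrix by a disk of the given radius
dilate_disk <- function(mask, radius = 2L) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dy in -radius:radius) {
    for (dx in -radius:radius) {
      if (dx == 0 && dy == 0) next
      if (dx * dx + dy * dy > radius * radius) next
      ys <- pmin(pmax(1:h - dy, 1), h)
      xs <- pmin(pmax(1:w - dx, 1), w)
      out <- out | mask[ys, xs, drop = FALSE]
    }
  }
  out
}

#' Fixture reproducing the wrong-mask artifact
#'
#' A stationary (no-shift) series whose T0 mask is dilated to include a ring
#' of background pixels, emulating an annotation error where the coral mask
#' was too large and took in non-coral ground pixels at one time point.
#' Because those pixels have a flat background spectrum present only at T0,
#' they form time-point-exclusive structure in the embedding.
#'
#' @param cfg A [synthetic_config()]; its `shift_fraction` is forced to 0.
#' @param radius Dilation radius in pixels (default 2).
#' @return As [simulate_timeseries()]; `truth` additionally carries
#'   `background_pixels_T0`, the data frame of T0 mask pixels that are
#'   actually background.
#' @export
wrong_mask_fixture <- function(cfg, radius = 2L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cfg$shift_fraction <- 0
  sim <- simulate_timeseries(cfg)
  t0 <- sim$ts$cubes[["T0"]]
  big <- dilate_disk(t0$mask, radius)
  ring <- big & !t0$mask
  idx0 <- which(ring) - 1L
  t0$mask <- big
  sim$ts$cubes[["T0"]] <- t0
  sim$truth$background_pixels_T0 <- data.frame(x = idx0 %/% nrow(ring),
                                               y = idx0 %% nrow(ring))
  sim
}

#' Jaccard similarity of two pixel sets
#'
#' @param a,b Data frames with `x`, `y` columns (0-based pixel coordinates).
#' @return Scalar in [0, 1]; 1 for two empty sets.
#' @export
pixel_jaccard <- function(a, b) {
  ka <- unique(paste(a$x, a$y, sep = "\r"))
  kb <- unique(paste(b$x, b$y, sep = "\r"))
  if (length(ka) == 0 && length(kb) == 0) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}
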