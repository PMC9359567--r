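# Spectral change quantification between time points (crossing wavelengths,
# blue/red band-shift index), automated detection of time-point-exclusive
# embedding regions, and observer change-rating aggregation.

#' Wavelengths at which two spectra cross
#'
#' A crossing is a sign change of `d(s) = a(s) - b(s)` between adjacent
#' channels, localized by linear interpolation (the curves are piecewise
#' linear between channels, so a crossing generally falls between two
#' channels). Exact zeros at a channel report that channel's wavelength once;
#' a run of consecutive zeros reports its boundary wavelengths once.
#' Identical spectra cross nowhere and yield an empty vector.
#'
#' @param a,b `spectrum` objects on the same wavelength axis.
#' @return Sorted numeric vector of crossing wavelengths (nm), possibly empty.
#' @export
crossing_wavelengths <- function(a, b) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths))) {
    stop("spectra are on different wavelength axes", call. = FALSE)
  }
  wl <- a$wavelengths
  d <- a$values - b$values
  if (all(d == 0)) return(numeric(0))
  out <- numeric(0)
  # proper sign changes between adjacent nonzero channels
  for (i in seq_len(length(d) - 1)) {
    if (d[i] * d[i + 1] < 0) {
      out <- c(out, wl[i] + (wl[i + 1] - wl[i]) * d[i] / (d[i] - d[i + 1]))
    }
  }
  # exact-zero channels: report each maximal zero run by its boundary wavelengths
  z <- rle(d == 0)
  pos <- cumsum(c(1, z$lengths))
  for (j in seq_along(z$values)) {
    if (z$values[j]) {
      i0 <- pos[j]; i1 <- pos[j] + z$lengths[j] - 1
      out <- c(out, wl[i0], wl[i1])
    }
  }
  sort(unique(out))
}

channels_in_band <- function(wl, band) which(wl >= band[1] & wl <= band[2])

#' Blue/red band-shift index between two spectra
#'
#' Quantifies a red shift -- lowered blue values together with elevated red
#' values -- as
#' `(mean_b(red) - mean_a(red)) - (mean_b(blue) - mean_a(blue))`,
#' i.e. the gain in the red band minus the gain in the blue band going from
#' spectrum `a` to spectrum `b`. Positive values indicate a red shift from
#' `a` to `b`; the index is antisymmetric in its arguments. Meaningful on
#' l1-normalized spectra (amplitude changes cancel out of the comparison).
#'
#' @param a,b `spectrum` objects on the same axis (l1-normalized).
#' @param blue_band,red_band Wavelength intervals in nm (`c(lo, hi)`,
#'   inclusive), disjoint and within the axis. Defaults 400-500 and
#'   600-700 nm, conventional blue/red bands inside a 380-750 nm instrument
#'   range.
#' @return Signed scalar index.
#' @export
band_shift_index <- function(a, b, blue_band = c(400, 500), red_band = c(600, 700)) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths))) {
    stop("spectra are on different wavelength axes", call. = FALSE)
  }
  if (!(blue_band[2] < red_band[1] || red_band[2] < blue_band[1])) {
    stop("blue and red bands must be disjoint", call. = FALSE)
  }
  wl <- a$wavelengths
  ib <- channels_in_band(wl, blue_band)
  ir <- channels_in_band(wl, red_band)
  if (length(ib) == 0) stop("blue band contains no channels", call. = FALSE)
  if (length(ir) == 0) stop("red band contains no channels", call. = FALSE)
  (mean(b$values[ir]) - mean(a$values[ir])) - (mean(b$values[ib]) - mean(a$values[ib]))
}

#' Detect embedding regions populated by one time point only
#'
#' Automates the manual gating step of selecting regions of the embedding
#' display dominated by a single time point: restricted to rows of the two
#' compared time points, each row's k nearest neighbors (euclidean, in
#' embedding coordinates) are inspected and rows whose same-time-point
#' neighbor fraction reaches `purity` are returned. In a well-mixed
#' (no-change) embedding the expected fraction is about 0.5, so high-purity
#' rows mark genuinely time-point-exclusive structure.
#'
#' @param e An `hsi_embedding`.
#' @param tA,tB The two time points to compare (both present in `e`).
#' @param k Neighbor count, >= 1 and < number of restricted rows.
#' @param purity Purity threshold in (0.5, 1].
#' @return An `hsi_selection` (provenance `"time_filter"`, visible
#'   time points `{tA, tB}`) of the exclusive-region pixels; may be empty.
#' @export
detect_timepoint_exclusive_regions <- function(e, tA, tB, k = 15, purity = 0.9) {
  stopifnot(inherits(e, "hsi_embedding"))
  tA <- match.arg(tA, TIMEPOINTS); tB <- match.arg(tB, TIMEPOINTS)
  if (tA == tB) stop("tA and tB must differ", call. = FALSE)
  if (!(purity > 0.5 && purity <= 1)) stop("purity must be in (0.5, 1]", call. = FALSE)
  lab <- as.character(e$index$time_point)
  keep <- lab %in% c(tA, tB)
  if (!any(lab == tA) || !any(lab == tB)) {
    stop("embedding lacks rows for ", tA, " or ", tB, call. = FALSE)
  }
  coords <- e$coords[keep, , drop = FALSE]
  lab <- lab[keep]
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of restricted rows", call. = FALSE)
  nn <- FNN::get.knn(coords, k = k)$nn.index
  same <- matrix(lab[nn], nrow = n) == lab
  frac <- rowMeans(same)
  hit <- frac >= purity
  selection(e$index[keep, , drop = FALSE][hit, , drop = FALSE],
            provenance = "time_filter", visible_timepoints = c(tA, tB))
}

# ---- observer change ratings ----------------------------------------------

#' Read an observer change-rating table from CSV
#'
#' Columns: `user`, `sample_id`, `condition`, `concentration_mg_per_L`,
#' `time_point` (T0.5/T1/T2, the comparison against T0), `rating`
#' (integer 1 = no change ... 5 = highest change).
#'
#' @param path CSV path.
#' @return Data frame with validated columns.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user", "sample_id", "condition", "concentration_mg_per_L",
            "time_point", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("ratings CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  validate_ratings(df)
}

validate_ratings <- function(df) {
  if (!all(df$rating %in% 1:5)) stop("ratings must be integers in 1..5", call. = FALSE)
  if (!all(df$time_point %in% c("T0.5", "T1", "T2"))) {
    stop("rating time points must be T0.5, T1 or T2 (comparisons against T0)", call. = FALSE)
  }
  df$rating <- as.integer(df$rating)
  df
}

#' Average change rating
#'
#' Arithmetic mean of the observers' ratings for one sample / time
#' comparison; always within [1, 5].
#'
#' @param ratings Integer vector of ratings in 1..5, or a ratings data frame
#'   (its `rating` column is used); nonempty.
#' @return Scalar mean rating.
#' @export
average_change_rating <- function(ratings) {
  r <- if (is.data.frame(ratings)) ratings$rating else ratings
  if (length(r) == 0) stop("no ratings to average", call. = FALSE)
  if (!all(r %in% 1:5)) stop("ratings must be integers in 1..5", call. = FALSE)
  mean(r)
}

rating_item_key <- function(df) {
  paste(df$sample_id, df$condition, df$concentration_mg_per_L, df$time_point,
        sep = "\r")
}

#' Inter-observer agreement of change ratings
#'
#' Two estimators of rating spread between observers are provided, since the
#' summary can reasonably be computed either way:
#' * `"pairwise"` (default): the standard deviation of all pairwise
#'   between-observer rating differences over all jointly rated items. A
#'   constant offset between two observers contributes zero spread.
#' * `"per_item"`: the mean over items of the across-observer standard
#'   deviation of that item's ratings.
#'
#' @param ratings Ratings data frame (see [read_ratings()]) with >= 2
#'   observers sharing at least one rated item.
#' @param method `"pairwise"` or `"per_item"`.
#' @return Scalar standard deviation (>= 0).
#' @export
inter_observer_sd <- function(ratings, method = c("pairwise", "per_item")) {
  method <- match.arg(method)
  df <- validate_ratings(as.data.frame(ratings))
  users <- unique(df$user)
  if (length(users) < 2) stop("need ratings from at least 2 observers", call. = FALSE)
  df$item <- rating_item_key(df)
  if (method == "pairwise") {
    diffs <- numeric(0)
    for (i in seq_len(length(users) - 1)) {
      for (j in (i + 1):length(users)) {
        a <- df[df$user == users[i], ]; b <- df[df$user == users[j], ]
        shared <- intersect(a$item, b$item)
        if (length(shared) == 0) next
        diffs <- c(diffs,
                   a$rating[match(shared, a$item)] - b$rating[match(shared, b$item)])
      }
    }
    if (length(diffs) < 2) stop("observers share too few rated items", call. = FALSE)
    stats::sd(diffs)
  } else {
    per_item <- tapply(df$rating, df$item, function(r) if (length(r) >= 2) stats::sd(r) else NA_real_)
    per_item <- per_item[!is.na(per_item)]
    if (length(per_item) == 0) stop("no item was rated by >= 2 observers", call. = FALSE)
    mean(per_item)
  }
}

#' Star-glyph table of average change ratings
#'
#' Aggregates a full rating table into, per experimental condition
#' (condition x concentration), a matrix of average change ratings indexed
#' by coral sample x time comparison (T0.5, T1, T2) -- the data behind one
#' star glyph per condition.
#'
#' @param ratings Ratings data frame (see [read_ratings()]).
#' @return Object of class `rating_aggregate`: `table` (long data frame with
#'   `condition`, `concentration_mg_per_L`, `sample_id`, `time_point`,
#'   `r_hat`), `glyphs` (named list of sample x time-comparison matrices,
#'   one per condition x concentration).
#' @export
star_glyph_table <- function(ratings) {
  df <- validate_ratings(as.data.frame(ratings))
  agg <- stats::aggregate(rating ~ condition + concentration_mg_per_L +
                            sample_id + time_point, data = df, FUN = mean)
  names(agg)[names(agg) == "rating"] <- "r_hat"
  agg <- agg[order(agg$condition, agg$concentration_mg_per_L,
                   agg$sample_id, match(agg$time_point, TIMEPOINTS)), ]
  rownames(agg) <- NULL
  glyphs <- list()
  for (key in unique(paste(agg$condition, agg$concentration_mg_per_L, sep = "@"))) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    sub <- agg[agg$condition == parts[1] &
                 agg$concentration_mg_per_L == as.numeric(parts[2]), ]
    samples <- sort(unique(sub$sample_id))
    m <- matrix(NA_real_, length(samples), 3,
                dimnames = list(samples, c("T0.5", "T1", "T2")))
    m[cbind(match(sub$sample_id, samples), match(sub$time_point, colnames(m)))] <- sub$r_hat
    glyphs[[paste0(parts[1], "_", parts[2], "mg")]] <- m
  }
  structure(list(table = agg, glyphs = glyphs), class = "rating_aggregate")
}

#' @export
print.rating_aggregate <- function(x, ...) {
  cat(sprintf("<rating_aggregate> %d conditions, %d cells\n",
              length(x$glyphs), nrow(x$table)))
  invisible(x)
}

#' Plot star glyphs of average change ratings
#'
#' One radial glyph per experimental condition: axes are the coral samples'
#' average change ratings for one time comparison, drawn as overlaid polygons
#' for T0.5, T1 and T2. Ratings of 1 (no change) give a minimal glyph.
#'
#' @param x A `rating_aggregate`.
#' @param ... Further graphics parameters (unused).
#' @export
plot.rating_aggregate <- function(x, ...) {
  ng <- length(x$glyphs)
  old <- graphics::par(mfrow = c(ceiling(ng / 3), min(ng, 3)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  cols <- c("T0.5" = "#ffbf00", "T1" = "#d62728", "T2" = "#2ca02c")
  for (nm in names(x$glyphs)) {
    m <- x$glyphs[[nm]]
    n <- nrow(m)
    theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + pi / 2
    graphics::plot(NA, xlim = c(-5, 5), ylim = c(-5, 5), asp = 1, axes = FALSE,
                   xlab = "", ylab = "", main = nm, cex.main = 0.9)
    for (r in 1:5) {
      graphics::polygon(r * cos(theta), r * sin(theta), border = "grey85")
    }
    for (tp in colnames(m)) {
      v <- m[, tp]; v[is.na(v)] <- 1
      graphics::polygon(v * cos(theta), v * sin(theta), border = cols[tp],
                        col = grDevices::adjustcolor(cols[tp], 0.15), lwd = 2)
    }
    graphics::text(5.2 * cos(theta), 5.2 * sin(theta), rownames(m), cex = 0.6, xpd = NA)
  }
  invisible(x)
}

#' Spectral change report between two time points
#'
#' Bundles the change statistics for a detected (or supplied) pixel region:
#' the per-time-point agglomerated spectra, the crossing wavelengths and the
#' blue/red band-shift index between them.
#'
#' @param spec_a,spec_b Agglomerated `spectrum` of the region at the two time
#'   points (l1-normalized for a meaningful band-shift index).
#' @param time_pair Character vector `c(tA, tB)`.
#' @param detected Optional `hsi_selection` the spectra came from.
#' @param blue_band,red_band Passed to [band_shift_index()].
#' @return Object of class `shift_report`: `time_pair`, `crossings` (nm),
#'   `band_shift` (signed), `detected`, `per_t_spectra` (named list).
#' @export
shift_report <- function(spec_a, spec_b, time_pair, detected = NULL,
                         blue_band = c(400, 500), red_band = c(600, 700)) {
  structure(list(
    time_pair = time_pair,
    crossings = crossing_wavelengths(spec_a, spec_b),
    band_shift = band_shift_index(spec_a, spec_b, blue_band, red_band),
    detected = detected,
    per_t_spectra = stats::setNames(list(spec_a, spec_b), time_pair)),
    class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("<shift_report> %s vs %s: band shift %+.4g, %d crossing(s)%s\n",
              x$time_pair[1], x$time_pair[2], x$band_shift, length(x$crossings),
              if (length(x$crossings) > 0)
                paste0(" at ", paste(sprintf("%.1f", x$crossings), collapse = ", "), " nm")
              else ""))
  invisible(x)
}
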