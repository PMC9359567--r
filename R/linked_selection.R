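# Linked selection (link and brush): selections made in any domain resolve to
# a canonical pixel set and project into the other two domains.

SELECTION_PROVENANCE <- c("image_polygon", "embedding_lasso", "embedding_rect",
                          "time_filter", "composite")

canonical_pixels <- function(px) {
  px <- data.frame(time_point = tp_factor(px$time_point),
                   x = as.integer(px$x), y = as.integer(px$y))
  px <- unique(px)
  px[order(px$time_point, px$y, px$x), , drop = FALSE]
}

#' Construct a pixel selection
#'
#' A selection is the canonical currency of link and brush: a set of
#' `(time_point, x, y)` pixel references with a provenance tag and a set of
#' visible time points. Pixels at hidden time points stay in the set but are
#' excluded from projections.
#'
#' @param pixels Data frame with columns `time_point`, `x`, `y`
#'   (0-based coordinates). Deduplicated and canonically ordered.
#' @param provenance One of `"image_polygon"`, `"embedding_lasso"`,
#'   `"embedding_rect"`, `"time_filter"`, `"composite"`.
#' @param visible_timepoints Subset of [TIMEPOINTS]; default all.
#' @return Object of class `hsi_selection`.
#' @export
selection <- function(pixels,
                      provenance = c("composite", "image_polygon", "embedding_lasso",
                                     "embedding_rect", "time_filter"),
                      visible_timepoints = TIMEPOINTS) {
  provenance <- match.arg(provenance)
  if (is.null(pixels) || nrow(as.data.frame(pixels)) == 0) {
    pixels <- data.frame(time_point = tp_factor(character(0)),
                         x = integer(0), y = integer(0))
  } else {
    pixels <- canonical_pixels(as.data.frame(pixels))
  }
  visible_timepoints <- intersect(TIMEPOINTS, visible_timepoints)
  if (length(visible_timepoints) == 0) stop("visible time-point set must be nonempty", call. = FALSE)
  structure(list(pixels = pixels, provenance = provenance,
                 visible_timepoints = visible_timepoints),
            class = "hsi_selection")
}

#' @export
print.hsi_selection <- function(x, ...) {
  cat(sprintf("<hsi_selection> %d pixels (%s), visible: %s\n",
              nrow(x$pixels), x$provenance,
              paste(x$visible_timepoints, collapse = ", ")))
  if (nrow(x$pixels) > 0) print(table(droplevels(x$pixels$time_point)))
  invisible(x)
}

#' @export
length.hsi_selection <- function(x) nrow(x$pixels)

# pixels currently visible (provenance for projections)
visible_pixels <- function(sel) {
  sel$pixels[as.character(sel$pixels$time_point) %in% sel$visible_timepoints, ,
             drop = FALSE]
}

#' Select pixels by drawing a polygon in the image domain
#'
#' Rasterizes the polygon over the cube of one time point (pixel-center rule,
#' see [split_scan()]) and intersects with the coral mask. The images of the
#' four time points are not spatially registered, so an image ROI binds to
#' exactly one time point.
#'
#' @param ts An `hsi_timeseries`.
#' @param time_point The time point the ROI refers to.
#' @param polygon A [polygon_annotation()] (or n x 2 vertex matrix) in that
#'   cube's pixel coordinates.
#' @return An `hsi_selection` with provenance `"image_polygon"`; empty (with
#'   a warning) if the polygon covers no masked pixel.
#' @export
select_in_image <- function(ts, time_point, polygon) {
  stopifnot(inherits(ts, "hsi_timeseries"))
  time_point <- match.arg(time_point, TIMEPOINTS)
  verts <- if (inherits(polygon, "polygon_annotation")) polygon$vertices else as.matrix(polygon)
  cube <- ts$cubes[[time_point]]
  d <- dim(cube$values)
  if (max(verts[, 1]) <= 0 || min(verts[, 1]) >= d[2] ||
      max(verts[, 2]) <= 0 || min(verts[, 2]) >= d[1]) {
    stop("polygon does not intersect the image bounds", call. = FALSE)
  }
  m <- rasterize_polygon(verts, d[2], d[1]) & cube$mask
  idx <- which(m) - 1L
  if (length(idx) == 0) {
    warning("selection is empty: polygon covers no masked pixel")
    return(selection(NULL, "image_polygon"))
  }
  selection(data.frame(time_point = time_point, x = idx %/% d[1], y = idx %% d[1]),
            provenance = "image_polygon")
}

# membership of 2-D points in a selection shape
points_in_shape <- function(pts, shape) {
  if (is.list(shape) && identical(shape$type, "rect")) {
    pts[, 1] >= shape$xmin & pts[, 1] <= shape$xmax &
      pts[, 2] >= shape$ymin & pts[, 2] <= shape$ymax
  } else {
    verts <- if (inherits(shape, "polygon_annotation")) shape$vertices else as.matrix(shape)
    points_in_polygon(pts[, 1], pts[, 2], verts)
  }
}

#' Select pixels by a lasso or rectangle in the embedding domain
#'
#' @param e An `hsi_embedding`.
#' @param shape Either a polygon (n x 2 vertex matrix / `polygon_annotation`)
#'   in embedding coordinates, or a rectangle
#'   `list(type = "rect", xmin =, xmax =, ymin =, ymax =)` (inclusive bounds).
#' @param visible Subset of [TIMEPOINTS]; rows at other time points are not
#'   selectable (they are hidden in the display).
#' @return An `hsi_selection` with provenance `"embedding_lasso"` or
#'   `"embedding_rect"`; may be empty.
#' @export
select_in_embedding <- function(e, shape, visible = TIMEPOINTS) {
  stopifnot(inherits(e, "hsi_embedding"))
  inside <- points_in_shape(e$coords, shape)
  inside <- inside & (as.character(e$index$time_point) %in% visible)
  prov <- if (is.list(shape) && identical(shape$type, "rect")) "embedding_rect" else "embedding_lasso"
  selection(e$index[inside, , drop = FALSE], provenance = prov,
            visible_timepoints = visible)
}

#' Rows of an embedding corresponding to a selection
#'
#' Uses the row-to-pixel bijection of the embedding index; only visible
#' pixels are mapped.
#'
#' @param sel An `hsi_selection`.
#' @param e An `hsi_embedding`.
#' @return Integer vector of row indices into `e$coords`.
#' @export
selection_rows <- function(sel, e) {
  stopifnot(inherits(sel, "hsi_selection"), inherits(e, "hsi_embedding"))
  px <- visible_pixels(sel)
  if (nrow(px) == 0) return(integer(0))
  key <- function(df) paste(df$time_point, df$x, df$y, sep = "\r")
  sort(which(key(e$index) %in% key(px)))
}

#' Project a selection into the image, spectral and embedding domains
#'
#' The core of link and brush: whatever domain a selection came from, it is
#' materialized as (i) one highlight mask per visible time point, (ii) one
#' agglomerated spectrum per visible time point with selected pixels, and
#' (iii) the corresponding embedding row indices.
#'
#' @param sel An `hsi_selection`, nonempty for at least one visible time point.
#' @param ts The `hsi_timeseries` the selection refers to.
#' @param e Optional `hsi_embedding` for the embedding-row projection.
#' @param method Aggregation operator for the spectra (see [agg_spectrum()]).
#' @param normalized Passed to [agg_spectrum()].
#' @return List with `masks` (named list of h x w logicals, one per visible
#'   time point), `spectra` (named list of `spectrum`, only for time points
#'   holding selected pixels) and `embedding_rows` (integer vector, or `NULL`
#'   without `e`).
#' @export
project <- function(sel, ts, e = NULL, method = "mean", normalized = FALSE) {
  stopifnot(inherits(sel, "hsi_selection"), inherits(ts, "hsi_timeseries"))
  px <- visible_pixels(sel)
  if (nrow(px) == 0) stop("empty selection: nothing to project", call. = FALSE)
  masks <- list(); spectra <- list()
  for (tp in sel$visible_timepoints) {
    cube <- ts$cubes[[tp]]
    d <- dim(cube$values)
    m <- matrix(FALSE, d[1], d[2])
    sub <- px[as.character(px$time_point) == tp, , drop = FALSE]
    if (nrow(sub) > 0) {
      m[cbind(sub$y + 1, sub$x + 1)] <- TRUE
      spectra[[tp]] <- agg_spectrum(cube, sub, method = method, normalized = normalized)
    }
    masks[[tp]] <- m
  }
  list(masks = masks, spectra = spectra,
       embedding_rows = if (!is.null(e)) selection_rows(sel, e) else NULL)
}

#' Change the visible time points of a selection
#'
#' Hiding time points removes them from subsequent projections without
#' touching the underlying pixel set, mirroring the (de)selection of time
#' points in the linked displays; un-hiding restores the original behaviour.
#'
#' @param sel An `hsi_selection`.
#' @param subset Nonempty subset of [TIMEPOINTS].
#' @return The modified selection.
#' @export
set_visible_timepoints <- function(sel, subset) {
  stopifnot(inherits(sel, "hsi_selection"))
  subset <- intersect(TIMEPOINTS, subset)
  if (length(subset) == 0) stop("visible time-point set must be nonempty", call. = FALSE)
  sel$visible_timepoints <- subset
  sel
}

sel_binop <- function(a, b, op) {
  stopifnot(inherits(a, "hsi_selection"), inherits(b, "hsi_selection"))
  key <- function(df) paste(df$time_point, df$x, df$y, sep = "\r")
  ka <- key(a$pixels); kb <- key(b$pixels)
  keep <- switch(op,
    union = rbind(a$pixels, b$pixels),
    intersect = a$pixels[ka %in% kb, , drop = FALSE],
    subtract = a$pixels[!ka %in% kb, , drop = FALSE])
  selection(keep, provenance = "composite",
            visible_timepoints = union(a$visible_timepoints, b$visible_timepoints))
}

#' Selection set algebra
#'
#' Union, intersection and difference of selections (by pixel reference);
#' the result has provenance `"composite"`. Needed to script multi-step
#' gating that a user would perform interactively.
#'
#' @param a,b `hsi_selection`s over the same sample.
#' @return An `hsi_selection`.
#' @export
selection_union <- function(a, b) sel_binop(a, b, "union")

#' @rdname selection_union
#' @export
selection_intersect <- function(a, b) sel_binop(a, b, "intersect")

#' @rdname selection_union
#' @export
selection_subtract <- function(a, b) sel_binop(a, b, "subtract")
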