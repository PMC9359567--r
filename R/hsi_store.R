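# HSI cube store: constructors, validation, HDF5 I/O, polygon annotations and
# scan splitting.
#
# Coordinate convention (used by every module): 0-based pixel coordinates,
# (x, y) = (column, row); value arrays are stored as (y, x, s), i.e. an R
# array of dim c(h, w, S) indexed values[y + 1, x + 1, s].

#' Construct and validate a wavelength axis
#'
#' @param values Numeric vector of S wavelengths in nm. Must be strictly
#'   increasing, finite, positive, with S >= 2.
#' @return The validated numeric vector (invisibly classed as used internally).
#' @export
wavelength_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("wavelength axis needs at least 2 channels", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("wavelengths must be finite and > 0", call. = FALSE)
  }
  if (any(diff(values) <= 0)) stop("wavelengths must be strictly increasing", call. = FALSE)
  values
}

#' Construct a hyperspectral image cube
#'
#' One sample at one time point: a `h x w x S` radiance array with a
#' wavelength axis and a boolean coral mask. Radiance is in arbitrary
#' (sensor) units; no radiometric assumptions are made beyond nonnegativity.
#'
#' @param values Numeric array of dim `c(h, w, S)`, indexed `(y, x, s)`;
#'   nonnegative radiance.
#' @param wavelengths Wavelength axis (nm), length S, strictly increasing.
#' @param mask Logical `h x w` matrix, `TRUE` marks a sample (coral) pixel.
#'   At least one pixel must be `TRUE`.
#' @param sample_id Sample identifier string.
#' @param time_point One of `"T0"`, `"T0.5"`, `"T1"`, `"T2"`.
#' @param condition One of [CONDITIONS].
#' @param concentration Exposure concentration in mg/L (0 for control).
#' @return An object of class `hsi_cube` with fields `values`, `wavelengths`,
#'   `mask`, `sample_id`, `time_point`, `condition`, `concentration`.
#' @export
hsi_cube <- function(values, wavelengths, mask, sample_id,
                     time_point = "T0", condition = "control",
                     concentration = 0) {
  wavelengths <- wavelength_axis(wavelengths)
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be a 3-d array (h, w, S)", call. = FALSE)
  }
  d <- dim(values)
  if (d[3] != length(wavelengths)) {
    stop("shape mismatch: values have S=", d[3], " channels but axis has ",
         length(wavelengths), call. = FALSE)
  }
  if (!is.matrix(mask) || !is.logical(mask)) mask <- matrix(as.logical(mask), d[1], d[2])
  if (!all(dim(mask) == d[1:2])) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(d[1:2], collapse = "x"), call. = FALSE)
  }
  if (!any(mask)) stop("mask has no TRUE pixel", call. = FALSE)
  vm <- matrix(values, d[1] * d[2], d[3])
  if (anyNA(vm[as.vector(mask), , drop = FALSE])) {
    stop("NaN/NA radiance under the mask", call. = FALSE)
  }
  condition <- match.arg(condition, CONDITIONS)
  time_point <- match.arg(time_point, TIMEPOINTS)
  structure(
    list(values = values, wavelengths = wavelengths, mask = mask,
         sample_id = as.character(sample_id), time_point = time_point,
         condition = condition, concentration = as.numeric(concentration)),
    class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<hsi_cube> sample '%s' %s (%s, %g mg/L)\n  %d x %d pixels, %d channels (%.0f-%.0f nm), %d masked\n",
    x$sample_id, x$time_point, x$condition, x$concentration,
    d[2], d[1], d[3], min(x$wavelengths), max(x$wavelengths), sum(x$mask)))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

#' Assemble the four-cube time series of one sample
#'
#' @param cubes List of four `hsi_cube`s covering T0, T0.5, T1 and T2 (any
#'   order; they are stored keyed by time point). All cubes must share
#'   `sample_id`, `condition` and wavelength axis. Image sizes may differ
#'   across time points: acquisitions are not spatially registered.
#' @return An object of class `hsi_timeseries`: list with `sample_id`,
#'   `condition`, `concentration` and `cubes` (named list keyed by
#'   time point).
#' @export
hsi_timeseries <- function(cubes) {
  if (!all(vapply(cubes, inherits, logical(1), "hsi_cube"))) {
    stop("all elements must be hsi_cube objects", call. = FALSE)
  }
  tps <- vapply(cubes, `[[`, character(1), "time_point")
  if (!setequal(tps, TIMEPOINTS) || anyDuplicated(tps)) {
    stop("need exactly one cube per time point ",
         paste(TIMEPOINTS, collapse = ", "), call. = FALSE)
  }
  names(cubes) <- tps
  cubes <- cubes[TIMEPOINTS]
  ids <- unique(vapply(cubes, `[[`, character(1), "sample_id"))
  cond <- unique(vapply(cubes, `[[`, character(1), "condition"))
  if (length(ids) != 1 || length(cond) != 1) {
    stop("cubes disagree on sample_id or condition", call. = FALSE)
  }
  ax <- cubes[[1]]$wavelengths
  for (cb in cubes[-1]) {
    if (!isTRUE(all.equal(cb$wavelengths, ax))) {
      stop("cubes disagree on the wavelength axis", call. = FALSE)
    }
  }
  structure(list(sample_id = ids, condition = cond,
                 concentration = cubes[[1]]$concentration, cubes = cubes),
            class = "hsi_timeseries")
}

#' @export
print.hsi_timeseries <- function(x, ...) {
  cat(sprintf("<hsi_timeseries> sample '%s' (%s, %g mg/L), 4 time points\n",
              x$sample_id, x$condition, x$concentration))
  for (tp in TIMEPOINTS) {
    d <- dim(x$cubes[[tp]]$values)
    cat(sprintf("  %-4s %d x %d px, %d masked\n", tp, d[2], d[1], sum(x$cubes[[tp]]$mask)))
  }
  invisible(x)
}

# snap doubles to float32 precision (the on-disk dtype of /values)
snap_float32 <- function(x) {
  readBin(writeBin(as.vector(as.double(x)), raw(), size = 4L),
          "double", n = length(x), size = 4L)
}

#' Write a cube to an HDF5 file
#'
#' File layout (C order, as seen by any HDF5 reader): datasets `/values`
#' (h x w x S, float32), `/wavelengths` (S, float64), `/mask` (h x w, uint8);
#' root attributes `sample_id`, `time_point`, `condition`,
#' `concentration_mg_per_L`. One file per sample per time point. Values are
#' stored as float32, so `save_cube` snaps them to float32 precision; for
#' float32 data the round trip through [load_cube()] is bit-exact.
#'
#' @param cube An `hsi_cube`.
#' @param path Output file path; an existing file is overwritten.
#' @return `path`, invisibly.
#' @export
save_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop("cannot create HDF5 file at '", path, "'", call. = FALSE)
  d <- dim(cube$values)
  v32 <- array(snap_float32(cube$values), d)
  # dims passed in file (C) order; native = TRUE writes the R array row-major
  rhdf5::h5createDataset(path, "values", dims = rev(d), H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(v32, path, "values", native = TRUE)
  rhdf5::h5write(cube$wavelengths, path, "wavelengths")
  rhdf5::h5createDataset(path, "mask", dims = rev(dim(cube$mask)),
                         H5type = "H5T_NATIVE_UINT8")
  rhdf5::h5write(matrix(as.integer(cube$mask), nrow(cube$mask)), path, "mask",
                 native = TRUE)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(cube$sample_id, fid, "sample_id")
  rhdf5::h5writeAttribute(cube$time_point, fid, "time_point")
  rhdf5::h5writeAttribute(cube$condition, fid, "condition")
  rhdf5::h5writeAttribute(cube$concentration, fid, "concentration_mg_per_L")
  invisible(path)
}

#' Read a cube from an HDF5 file
#'
#' @param path Path to a file written by [save_cube()] (layout documented
#'   there). All cube invariants are validated; a missing dataset, an
#'   axis/values shape mismatch or an all-false mask each raise a distinct
#'   error.
#' @return An `hsi_cube`.
#' @export
load_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  have <- tryCatch(rhdf5::h5ls(path)$name, error = function(e) {
    stop("not a readable HDF5 file: '", path, "'", call. = FALSE)
  })
  for (ds in c("values", "wavelengths", "mask")) {
    if (!ds %in% have) stop("missing dataset /", ds, " in '", path, "'", call. = FALSE)
  }
  values <- rhdf5::h5read(path, "values", native = TRUE)
  wavelengths <- as.numeric(rhdf5::h5read(path, "wavelengths"))
  mask <- rhdf5::h5read(path, "mask", native = TRUE)
  storage.mode(mask) <- "integer"
  at <- rhdf5::h5readAttributes(path, "/")
  hsi_cube(values = array(as.double(values), dim(values)),
           wavelengths = wavelengths,
           mask = mask > 0L,
           sample_id = at$sample_id %||% "unknown",
           time_point = as.character(at$time_point %||% "T0"),
           condition = as.character(at$condition %||% "control"),
           concentration = as.numeric(at$concentration_mg_per_L %||% 0))
}

#' Load a full time series from a directory of cube files
#'
#' @param dir Directory containing exactly one saved cube per time point
#'   (any file names ending in `.h5`).
#' @return An `hsi_timeseries`.
#' @export
load_timeseries <- function(dir) {
  files <- list.files(dir, pattern = "\\.h5$", full.names = TRUE)
  hsi_timeseries(lapply(files, load_cube))
}

#' Save a full time series, one HDF5 file per time point
#'
#' @param ts An `hsi_timeseries`.
#' @param dir Output directory (created if absent). Files are named
#'   `<sample_id>_<time point>.h5` with `.` replaced by `p`.
#' @return Character vector of the four file paths, invisibly.
#' @export
save_timeseries <- function(ts, dir) {
  stopifnot(inherits(ts, "hsi_timeseries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tp in TIMEPOINTS) {
    fn <- file.path(dir, paste0(ts$sample_id, "_", gsub(".", "p", tp, fixed = TRUE), ".h5"))
    save_cube(ts$cubes[[tp]], fn)
    paths <- c(paths, fn)
  }
  invisible(paths)
}

# ---- polygon annotations ---------------------------------------------------

# do segments (p1,p2) and (p3,p4) properly intersect (excluding shared endpoints)?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Construct a polygon annotation
#'
#' An outline of one sample in a larger scan, in scan pixel coordinates.
#'
#' @param label Sample label (becomes the `sample_id` after [split_scan()]).
#' @param vertices Numeric matrix (n x 2) or list of `(x, y)` pairs; n >= 3.
#'   The polygon must not self-intersect.
#' @return An object of class `polygon_annotation` with fields `label` and
#'   `vertices` (n x 2 matrix).
#' @export
polygon_annotation <- function(label, vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("polygon needs >= 3 (x, y) vertices", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("polygon vertices must be finite", call. = FALSE)
  n <- nrow(vertices)
  # O(n^2) proper-intersection check over non-adjacent edge pairs
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segments_cross(vertices[i, ], vertices[i %% n + 1, ],
                         vertices[j, ], vertices[j %% n + 1, ])) {
        stop("polygon is self-intersecting", call. = FALSE)
      }
    }
  }
  structure(list(label = as.character(label), vertices = unname(vertices)),
            class = "polygon_annotation")
}

#' Read polygon annotations from JSON
#'
#' Schema: `{"annotations": [{"label": "...", "polygon": [[x, y], ...]}]}`.
#'
#' @param path JSON file path.
#' @return List of `polygon_annotation`s.
#' @export
read_annotations <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  lapply(js$annotations, function(a) polygon_annotation(a$label, a$polygon))
}

# vectorized crossing-number point-in-polygon (half-open semantics: for an
# axis-aligned box [x0,x1) x [y0,y1) a center on the low edge is in, on the
# high edge out)
points_in_polygon <- function(px, py, verts) {
  vx <- verts[, 1]; vy <- verts[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- vx[i] + (py[cross] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      hit <- which(cross)[px[cross] < xint]
      inside[hit] <- !inside[hit]
    }
    j <- i
  }
  inside
}

# rasterize a polygon over a w x h pixel grid: pixel (x, y) is in iff its
# center (x + 0.5, y + 0.5) is inside. Returns logical h x w matrix.
rasterize_polygon <- function(verts, w, h) {
  xs <- rep(0:(w - 1), each = h)   # column-major over (y, x)
  ys <- rep(0:(h - 1), times = w)
  inside <- points_in_polygon(xs + 0.5, ys + 0.5, verts)
  matrix(inside, nrow = h, ncol = w)
}

#' Split a multi-sample scan into per-sample masked cubes
#'
#' Each acquisition images several samples in one large cube; sample outlines
#' are delivered as polygon annotations. For every polygon the scan is cropped
#' to the polygon's pixel bounding box and the mask is the rasterized polygon
#' (a pixel belongs iff its center `(x + 0.5, y + 0.5)` lies inside;
#' axis-aligned rectangles therefore behave as half-open boxes).
#'
#' @param scan An `hsi_cube` covering the full scan.
#' @param annotations List of [polygon_annotation()]s, each within scan bounds.
#' @return List of `hsi_cube`s, one per polygon, `sample_id` taken from the
#'   polygon label. Each cube carries an attribute `origin` = `c(x0, y0)`,
#'   the scan coordinates of its pixel (0, 0).
#' @export
split_scan <- function(scan, annotations) {
  stopifnot(inherits(scan, "hsi_cube"))
  if (inherits(annotations, "polygon_annotation")) annotations <- list(annotations)
  d <- dim(scan$values); h <- d[1]; w <- d[2]
  lapply(annotations, function(ann) {
    v <- ann$vertices
    if (max(v[, 1]) <= 0 || min(v[, 1]) >= w || max(v[, 2]) <= 0 || min(v[, 2]) >= h) {
      stop("polygon '", ann$label, "' lies fully outside the scan", call. = FALSE)
    }
    # candidate pixels whose centers can fall inside
    x_lo <- max(0L, as.integer(ceiling(min(v[, 1]) - 0.5)))
    x_hi <- min(w - 1L, as.integer(floor(max(v[, 1]) - 0.5)))
    y_lo <- max(0L, as.integer(ceiling(min(v[, 2]) - 0.5)))
    y_hi <- min(h - 1L, as.integer(floor(max(v[, 2]) - 0.5)))
    if (x_hi < x_lo || y_hi < y_lo) {
      stop("polygon '", ann$label, "' rasterizes to zero pixels", call. = FALSE)
    }
    vv <- cbind(v[, 1] - x_lo, v[, 2] - y_lo)
    sub_w <- x_hi - x_lo + 1L; sub_h <- y_hi - y_lo + 1L
    m <- rasterize_polygon(vv, sub_w, sub_h)
    if (!any(m)) {
      stop("polygon '", ann$label, "' rasterizes to zero pixels", call. = FALSE)
    }
    cube <- hsi_cube(values = scan$values[(y_lo + 1):(y_hi + 1), (x_lo + 1):(x_hi + 1), , drop = FALSE],
                     wavelengths = scan$wavelengths, mask = m,
                     sample_id = ann$label, time_point = scan$time_point,
                     condition = scan$condition, concentration = scan$concentration)
    attr(cube, "origin") <- c(x0 = x_lo, y0 = y_lo)
    cube
  })
}
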