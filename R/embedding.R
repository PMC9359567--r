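# Embedding domain: 2-D embeddings (UMAP / t-SNE) of all masked, l1-normalized
# pixel spectra pooled over a sample's four time points, their persistence,
# and the PCA biplot of selected spectra.

# mask-true pixel coordinates of a cube in canonical row order:
# y-major (y varies slowest), then x
mask_pixels_ymajor <- function(cube) {
  d <- dim(cube$values)
  idx <- which(cube$mask) - 1L          # column-major linear indices
  x <- idx %/% d[1]; y <- idx %% d[1]
  o <- order(y, x)
  data.frame(x = x[o], y = y[o])
}

#' Embed all masked pixel spectra of a time series in 2-D
#'
#' Stacks the l1-normalized spectra of every mask-true pixel from all four
#' time points of one sample and maps them jointly to 2-D with UMAP or t-SNE.
#' The returned object keeps an explicit bijection between embedding rows and
#' pixel references `(time_point, x, y)`; row order is time-point order, then
#' y-major pixel order. Normalization is mandatory here: the embedding is
#' meant to compare spectral *shape*, not amplitude. Degenerate (all-zero)
#' pixels are excluded with a warning and are absent from the index.
#'
#' @param ts An `hsi_timeseries`.
#' @param method `"umap"` or `"tsne"`.
#' @param metric `"euclidean"` or `"cosine"`. t-SNE supports euclidean only;
#'   `tsne` + `cosine` raises an unsupported-combination error.
#' @param seed Integer seed; embeddings are bit-reproducible for equal seeds
#'   and parameters (UMAP runs single-threaded for this reason).
#' @param params Named list of method parameters. UMAP: `n_neighbors`
#'   (default 15), `min_dist` (0.1). t-SNE: `perplexity` (30). Optional
#'   `subsample_n`: uniform seeded subsampling to at most this many pixels
#'   per time point (off by default).
#' @return Object of class `hsi_embedding`: `coords` (N x 2), `index`
#'   (data.frame `time_point`, `x`, `y`; the row bijection), `method`,
#'   `metric`, `seed`, `params`, `sample_id`.
#' @export
compute_embedding <- function(ts, method = c("umap", "tsne"),
                              metric = c("euclidean", "cosine"),
                              seed = 42, params = list()) {
  stopifnot(inherits(ts, "hsi_timeseries"))
  method <- match.arg(method)
  metric <- match.arg(metric)
  if (method == "tsne" && metric == "cosine") {
    stop("unsupported combination: t-SNE backend supports the euclidean metric only",
         call. = FALSE)
  }
  set.seed(seed)
  rows <- list(); mats <- list()
  n_degenerate <- 0L
  for (tp in TIMEPOINTS) {
    cube <- ts$cubes[[tp]]
    px <- mask_pixels_ymajor(cube)
    if (!is.null(params$subsample_n) && nrow(px) > params$subsample_n) {
      keep <- sort(sample.int(nrow(px), params$subsample_n))
      px <- px[keep, , drop = FALSE]
    }
    M <- pixel_spectra_matrix(cube, px$x, px$y)
    sums <- rowSums(abs(M))
    if (any(sums == 0)) {
      n_degenerate <- n_degenerate + sum(sums == 0)
      M <- M[sums > 0, , drop = FALSE]
      px <- px[sums > 0, , drop = FALSE]
      sums <- sums[sums > 0]
    }
    mats[[tp]] <- M / sums
    rows[[tp]] <- data.frame(time_point = tp_factor(rep(tp, nrow(px))),
                             x = px$x, y = px$y)
  }
  if (n_degenerate > 0) {
    warning(n_degenerate, " degenerate all-zero pixels excluded from the embedding")
  }
  X <- do.call(rbind, mats)
  index <- do.call(rbind, rows)
  rownames(index) <- NULL
  coords <- if (method == "umap") {
    uwot::umap(X,
               n_neighbors = params$n_neighbors %||% 15,
               min_dist = params$min_dist %||% 0.1,
               metric = metric, seed = seed,
               n_threads = 1, n_sgd_threads = 0)
  } else {
    out <- Rtsne::Rtsne(X, perplexity = params$perplexity %||% 30,
                        check_duplicates = FALSE)
    out$Y
  }
  params_full <- if (method == "umap") {
    list(n_neighbors = params$n_neighbors %||% 15,
         min_dist = params$min_dist %||% 0.1)
  } else {
    list(perplexity = params$perplexity %||% 30)
  }
  if (!is.null(params$subsample_n)) params_full$subsample_n <- params$subsample_n
  coords <- as.matrix(coords)
  coords <- matrix(as.vector(coords), nrow(coords), 2)  # drop uwot attributes
  structure(list(coords = coords, index = index,
                 method = method, metric = metric, seed = as.integer(seed),
                 params = params_full, sample_id = ts$sample_id),
            class = "hsi_embedding")
}

#' @export
print.hsi_embedding <- function(x, ...) {
  cat(sprintf("<hsi_embedding> %s/%s, seed %d: %d pixels x 2\n",
              x$method, x$metric, x$seed, nrow(x$coords)))
  print(table(x$index$time_point))
  invisible(x)
}

#' @export
plot.hsi_embedding <- function(x, ..., cex = 0.3) {
  cols <- c("T0" = "#1f77b4", "T0.5" = "#ffbf00", "T1" = "#d62728", "T2" = "#2ca02c")
  graphics::plot(x$coords, col = cols[as.character(x$index$time_point)],
                 pch = 16, cex = cex, xlab = "dim 1", ylab = "dim 2", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16, cex = 0.8)
  invisible(x)
}

EMBEDDING_SCHEMA_VERSION <- 1L

#' Persist an embedding to HDF5
#'
#' Embeddings are expensive, so they are computed once, saved, and reloaded
#' on demand. Layout: `/coords` (N x 2 float64), `/index_tp` (N int, 1-based
#' position in [TIMEPOINTS]), `/index_x`, `/index_y` (N int); root attributes
#' `schema_version`, `method`, `metric`, `seed`, `params_json`, `sample_id`.
#'
#' @param e An `hsi_embedding`.
#' @param path Output HDF5 path (overwritten).
#' @return `path`, invisibly.
#' @export
persist_embedding <- function(e, path) {
  stopifnot(inherits(e, "hsi_embedding"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "coords", dims = rev(dim(e$coords)),
                         H5type = "H5T_IEEE_F64LE")
  rhdf5::h5write(e$coords, path, "coords", native = TRUE)
  rhdf5::h5write(as.integer(e$index$time_point), path, "index_tp")
  rhdf5::h5write(as.integer(e$index$x), path, "index_x")
  rhdf5::h5write(as.integer(e$index$y), path, "index_y")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(EMBEDDING_SCHEMA_VERSION, fid, "schema_version")
  rhdf5::h5writeAttribute(e$method, fid, "method")
  rhdf5::h5writeAttribute(e$metric, fid, "metric")
  rhdf5::h5writeAttribute(e$seed, fid, "seed")
  rhdf5::h5writeAttribute(as.character(jsonlite::toJSON(e$params, auto_unbox = TRUE)),
                          fid, "params_json")
  rhdf5::h5writeAttribute(e$sample_id, fid, "sample_id")
  invisible(path)
}

#' Load a persisted embedding
#'
#' @param path HDF5 file written by [persist_embedding()]. The stored schema
#'   version must match; an index whose length disagrees with the coordinate
#'   rows is rejected.
#' @return An `hsi_embedding`.
#' @export
load_embedding <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "/")
  ver <- as.integer(at$schema_version %||% -1L)
  if (!identical(ver, EMBEDDING_SCHEMA_VERSION)) {
    stop("embedding schema version mismatch: file has ", ver,
         ", expected ", EMBEDDING_SCHEMA_VERSION, call. = FALSE)
  }
  coords <- rhdf5::h5read(path, "coords", native = TRUE)
  tp <- as.integer(rhdf5::h5read(path, "index_tp"))
  x <- as.integer(rhdf5::h5read(path, "index_x"))
  y <- as.integer(rhdf5::h5read(path, "index_y"))
  if (length(tp) != nrow(coords) || length(x) != nrow(coords) ||
      length(y) != nrow(coords)) {
    stop("corrupt embedding file: index length does not match coords rows",
         call. = FALSE)
  }
  if (any(tp < 1L | tp > 4L)) stop("corrupt embedding file: bad time-point codes", call. = FALSE)
  index <- data.frame(time_point = factor(TIMEPOINTS[tp], levels = TIMEPOINTS),
                      x = x, y = y)
  structure(list(coords = unname(as.matrix(coords)), index = index,
                 method = as.character(at$method), metric = as.character(at$metric),
                 seed = as.integer(at$seed),
                 params = jsonlite::fromJSON(as.character(at$params_json)),
                 sample_id = as.character(at$sample_id)),
            class = "hsi_embedding")
}

#' PCA biplot of a set of spectra
#'
#' Principal component analysis of (typically l1-normalized) spectra selected
#' in the embedding display: scores are the centered data projected on the
#' top two principal axes, loadings are those axes, one arrow per wavelength.
#' Each wavelength is assigned a display color from its nm value so arrows
#' can be read as spectral bands.
#'
#' @param spectra An M x S numeric matrix (rows = spectra) or a list of
#'   `spectrum` objects sharing one axis; M >= 3.
#' @param wavelengths Wavelength axis (nm); required when `spectra` is a bare
#'   matrix without one attached.
#' @return Object of class `pca_biplot`: `scores` (M x 2), `loadings` (S x 2,
#'   orthonormal columns), `explained_variance` (length 2),
#'   `wavelength_colors` (S hex colors), `wavelengths`, `degenerate` (TRUE
#'   when the data have rank < 2; the second component is then meaningless
#'   but no error is raised).
#' @export
pca_biplot <- function(spectra, wavelengths = NULL) {
  if (is.list(spectra) && !is.data.frame(spectra) && !is.matrix(spectra)) {
    stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
    wavelengths <- spectra[[1]]$wavelengths
    spectra <- do.call(rbind, lapply(spectra, `[[`, "values"))
  }
  M <- as.matrix(spectra)
  if (nrow(M) < 3) stop("PCA biplot needs at least 3 spectra", call. = FALSE)
  if (is.null(wavelengths)) stop("wavelengths required", call. = FALSE)
  wavelengths <- wavelength_axis(wavelengths)
  stopifnot(length(wavelengths) == ncol(M))
  pr <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  k <- ncol(pr$rotation)
  loadings <- matrix(0, ncol(M), 2)
  scores <- matrix(0, nrow(M), 2)
  ev <- c(0, 0)
  take <- min(2L, k)
  loadings[, 1:take] <- pr$rotation[, 1:take]
  scores[, 1:take] <- pr$x[, 1:take]
  ev[1:take] <- pr$sdev[1:take]^2
  degenerate <- k < 2 || pr$sdev[2] < 1e-12 * max(pr$sdev[1], 1e-300)
  if (degenerate && k >= 2) {
    # keep the axis (orthonormality) but flag the component as meaningless
    loadings[, 2] <- pr$rotation[, 2]
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev,
                 wavelength_colors = wavelength_to_rgb(wavelengths),
                 wavelengths = wavelengths, degenerate = degenerate),
            class = "pca_biplot")
}

#' @export
print.pca_biplot <- function(x, ...) {
  cat(sprintf("<pca_biplot> %d spectra x %d wavelengths; var = (%.3g, %.3g)%s\n",
              nrow(x$scores), nrow(x$loadings),
              x$explained_variance[1], x$explained_variance[2],
              if (x$degenerate) " [rank-degenerate 2nd axis]" else ""))
  invisible(x)
}

#' @export
plot.pca_biplot <- function(x, ..., arrow_scale = NULL) {
  s <- x$scores
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(s)) / max(sqrt(rowSums(x$loadings^2)), 1e-12)
  }
  graphics::plot(s, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "PC1", ylab = "PC2", ...)
  graphics::arrows(0, 0, x$loadings[, 1] * arrow_scale, x$loadings[, 2] * arrow_scale,
                   col = x$wavelength_colors, length = 0.05)
  invisible(x)
}

#' Approximate display color of a wavelength
#'
#' Smooth visible-light approximation mapping 380-750 nm to hex RGB;
#' wavelengths outside the visible range clamp to its ends.
#'
#' @param nm Numeric vector of wavelengths in nm.
#' @return Character vector of hex colors.
#' @export
wavelength_to_rgb <- function(nm) {
  one <- function(w) {
    w <- min(max(w, 380), 750)
    if (w < 440)      rgbv <- c(-(w - 440) / 60, 0, 1)
    else if (w < 490) rgbv <- c(0, (w - 440) / 50, 1)
    else if (w < 510) rgbv <- c(0, 1, -(w - 510) / 20)
    else if (w < 580) rgbv <- c((w - 510) / 70, 1, 0)
    else if (w < 645) rgbv <- c(1, -(w - 645) / 65, 0)
    else              rgbv <- c(1, 0, 0)
    # intensity falloff near the range ends
    f <- if (w < 420) 0.3 + 0.7 * (w - 380) / 40 else if (w > 700) 0.3 + 0.7 * (750 - w) / 50 else 1
    grDevices::rgb(rgbv[1] * f, rgbv[2] * f, rgbv[3] * f)
  }
  vapply(as.numeric(nm), one, character(1))
}
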