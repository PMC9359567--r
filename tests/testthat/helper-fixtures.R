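# Fixtures built in code; no data files.

# a small deterministic cube with arbitrary (seeded) radiance values
random_cube <- function(seed = 1, w = 6, h = 5, S = 9, time_point = "T0",
                        mask = NULL, sample_id = "fix") {
  set.seed(seed)
  vals <- array(runif(h * w * S, 0.1, 2), c(h, w, S))
  if (is.null(mask)) {
    mask <- matrix(runif(h * w) < 0.7, h, w)
    mask[1, 1] <- TRUE  # guarantee nonempty
  }
  hsi_cube(vals, seq(400, 700, length.out = S), mask,
           sample_id = sample_id, time_point = time_point)
}

# a tiny full-mask time series (all four time points, same size)
tiny_series <- function(seed = 1, w = 5, h = 4, S = 6) {
  cubes <- lapply(seq_along(TIMEPOINTS), function(i) {
    random_cube(seed + i, w = w, h = h, S = S, time_point = TIMEPOINTS[i],
                mask = matrix(TRUE, h, w), sample_id = "tiny")
  })
  hsi_timeseries(cubes)
}

# brute-force per-pixel point-in-polygon oracle (sp backend, independent of
# the package's crossing-number rasterizer)
oracle_rasterize <- function(verts, w, h) {
  m <- matrix(FALSE, h, w)
  for (x in 0:(w - 1)) {
    for (y in 0:(h - 1)) {
      m[y + 1, x + 1] <- sp::point.in.polygon(x + 0.5, y + 0.5,
                                              verts[, 1], verts[, 2]) > 0
    }
  }
  m
}

# brute-force channel-wise aggregation oracle over an explicit pixel list
oracle_agg <- function(cube, px, method, normalized = FALSE) {
  S <- dim(cube$values)[3]
  rows <- t(vapply(seq_len(nrow(px)), function(i) {
    v <- cube$values[px$y[i] + 1, px$x[i] + 1, ]
    if (normalized) v <- v / sum(abs(v))
    v
  }, numeric(S)))
  out <- numeric(S)
  for (s in seq_len(S)) {
    col <- rows[, s]
    out[s] <- switch(method, mean = mean(col), max = max(col),
                     min = min(col), median = median(col))
  }
  out
}

# brute-force k-NN time-purity oracle on embedding coords
oracle_knn_purity <- function(coords, labels, k) {
  n <- nrow(coords)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, 2, byrow = TRUE))^2))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    frac[i] <- mean(labels[nb] == labels[i])
  }
  frac
}
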