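# Link and brush: cross-domain selection resolution and projection.

test_that("an image polygon selects rasterized-polygon-and-mask pixels of one time point", {
  ts <- tiny_series(61, w = 8, h = 6, S = 5)
  # rectangle over everything at T0
  all_rect <- rbind(c(-1, -1), c(9, -1), c(9, 7), c(-1, 7))
  sel <- select_in_image(ts, "T0", all_rect)
  expect_equal(nrow(sel$pixels), 48)
  expect_true(all(sel$pixels$time_point == "T0"))

  # a triangle matches the brute-force oracle intersected with the mask
  mask <- matrix(runif(48) < 0.6, 6, 8); mask[3, 3] <- TRUE
  cubes <- lapply(TIMEPOINTS, function(tp)
    random_cube(62, w = 8, h = 6, S = 5, time_point = tp, mask = mask,
                sample_id = "m"))
  ts2 <- hsi_timeseries(cubes)
  tri <- rbind(c(0.3, 0.2), c(7.6, 1.1), c(3.2, 5.7))
  sel2 <- select_in_image(ts2, "T1", tri)
  oracle <- oracle_rasterize(tri, 8, 6) & mask
  got <- matrix(FALSE, 6, 8)
  got[cbind(sel2$pixels$y + 1, sel2$pixels$x + 1)] <- TRUE
  expect_identical(got, unname(oracle))

  # polygon over background only -> empty selection with warning
  bg <- which(!mask)
  expect_gt(length(bg), 0)
  x0 <- (bg[1] - 1) %/% 6; y0 <- (bg[1] - 1) %% 6
  tiny_poly <- rbind(c(x0 + 0.3, y0 + 0.3), c(x0 + 0.7, y0 + 0.3), c(x0 + 0.5, y0 + 0.7))
  expect_warning(sel3 <- select_in_image(ts2, "T0", tiny_poly), "empty")
  expect_length(sel3, 0)
})

test_that("embedding selections honor shape membership and visible time points", {
  ts <- tiny_series(63, w = 5, h = 4, S = 6)
  e <- compute_embedding(ts, "umap", "euclidean", seed = 3,
                         params = list(n_neighbors = 8))
  box <- list(type = "rect",
              xmin = min(e$coords[, 1]) - 1, xmax = max(e$coords[, 1]) + 1,
              ymin = min(e$coords[, 2]) - 1, ymax = max(e$coords[, 2]) + 1)
  sel <- select_in_embedding(e, box, visible = "T0")
  t0 <- e$index[e$index$time_point == "T0", ]
  expect_equal(nrow(sel$pixels), nrow(t0))
  expect_true(all(sel$pixels$time_point == "T0"))

  # single point -> singleton selection (single-pixel spectrum inspection)
  pt <- e$coords[17, ]
  eps <- 1e-9
  tiny <- list(type = "rect", xmin = pt[1] - eps, xmax = pt[1] + eps,
               ymin = pt[2] - eps, ymax = pt[2] + eps)
  sel1 <- select_in_embedding(e, tiny)
  expect_equal(nrow(sel1$pixels), 1)
  expect_equal(sel1$pixels$x, e$index$x[17])

  # random lasso polygon matches brute-force membership over all rows
  set.seed(64)
  ctr <- colMeans(e$coords)
  rad <- 0.6 * max(abs(sweep(e$coords, 2, ctr)))
  ang <- seq(0, 2 * pi, length.out = 8)[-8]
  lasso <- cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang))
  sel2 <- select_in_embedding(e, lasso)
  inside <- vapply(seq_len(nrow(e$coords)), function(i) {
    sp::point.in.polygon(e$coords[i, 1], e$coords[i, 2], lasso[, 1], lasso[, 2]) > 0
  }, logical(1))
  got <- rep(FALSE, nrow(e$coords))
  got[selection_rows(sel2, e)] <- TRUE
  expect_identical(got, inside)
})

test_that("projection produces per-time-point masks, spectra and embedding rows", {
  ts <- tiny_series(65, w = 5, h = 4, S = 6)
  e <- compute_embedding(ts, "umap", "euclidean", seed = 9,
                         params = list(n_neighbors = 8))
  all_rect <- rbind(c(-1, -1), c(6, -1), c(6, 5), c(-1, 5))
  sel <- select_in_image(ts, "T0", all_rect)
  pr <- project(sel, ts, e)
  expect_true(all(pr$masks[["T0"]]))
  for (tp in c("T0.5", "T1", "T2")) expect_false(any(pr$masks[[tp]]))
  expect_length(pr$spectra, 1)
  # spectra equal brute-force means over the selection
  px <- sel$pixels[, c("x", "y")]
  expect_equal(pr$spectra[["T0"]]$values, oracle_agg(ts$cubes$T0, px, "mean"),
               tolerance = 1e-12)
  # round trip image -> embedding rows -> selection -> identical pixel set
  sel_back <- selection(e$index[pr$embedding_rows, ], provenance = "composite")
  expect_equal(sel_back$pixels, sel$pixels, ignore_attr = TRUE)
  expect_error(project(selection(NULL), ts, e), "empty selection")
})

test_that("embedding -> image -> embedding round trip is idempotent", {
  ts <- tiny_series(67, w = 5, h = 4, S = 6)
  e <- compute_embedding(ts, "umap", "euclidean", seed = 2,
                         params = list(n_neighbors = 8))
  box <- list(type = "rect", xmin = median(e$coords[, 1]), xmax = max(e$coords[, 1]),
              ymin = min(e$coords[, 2]), ymax = max(e$coords[, 2]))
  sel <- select_in_embedding(e, box)
  rows1 <- selection_rows(sel, e)
  expect_gt(length(rows1), 0)
  pr <- project(sel, ts, e)
  # rebuild the selection from the projected masks
  px <- do.call(rbind, lapply(names(pr$masks), function(tp) {
    idx <- which(pr$masks[[tp]]) - 1L
    if (length(idx) == 0) return(NULL)
    data.frame(time_point = tp, x = idx %/% nrow(pr$masks[[tp]]),
               y = idx %% nrow(pr$masks[[tp]]))
  }))
  sel2 <- selection(px, provenance = "composite")
  expect_identical(selection_rows(sel2, e), rows1)
  expect_equal(sel2$pixels, sel$pixels, ignore_attr = TRUE)
})

test_that("hiding time points filters projections reversibly", {
  ts <- tiny_series(69, w = 5, h = 4, S = 6)
  all_px <- do.call(rbind, lapply(TIMEPOINTS, function(tp)
    data.frame(time_point = tp, x = c(0, 1), y = c(0, 0))))
  sel <- selection(all_px)
  pr_all <- project(sel, ts)
  expect_setequal(names(pr_all$spectra), TIMEPOINTS)

  hid <- set_visible_timepoints(sel, c("T0", "T2"))
  pr_hid <- project(hid, ts)
  expect_setequal(names(pr_hid$spectra), c("T0", "T2"))
  expect_equal(nrow(hid$pixels), nrow(sel$pixels))  # pixel set untouched

  # un-hide restores the original projections
  back <- set_visible_timepoints(hid, TIMEPOINTS)
  pr_back <- project(back, ts)
  expect_equal(pr_back$spectra, pr_all$spectra)
  expect_error(set_visible_timepoints(sel, character(0)), "nonempty")

  # hiding a time point with no selected pixels changes nothing visible
  sel_t0 <- selection(data.frame(time_point = "T0", x = 0:1, y = 0))
  pr1 <- project(sel_t0, ts)
  pr2 <- project(set_visible_timepoints(sel_t0, c("T0", "T1")), ts)
  expect_equal(pr1$spectra[["T0"]], pr2$spectra[["T0"]])
})

test_that("selection algebra is well-defined and associative", {
  mk <- function(tp, xs) selection(data.frame(time_point = tp, x = xs, y = 0))
  a <- mk("T0", 0:3); b <- mk("T0", 2:5); c <- mk("T1", 0:1)
  u <- selection_union(a, b)
  expect_equal(nrow(u$pixels), 6)
  expect_identical(u$provenance, "composite")
  expect_equal(nrow(selection_intersect(a, b)$pixels), 2)
  expect_equal(nrow(selection_subtract(a, b)$pixels), 2)
  # associativity of union on the pixel sets
  lhs <- selection_union(selection_union(a, b), c)
  rhs <- selection_union(a, selection_union(b, c))
  expect_equal(lhs$pixels, rhs$pixels, ignore_attr = TRUE)
  # each projected mask marks only its own time point's refs (refs are disjoint)
  ts <- tiny_series(71, w = 6, h = 4, S = 6)
  pr <- project(selection_union(a, c), ts)
  expect_equal(sum(pr$masks[["T0"]]), 4)
  expect_equal(sum(pr$masks[["T1"]]), 2)
  expect_false(any(pr$masks[["T0.5"]]) || any(pr$masks[["T2"]]))
})
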