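# Change quantification: crossings, band shift, exclusive-region detection,
# rating aggregation.

test_that("crossing wavelengths are localized by linear interpolation", {
  wl3 <- c(400, 500, 600)
  a <- spectrum(c(1, 2, 3), wl3); b <- spectrum(c(3, 2, 1), wl3)
  expect_equal(crossing_wavelengths(a, b), 500)

  # d goes -1 -> +2 between 400 and 500: crossing at 400 + 100 * 1/3
  a2 <- spectrum(c(0, 2), c(400, 500)); b2 <- spectrum(c(1, 0), c(400, 500))
  expect_equal(crossing_wavelengths(a2, b2), 400 + 100 / 3, tolerance = 1e-9)

  expect_equal(crossing_wavelengths(a, a), numeric(0))
  # symmetry in the arguments
  set.seed(81)
  for (i in 1:5) {
    u <- spectrum(runif(10), seq(400, 700, length.out = 10))
    v <- spectrum(runif(10), seq(400, 700, length.out = 10))
    expect_equal(crossing_wavelengths(u, v), crossing_wavelengths(v, u))
  }
})

test_that("zero plateaus report boundary wavelengths once", {
  wl <- seq(400, 800, by = 100)
  a <- spectrum(c(1, 2, 2, 2, 1), wl)
  b <- spectrum(c(2, 2, 2, 2, 0), wl)  # d = -1, 0, 0, 0, 1
  expect_equal(crossing_wavelengths(a, b), c(500, 700))
  a3 <- spectrum(c(1, 2, 1), c(400, 500, 600))
  b3 <- spectrum(c(2, 2, 0), c(400, 500, 600))  # single zero channel
  expect_equal(crossing_wavelengths(a3, b3), 500)
})

test_that("band-shift index implements the red-minus-blue gain, antisymmetrically", {
  wl <- seq(400, 700, length.out = 31)
  a <- spectrum(rep(1 / 31, 31), wl)
  bvals <- a$values
  bvals[wl >= 600 & wl <= 700] <- bvals[wl >= 600 & wl <= 700] + 0.1
  bvals[wl >= 400 & wl <= 500] <- bvals[wl >= 400 & wl <= 500] - 0.1
  b <- spectrum(bvals, wl)
  expect_equal(band_shift_index(a, b), 0.2, tolerance = 1e-12)
  expect_equal(band_shift_index(a, a), 0)
  expect_equal(band_shift_index(b, a), -band_shift_index(a, b))
  expect_error(band_shift_index(a, b, blue_band = c(400, 650)), "disjoint")
  expect_error(band_shift_index(a, b, blue_band = c(401, 402)), "no channels")
})

test_that("exclusive-region detection separates clusters and rejects mixtures", {
  # two well-separated clusters, one per time point -> everything detected
  set.seed(83)
  n <- 60
  coords <- rbind(matrix(rnorm(n, 0, 0.2), n / 2, 2),
                  matrix(rnorm(n, 10, 0.2), n / 2, 2))
  idx <- data.frame(time_point = tp_factor(rep(c("T0", "T2"), each = n / 2)),
                    x = seq_len(n), y = 0L)
  e <- structure(list(coords = coords, index = idx, method = "umap",
                      metric = "euclidean", seed = 1L, params = list(),
                      sample_id = "s"), class = "hsi_embedding")
  det <- detect_timepoint_exclusive_regions(e, "T0", "T2", k = 5, purity = 0.9)
  expect_equal(nrow(det$pixels), n)

  # perfectly interleaved lattice -> purity ~0.5, nothing at 0.9
  g <- expand.grid(x = 0:9, y = 0:9)
  lab <- (g$x + g$y) %% 2 == 0
  e2 <- structure(list(coords = as.matrix(g),
                       index = data.frame(time_point = tp_factor(ifelse(lab, "T0", "T2")),
                                          x = g$x, y = g$y),
                       method = "umap", metric = "euclidean", seed = 1L,
                       params = list(), sample_id = "s"),
                  class = "hsi_embedding")
  det2 <- detect_timepoint_exclusive_regions(e2, "T0", "T2", k = 4, purity = 0.9)
  expect_equal(nrow(det2$pixels), 0)

  expect_error(detect_timepoint_exclusive_regions(e, "T0", "T2", k = n),
               "k must satisfy")
  expect_error(detect_timepoint_exclusive_regions(e, "T0", "T0"), "differ")
})

test_that("detection membership equals brute-force k-NN purity on random points", {
  set.seed(85)
  n <- 300
  coords <- matrix(rnorm(2 * n), n, 2)
  labs <- sample(c("T0", "T2"), n, TRUE)
  e <- structure(list(coords = coords,
                      index = data.frame(time_point = tp_factor(labs),
                                         x = seq_len(n), y = 0L),
                      method = "umap", metric = "euclidean", seed = 1L,
                      params = list(), sample_id = "s"),
                 class = "hsi_embedding")
  for (pur in c(0.7, 0.9, 1.0)) {
    det <- detect_timepoint_exclusive_regions(e, "T0", "T2", k = 7, purity = pur)
    frac <- oracle_knn_purity(coords, labs, 7)
    expect_setequal(det$pixels$x, which(frac >= pur))
  }
  # monotonicity: purity = 1 result is a subset of lower-purity results
  d1 <- detect_timepoint_exclusive_regions(e, "T0", "T2", k = 7, purity = 1.0)
  d07 <- detect_timepoint_exclusive_regions(e, "T0", "T2", k = 7, purity = 0.7)
  expect_true(all(d1$pixels$x %in% d07$pixels$x))
})

test_that("average change rating is the arithmetic mean within [1, 5]", {
  expect_equal(average_change_rating(c(3, 4, 4)), 11 / 3, tolerance = 1e-9)
  expect_equal(average_change_rating(c(1, 1, 1)), 1)
  set.seed(87)
  for (i in 1:5) {
    r <- sample(1:5, sample(2:9, 1), TRUE)
    m <- average_change_rating(r)
    expect_true(m >= 1 && m <= 5)
    expect_true(m >= min(r) && m <= max(r))
  }
  expect_error(average_change_rating(integer(0)), "no ratings")
  expect_error(average_change_rating(c(2, 6)), "1..5")
})

# a small synthetic ratings table (3 observers x 2 samples x 3 comparisons)
synthetic_ratings <- function(offset_user3 = 0L) {
  grid <- expand.grid(sample_id = c("c0", "c1"), time_point = c("T0.5", "T1", "T2"),
                      stringsAsFactors = FALSE)
  base <- c(2, 3, 4, 1, 2, 2)
  do.call(rbind, lapply(1:3, function(u) {
    r <- base + if (u == 3) offset_user3 else 0L
    data.frame(user = paste0("u", u), sample_id = grid$sample_id,
               condition = "bentonite", concentration_mg_per_L = 100,
               time_point = grid$time_point, rating = pmin(pmax(r, 1), 5))
  }))
}

test_that("inter-observer SD: identical raters give 0, constant offsets give 0 pairwise", {
  tab <- synthetic_ratings()
  expect_equal(inter_observer_sd(tab, "pairwise"), 0)
  # two observers differing by a constant offset: pairwise differences are
  # constant, so their SD is 0
  tab2 <- synthetic_ratings(offset_user3 = 1L)
  two <- tab2[tab2$user %in% c("u1", "u3"), ]
  expect_equal(inter_observer_sd(two, "pairwise"), 0)
  # but the per-item formula sees the offset as spread
  expect_gt(inter_observer_sd(two, "per_item"), 0)
  one <- tab[tab$user == "u1", ]
  expect_error(inter_observer_sd(one), "2 observers")
})

test_that("inter-observer SD estimators match hand computation on a known table", {
  tab <- synthetic_ratings()
  # perturb specific cells so the answer is computable by hand
  tab$rating[tab$user == "u2" & tab$sample_id == "c0" & tab$time_point == "T1"] <- 5
  # u1 rates that item 4, so pairwise diffs over the 3 pairs x 6 items are one
  # -1 (u1-u2), one +1 (u2-u3) and sixteen 0s
  d <- c(-1, rep(0, 16), 1)
  expect_equal(inter_observer_sd(tab, "pairwise"), sd(d), tolerance = 1e-12)
  # per-item: one item has ratings (4, 5, 4), the other five agree exactly
  expect_equal(inter_observer_sd(tab, "per_item"),
               mean(c(sd(c(4, 5, 4)), rep(0, 5))), tolerance = 1e-12)
})

test_that("star glyph table cells equal the average change rating of their groups", {
  tab <- synthetic_ratings(offset_user3 = 1L)
  agg <- star_glyph_table(tab)
  expect_length(agg$glyphs, 1)
  m <- agg$glyphs[["bentonite_100mg"]]
  expect_equal(dim(m), c(2, 3))
  for (sid in rownames(m)) {
    for (tp in colnames(m)) {
      sub <- tab[tab$sample_id == sid & tab$time_point == tp, ]
      expect_equal(m[sid, tp], average_change_rating(sub$rating))
    }
  }
  expect_true(all(agg$table$r_hat >= 1 & agg$table$r_hat <= 5))
})

test_that("ratings CSV reader validates schema and values", {
  tab <- synthetic_ratings()
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read_ratings(f)
  expect_equal(nrow(back), nrow(tab))
  bad <- tab; bad$rating[1] <- 7
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_ratings(f), "1..5")
  write.csv(tab[, -1], f, row.names = FALSE)
  expect_error(read_ratings(f), "missing columns")
})
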