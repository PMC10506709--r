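test_that("window_config enforces odd widths and the studied range", {
  cfg <- window_config()
  expect_equal(cfg$width, 33L)
  expect_equal(cfg$flank, 16L)
  expect_error(window_config(32), "odd")
  expect_error(window_config(19), "21, 41")
  expect_equal(window_config(1, enforce_range = FALSE)$width, 1L)
})

test_that("extract_window equals direct index arithmetic with zero padding", {
  set.seed(10)
  L <- 100L; D <- 7L
  feats <- residue_features(matrix(rnorm(L * D), L, D), "p")
  for (w in seq(21L, 41L, 2L)) {
    cfg <- window_config(w)
    flank <- (w - 1L) %/% 2L
    for (center in c(1L, 2L, flank, flank + 1L, 50L, L - flank, L)) {
      win <- extract_window(feats, center, cfg)
      # oracle: assemble the window row by row
      oracle <- t(vapply((center - flank):(center + flank), function(i) {
        if (i >= 1L && i <= L) unclass(feats)[i, ] else rep(0, D)
      }, numeric(D)))
      expect_equal(win, oracle)
    }
  }
})

test_that("interior windows are exact slices and edge windows zero-pad", {
  set.seed(11)
  feats <- residue_features(matrix(rnorm(100 * 3), 100, 3), "p")
  cfg <- window_config(33)
  mid <- extract_window(feats, 50, cfg)
  expect_equal(mid, unclass(feats)[34:66, ])
  expect_false(any(rowSums(abs(mid)) == 0))

  edge <- extract_window(feats, 1, cfg)
  expect_equal(edge[1:16, ], matrix(0, 16, 3))
  expect_equal(edge[17, ], unclass(feats)[1, ])

  one <- extract_window(feats, 42, window_config(1, enforce_range = FALSE))
  expect_equal(one, unclass(feats)[42, , drop = FALSE])

  expect_error(extract_window(feats, 0, cfg), "center")
  expect_error(extract_window(feats, 101, cfg), "center")
})

test_that("build_window_dataset makes one ordered example per labeled residue", {
  ds <- tiny_corpus()
  feats <- one_hot_embed_all(ds$proteins)
  cfg <- window_config(5, enforce_range = FALSE)
  wd <- build_window_dataset(ds, feats, cfg)
  expect_equal(n_windows(wd), 6L)
  expect_equal(wd$width, 5L)
  expect_equal(wd$dim, 21L)
  # deterministic (protein_id, position) order
  expect_equal(wd$meta$protein_id, c("p1", "p1", "p1", "p2", "p2", "p2"))
  expect_equal(wd$meta$position, c(2L, 5L, 9L, 1L, 7L, 12L))
  expect_equal(wd$y, c(1L, 0L, 0L, 0L, 1L, 1L))

  # unknown labels are skipped
  ds2 <- ds
  ds2$annotations$label[2] <- NA
  expect_equal(n_windows(build_window_dataset(ds2, feats, cfg)), 5L)

  # shuffling annotation rows does not change the result
  set.seed(4)
  ds3 <- ds
  ds3$annotations <- ds3$annotations[sample.int(6), ]
  wd3 <- build_window_dataset(ds3, feats, cfg)
  expect_equal(wd3$X, wd$X)
  expect_equal(wd3$meta, wd$meta)

  expect_error(build_window_dataset(ds, feats["p1"], cfg), "p2")
})

test_that("padded rows are exactly zero and real rows match the source", {
  ds <- tiny_corpus()
  feats <- one_hot_embed_all(ds$proteins)
  cfg <- window_config(7, enforce_range = FALSE)
  wd <- build_window_dataset(ds, feats, cfg)
  for (i in seq_len(n_windows(wd))) {
    f <- unclass(feats[[wd$meta$protein_id[i]]])
    idx <- (wd$meta$position[i] - cfg$flank):(wd$meta$position[i] + cfg$flank)
    for (j in seq_along(idx)) {
      row <- wd$X[i, j, ]
      if (idx[j] < 1L || idx[j] > nrow(f)) {
        expect_identical(sum(abs(row)), 0)
      } else {
        expect_identical(row, unname(f[idx[j], ]))
      }
    }
  }
  # residues at distance >= flank from both ends have no padding at all
  interior <- wd$meta$position > cfg$flank &
    wd$meta$position <= nchar("ACDEFGHIKL") - cfg$flank
  stopifnot(any(interior))
})

test_that("flattening windows and slicing back reproduces every example", {
  wd <- separable_windows(n_per_class = 6L, width = 5L, dim = 3L)
  flat <- flatten_windows(wd)
  expect_equal(dim(flat), c(12L, 15L))
  back <- hotspotcnn:::unflatten_windows(flat, 5L, 3L)
  expect_equal(back, wd$X)
})

test_that("dense windows cover every residue of every protein", {
  ds <- tiny_corpus()
  feats <- one_hot_embed_all(ds$proteins)
  wd <- dense_windows(ds$proteins, feats, window_config(5, enforce_range = FALSE))
  expect_equal(n_windows(wd), sum(ds$proteins$length))
  expect_true(all(is.na(wd$y)))
})
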