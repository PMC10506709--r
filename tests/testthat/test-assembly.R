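test_that("split sizes follow round-to-nearest fifths", {
  wd <- separable_windows(n_per_class = 349L, width = 5L, dim = 2L)
  expect_equal(n_windows(wd), 698L)
  sp <- split_dataset(wd, seed = 7)
  expect_equal(n_windows(sp$test), 140L)        # round(698 / 5)
  expect_equal(n_windows(sp$validation), 112L)  # round(558 / 5)
  expect_equal(n_windows(sp$train), 446L)

  tiny <- separable_windows(n_per_class = 3L, width = 5L, dim = 2L)
  tiny <- window_subset(tiny, 1:5)
  sp5 <- split_dataset(tiny, seed = 1)
  expect_equal(n_windows(sp5$test), 1L)
  expect_equal(n_windows(sp5$validation), 1L)
  expect_equal(n_windows(sp5$train), 3L)

  expect_error(split_dataset(wd, test_fraction = 1.2), "between 0 and 1")
})

test_that("split partitions are disjoint, exhaustive and seed-deterministic", {
  wd <- separable_windows(n_per_class = 60L, width = 5L, dim = 2L)
  sp <- split_dataset(wd, seed = 5)
  keys <- function(x) paste(x$meta$protein_id, x$meta$position)
  all_keys <- c(keys(sp$train), keys(sp$validation), keys(sp$test))
  expect_equal(sort(all_keys), sort(keys(wd)))
  expect_equal(anyDuplicated(all_keys), 0L)

  sp2 <- split_dataset(wd, seed = 5)
  expect_identical(sp2$test$meta, sp$test$meta)
  sp3 <- split_dataset(wd, seed = 6)
  expect_false(identical(sp3$test$meta, sp$test$meta))

  strat <- split_dataset(wd, seed = 5, stratify = TRUE)
  expect_equal(mean(strat$test$y), 0.5)
})

test_that("split manifests round-trip and are byte-stable under a seed", {
  wd <- separable_windows(n_per_class = 20L, width = 5L, dim = 2L)
  sp <- split_dataset(wd, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(sp, p1)
  write_split_manifest(split_dataset(wd, seed = 11), p2)
  expect_identical(readLines(p1), readLines(p2))

  mf <- read_split_manifest(p1)
  expect_equal(mf$seed, 11L)
  expect_equal(nrow(mf$assignments), 40L)
  expect_equal(sum(mf$assignments$partition == "test"), n_windows(sp$test))
})

test_that("interval subsampling strides, truncates and stays disjoint", {
  items <- 0:9
  expect_equal(interval_subsample(items, 3, 0), c(0L, 3L, 6L, 9L))
  expect_equal(interval_subsample(items, 3, 0, subset_size = 3), c(0L, 3L, 6L))
  expect_equal(interval_subsample(items, 3, 2), c(2L, 5L, 8L))
  expect_error(interval_subsample(items, 3, 3), "offset")
  expect_error(interval_subsample(items, 3, 0, subset_size = 10), "yields")

  # five stride-63 subsets of 349 from a 22244-item pool: disjoint union 1745
  pool <- seq_len(22244L)
  subsets <- lapply(0:4, function(o) {
    interval_subsample(pool, 63L, o, subset_size = 349L)
  })
  expect_true(all(lengths(subsets) == 349L))
  expect_equal(length(unique(unlist(subsets))), 1745L)
})

test_that("SMOTE endpoints reproduce the interpolation formula", {
  cloud <- generate_feature_cloud(n_minority = 30L, dim = 4L, seed = 3)
  minority <- cloud$minority
  at_old <- smote_generate(minority, n_new = 10L, k = 5L, seed = 9, r = 0)
  expect_true(all(apply(at_old, 1, function(row) {
    any(apply(minority, 1, function(m) isTRUE(all.equal(m, row))))
  })))
  at_n <- smote_generate(minority, n_new = 10L, k = 5L, seed = 9, r = 1)
  expect_true(all(apply(at_n, 1, function(row) {
    any(apply(minority, 1, function(m) isTRUE(all.equal(m, row))))
  })))
  # r = 0 and r = 1 with the same seed pick the same (X_old, X_n) pairs,
  # so they differ unless the pair coincides
  expect_false(identical(at_old, at_n))
})

test_that("every SMOTE sample lies on a minority-to-neighbor segment", {
  cloud <- generate_feature_cloud(n_minority = 60L, dim = 6L, seed = 13)
  minority <- cloud$minority
  k <- 5L
  synth <- smote_generate(minority, n_new = 40L, k = k, seed = 21)
  d <- as.matrix(dist(minority))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  on_segment <- vapply(seq_len(nrow(synth)), function(s) {
    new <- synth[s, ]
    any(vapply(seq_len(nrow(minority)), function(i) {
      any(vapply(nn[i, ], function(j) {
        a <- sqrt(sum((new - minority[i, ])^2))
        b <- sqrt(sum((minority[j, ] - new)^2))
        ab <- sqrt(sum((minority[j, ] - minority[i, ])^2))
        abs(a + b - ab) < 1e-8
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
})

test_that("SMOTE validates inputs and is deterministic under seed", {
  minority <- matrix(rnorm(40), 10, 4)
  expect_error(smote_generate(minority[1:5, ], 3, k = 5), "minority samples")
  expect_error(smote_generate(minority, -1), "nonnegative")
  expect_equal(nrow(smote_generate(minority, 0)), 0L)
  s1 <- smote_generate(minority, 8, seed = 2)
  s2 <- smote_generate(minority, 8, seed = 2)
  expect_identical(s1, s2)
})

test_that("class weights are balanced inverse frequencies", {
  cw <- compute_class_weights(rep(c(0L, 1L), each = 30L))
  expect_equal(cw$weight, c(1, 1))

  cw2 <- compute_class_weights(c(rep(0L, 100L), rep(1L, 25L)))
  expect_equal(cw2$weight[cw2$class == 0L], 0.625)
  expect_equal(cw2$weight[cw2$class == 1L], 2.5)
  # weighted class totals agree
  expect_equal(prod(cw2$n[1] * cw2$weight[1]),
               prod(cw2$n[2] * cw2$weight[2]))
  expect_error(compute_class_weights(rep(1L, 10L)), "Both classes")
})

test_that("assemble_training_set balances classes and guards leakage", {
  wd <- separable_windows(n_per_class = 12L, width = 5L, dim = 3L)
  train <- window_subset(wd, c(1:8, 13:18))  # 8 pos, 6 neg
  extra <- window_subset(wd, 19:24)          # 6 more neg
  out <- assemble_training_set(train, extra, smote_k = 3L, seed = 4)
  expect_equal(sum(out$y == 1L), sum(out$y == 0L))
  expect_equal(n_windows(out), 24L)  # 12 neg total, balanced
  expect_equal(sum(out$meta$protein_id == ".smote"), 4L)

  # already balanced: identity up to shuffling
  bal <- window_subset(wd, c(1:6, 13:18))
  out2 <- assemble_training_set(bal, seed = 4)
  expect_equal(n_windows(out2), 12L)
  expect_equal(sum(out2$meta$protein_id == ".smote"), 0L)

  # more positives than negatives cannot be fixed by SMOTE
  lop <- window_subset(wd, c(1:10, 13:14))
  expect_error(assemble_training_set(lop, seed = 1), "cannot remove")

  # leakage guard
  expect_error(
    assemble_training_set(train, extra, smote_k = 3L, seed = 4,
                          forbid = extra$meta[1, ]),
    "held-out"
  )
})

test_that("training assembly is seed-deterministic", {
  wd <- separable_windows(n_per_class = 15L, width = 5L, dim = 3L)
  train <- window_subset(wd, c(1:8, 16:27))
  a <- assemble_training_set(train, smote_k = 4L, seed = 8)
  b <- assemble_training_set(train, smote_k = 4L, seed = 8)
  expect_identical(a$X, b$X)
  expect_identical(a$meta, b$meta)
})
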