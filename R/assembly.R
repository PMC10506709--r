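# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# round half away from zero (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Split examples into train / validation / test partitions
#'
#' The test set takes `test_fraction` of all examples (rounded to the
#' nearest integer, half away from zero) and the validation set takes
#' `val_fraction` of the remainder; 698 examples at the default fifths give
#' a 140-example test set and a 112-example validation set. Selection is
#' uniform at random under `seed`; partitions are disjoint and exhaustive.
#'
#' @param wd A `window_dataset`.
#' @param test_fraction Fraction of all examples held out for testing
#'   (default 1/5).
#' @param val_fraction Fraction of the post-test remainder held out for
#'   validation (default 1/5).
#' @param seed Integer seed controlling the random assignment.
#' @param stratify Sample each class separately so partition class ratios
#'   match the corpus (default `FALSE`: plain uniform sampling).
#' @return An object of class `dataset_split`: a list with `window_dataset`
#'   elements `train`, `validation`, `test`, plus the `seed`.
#' @export
split_dataset <- function(wd, test_fraction = 0.2, val_fraction = 0.2,
                          seed = 1L, stratify = FALSE) {
  stopifnot(inherits(wd, "window_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction <= 0 || val_fraction >= 1) {
    abort("Fractions must lie strictly between 0 and 1.")
  }
  N <- n_windows(wd)
  if (N < 3L) abort("Need at least 3 examples to split.")

  assign_one <- function(idx) {
    n <- length(idx)
    n_test <- round_half_up(n * test_fraction)
    n_val <- round_half_up((n - n_test) * val_fraction)
    perm <- idx[sample.int(n)]
    list(
      test = perm[seq_len(n_test)],
      validation = perm[n_test + seq_len(n_val)],
      train = perm[-seq_len(n_test + n_val)]
    )
  }

  parts <- with_seed(seed, {
    if (stratify) {
      by_class <- split(seq_len(N), wd$y)
      merged <- lapply(by_class, assign_one)
      list(
        test = unlist(lapply(merged, `[[`, "test"), use.names = FALSE),
        validation = unlist(lapply(merged, `[[`, "validation"), use.names = FALSE),
        train = unlist(lapply(merged, `[[`, "train"), use.names = FALSE)
      )
    } else {
      assign_one(seq_len(N))
    }
  })

  structure(
    list(
      train = window_subset(wd, sort(parts$train)),
      validation = window_subset(wd, sort(parts$validation)),
      test = window_subset(wd, sort(parts$test)),
      seed = as.integer(seed)
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "<dataset_split> train %d / validation %d / test %d (seed %d)\n",
    n_windows(x$train), n_windows(x$validation), n_windows(x$test), x$seed
  ))
  invisible(x)
}

#' Write a split manifest
#'
#' Records every example's partition as TSV (`protein_id`, `position`,
#' `partition`) with the seed in a comment header, so a run can be exactly
#' reconstructed.
#'
#' @param split A `dataset_split`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  rows <- dplyr::bind_rows(
    dplyr::mutate(split$train$meta, partition = "train"),
    dplyr::mutate(split$validation$meta, partition = "validation"),
    dplyr::mutate(split$test$meta, partition = "test")
  )
  writeLines(c(sprintf("# seed: %d", split$seed),
               "protein_id\tposition\tpartition"), path)
  readr::write_tsv(rows, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a split manifest
#'
#' @param path Manifest TSV written by [write_split_manifest()].
#' @return A list with `seed` and `assignments` (tibble `protein_id`,
#'   `position`, `partition`).
#' @export
read_split_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seed_line <- grep("^# seed:", lines, value = TRUE)
  seed <- if (length(seed_line)) as.integer(sub("^# seed:\\s*", "", seed_line[1])) else NA_integer_
  tab <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           position = readr::col_integer(),
                           partition = readr::col_character()
                         ), progress = FALSE)
  list(seed = seed, assignments = tab)
}

#' Select every interval-th item from an ordered pool
#'
#' Deterministic stride sampling of the majority class: starting `offset`
#' items in (0-based), every `interval`-th item is taken. Subsets at distinct
#' offsets are pairwise disjoint; with `subset_size` the result is truncated
#' to its first `subset_size` elements.
#'
#' @param items A vector, data frame, or `window_dataset`, already in a
#'   fixed documented order (canonically protein id, then position).
#' @param interval Positive integer stride (e.g. 63 for a 1:63-imbalanced
#'   corpus).
#' @param offset 0-based start offset, `0 <= offset < interval`.
#' @param subset_size Optional truncation target; an error if the stride
#'   yields fewer items.
#' @return The selected items, same type as `items`.
#' @export
interval_subsample <- function(items, interval, offset = 0L, subset_size = NULL) {
  interval <- as.integer(interval)
  offset <- as.integer(offset)
  if (interval < 1L) abort("`interval` must be a positive integer.")
  if (offset < 0L || offset >= interval) {
    abort(sprintf("`offset` must satisfy 0 <= offset < %d", interval))
  }
  n <- if (inherits(items, "window_dataset")) n_windows(items)
       else if (is.data.frame(items)) nrow(items)
       else length(items)
  idx <- seq.int(offset + 1L, n, by = interval)
  if (!is.null(subset_size)) {
    if (subset_size > length(idx)) {
      abort(sprintf(
        "subset_size %d exceeds the %d items this stride yields",
        subset_size, length(idx)
      ))
    }
    idx <- idx[seq_len(subset_size)]
  }
  if (inherits(items, "window_dataset")) window_subset(items, idx)
  else if (is.data.frame(items)) items[idx, , drop = FALSE]
  else items[idx]
}

#' Generate synthetic minority samples by SMOTE interpolation
#'
#' Each synthetic sample is `X_old + r * (X_n - X_old)`: a uniformly chosen
#' minority point `X_old`, a uniformly chosen member `X_n` of its `k`
#' nearest minority neighbors under Euclidean distance (itself excluded),
#' and `r` uniform on the open interval (0, 1). Synthetic points therefore
#' lie on segments between minority points, inside the minority convex hull.
#'
#' @param minority M x D numeric matrix of minority-class samples (M > k).
#' @param n_new Number of synthetic rows to generate.
#' @param k Number of nearest neighbors considered (default 5, the
#'   original SMOTE setting).
#' @param seed Integer seed; the output is deterministic under it.
#' @param r Test hook: fixed interpolation coefficient(s) in \[0, 1\]
#'   replacing the random draw (`r = 0` reproduces `X_old`, `r = 1`
#'   reproduces `X_n`).
#' @return An `n_new` x D numeric matrix.
#' @export
smote_generate <- function(minority, n_new, k = 5L, seed = 1L, r = NULL) {
  minority <- as.matrix(minority)
  M <- nrow(minority)
  if (n_new < 0L) abort("`n_new` must be nonnegative.")
  if (M <= k) {
    abort(sprintf("Need more minority samples (%d) than neighbors k = %d", M, k))
  }
  if (n_new == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = ncol(minority)))
  }
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  # k nearest neighbor indices per row (stable order on ties)
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))

  with_seed(seed, {
    old_i <- sample.int(M, n_new, replace = TRUE)
    nb_j <- sample.int(k, n_new, replace = TRUE)
    rr <- if (is.null(r)) runif(n_new) else rep_len(r, n_new)
    if (any(rr < 0 | rr > 1)) abort("`r` must lie in [0, 1].")
    x_old <- minority[old_i, , drop = FALSE]
    x_n <- minority[nn[cbind(old_i, nb_j)], , drop = FALSE]
    x_old + rr * (x_n - x_old)
  })
}

#' Balanced inverse-frequency class weights
#'
#' The alternative to SMOTE for imbalanced training: each class receives
#' weight `N / (2 * N_c)`, so the minority class weighs more than 1 and the
#' weighted totals of the two classes are equal.
#'
#' @param y Integer/logical vector of binary labels (1 = hotspot).
#' @return A tibble with columns `class` (0/1), `n` and `weight`.
#' @export
compute_class_weights <- function(y) {
  y <- as.integer(y)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L) abort("Both classes must be present.")
  N <- n0 + n1
  tibble(class = c(0L, 1L), n = c(n0, n1), weight = N / (2 * c(n0, n1)))
}

#' Assemble a balanced SMOTE training set
#'
#' Combines the training partition with extra interval-sampled negatives,
#' then synthesizes exactly enough minority (hotspot) windows by
#' [smote_generate()] on the flattened training positives to balance the
#' classes, and shuffles the result. With the published corpus composition
#' (232 training hotspots, 214 training non-hotspots, 4 extra stride-63
#' subsets of 349 negatives) this synthesizes 1378 windows for a 3220-example
#' balanced training set.
#'
#' @param train `window_dataset`: the (labeled) training partition.
#' @param extra_neg Optional `window_dataset` of additional negatives (all
#'   labels 0), e.g. stride subsets via [interval_subsample()].
#' @param smote_k Neighbors used by SMOTE (default 5).
#' @param seed Integer seed for SMOTE draws and the final shuffle.
#' @param forbid Optional meta tibble (`protein_id`, `position`) of
#'   validation/test examples; assembly aborts if any appears in the inputs
#'   (leakage guard).
#' @return A balanced, shuffled `window_dataset`; synthetic windows carry
#'   `protein_id = ".smote"` in `meta`.
#' @export
assemble_training_set <- function(train, extra_neg = NULL, smote_k = 5L,
                                  seed = 1L, forbid = NULL) {
  stopifnot(inherits(train, "window_dataset"))
  if (!is.null(forbid)) {
    inputs <- dplyr::bind_rows(
      train$meta, if (!is.null(extra_neg)) extra_neg$meta
    )
    leaked <- dplyr::inner_join(inputs, forbid,
                                by = c("protein_id", "position"))
    if (nrow(leaked) > 0L) {
      abort(sprintf(
        "%d training example(s) also appear in the held-out partitions",
        nrow(leaked)
      ))
    }
  }
  if (!is.null(extra_neg)) {
    if (any(extra_neg$y != 0L)) abort("`extra_neg` must contain only negatives.")
  }

  pos <- window_subset(train, which(train$y == 1L))
  neg <- window_subset(train, which(train$y == 0L))
  if (!is.null(extra_neg) && n_windows(extra_neg) > 0L) {
    neg <- window_bind(neg, extra_neg)
  }
  n_new <- n_windows(neg) - n_windows(pos)
  if (n_new < 0L) {
    abort(sprintf(
      "More positives (%d) than negatives (%d): SMOTE cannot remove samples",
      n_windows(pos), n_windows(neg)
    ))
  }

  if (n_new > 0L) {
    synth <- smote_generate(flatten_windows(pos), n_new, k = smote_k,
                            seed = seed)
    synth_wd <- new_window_dataset(
      unflatten_windows(synth, train$width, train$dim),
      rep(1L, n_new),
      tibble(protein_id = ".smote", position = seq_len(n_new)),
      train$width, train$dim
    )
    out <- window_bind(pos, synth_wd, neg)
  } else {
    out <- window_bind(pos, neg)
  }
  with_seed(seed + 1L, window_subset(out, sample.int(n_windows(out))))
}
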