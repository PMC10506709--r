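#' Prepare balanced training data from a labeled corpus
#'
#' Runs the dataset-construction recipe end to end: order the labeled
#' annotations, carve a class-balanced working set out of the imbalanced
#' corpus (all hotspots plus one stride-`interval` subset of non-hotspots of
#' equal size), split it into train/validation/test fifths, draw
#' `n_extra_subsets` further disjoint stride subsets of negatives for
#' training only, and balance the training classes either by SMOTE synthesis
#' of hotspot windows or by inverse-frequency class weights.
#'
#' Windows are built only for annotations that enter a partition, so the
#' full negative pool is never featurized.
#'
#' @param ds A [hotspot_dataset()].
#' @param features Named list of `residue_features` (e.g.
#'   [one_hot_embed_all()]).
#' @param width Sliding-window width (default 33).
#' @param interval Stride between sampled negatives; default
#'   `floor(n_non_hotspot / n_hotspot)` (the corpus imbalance).
#' @param n_extra_subsets Extra stride subsets of negatives added to
#'   training (default 4; offsets 1..n after the offset-0 working subset).
#' @param subset_size Negatives per stride subset (default: the hotspot
#'   count, so the working set is balanced).
#' @param test_fraction,val_fraction Split fractions (defaults 1/5 each, see
#'   [split_dataset()]).
#' @param balancing `"smote"` (synthesize minority windows) or
#'   `"class_weight"` (keep the imbalance, weight the loss).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param seed Integer seed driving the split, SMOTE and shuffling.
#' @return An object of class `hotspot_prep`: list with `split`
#'   (`dataset_split` of the working set), `training` (the balanced or
#'   weighted training `window_dataset`), `class_weights` (tibble, only for
#'   `balancing = "class_weight"`), `extra_negatives`, `interval`,
#'   `balancing` and `seed`.
#' @export
prepare_hotspot_run <- function(ds, features, width = 33L, interval = NULL,
                                n_extra_subsets = 4L, subset_size = NULL,
                                test_fraction = 0.2, val_fraction = 0.2,
                                balancing = c("smote", "class_weight"),
                                smote_k = 5L, seed = 1L) {
  balancing <- match.arg(balancing)
  stopifnot(inherits(ds, "hotspot_dataset"))
  cfg <- window_config(width, enforce_range = FALSE)

  ann <- ds$annotations[!is.na(ds$annotations$label), , drop = FALSE]
  ann <- ann[order(ann$protein_id, ann$position, method = "radix"), ,
             drop = FALSE]
  pos_ann <- ann[ann$label == "hotspot", , drop = FALSE]
  neg_ann <- ann[ann$label == "non_hotspot", , drop = FALSE]
  n_pos <- nrow(pos_ann); n_neg <- nrow(neg_ann)
  if (n_pos == 0L || n_neg == 0L) abort("Corpus must contain both classes.")

  if (is.null(interval)) interval <- max(1L, n_neg %/% n_pos)
  if (is.null(subset_size)) subset_size <- n_pos
  if (n_extra_subsets + 1L > interval) {
    abort(sprintf("Cannot draw %d disjoint subsets with stride %d",
                  n_extra_subsets + 1L, interval))
  }

  working_neg <- interval_subsample(neg_ann, interval, 0L, subset_size)
  extra_neg_ann <- if (n_extra_subsets > 0L) {
    dplyr::bind_rows(lapply(seq_len(n_extra_subsets), function(o) {
      interval_subsample(neg_ann, interval, o, subset_size)
    }))
  } else NULL

  subset_ds <- function(rows) {
    structure(list(proteins = ds$proteins, annotations = rows),
              class = "hotspot_dataset")
  }
  working <- build_window_dataset(
    subset_ds(dplyr::bind_rows(pos_ann, working_neg)), features, cfg
  )
  split <- split_dataset(working, test_fraction, val_fraction, seed = seed)

  extra_wd <- if (!is.null(extra_neg_ann)) {
    build_window_dataset(subset_ds(extra_neg_ann), features, cfg)
  } else NULL
  heldout <- dplyr::bind_rows(split$validation$meta, split$test$meta)

  if (balancing == "smote") {
    training <- assemble_training_set(split$train, extra_wd,
                                      smote_k = smote_k, seed = seed,
                                      forbid = heldout)
    class_weights <- NULL
  } else {
    leaked <- if (!is.null(extra_wd)) {
      dplyr::inner_join(extra_wd$meta, heldout,
                        by = c("protein_id", "position"))
    } else heldout[0, ]
    if (nrow(leaked)) abort("Extra negatives overlap the held-out partitions.")
    training <- if (is.null(extra_wd)) split$train else
      window_bind(split$train, extra_wd)
    training <- with_seed(seed + 1L,
                          window_subset(training, sample.int(n_windows(training))))
    class_weights <- compute_class_weights(training$y)
  }

  structure(
    list(split = split, training = training, class_weights = class_weights,
         extra_negatives = extra_wd, interval = as.integer(interval),
         balancing = balancing, seed = as.integer(seed), width = cfg$width),
    class = "hotspot_prep"
  )
}

#' @export
print.hotspot_prep <- function(x, ...) {
  cat(sprintf(
    "<hotspot_prep> %s balancing: training %d (%d pos / %d neg), validation %d, test %d\n",
    x$balancing, n_windows(x$training), sum(x$training$y == 1L),
    sum(x$training$y == 0L), n_windows(x$split$validation),
    n_windows(x$split$test)
  ))
  invisible(x)
}

#' Train and evaluate a prepared run
#'
#' Fits the CNN on the prepared training set (with class weights when the
#' preparation used them) and scores the validation and test partitions.
#'
#' @param prep A [prepare_hotspot_run()] result.
#' @param model_config A [cnn_config()].
#' @param threshold Decision threshold for the metric report (default 0.5).
#' @param verbose Print per-epoch progress.
#' @return A list with `fit` (`cnn1d_fit`) and `metrics` (tibble with a
#'   `set` column for validation and test rows).
#' @export
fit_hotspot_cnn <- function(prep, model_config = cnn_config(),
                            threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(prep, "hotspot_prep"))
  model <- build_cnn(model_config, prep$training$width, prep$training$dim)
  fit <- train_cnn(model, prep$training, prep$split$validation,
                   class_weights = prep$class_weights, verbose = verbose)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(
      evaluate_predictions(prep$split$validation$y,
                           predict(fit, prep$split$validation)$score,
                           threshold),
      set = "validation", .before = 1L
    ),
    dplyr::mutate(
      evaluate_predictions(prep$split$test$y,
                           predict(fit, prep$split$test)$score,
                           threshold),
      set = "test", .before = 1L
    )
  )
  list(fit = fit, metrics = metrics)
}

#' Sweep sliding-window widths
#'
#' Re-prepares, re-trains and re-evaluates the pipeline at each width,
#' mirroring the window-length experiment: performance should peak at an
#' intermediate width and degrade when the window is too narrow to contain
#' the signal.
#'
#' @param ds,features,model_config,seed As in [prepare_hotspot_run()] /
#'   [fit_hotspot_cnn()].
#' @param widths Odd widths to try (default `seq(21, 41, 2)`).
#' @param ... Further arguments passed to [prepare_hotspot_run()].
#' @return A tibble of test metrics with a `width` column.
#' @export
width_sweep <- function(ds, features, widths = seq(21L, 41L, 2L),
                        model_config = cnn_config(), seed = 1L, ...) {
  purrr::map_dfr(widths, function(w) {
    prep <- prepare_hotspot_run(ds, features, width = w, seed = seed, ...)
    res <- fit_hotspot_cnn(prep, model_config)
    dplyr::mutate(res$metrics[res$metrics$set == "test", ],
                  width = as.integer(w), .before = 1L)
  })
}
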