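#' Sliding-window configuration
#'
#' Windows are odd-width stretches of residues centered on a target residue;
#' positions beyond the sequence ends are zero-padded. The widths studied for
#' this task are the odd numbers 21 to 41, with 33 the best-performing
#' default; `enforce_range = FALSE` relaxes the range check (any odd width
#' >= 1) for experimentation.
#'
#' @param width Odd window width in residues (default 33).
#' @param enforce_range Keep the width inside \[21, 41\] (default `TRUE`).
#' @return An object of class `window_config` with fields `width` and
#'   `flank` = `(width - 1) / 2`.
#' @export
window_config <- function(width = 33L, enforce_range = TRUE) {
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L || width %% 2L == 0L) {
    abort("`width` must be a single odd positive integer.")
  }
  if (enforce_range && (width < 21L || width > 41L)) {
    abort("`width` must be in [21, 41]; use enforce_range = FALSE to relax.")
  }
  structure(list(width = width, flank = (width - 1L) %/% 2L),
            class = "window_config")
}

#' Extract one zero-padded window from a feature matrix
#'
#' Returns rows `center - flank` ... `center + flank` of `features`; any row
#' index outside `1..L` contributes an all-zero row of the same feature
#' width, so the center residue always sits at row `flank + 1`.
#'
#' @param features A `residue_features` (or plain) L x D matrix.
#' @param center 1-based residue index of the window center.
#' @param config A [window_config()].
#' @return A `width x D` numeric matrix.
#' @export
extract_window <- function(features, center, config = window_config()) {
  L <- nrow(features)
  if (length(center) != 1L || is.na(center) || center < 1L || center > L) {
    abort(sprintf("`center` must be in [1, %d], got %s", L, format(center)))
  }
  idx <- (center - config$flank):(center + config$flank)
  out <- matrix(0, nrow = config$width, ncol = ncol(features))
  inb <- idx >= 1L & idx <= L
  out[inb, ] <- unclass(features)[idx[inb], , drop = FALSE]
  out
}

new_window_dataset <- function(X, y, meta, width, dim) {
  structure(
    list(X = X, y = y, meta = meta, width = as.integer(width),
         dim = as.integer(dim)),
    class = "window_dataset"
  )
}

#' Build the window dataset of a labeled corpus
#'
#' Creates one `width x D` example per labeled annotation (rows with an
#' unknown label are skipped), in deterministic order (protein id, then
#' position). Every annotated protein must have a feature matrix whose row
#' count equals its length, and all matrices must share one feature
#' dimension D.
#'
#' @param ds A [hotspot_dataset()].
#' @param features Named list of `residue_features`, keyed by protein id
#'   (e.g. from [one_hot_embed_all()]).
#' @param config A [window_config()].
#' @return A `window_dataset`: list with `X` (N x width x D array), `y`
#'   (integer 0/1, 1 = hotspot), `meta` (tibble of `protein_id`,
#'   `position`), `width`, `dim`.
#' @export
build_window_dataset <- function(ds, features, config = window_config()) {
  stopifnot(inherits(ds, "hotspot_dataset"))
  ann <- ds$annotations[!is.na(ds$annotations$label), , drop = FALSE]
  ids <- unique(ann$protein_id)
  missing <- setdiff(ids, names(features))
  if (length(missing)) {
    abort(sprintf("No feature matrix for protein(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dims <- vapply(features[ids], ncol, integer(1))
  if (length(ids) && length(unique(dims)) > 1L) {
    abort("Feature matrices have differing dimensions across proteins.")
  }
  plen <- setNames(ds$proteins$length, ds$proteins$id)
  nr <- vapply(features[ids], nrow, integer(1))
  bad <- ids[nr != plen[ids]]
  if (length(bad)) {
    abort(sprintf("Feature matrix length differs from protein length for: %s",
                  paste(bad, collapse = ", ")))
  }

  ord <- order(ann$protein_id, ann$position, method = "radix")
  ann <- ann[ord, , drop = FALSE]
  D <- if (length(ids)) unique(dims) else 0L
  n <- nrow(ann)
  X <- array(0, dim = c(n, config$width, D))
  for (i in seq_len(n)) {
    X[i, , ] <- extract_window(features[[ann$protein_id[i]]],
                               ann$position[i], config)
  }
  new_window_dataset(
    X, as.integer(ann$label == "hotspot"),
    tibble(protein_id = ann$protein_id, position = ann$position),
    config$width, D
  )
}

#' Dense windows over every residue of a corpus
#'
#' Prediction-time counterpart of [build_window_dataset()]: one window per
#' residue of every supplied protein, labels unknown (`NA`).
#'
#' @inheritParams build_window_dataset
#' @param proteins Tibble with columns `id` and `length` (e.g. from
#'   [read_fasta()]).
#' @return A `window_dataset` with `y` all `NA`.
#' @export
dense_windows <- function(proteins, features, config = window_config()) {
  ann <- tibble(
    protein_id = rep(proteins$id, proteins$length),
    position = unlist(lapply(proteins$length, seq_len), use.names = FALSE)
  )
  ds <- structure(
    list(
      proteins = proteins,
      annotations = tibble(
        protein_id = ann$protein_id, position = ann$position,
        wild_type = NA_character_, ddg = NA_real_, label = "non_hotspot"
      )
    ),
    class = "hotspot_dataset"
  )
  wd <- build_window_dataset(ds, features, config)
  wd$y <- rep(NA_integer_, n_windows(wd))
  wd
}

#' Number of examples in a window dataset
#' @param wd A `window_dataset`.
#' @return Integer count.
#' @export
n_windows <- function(wd) length(wd$y)

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf(
    "<window_dataset> %d examples of %d x %d (%d hotspot / %d non-hotspot)\n",
    n_windows(x), x$width, x$dim,
    sum(x$y == 1L, na.rm = TRUE), sum(x$y == 0L, na.rm = TRUE)
  ))
  invisible(x)
}

#' Subset a window dataset by example index
#'
#' @param wd A `window_dataset`.
#' @param idx Integer (or logical) example indices.
#' @return A `window_dataset` with the selected examples, in `idx` order.
#' @export
window_subset <- function(wd, idx) {
  new_window_dataset(
    wd$X[idx, , , drop = FALSE], wd$y[idx],
    wd$meta[idx, , drop = FALSE], wd$width, wd$dim
  )
}

#' Concatenate window datasets
#'
#' @param ... `window_dataset` objects with identical width and feature
#'   dimension.
#' @return The combined `window_dataset`.
#' @export
window_bind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, n_windows, integer(1)) > 0L]
  if (length(parts) == 0L) abort("Nothing to bind.")
  w <- unique(vapply(parts, `[[`, integer(1), "width"))
  d <- unique(vapply(parts, `[[`, integer(1), "dim"))
  if (length(w) != 1L || length(d) != 1L) {
    abort("Window datasets have mismatched shapes.")
  }
  ns <- vapply(parts, n_windows, integer(1))
  X <- array(0, dim = c(sum(ns), w, d))
  at <- 0L
  for (p in parts) {
    X[at + seq_len(n_windows(p)), , ] <- p$X
    at <- at + n_windows(p)
  }
  new_window_dataset(
    X,
    unlist(lapply(parts, `[[`, "y"), use.names = FALSE),
    dplyr::bind_rows(lapply(parts, `[[`, "meta")),
    w, d
  )
}

#' Flatten window examples to a design matrix
#'
#' Each `width x D` example becomes one row of `width * D` values (fixed
#' column order), the representation used for SMOTE interpolation.
#'
#' @param wd A `window_dataset`.
#' @return An N x (width * D) numeric matrix.
#' @export
flatten_windows <- function(wd) {
  matrix(wd$X, nrow = n_windows(wd), ncol = wd$width * wd$dim)
}

# inverse of flatten_windows for synthetic rows
unflatten_windows <- function(m, width, dim) {
  array(m, dim = c(nrow(m), width, dim))
}
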