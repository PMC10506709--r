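#' Per-residue feature matrices
#'
#' A residue feature matrix is an L x D numeric matrix, one row per residue
#' of a protein, tagged with the protein id. All embedders used on a corpus
#' must produce the same D.
#'
#' @param values Numeric L x D matrix with finite entries.
#' @param protein_id Protein identifier the matrix describes.
#' @return The matrix with class `residue_features` and a `protein_id`
#'   attribute.
#' @export
residue_features <- function(values, protein_id) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (nrow(values) < 1L) abort("Feature matrix must have at least one row.")
  if (!all(is.finite(values))) abort("Feature matrix contains non-finite entries.")
  attr(values, "protein_id") <- protein_id
  class(values) <- c("residue_features", "matrix", "array")
  values
}

#' @export
print.residue_features <- function(x, ...) {
  cat(sprintf("<residue_features> %s: %d residues x %d features\n",
              attr(x, "protein_id"), nrow(x), ncol(x)))
  invisible(x)
}

#' One-hot encode a protein sequence
#'
#' Each residue becomes a 21-dimensional indicator vector over the fixed
#' alphabet [aa_alphabet] (20 standard amino acids in alphabetical order,
#' catch-all `"X"` last).
#'
#' @param sequence Protein sequence (a single string), normalized to the
#'   21-symbol alphabet (see [normalize_sequence()]).
#' @param protein_id Identifier recorded on the result.
#' @return A `residue_features` matrix of shape L x 21; every row has
#'   exactly one 1.
#' @examples
#' one_hot_embed("ACDX", "toy")
#' @export
one_hot_embed <- function(sequence, protein_id = "protein") {
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, aa_alphabet)
  if (anyNA(idx)) {
    abort(sprintf("Symbol(s) outside the 21-letter alphabet: %s",
                  paste(unique(chars[is.na(idx)]), collapse = ", ")))
  }
  m <- matrix(0, nrow = length(chars), ncol = length(aa_alphabet),
              dimnames = list(NULL, aa_alphabet))
  m[cbind(seq_along(idx), idx)] <- 1
  residue_features(m, protein_id)
}

#' One-hot encode every protein of a corpus
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @return Named list of `residue_features` matrices, keyed by protein id.
#' @export
one_hot_embed_all <- function(proteins) {
  setNames(
    purrr::map2(proteins$sequence, proteins$id, one_hot_embed),
    proteins$id
  )
}

#' Write per-protein feature matrices to a keyed text container
#'
#' The container holds one block per protein: a `>protein_id` header line
#' followed by L whitespace-delimited rows of D values. A pretrained
#' language model's per-residue output (e.g. 4096-dimensional vectors) is
#' exchanged with the pipeline in this form.
#'
#' @param features Named list of matrices (or `residue_features`), keyed by
#'   protein id.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_store <- function(features, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(features)) {
    m <- features[[id]]
    writeLines(paste0(">", id), con)
    utils::write.table(unclass(m), con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Load a precomputed per-residue feature matrix
#'
#' Reads the matrix stored for `protein_id` in a keyed text container
#' written by [write_feature_store()]. A headerless file holding a single
#' whitespace-delimited matrix is accepted as a per-protein fallback (the
#' requested id is then attached to it).
#'
#' @param path Container file path.
#' @param protein_id Id to look up.
#' @param expected_length If given, the stored row count must equal this
#'   protein length.
#' @return A `residue_features` matrix.
#' @export
load_precomputed <- function(path, protein_id, expected_length = NULL) {
  if (!file.exists(path)) abort(sprintf("Feature store not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("Feature store is empty: %s", path))
  headers <- which(startsWith(lines, ">"))

  if (length(headers) == 0L) {
    block <- lines  # headerless single-matrix fallback
  } else {
    ids <- sub("^>", "", trimws(lines[headers]))
    hit <- which(ids == protein_id)
    if (length(hit) == 0L) {
      abort(sprintf("Protein id '%s' not found in feature store %s",
                    protein_id, path))
    }
    from <- headers[hit[1]] + 1L
    to <- if (hit[1] < length(headers)) headers[hit[1] + 1L] - 1L else length(lines)
    if (to < from) abort(sprintf("Empty matrix block for id '%s'", protein_id))
    block <- lines[from:to]
  }

  rows <- strsplit(trimws(block), "[[:space:]]+")
  d <- unique(lengths(rows))
  if (length(d) != 1L) {
    abort(sprintf("Ragged matrix block for id '%s' (row widths: %s)",
                  protein_id, paste(d, collapse = ", ")))
  }
  values <- matrix(as.numeric(unlist(rows)), nrow = length(rows),
                   ncol = d, byrow = TRUE)
  if (anyNA(values)) abort(sprintf("Non-numeric entries in block for '%s'", protein_id))
  if (!is.null(expected_length) && nrow(values) != expected_length) {
    abort(sprintf(
      "Feature matrix for '%s' has %d rows but the protein has %d residues",
      protein_id, nrow(values), expected_length
    ))
  }
  residue_features(values, protein_id)
}

#' Concatenate two per-residue feature matrices row-wise
#'
#' Row i of the result is row i of `a` followed by row i of `b`; the feature
#' dimension is the sum of the two. Used to join pretrained embeddings
#' (e.g. 4096-dim) with the 21-dim one-hot encoding into a combined
#' per-residue vector (4117-dim).
#'
#' @param a,b `residue_features` matrices for the same protein with equal row
#'   counts.
#' @return A `residue_features` matrix of dimension `ncol(a) + ncol(b)`.
#' @export
concat_embed <- function(a, b) {
  id_a <- attr(a, "protein_id"); id_b <- attr(b, "protein_id")
  if (!is.null(id_a) && !is.null(id_b) && !identical(id_a, id_b)) {
    abort(sprintf("Protein id mismatch: '%s' vs '%s'", id_a, id_b))
  }
  if (nrow(a) != nrow(b)) {
    abort(sprintf("Row count mismatch: %d vs %d residues", nrow(a), nrow(b)))
  }
  residue_features(cbind(unclass(a), unclass(b)), id_a %||% id_b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
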