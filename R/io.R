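#' Read protein sequences from a FASTA file
#'
#' Sequences are normalized to the 21-symbol alphabet: lowercase letters are
#' uppercased and any non-standard residue code becomes `"X"`. The record id
#' is the header token up to the first whitespace.
#'
#' @param path Path to a FASTA file. Multi-line sequences are allowed.
#' @return A tibble with columns `id`, `sequence`, `length`, one row per
#'   FASTA entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warn(sprintf("FASTA file is empty: %s", path))
    return(tibble(id = character(), sequence = character(), length = integer()))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    abort(sprintf(
      "Malformed FASTA: sequence data before first header at line %d of %s",
      nonempty[1], path
    ))
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicate FASTA ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  sequence <- normalize_sequence(as.character(seqs))
  if (any(!nzchar(sequence))) {
    abort(sprintf(
      "Empty sequence for FASTA entry: %s",
      paste(ids[!nzchar(sequence)], collapse = ", ")
    ))
  }
  tibble(id = ids, sequence = unname(sequence), length = nchar(sequence))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a residue annotation table
#'
#' The expected format is a UTF-8 tab-separated table with header columns
#' `protein_id`, `position`, `wild_type`, `ddg`, `label`. Positions are
#' 1-based. `ddg` (kcal/mol) or `label` may be empty per row, but not both.
#' `label` values are `hotspot` or `non_hotspot`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id` (character), `position`
#'   (integer), `wild_type` (character), `ddg` (double, `NA` when absent) and
#'   `label` (character, `NA` when absent).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  required <- c("protein_id", "position", "wild_type", "ddg", "label")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("Annotation table lacks columns: %s",
                  paste(missing, collapse = ", ")))
  }
  n <- nrow(raw)
  blank <- function(x) is.na(x) | !nzchar(trimws(x))

  bad_pos <- which(!grepl("^[0-9]+$", trimws(raw$position)))
  if (length(bad_pos)) {
    abort(sprintf("Non-integer position in annotation row(s): %s",
                  paste(bad_pos, collapse = ", ")))
  }
  position <- as.integer(raw$position)
  if (any(position < 1L)) {
    abort(sprintf("Position below 1 in annotation row(s): %s",
                  paste(which(position < 1L), collapse = ", ")))
  }

  no_value <- which(blank(raw$ddg) & blank(raw$label))
  if (length(no_value)) {
    abort(sprintf("Annotation row(s) with neither ddg nor label: %s",
                  paste(no_value, collapse = ", ")))
  }

  ddg <- rep(NA_real_, n)
  has_ddg <- !blank(raw$ddg)
  suppressWarnings(ddg[has_ddg] <- as.numeric(raw$ddg[has_ddg]))
  if (any(has_ddg & is.na(ddg))) {
    abort(sprintf("Unparseable ddg in annotation row(s): %s",
                  paste(which(has_ddg & is.na(ddg)), collapse = ", ")))
  }

  label <- rep(NA_character_, n)
  has_label <- !blank(raw$label)
  label[has_label] <- trimws(raw$label[has_label])
  bad_label <- has_label & !label %in% c("hotspot", "non_hotspot")
  if (any(bad_label)) {
    abort(sprintf("Unknown label value(s): %s",
                  paste(unique(label[bad_label]), collapse = ", ")))
  }

  wild_type <- toupper(trimws(raw$wild_type))
  wild_type[!nzchar(wild_type)] <- NA_character_

  tibble(
    protein_id = raw$protein_id,
    position = position,
    wild_type = wild_type,
    ddg = ddg,
    label = label
  )
}

#' Write a residue annotation table
#'
#' Inverse of [read_annotations()]: absent `ddg`/`label` values are written as
#' empty strings so the table round-trips exactly.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("protein_id", "position", "wild_type", "ddg", "label")
  readr::write_tsv(annotations[cols], path, na = "")
  invisible(path)
}

#' Classify a ddG value as hot spot or not
#'
#' An interface residue is a hot spot when its alanine-mutation binding
#' free-energy change strictly exceeds the threshold; the conventional cutoff
#' is 2 kcal/mol, so a residue at exactly 2.0 is a non-hotspot.
#'
#' @param ddg Numeric vector of binding free-energy changes (kcal/mol).
#' @param threshold Classification cutoff in kcal/mol (default 2).
#' @return Character vector of `"hotspot"` / `"non_hotspot"`.
#' @examples
#' label_from_ddg(c(2.5, 2.0, -1.0))
#' @export
label_from_ddg <- function(ddg, threshold = 2) {
  if (!is.numeric(ddg)) abort("`ddg` must be numeric.")
  if (any(!is.finite(ddg))) abort("`ddg` contains non-finite values.")
  ifelse(ddg > threshold, "hotspot", "non_hotspot")
}

#' Bundle proteins and residue annotations into a validated dataset
#'
#' Checks that every annotation references a known protein at a valid
#' position, fills missing labels from `ddg` via [label_from_ddg()], and
#' verifies that stored labels agree with the ddG rule and that annotated
#' wild-type residues match the sequence.
#'
#' @param proteins Tibble from [read_fasta()] (columns `id`, `sequence`).
#' @param annotations Tibble from [read_annotations()].
#' @param ddg_threshold Hot-spot cutoff in kcal/mol passed to
#'   [label_from_ddg()].
#' @param wild_type_mismatch What to do when an annotated wild-type residue
#'   disagrees with the sequence: `"error"` (default) or `"warn"` — real
#'   datasets contain numbering discrepancies.
#' @return An object of class `hotspot_dataset`: a list with elements
#'   `proteins` and `annotations` (labels filled in).
#' @export
hotspot_dataset <- function(proteins, annotations,
                            ddg_threshold = 2,
                            wild_type_mismatch = c("error", "warn")) {
  wild_type_mismatch <- match.arg(wild_type_mismatch)
  proteins <- as_tibble(proteins)
  annotations <- as_tibble(annotations)
  if (!"length" %in% names(proteins)) {
    proteins$length <- nchar(proteins$sequence)
  }

  unknown <- setdiff(annotations$protein_id, proteins$id)
  if (length(unknown)) {
    abort(sprintf("Annotations reference unknown protein(s): %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  plen <- setNames(proteins$length, proteins$id)
  bad <- annotations$position < 1L |
    annotations$position > plen[annotations$protein_id]
  if (any(bad)) {
    abort(sprintf("Annotation position outside protein in row(s): %s",
                  paste(which(bad), collapse = ", ")))
  }

  seq_res <- substr_at(proteins, annotations)
  has_wt <- !is.na(annotations$wild_type)
  mism <- has_wt & normalize_sequence(annotations$wild_type) != seq_res
  if (any(mism)) {
    msg <- sprintf(
      "Wild-type mismatch with sequence in annotation row(s): %s",
      paste(which(mism), collapse = ", ")
    )
    if (wild_type_mismatch == "error") abort(msg) else warn(msg)
  }

  derived <- rep(NA_character_, nrow(annotations))
  has_ddg <- !is.na(annotations$ddg)
  derived[has_ddg] <- label_from_ddg(annotations$ddg[has_ddg], ddg_threshold)
  both <- has_ddg & !is.na(annotations$label)
  if (any(both & annotations$label != derived)) {
    abort(sprintf(
      "Stored label contradicts the ddG > %g kcal/mol rule in row(s): %s",
      ddg_threshold,
      paste(which(both & annotations$label != derived), collapse = ", ")
    ))
  }
  annotations$label <- dplyr::coalesce(annotations$label, derived)

  structure(
    list(proteins = proteins, annotations = annotations),
    class = "hotspot_dataset"
  )
}

# residue letters of each annotation's (protein, position)
substr_at <- function(proteins, annotations) {
  seqs <- setNames(proteins$sequence, proteins$id)
  substr(seqs[annotations$protein_id],
         annotations$position, annotations$position)
}

#' @export
print.hotspot_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf(
    "<hotspot_dataset> %d proteins, %d annotations (%d hotspot / %d non-hotspot%s)\n",
    nrow(x$proteins), nrow(x$annotations), s$n_hotspot, s$n_non_hotspot,
    if (is.na(s$ratio_floor)) "" else sprintf(", ~1:%d", s$ratio_floor)
  ))
  invisible(x)
}

#' Class counts and imbalance ratio of a dataset
#'
#' @param ds A `hotspot_dataset`.
#' @return A one-row tibble with `n_hotspot`, `n_non_hotspot` and
#'   `ratio_floor` = `floor(n_non_hotspot / n_hotspot)` (`NA` when there are
#'   no hotspots).
#' @examples
#' # a 349 / 22244 corpus has ratio_floor 63
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "hotspot_dataset"))
  lab <- ds$annotations$label
  n_hot <- sum(lab == "hotspot", na.rm = TRUE)
  n_non <- sum(lab == "non_hotspot", na.rm = TRUE)
  tibble(
    n_hotspot = n_hot,
    n_non_hotspot = n_non,
    ratio_floor = if (n_hot > 0L) n_non %/% n_hot else NA_integer_
  )
}
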