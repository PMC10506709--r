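#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard amino acids in alphabetical one-letter order, followed by
#' the catch-all symbol `"X"` (index 21) that stands for every non-standard
#' residue code (B, Z, J, U, O, `*`, ...). This fixed ordering defines the
#' column order of the one-hot encoding.
#'
#' @format A character vector of length 21.
#' @export
aa_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X"
)

#' Normalize a protein sequence to the 21-symbol alphabet
#'
#' Uppercases the sequence and maps every character that is not one of the 20
#' standard amino-acid letters to the catch-all symbol `"X"`.
#'
#' @param x Character vector of sequences.
#' @return Character vector of normalized sequences.
#' @examples
#' normalize_sequence("acdBfg")  # "ACDXFG"
#' @export
normalize_sequence <- function(x) {
  if (!is.character(x)) abort("`x` must be a character vector of sequences.")
  x <- toupper(x)
  standard <- paste(aa_alphabet[1:20], collapse = "")
  gsub(sprintf("[^%s]", standard), "X", x)
}
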