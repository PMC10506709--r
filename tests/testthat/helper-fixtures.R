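# Shared fixtures, all built in code at test time.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("protein_id\tposition\twild_type\tddg\tlabel", rows), path)
  path
}

# two tiny proteins with hand-written annotations
tiny_corpus <- function() {
  proteins <- tibble::tibble(
    id = c("p1", "p2"),
    sequence = c("ACDEFGHIKL", "MNPQRSTVWYACDE"),
    length = c(10L, 14L)
  )
  annotations <- tibble::tibble(
    protein_id = c("p1", "p1", "p1", "p2", "p2", "p2"),
    position = c(2L, 5L, 9L, 1L, 7L, 12L),
    wild_type = c("C", "F", "K", "M", "T", "C"),
    ddg = c(3.5, 0.5, NA, 2.0, 4.25, NA),
    label = c(NA, NA, "non_hotspot", NA, NA, "hotspot")
  )
  hotspot_dataset(proteins, annotations)
}

# a labeled window dataset with a perfectly separable feature
separable_windows <- function(n_per_class = 40L, width = 9L, dim = 4L,
                              seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- array(stats::runif(n * width * dim, 0, 0.2), c(n, width, dim))
  y <- rep(c(1L, 0L), each = n_per_class)
  X[y == 1L, , 1L] <- X[y == 1L, , 1L] + 1
  hotspotcnn:::new_window_dataset(
    X, y,
    tibble::tibble(protein_id = sprintf("w%03d", seq_len(n)),
                   position = seq_len(n)),
    width, dim
  )
}

# exhaustive Mann-Whitney pair-counting AUC (independent oracle)
auc_pair_count <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}
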