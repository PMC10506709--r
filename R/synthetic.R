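#' Generate a motif-planted synthetic hot-spot corpus
#'
#' Stand-in for a curated alanine-scanning corpus: random sequences over the
#' 20 standard residues, each carrying one planted motif whose center residue
#' is the hotspot, plus uniformly sampled non-motif residues annotated as
#' non-hotspots at a chosen imbalance. ddG values are drawn consistently with
#' the labels (hotspots above, non-hotspots below the 2 kcal/mol cutoff), so
#' fixtures flow through the full labeling path. The hotspot signal depends
#' only on the window content, matching the sliding-window modeling
#' assumption, and is deterministic under `seed`.
#'
#' @param n_proteins Number of proteins (default 150).
#' @param length_range Integer (min, max) sequence lengths (default 80-120).
#' @param motif Planted residue string of odd length (default `"WYCKH"`).
#' @param substitution_noise Per-motif-position probability of replacing the
#'   planted letter with a random residue (default 0).
#' @param background_hotspot_rate Probability that a non-hotspot annotation
#'   is mislabeled as a hotspot — label noise (default 0).
#' @param imbalance_ratio Non-hotspot annotations per hotspot (default 63,
#'   the imbalance of real alanine-scanning corpora). The corpus-wide count
#'   is exact (`imbalance_ratio * n_proteins` negatives drawn without
#'   replacement from all non-motif positions); per-protein counts vary, as
#'   annotation density does in real corpora.
#' @param seed Integer seed.
#' @return A [hotspot_dataset()].
#' @export
generate_proteins <- function(n_proteins = 150L, length_range = c(80L, 120L),
                              motif = "WYCKH", substitution_noise = 0,
                              background_hotspot_rate = 0,
                              imbalance_ratio = 63L, seed = 1L) {
  m <- nchar(motif)
  if (m %% 2L == 0L) abort("`motif` must have odd length.")
  if (m >= length_range[1]) abort("`motif` must be shorter than the shortest protein.")
  if (substitution_noise < 0 || substitution_noise > 1 ||
      background_hotspot_rate < 0 || background_hotspot_rate > 1) {
    abort("Noise probabilities must lie in [0, 1].")
  }
  motif_chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(motif_chars %in% aa_alphabet[1:20])) {
    abort("`motif` must use the 20 standard residues.")
  }
  flank_m <- (m - 1L) %/% 2L
  standard <- aa_alphabet[1:20]

  with_seed(seed, {
    prot <- vector("list", n_proteins)
    seq_chars <- vector("list", n_proteins)
    centers <- integer(n_proteins)
    neg_pool <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      L <- sample(length_range[1]:length_range[2], 1L)
      chars <- sample(standard, L, replace = TRUE)
      center <- sample((flank_m + 1L):(L - flank_m), 1L)
      span <- (center - flank_m):(center + flank_m)
      planted <- motif_chars
      if (substitution_noise > 0) {
        hit <- runif(m) < substitution_noise
        planted[hit] <- sample(standard, sum(hit), replace = TRUE)
      }
      chars[span] <- planted
      id <- sprintf("syn%04d", i)
      prot[[i]] <- tibble(id = id, sequence = paste(chars, collapse = ""),
                          length = L)
      seq_chars[[i]] <- chars
      centers[i] <- center
      neg_pool[[i]] <- setdiff(seq_len(L), span)
    }

    # negatives drawn corpus-wide so per-protein annotation density varies
    pool <- tibble(
      pidx = rep(seq_len(n_proteins), lengths(neg_pool)),
      position = unlist(neg_pool, use.names = FALSE)
    )
    n_neg <- imbalance_ratio * n_proteins
    if (n_neg > nrow(pool)) {
      abort(sprintf(
        "imbalance_ratio %d infeasible: corpus offers only %d non-motif residues",
        imbalance_ratio, nrow(pool)
      ))
    }
    picked <- pool[sample.int(nrow(pool), n_neg), , drop = FALSE]

    ids <- vapply(prot, function(p) p$id, character(1))
    ann <- tibble(
      pidx = c(seq_len(n_proteins), picked$pidx),
      position = c(centers, picked$position),
      label = c(rep("hotspot", n_proteins), rep("non_hotspot", n_neg))
    )
    if (background_hotspot_rate > 0) {
      flip <- ann$label == "non_hotspot" &
        runif(nrow(ann)) < background_hotspot_rate
      ann$label[flip] <- "hotspot"
    }
    ann <- ann[order(ann$pidx, ann$position), , drop = FALSE]
    ddg <- ifelse(ann$label == "hotspot", runif(nrow(ann), 2.5, 8),
                  runif(nrow(ann), -2, 1.5))
    annotations <- tibble(
      protein_id = ids[ann$pidx],
      position = ann$position,
      wild_type = vapply(seq_len(nrow(ann)), function(j) {
        seq_chars[[ann$pidx[j]]][ann$position[j]]
      }, character(1)),
      ddg = round(ddg, 2),
      label = ann$label
    )
    hotspot_dataset(dplyr::bind_rows(prot), annotations)
  })
}

#' Generate two Gaussian feature clouds
#'
#' Minority and majority isotropic Gaussian clusters for exercising the
#' k-nearest-neighbor geometry of SMOTE and of simple classifiers.
#'
#' @param n_minority,n_majority Points per class.
#' @param dim Feature dimension.
#' @param minority_mean,majority_mean Cluster centers (length-`dim` vectors
#'   or scalars, recycled).
#' @param spread Common standard deviation (> 0).
#' @param seed Integer seed.
#' @return A list with matrices `minority` (`n_minority` x `dim`) and
#'   `majority` (`n_majority` x `dim`).
#' @export
generate_feature_cloud <- function(n_minority = 50L, n_majority = 200L,
                                   dim = 5L, minority_mean = 0,
                                   majority_mean = 3, spread = 1,
                                   seed = 1L) {
  if (spread <= 0) abort("`spread` must be positive.")
  if (dim < 1L) abort("`dim` must be >= 1.")
  mu_min <- rep_len(minority_mean, dim)
  mu_maj <- rep_len(majority_mean, dim)
  with_seed(seed, {
    list(
      minority = matrix(rnorm(n_minority * dim, 0, spread), n_minority,
                        dim, byrow = TRUE) +
        matrix(mu_min, n_minority, dim, byrow = TRUE),
      majority = matrix(rnorm(n_majority * dim, 0, spread), n_majority,
                        dim, byrow = TRUE) +
        matrix(mu_maj, n_majority, dim, byrow = TRUE)
    )
  })
}
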