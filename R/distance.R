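#' Kimura two-parameter distance between two aligned sequences
#'
#' The K2P model corrects observed divergence for multiple hits while
#' distinguishing transitions (A<->G, C<->T) from transversions. With P and Q
#' the proportions of sites differing by a transition and a transversion over
#' the comparable columns, the distance is
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#' Only columns where both sequences carry an unambiguous base (A, C, G or T)
#' are compared; gaps and N are skipped.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return The K2P distance in substitutions per site.
#' @examples
#' k2p_distance("AAAA", "AAAA")   # 0
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("sequences must have equal aligned length", class = "cryptwebs_alignment_error")
  }
  a <- encode_dna(seq_a)
  b <- encode_dna(seq_b)
  d <- k2p_pair(a, b)
  if (is.na(d)) {
    # distinguish the two failure modes for the caller
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) {
      abort("no comparable columns between the two sequences",
            class = "cryptwebs_incomparable_error")
    }
    abort("K2P distance undefined (saturation: log argument <= 0)",
          class = "cryptwebs_saturation_error")
  }
  d
}

# A=1, C=2, G=3, T=4; everything else NA. Transitions then have |diff| == 2.
encode_dna <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  x
}

k2p_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) return(NA_real_)
  dif <- abs(a[ok] - b[ok])
  P <- sum(dif == 2L) / n
  Q <- sum(dif == 1L | dif == 3L) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix for one marker
#'
#' Computes all pairwise distances among a set of aligned sequences.
#' Incomparable pairs (no shared unambiguous columns) and saturated pairs
#' (undefined K2P correction) are recorded as `NA` and listed in the
#' `"missing_pairs"` attribute; a warning is raised when more than half of
#' all pairs are missing.
#'
#' @param seqs Tibble with columns `specimen_id` and `sequence`, one marker,
#'   at least two rows (as from [read_fasta_alignment()]).
#' @return A symmetric numeric matrix with zero diagonal, dimnames the
#'   specimen ids, and attribute `missing_pairs` (two-column tibble).
#' @export
k2p_matrix <- function(seqs) {
  stopifnot(is.data.frame(seqs), nrow(seqs) >= 2)
  if (anyDuplicated(seqs$specimen_id)) {
    abort("duplicate specimen ids in alignment", class = "cryptwebs_duplicate_error")
  }
  n <- nrow(seqs)
  lens <- nchar(seqs$sequence)
  if (length(unique(lens)) > 1) {
    abort("ragged alignment", class = "cryptwebs_alignment_error")
  }
  enc <- matrix(NA_integer_, nrow = lens[1], ncol = n)
  for (i in seq_len(n)) enc[, i] <- encode_dna(seqs$sequence[i])
  d <- matrix(0, n, n, dimnames = list(seqs$specimen_id, seqs$specimen_id))
  miss_u <- character(0); miss_v <- character(0)
  for (i in seq_len(n - 1)) {
    ai <- enc[, i]
    for (j in seq((i + 1), n)) {
      val <- k2p_pair(ai, enc[, j])
      d[i, j] <- d[j, i] <- val
      if (is.na(val)) {
        miss_u <- c(miss_u, seqs$specimen_id[i])
        miss_v <- c(miss_v, seqs$specimen_id[j])
      }
    }
  }
  missing_pairs <- tibble(id_a = miss_u, id_b = miss_v)
  if (nrow(missing_pairs) > 0.5 * n * (n - 1) / 2) {
    warn(sprintf("more than 50%% of pairs (%d of %d) have undefined K2P distance",
                 nrow(missing_pairs), n * (n - 1) %/% 2))
  }
  attr(d, "missing_pairs") <- missing_pairs
  d
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of comparable columns that differ; used as a lower bound on the
#' K2P distance.
#'
#' @inheritParams k2p_distance
#' @return Proportion of differing comparable sites.
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- encode_dna(seq_a)
  b <- encode_dna(seq_b)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) abort("no comparable columns", class = "cryptwebs_incomparable_error")
  mean(a[ok] != b[ok])
}
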