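#' Word length for feature frequency profiles
#'
#' The k-mer length rule for the FFP baseline: `k = floor(log4(n))` where `n`
#' is the minimum sequence length in the dataset. E.g. mitochondrial genomes
#' of ~16500 bp give k = 7; rhinovirus genomes of ~7200 nt give k = 6.
#'
#' @param min_length Minimum sequence length across the dataset (>= 4).
#' @return Positive integer word length.
#' @examples
#' choose_k(16500) # 7
#' @export
choose_k <- function(min_length) {
  stopifnot(is.numeric(min_length), length(min_length) == 1)
  if (min_length < 4) stop("minimum sequence length must be >= 4 to choose k")
  as.integer(floor(log(min_length, base = 4) + 1e-9))
}

#' k-mer feature frequency profile of one sequence
#'
#' Counts all `n - k + 1` overlapping words of length `k` and normalizes by
#' the word count. Words absent from the sequence are absent from the profile
#' (implicit zero), so profiles stay sparse even at k = 9 (4^9 = 262144
#' possible words).
#'
#' @param sequence A cleaned `ACGT` string of length >= `k`.
#' @param k Word length.
#' @param id Optional record id, used in error messages.
#' @return A named numeric vector of relative frequencies summing to 1, with
#'   attribute `k`.
#' @examples
#' kmer_profile("ACGAC", 2) # AC 0.5, CG 0.25, GA 0.25
#' @export
kmer_profile <- function(sequence, k, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            is.numeric(k), length(k) == 1, k >= 1)
  if (nchar(sequence) < k) {
    stop("sequence ", if (!is.null(id)) paste0("'", id, "' "),
         "is shorter (", nchar(sequence), ") than k = ", k)
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence),
                                                 width = as.integer(k))
  counts <- counts[counts > 0]
  freq <- counts / sum(counts)
  attr(freq, "k") <- as.integer(k)
  freq
}

#' Jensen-Shannon divergence between two k-mer profiles
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m` the entrywise mean
#' distribution and `H` the Shannon entropy in bits, so the value lies in
#' `[0, 1]`: 0 for identical profiles, 1 for disjoint support.
#'
#' @param p,q Profiles from [kmer_profile()] with equal `k`.
#' @return Divergence in `[0, 1]`.
#' @export
jensen_shannon <- function(p, q) {
  kp <- attr(p, "k"); kq <- attr(q, "k")
  if (!is.null(kp) && !is.null(kq) && kp != kq) {
    stop("profiles have different k (", kp, " vs ", kq, ")")
  }
  keys <- union(names(p), names(q))
  pv <- unname(p[keys]); pv[is.na(pv)] <- 0
  qv <- unname(q[keys]); qv[is.na(qv)] <- 0
  m <- (pv + qv) / 2
  h <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  d <- h(m) - (h(pv) + h(qv)) / 2
  max(0, min(1, d))   # clamp floating noise at the boundaries
}

#' Pairwise FFP distance matrix under Jensen-Shannon divergence
#'
#' The k-mer baseline: profiles at `k = choose_k(min sequence length)` (unless
#' overridden) compared pairwise by [jensen_shannon()].
#'
#' @param seqs A data frame with columns `id` and `sequence`, >= 2 rows.
#' @param k Optional word-length override; default applies [choose_k()].
#' @return A `mev_dist` matrix (see [mev_distance()]); attribute `k` records
#'   the word length used.
#' @export
ffp_distance <- function(seqs, k = NULL) {
  seqs <- validate_seq_table(seqs, require_n = 2)
  if (is.null(k)) k <- choose_k(min(nchar(seqs$sequence)))
  profiles <- purrr::map(seq_len(nrow(seqs)),
                         function(i) kmer_profile(seqs$sequence[i], k, id = seqs$id[i]))
  n <- nrow(seqs)
  m <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jensen_shannon(profiles[[i]], profiles[[j]])
    }
  }
  out <- new_mev_dist(m, method = paste0("jensen-shannon-ffp (k=", k, ")"))
  attr(out, "k") <- as.integer(k)
  out
}
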