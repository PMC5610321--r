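#' The three binary encodings of the DNA alphabet
#'
#' Each scheme partitions \{A,C,G,T\} into two letters by a chemical or
#' physical property: purine/pyrimidine (R = \{A,G\}, Y = \{C,T\}), amino/keto
#' (M = \{A,C\}, K = \{G,T\}) and strong/weak hydrogen bond (S = \{G,C\},
#' W = \{A,T\}).
#'
#' @return A named list of six character vectors, one base set per letter, in
#'   the fixed feature order R, Y, M, K, S, W.
#' @export
encoding_letters <- function() {
  list(
    R = c("A", "G"), Y = c("C", "T"),
    M = c("A", "C"), K = c("G", "T"),
    S = c("G", "C"), W = c("A", "T")
  )
}

# column names of the 18 features, in fixed order
mev_feature_names <- function() {
  as.vector(vapply(names(encoding_letters()),
                   function(L) paste0(c("n_", "mu_", "D2_"), L),
                   character(3)))
}

#' Positional moment statistics of one letter
#'
#' For the positions `i = 1..n` at which the sequence carries a base from
#' `bases`, computes the letter count `n_L`, the mean position
#' `mu_L = mean(i)`, and the scaled second moment
#' `D2_L = sum((i - mu_L)^2) / (n_L * n)` — the positional variance of the
#' letter scaled by the sequence length. When the letter never occurs both
#' `mu_L` and `D2_L` are defined as 0 (the no-positional-mass limit), keeping
#' vectors of different sequences comparable.
#'
#' @param sequence A non-empty `ACGT` string.
#' @param bases Character vector of bases counted as the letter, a subset of
#'   `c("A","C","G","T")`.
#' @return A one-row tibble with columns `count`, `mean_position`,
#'   `scaled_second_moment`.
#' @examples
#' letter_stats("ATGC", c("A", "G")) # count 2, mean 2, D2 0.25
#' @export
letter_stats <- function(sequence, bases) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("[^ACGT]", sequence)) stop("sequence must contain only A, C, G, T")
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  codes <- utf8ToInt(sequence)
  s <- letter_triplet(codes %in% utf8ToInt(paste(bases, collapse = "")),
                      nchar(sequence))
  tibble::tibble(count = s[1], mean_position = s[2], scaled_second_moment = s[3])
}

# core: (count, mean position, scaled second moment) from a logical mask.
# centered two-pass form: no cancellation even at 10 Mb scale.
letter_triplet <- function(mask, n) {
  pos <- which(mask)
  n_l <- length(pos)
  if (n_l == 0) return(c(0, 0, 0))
  mu <- mean(pos)
  d <- pos - mu
  c(n_l, mu, sum(d * d) / (as.numeric(n_l) * n))
}

# 18 features of one cleaned ACGT string, paper order
encode_sequence <- function(sequence) {
  codes <- utf8ToInt(sequence)
  n <- length(codes)
  if (n == 0) stop("empty sequence")
  a <- utf8ToInt("A"); c_ <- utf8ToInt("C"); g <- utf8ToInt("G")
  is_a <- codes == a; is_c <- codes == c_; is_g <- codes == g
  masks <- list(
    R = is_a | is_g, Y = !(is_a | is_g),
    M = is_a | is_c, K = !(is_a | is_c),
    S = is_g | is_c, W = !(is_g | is_c)
  )
  out <- unlist(lapply(masks, letter_triplet, n = n), use.names = FALSE)
  names(out) <- mev_feature_names()
  out
}

#' Encode sequences as 18-dimensional multiple encoding vectors
#'
#' The core descriptor: each sequence is recoded under the three binary
#' encodings of [encoding_letters()] and, for each of the six letters, the
#' count, mean position and scaled second moment of positions are computed by
#' [letter_stats()]. The 18 features are reported in the fixed order
#' `(n_R, mu_R, D2_R, n_Y, mu_Y, D2_Y, n_M, mu_M, D2_M, n_K, mu_K, D2_K,
#' n_S, mu_S, D2_S, n_W, mu_W, D2_W)`.
#'
#' Counts grow like `n`, mean positions like `n/2` and `D2` like `n/12`, so
#' the raw vector (the default) is length-sensitive; sequences compared with
#' it should be approximately complete, equal-coverage genomes or genes.
#' `normalize = TRUE` divides every feature by the sequence length, giving a
#' scale-free variant for exploratory use.
#'
#' @param seqs A data frame with columns `id` and `sequence` (cleaned `ACGT`),
#'   e.g. from [read_fasta()] or [simulate_clades()].
#' @param normalize Divide all 18 features by sequence length? Default `FALSE`
#'   (the raw definition).
#' @param verbose Emit a progress message per record (useful at genome scale)?
#' @return A tibble with one row per input record, in input order: `id`,
#'   `length`, then the 18 named feature columns.
#' @examples
#' mev_encode(tibble::tibble(id = "s1", sequence = "ATGC"))
#' @export
mev_encode <- function(seqs, normalize = FALSE, verbose = FALSE) {
  seqs <- validate_seq_table(seqs)
  feats <- purrr::map(seq_len(nrow(seqs)), function(i) {
    if (verbose) message("encoding ", seqs$id[i], " (", nchar(seqs$sequence[i]), " bp)")
    encode_sequence(seqs$sequence[i])
  })
  out <- tibble::as_tibble(do.call(rbind, feats))
  n <- nchar(seqs$sequence)
  if (normalize) out <- out / n
  dplyr::bind_cols(tibble::tibble(id = seqs$id, length = n), out)
}

#' Write an encoding-vector table to CSV
#'
#' One row per sequence: `id`, `length`, then the 18 named features in fixed
#' order. Byte-identical across runs for identical input.
#'
#' @param vectors A tibble from [mev_encode()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vectors_csv <- function(vectors, path) {
  validate_vector_table(vectors)
  readr::write_csv(vectors[, c("id", "length", mev_feature_names())], path,
                   progress = FALSE)
  invisible(path)
}

validate_vector_table <- function(vectors) {
  need <- c("id", mev_feature_names())
  if (!is.data.frame(vectors) || !all(need %in% names(vectors))) {
    stop("expected an encoding-vector table with columns id and the 18 features (see mev_encode())")
  }
  invisible(vectors)
}
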