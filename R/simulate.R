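#' Random i.i.d. DNA sequence
#'
#' Uniform `ACGT` sequence, fully determined by `(length, seed)`. Randomness
#' is drawn from a local RNG stream, so the caller's RNG state is untouched.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @return A single `ACGT` string.
#' @export
random_sequence <- function(length, seed) {
  stopifnot(is.numeric(length), length(length) == 1)
  if (length < 1) stop("length must be >= 1")
  with_local_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
}

#' Point-mutate a DNA sequence
#'
#' Each position is independently substituted with probability `rate`; a
#' substituted base is redrawn uniformly from the three alternatives, so every
#' selected position really changes. Length is preserved (no indels): the
#' encoding-vector features are length-sensitive, so the default simulation
#' model holds length fixed.
#'
#' @param sequence A cleaned `ACGT` string.
#' @param rate Per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(sequence, rate, seed) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)")
  }
  if (grepl("[^ACGT]", sequence)) stop("sequence must contain only A, C, G, T")
  if (rate == 0) return(sequence)
  bases <- c("A", "C", "G", "T")
  with_local_seed(seed, {
    s <- strsplit(sequence, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(s)) < rate)
    if (length(hit) > 0) {
      # draw among the 3 alternatives of each hit base
      alt <- matrix(bases, nrow = 4, ncol = 4)
      alt <- alt[alt != rep(bases, each = 4)]          # 3 x 4: alternatives by base
      dim(alt) <- c(3, 4)
      colnames(alt) <- bases
      pick <- sample.int(3, length(hit), replace = TRUE)
      s[hit] <- alt[cbind(pick, match(s[hit], bases))]
    }
    paste(s, collapse = "")
  })
}

#' Simulate a clade-structured sequence family
#'
#' Generates a dataset with planted clade structure: a random root ancestor, a
#' per-clade ancestor obtained by mutating the root at `between_rate`, and
#' `taxa_per_clade` taxa per clade obtained by mutating the clade ancestor at
#' `within_rate`. With `between_rate` well above `within_rate`, the clades are
#' separable and tree methods should recover the planted partition. Ids encode
#' clade membership (`c<K>_t<J>`, short enough to survive the 10-character
#' name field of PHYLIP output), and the planted partition is carried both in
#' the `clade` column and (for ids alone) by name.
#'
#' @param n_clades Number of clades (>= 1).
#' @param taxa_per_clade Taxa per clade (>= 1).
#' @param sequence_length Length of every sequence (>= 1).
#' @param within_rate Per-site substitution rate clade ancestor -> taxon, in `[0, 1)`.
#' @param between_rate Per-site substitution rate root -> clade ancestor, in
#'   `[0, 1)`; must exceed `within_rate`.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the design and this seed (stable per-record sub-seeding).
#' @return A tibble with columns `id`, `clade` (integer), `sequence`.
#' @examples
#' simulate_clades(2, 2, 50, within_rate = 0.02, between_rate = 0.3, seed = 7)
#' @export
simulate_clades <- function(n_clades, taxa_per_clade, sequence_length,
                            within_rate, between_rate, seed) {
  stopifnot(n_clades >= 1, taxa_per_clade >= 1, sequence_length >= 1)
  if (!(between_rate > within_rate)) {
    stop("between_rate must exceed within_rate (clade separability)")
  }
  seeds <- sub_seeds(seed, 1 + n_clades * (1 + taxa_per_clade))
  root <- random_sequence(sequence_length, seeds[1])
  s <- 2
  rows <- vector("list", n_clades * taxa_per_clade)
  r <- 1
  for (k in seq_len(n_clades)) {
    anc <- mutate_sequence(root, between_rate, seeds[s]); s <- s + 1
    for (j in seq_len(taxa_per_clade)) {
      rows[[r]] <- tibble::tibble(
        id = sprintf("c%d_t%d", k, j),
        clade = k,
        sequence = mutate_sequence(anc, within_rate, seeds[s])
      )
      s <- s + 1; r <- r + 1
    }
  }
  dplyr::bind_rows(rows)
}

#' Write the planted clade truth table
#'
#' Tab-separated `id<TAB>clade`, one row per taxon, matching the FASTA written
#' by [write_fasta()].
#'
#' @param seqs A tibble from [simulate_clades()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(seqs, path) {
  stopifnot(all(c("id", "clade") %in% names(seqs)))
  readr::write_tsv(seqs[, c("id", "clade")], path, progress = FALSE)
  invisible(path)
}

# run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# stable stream of k sub-seeds derived from one master seed
sub_seeds <- function(seed, k) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
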