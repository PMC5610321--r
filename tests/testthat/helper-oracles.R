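# Independent brute-force oracles, deliberately written along different code
# paths than the package internals.

# definitional encoding: explicit indicator sums over i = 1..n per letter
oracle_encode <- function(sequence) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(s)
  out <- numeric(0)
  for (bases in encoding_letters()) {
    w <- as.numeric(s %in% bases)
    n_l <- sum(w)
    if (n_l == 0) {
      out <- c(out, 0, 0, 0)
      next
    }
    mu <- sum(seq_len(n) * w / n_l)
    d2 <- sum((seq_len(n) - mu)^2 * w / (n_l * n))
    out <- c(out, n_l, mu, d2)
  }
  out
}

# UPGMA recomputing every cluster-pair average from the ORIGINAL matrix at
# each step; returns the cophenetic matrix of the result.
oracle_upgma_cophenetic <- function(m) {
  n <- nrow(m)
  labels <- rownames(m)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        avg <- mean(m[clusters[[i]], clusters[[j]]])
        if (is.null(best) || avg < best$d - 1e-12) best <- list(i = i, j = j, d = avg)
      }
    }
    for (a in clusters[[best$i]]) {
      for (b in clusters[[best$j]]) {
        coph[a, b] <- coph[b, a] <- best$d
      }
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# JSD by explicit per-key summation over the union of supports
oracle_jsd <- function(p, q) {
  keys <- union(names(p), names(q))
  total <- 0
  for (key in keys) {
    pv <- if (key %in% names(p)) p[[key]] else 0
    qv <- if (key %in% names(q)) q[[key]] else 0
    mv <- (pv + qv) / 2
    term <- function(x) if (x > 0) -x * log2(x) else 0
    total <- total + term(mv) - (term(pv) + term(qv)) / 2
  }
  total
}

# all 4^len ACGT strings of a given length
all_sequences <- function(len) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), len))
  apply(as.matrix(grid), 1, paste, collapse = "")
}

# random labelled distance matrix from points in R^dim (a genuine metric)
random_point_matrix <- function(n_taxa, dim = 3) {
  x <- matrix(stats::rnorm(n_taxa * dim), n_taxa)
  rownames(x) <- paste0("t", seq_len(n_taxa))
  as.matrix(stats::dist(x))
}

# minimal sequence table constructor used across tests
seq_table <- function(...) {
  s <- c(...)
  tibble::tibble(id = names(s), sequence = unname(s))
}

mev_features <- function(vectors) {
  as.matrix(vectors[, mevtree:::mev_feature_names()])
}
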