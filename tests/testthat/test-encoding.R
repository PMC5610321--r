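worked_atgc <- c(2, 2, 0.25, 2, 3, 0.25, 2, 2.5, 0.5625,
                 2, 2.5, 0.0625, 2, 3.5, 0.0625, 2, 1.5, 0.0625)

test_that("letter_stats matches hand-derived positional moments", {
  s <- letter_stats("ATGC", c("A", "G"))
  expect_equal(s$count, 2)
  expect_equal(s$mean_position, 2)
  expect_equal(s$scaled_second_moment, 0.25)

  s <- letter_stats("AAAA", c("A", "G"))
  expect_equal(s$count, 4)
  expect_equal(s$mean_position, 2.5)
  expect_equal(s$scaled_second_moment, 0.3125)

  # empty-letter convention: no positional mass -> zeros
  s <- letter_stats("AAAA", c("C", "T"))
  expect_equal(unlist(s), c(count = 0, mean_position = 0, scaled_second_moment = 0))

  expect_error(letter_stats("", c("A", "G")), "empty")
  expect_error(letter_stats("ACGN", c("A", "G")), "only A, C, G, T")
})

test_that("the 18-vector of ATGC equals the hand calculation, in fixed order", {
  v <- mev_encode(seq_table(s1 = "ATGC"))
  expect_equal(names(v), c("id", "length", mevtree:::mev_feature_names()))
  expect_equal(v$length, 4L)
  expect_equal(as.numeric(v[1, -(1:2)]), worked_atgc)
})

test_that("encoding agrees with the brute-force oracle on short sequences", {
  set.seed(91)
  seqs <- c(
    all_sequences(1), all_sequences(2), all_sequences(3),
    vapply(1:40, function(i) random_sequence(sample(4:200, 1), seed = 9000 + i),
           character(1))
  )
  vecs <- mev_features(mev_encode(seq_table(stats::setNames(seqs, paste0("q", seq_along(seqs))))))
  for (i in seq_along(seqs)) {
    expect_equal(unname(vecs[i, ]), oracle_encode(seqs[i]), tolerance = 1e-12)
  }
})

test_that("partition conservation and position-mass identities hold exactly", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(c(2:10, 50, 1000, 10000), 1)
    s <- random_sequence(n, seed = 500 + i)
    v <- as.numeric(mev_features(mev_encode(seq_table(q = s))))
    counts <- v[c(1, 4, 7, 10, 13, 16)]
    mus <- v[c(2, 5, 8, 11, 14, 17)]
    # n_R+n_Y = n_M+n_K = n_S+n_W = n, exact integers
    expect_identical(counts[1] + counts[2], as.numeric(n))
    expect_identical(counts[3] + counts[4], as.numeric(n))
    expect_identical(counts[5] + counts[6], as.numeric(n))
    # n_L*mu_L summed per scheme = n(n+1)/2
    half <- n * (n + 1) / 2
    for (scheme in list(1:2, 3:4, 5:6)) {
      expect_equal(sum(counts[scheme] * mus[scheme]), half,
                   tolerance = 1e-9 * n^2 / max(half, 1))
    }
  }
})

test_that("reversing a sequence preserves counts and D2 and reflects means", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:300, 1)
    s <- random_sequence(n, seed = 700 + i)
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    vs <- as.numeric(mev_features(mev_encode(seq_table(q = s))))
    vr <- as.numeric(mev_features(mev_encode(seq_table(q = r))))
    idx_n <- c(1, 4, 7, 10, 13, 16)
    expect_equal(vr[idx_n], vs[idx_n])
    expect_equal(vr[idx_n + 2], vs[idx_n + 2], tolerance = 1e-9)
    present <- vs[idx_n] > 0
    expect_equal(vr[idx_n + 1][present], (n + 1 - vs[idx_n + 1])[present],
                 tolerance = 1e-9)
  }
})

test_that("D2 is bounded by (n-1)^2/(4n), tight for end-position pairs", {
  # exhaustive at small lengths, randomized at larger ones
  for (len in 2:5) {
    vecs <- mev_features(mev_encode(seq_table(
      stats::setNames(all_sequences(len), paste0("q", seq_len(4^len))))))
    d2 <- vecs[, c(3, 6, 9, 12, 15, 18)]
    expect_true(all(d2 >= 0))
    expect_true(all(d2 <= (len - 1)^2 / (4 * len) + 1e-12))
  }
  set.seed(41)
  for (i in 1:10) {
    n <- sample(10:2000, 1)
    v <- as.numeric(mev_features(mev_encode(seq_table(q = random_sequence(n, 40 + i)))))
    expect_true(all(v[c(3, 6, 9, 12, 15, 18)] <= (n - 1)^2 / (4 * n) + 1e-12))
  }
  # the bound is attained when a letter sits only at the two end positions
  n <- 11
  s <- paste0("A", strrep("C", n - 2), "A")
  v <- mev_features(mev_encode(seq_table(q = s)))
  expect_equal(unname(v[1, "D2_R"]), (n - 1)^2 / (4 * n))
})

test_that("centered D2 agrees with the one-pass moment form", {
  set.seed(59)
  for (i in 1:10) {
    n <- sample(c(100, 5000, 2e5), 1)
    s <- random_sequence(n, 90 + i)
    v <- as.numeric(mev_features(mev_encode(seq_table(q = s))))
    codes <- strsplit(s, "")[[1]]
    for (L in 1:6) {
      bases <- encoding_letters()[[L]]
      pos <- which(codes %in% bases)
      n_l <- v[3 * L - 2]; mu <- v[3 * L - 1]
      one_pass <- (sum(pos^2) - n_l * mu^2) / (n_l * n)
      expect_equal(v[3 * L], one_pass, tolerance = 1e-9)
    }
  }
})

test_that("normalize divides every feature by sequence length", {
  seqs <- seq_table(a = "ATGCATGCAT", b = "GGGCCCAATT")
  raw <- mev_encode(seqs)
  norm <- mev_encode(seqs, normalize = TRUE)
  expect_equal(mev_features(norm), mev_features(raw) / 10)
  expect_equal(rowSums(mev_features(norm)[, c(1, 4)]), c(1, 1), ignore_attr = TRUE)
})

test_that("encoding is order-preserving, deterministic and validates input", {
  seqs <- seq_table(x = "ACGT", y = "ACGT")
  v <- mev_encode(seqs)
  expect_equal(v$id, c("x", "y"))
  expect_equal(as.numeric(v[1, -(1:2)]), as.numeric(v[2, -(1:2)]))
  expect_error(mev_encode(tibble::tibble(id = character(), sequence = character())),
               "at least 1")
  expect_error(mev_encode(seq_table(x = "ACGT", x = "AC")), "duplicate")
  expect_error(mev_encode(seq_table(x = "ACGN")), "x")
})
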