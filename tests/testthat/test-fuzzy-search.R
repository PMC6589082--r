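test_that("basic semi-global matches behave as specified", {
  # exact self-match: one match covering the whole text
  m <- search_levenshtein("ACGT", "ACGT", k = 0)
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, c("start", "end", "edits")], use.names = FALSE),
               c(0L, 4L, 0L))

  # empty text: matching j pattern characters against nothing costs j
  m <- search_levenshtein("AC", "", k = 2)
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, c("start", "end", "edits", "length")],
                      use.names = FALSE), c(0L, 0L, 2L, 0L))
  expect_equal(nrow(search_levenshtein("AC", "", k = 1)), 0L)

  # a transposition costs one edit under the restricted Damerau metric
  m <- search_damerau("ACGT", "ACTG", k = 1)
  expect_true(any(m$end == 4L & m$edits == 1L))
  expect_equal(nrow(search_damerau("ACGT", "ACGT", k = 0)), 1L)
  # ... but two edits under plain Levenshtein
  expect_false(any(search_levenshtein("ACGT", "ACTG", k = 1)$end == 4L))

  # Hamming window
  m <- search_hamming_bitap("ACGT", "AACGTT", k = 0)
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, c("start", "end", "edits")], use.names = FALSE),
               c(1L, 5L, 0L))
  expect_equal(bitap_word_count(100, 63), 2L)
})

test_that("edit-distance searchers agree with brute-force oracles", {
  # exhaustive over a binary alphabet at small sizes
  pats <- all_strings(3, c("A", "C"), min_len = 1)
  txts <- all_strings(4, c("A", "C"))
  for (P in pats) {
    for (T in txts) {
      for (k in 0:2) {
        expect_matches_oracle(
          search_levenshtein(P, T, k, wildcards = ""), P, T, k, lev_dist)
        expect_matches_oracle(
          search_damerau(P, T, k, wildcards = ""), P, T, k, osa_dist)
      }
    }
  }
  # randomized at the full size bounds
  set.seed(101)
  for (rep in 1:120) {
    P <- rseq(sample(1:6, 1))
    T <- rseq(sample(0:10, 1))
    k <- sample(0:2, 1)
    expect_matches_oracle(
      search_levenshtein(P, T, k, wildcards = ""), P, T, k, lev_dist)
    expect_matches_oracle(
      search_damerau(P, T, k, wildcards = ""), P, T, k, osa_dist)
  }
})

test_that("the Bitap Hamming searcher equals a sliding mismatch counter", {
  set.seed(102)
  for (rep in 1:150) {
    P <- rseq(sample(1:6, 1))
    T <- rseq(sample(0:12, 1))
    k <- sample(0:3, 1)
    w <- sample(c(2L, 3L, 7L, 63L), 1)  # multi-word masks included
    got <- search_hamming_bitap(P, T, k, word_width = w, wildcards = "")
    oracle <- hamming_windows_oracle(P, T)
    oracle <- oracle[oracle[, 3] <= k, , drop = FALSE]
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got)) {
      expect_equal(as.matrix(got[, c("start", "end", "edits")]),
                   oracle, ignore_attr = TRUE)
    }
  }
  # a pattern longer than one machine word
  set.seed(103)
  P <- rseq(100)
  T <- paste0(rseq(40), P, rseq(40))
  got <- search_hamming_bitap(P, T, k = 1, word_width = 63)
  expect_true(any(got$start == 40 & got$edits == 0))
})

test_that("the cutoff heuristic never changes results", {
  set.seed(104)
  for (rep in 1:150) {
    P <- rseq(sample(1:8, 1))
    T <- rseq(sample(0:14, 1))
    k <- sample(0:3, 1)
    anch <- sample(c(TRUE, FALSE), 1)
    expect_identical(
      search_levenshtein(P, T, k, cutoff = TRUE, anchored = anch),
      search_levenshtein(P, T, k, cutoff = FALSE, anchored = anch))
    expect_identical(
      search_damerau(P, T, k, cutoff = TRUE, anchored = anch),
      search_damerau(P, T, k, cutoff = FALSE, anchored = anch))
  }
})

test_that("match sets are monotone in k and Hamming implies Levenshtein", {
  set.seed(105)
  for (rep in 1:80) {
    P <- rseq(sample(1:6, 1))
    T <- rseq(sample(1:10, 1))
    k <- sample(0:2, 1)
    for (fn in list(search_levenshtein, search_damerau)) {
      a <- fn(P, T, k)
      b <- fn(P, T, k + 1L)
      expect_true(all(a$end %in% b$end))
      # per shared end, the reported minimal edit count is identical
      shared <- merge(a, b, by = "end")
      expect_equal(shared$edits.x, shared$edits.y)
    }
    h <- search_hamming_bitap(P, T, k)
    l <- search_levenshtein(P, T, k)
    for (r in seq_len(nrow(h))) {
      row <- l[l$end == h$end[r], , drop = FALSE]
      expect_equal(nrow(row), 1L)
      expect_true(row$edits <= h$edits[r])
    }
  }
})

test_that("anchored search reports alignments pinned to the text start", {
  # shifted exact occurrence: unanchored finds it at start 1 with 0 edits,
  # anchored absorbs the leading character as one edit
  m <- search_levenshtein("ACGT", "XACGT", k = 1)
  expect_true(any(m$start == 1 & m$edits == 0))
  a <- search_levenshtein("ACGT", "XACGT", k = 1, anchored = TRUE)
  expect_true(all(a$start == 0))
  expect_true(any(a$end == 5 & a$edits == 1))
  # anchored edits equal the prefix edit distance
  set.seed(106)
  for (rep in 1:60) {
    P <- rseq(sample(1:6, 1))
    T <- rseq(sample(0:10, 1))
    k <- sample(0:2, 1)
    got <- search_levenshtein(P, T, k, anchored = TRUE, wildcards = "")
    for (i in 0:nchar(T)) {
      d <- lev_dist(P, substr(T, 1, i))
      row <- got[got$end == i, , drop = FALSE]
      if (d <= k) {
        expect_equal(nrow(row), 1L)
        expect_equal(row$edits, d)
        expect_equal(row$start, 0L)
      } else {
        expect_equal(nrow(row), 0L)
      }
    }
  }
})

test_that("wildcards match free and overlaps cost nothing past the ends", {
  # N in the pattern
  expect_equal(search_levenshtein("ACNT", "ACGT", k = 0)$edits, 0L)
  # N in the text
  expect_equal(search_levenshtein("ACGT", "ANGT", k = 0)$edits, 0L)
  # wildcards disabled
  expect_equal(nrow(search_levenshtein("ACNT", "ACGT", k = 0,
                                       wildcards = "")), 0L)
  expect_equal(search_hamming_bitap("ACNT", "ACGT", k = 0)$edits, 0L)

  # 3' overlap: pattern tail hangs past the text end for free
  m <- search_levenshtein("ACGT", "GGAC", k = 0, overlap = "end")
  expect_true(any(m$end == 4 & m$edits == 0 & m$start == 2))
  # min_overlap limits how little of the pattern must remain in-text
  m <- search_levenshtein("ACGT", "GGGA", k = 0, overlap = "end",
                          min_overlap = 2)
  expect_false(any(m$edits == 0))
  # 5' overlap: pattern head hangs before the text start
  m <- search_levenshtein("ACGT", "GTGG", k = 0, overlap = "start")
  expect_true(any(m$end == 2 & m$edits == 0 & m$start == 0))
})

test_that("auto n-gram sizing solves the length inequality", {
  expect_identical(max_ngram_size(30, 1), 15L)
  expect_identical(max_ngram_size(8, 1), 4L)
  for (L in c(1, 2, 5, 17, 30)) {
    expect_identical(max_ngram_size(L, 0), as.integer(L))
  }
  expect_identical(max_ngram_size(1, 1), 0L)  # filter unusable
  # property: returned n satisfies the inequality, n + 1 does not
  for (L in 1:40) {
    for (k in 0:3) {
      n <- max_ngram_size(L, k)
      if (n > 0) expect_true(n < (L - k) / (k + 1) + 1)
      expect_false((n + 1) < (L - k) / (k + 1) + 1)
    }
  }
})

test_that("the n-gram filter eliminates only provably absent subpatterns", {
  # a subpattern occurring verbatim survives any valid size
  T <- "GGGGACGTACGTGGGG"
  for (n in 1:4) {
    expect_true(0L %in% ngram_filter("ACGTACGT", T, k = 1, n = n))
  }
  # |P|=8, k=1, n=4 permits elimination when no 4-gram occurs
  expect_equal(length(ngram_filter("ACGTACGT", "GGGGGGGGGGGG", k = 1, n = 4)),
               0L)
  # a subpattern failing the length inequality always survives
  expect_equal(ngram_filter("ACGTACG", "GGGGGGGGGGGG", k = 1, n = 4), 0L)
  # wildcards disable elimination
  expect_equal(ngram_filter("ACGTNCGT", "GGGGGGGGGGGG", k = 1, n = 4), 0L)
  expect_equal(ngram_filter("ACGTACGT", "GGGGNGGGGGGG", k = 1, n = 4), 0L)

  # soundness sweep: a subpattern with a <= k-edit occurrence survives
  # whenever the length inequality holds
  set.seed(107)
  for (rep in 1:200) {
    P <- rseq(sample(4:10, 1), c("A", "C"))
    T <- rseq(sample(4:14, 1), c("A", "C"))
    k <- sample(0:2, 1)
    n <- sample(1:4, 1)
    if (nchar(P) <= (k + 1) * (n - 1) + k) next
    present <- min(substring_scan_oracle(P, T, lev_dist)) <= k
    if (present) {
      expect_true(0L %in% ngram_filter(P, T, k = k, n = n),
                  info = sprintf("P=%s T=%s k=%d n=%d", P, T, k, n))
    }
  }
})

test_that("candidate ordering is deterministic and filter-transparent", {
  p <- fuzzy_pattern(c("ACGTACGT", "TTGGCCAA"), edits = 1)
  T <- paste0("GG", "ACGTACGT", "TTTTTTTT")
  got <- best_subpattern_match(p, T)
  # ordered by ascending end, then edits, then subpattern index
  expect_true(!is.unsorted(got$end))
  for (e in unique(got$end)) {
    sub <- got[got$end == e, ]
    expect_true(!is.unsorted(sub$edits))
  }
  # the exact occurrence is ranked first at its end position
  at8 <- got[got$end == 10, ]
  expect_equal(at8$subpattern_idx[1], 0L)
  expect_equal(at8$edits[1], 0L)

  # two subpatterns within k at the same end: the 0-edit one wins
  p2 <- fuzzy_pattern(c("ACGA", "ACGT"), edits = 1)
  got2 <- best_subpattern_match(p2, "ACGT")
  full <- got2[got2$end == 4, ]
  expect_equal(full$subpattern_idx[1], 1L)
  expect_equal(full$edits[1], 0L)

  # the n-gram filter never changes the candidate list
  set.seed(108)
  for (rep in 1:40) {
    seqs <- vapply(1:3, function(i) rseq(sample(4:8, 1)), "")
    txt <- rseq(20)
    pf <- fuzzy_pattern(seqs, edits = 1, ngrams = "auto")
    pn <- fuzzy_pattern(seqs, edits = 1, ngrams = 0)
    expect_identical(best_subpattern_match(pf, txt),
                     best_subpattern_match(pn, txt))
  }

  # from= offsets results into text coordinates
  off <- best_subpattern_match(p, T, from = 2)
  expect_true(all(off$start >= 2))
  expect_true(any(off$start == 2 & off$edits == 0))
})
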