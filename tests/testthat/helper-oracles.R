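# Independent reference implementations used as test oracles.  These are
# deliberately naive (textbook DP / exhaustive enumeration) and share no
# code with the package's searchers.

rseq <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n == 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Textbook restricted Damerau-Levenshtein (optimal string alignment).
osa_dist <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j] + cost, d[i, j + 1] + 1L,
                             d[i + 1, j] + 1L)
      if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# Per-end minimal distance of P against every substring of T ending at i,
# for each end i in 0..nchar(T).  dist_fun(P, substring) is the metric.
substring_scan_oracle <- function(P, T, dist_fun) {
  n <- nchar(T)
  vapply(0:n, function(i) {
    min(vapply(0:i, function(a) dist_fun(P, substr(T, a + 1, i)), 1))
  }, 1)
}

lev_dist <- function(a, b) as.integer(utils::adist(a, b))

hamming_windows_oracle <- function(P, T) {
  m <- nchar(P)
  n <- nchar(T)
  if (n < m) return(matrix(0L, 0, 3))
  pc <- strsplit(P, "")[[1]]
  out <- lapply(0:(n - m), function(a) {
    mm <- sum(pc != strsplit(substr(T, a + 1, a + m), "")[[1]])
    c(a, a + m, mm)
  })
  do.call(rbind, out)
}

# Compare a searcher's (end, edits) pairs with the per-end oracle at
# budget k; also check every reported span really has the reported
# distance under dist_fun.
expect_matches_oracle <- function(got, P, T, k, dist_fun) {
  dmin <- substring_scan_oracle(P, T, dist_fun)
  for (i in 0:nchar(T)) {
    row <- got[got$end == i, , drop = FALSE]
    if (dmin[i + 1] <= k) {
      expect_equal(nrow(row), 1L,
                   info = sprintf("P=%s T=%s k=%d end=%d", P, T, k, i))
      expect_equal(row$edits, dmin[i + 1],
                   info = sprintf("P=%s T=%s k=%d end=%d", P, T, k, i))
      expect_equal(dist_fun(P, substr(T, row$start + 1, row$end)),
                   row$edits,
                   info = sprintf("span P=%s T=%s k=%d end=%d", P, T, k, i))
    } else {
      expect_equal(nrow(row), 0L,
                   info = sprintf("P=%s T=%s k=%d end=%d", P, T, k, i))
    }
  }
}

# Exhaustive strings over an alphabet, lengths 0..max_len (or 1..max_len).
all_strings <- function(max_len, alphabet, min_len = 0) {
  out <- character(0)
  if (min_len == 0) out <- ""
  for (len in seq_len(max_len)) {
    if (len < min_len) next
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# Brute-force segmentation oracle for interval-length wildcard chains:
# can patterns (list of list(min, max, chars) with chars NULL = universal)
# split `text` into in-order runs?
segmentation_oracle <- function(patterns, text) {
  rec <- function(pi, from) {
    if (pi > length(patterns)) return(from == nchar(text) + 1)
    p <- patterns[[pi]]
    maxlen <- min(p$max, nchar(text) - from + 1)
    if (maxlen < p$min) return(FALSE)
    for (len in p$min:maxlen) {
      ok <- TRUE
      if (len > 0 && !is.null(p$chars)) {
        seg <- substr(text, from, from + len - 1)
        ok <- all(strsplit(seg, "")[[1]] %in% p$chars)
      }
      if (ok && rec(pi + 1, from + len)) return(TRUE)
    }
    FALSE
  }
  rec(1, 1)
}

# Naive cubic recursion (window sum over the previous pattern's ends with
# an explicit character check), memoized.
naive_interval_f <- function(patterns, text) {
  n <- nchar(text)
  np <- length(patterns)
  chars <- strsplit(text, "")[[1]]
  f <- matrix(NA, n + 1, np + 1)
  f[1, 1] <- TRUE
  if (n > 0) f[2:(n + 1), 1] <- FALSE
  for (j in seq_len(np)) {
    p <- patterns[[j]]
    for (i in 0:n) {
      acc <- FALSE
      lo <- max(0, i - min(p$max, i))
      hi <- i - p$min
      if (hi >= lo) {
        for (s in lo:hi) {
          seg_ok <- TRUE
          if (s < i && !is.null(p$chars)) {
            seg_ok <- all(chars[(s + 1):i] %in% p$chars)
          }
          if (seg_ok && f[s + 1, j]) { acc <- TRUE; break }
        }
      }
      f[i + 1, j + 1] <- acc
    }
  }
  f[n + 1, np + 1]
}

# Convert plain pattern descriptions to interval_wildcard objects.
as_interval_patterns <- function(patterns) {
  lapply(patterns, function(p) {
    interval_wildcard(min = p$min,
                      max = if (is.finite(p$max)) p$max else Inf,
                      pattern = if (is.null(p$chars)) NULL
                                else paste(p$chars, collapse = ""))
  })
}

# Random interval-chain instance over a small alphabet.
random_interval_instance <- function(alphabet = c("a", "b", "c")) {
  np <- sample(0:3, 1)
  patterns <- lapply(seq_len(np), function(i) {
    mn <- sample(0:3, 1)
    mx <- mn + sample(0:3, 1)
    chars <- if (runif(1) < 0.3) NULL
             else sample(alphabet, sample(1:length(alphabet), 1))
    list(min = mn, max = mx, chars = chars)
  })
  text <- rseq(sample(0:7, 1), alphabet)
  list(patterns = patterns, text = text)
}
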