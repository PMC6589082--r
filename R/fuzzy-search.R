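#' Approximate subpattern search
#'
#' Find all approximate occurrences of a subpattern `P` in a text line `T`.
#' Matching is semi-global: the whole subpattern is aligned against any
#' substring of the text, and for every text end position whose best
#' alignment is within `k` edits one match is reported.  The match start is
#' recovered so that length information is retained (this is why the banded
#' DP is used rather than bit-vector edit-distance techniques); among
#' minimal-edit alignments the longest text span is chosen (traceback
#' preference diagonal > vertical > horizontal).
#'
#' * `search_levenshtein()`: insertions, deletions, substitutions, each one
#'   edit; Ukkonen's cutoff heuristic prunes DP rows that cannot return
#'   under budget, for an expected `O(k |T|)` run time, without changing any
#'   result.
#' * `search_damerau()`: additionally allows adjacent transpositions at one
#'   edit (restricted variant / optimal string alignment: each character
#'   takes part in at most one transposition).
#' * `search_hamming_bitap()`: substitutions only, via the bit-parallel
#'   Bitap algorithm with `k + 1` state vectors; masks are split across
#'   `ceiling(|P| / word_width)` machine words, worst case
#'   `O(k |T| ceiling(|P|/w))`.  Match length is always `|P|`.
#'
#' Wildcard characters (default `"N"`) match anything at zero cost whether
#' they occur in the pattern or in the text.  With `overlap`, pattern
#' characters hanging past the corresponding text boundary cost nothing
#' (at least `min_overlap` pattern characters must stay inside the text).
#'
#' All coordinates are 0-based, half-open `[start, end)`.
#'
#' @param pattern Subpattern string (length >= 1).
#' @param text Text line to search.
#' @param k Maximum number of edits (>= 0).
#' @param overlap `"none"`, `"start"`, `"end"`, or `"both"`.
#' @param min_overlap Minimum in-text pattern characters when overlapping.
#' @param wildcards String of wildcard characters (`""` for none).
#' @param cutoff Use the cutoff heuristic (results are identical either
#'   way; exposed for verification).
#' @param anchored Constrain every alignment to start at the beginning of
#'   `text` (`d(i, 0) = i` instead of 0).  The line matcher uses this when
#'   a pattern's start position is pinned -- by an empty preceding interval
#'   chunk or by the previous pattern of its chunk -- so that a within-`k`
#'   alignment at the pinned start is found even when a cheaper shifted
#'   alignment ends at the same position.
#' @param word_width Bits per machine word for the Bitap searcher (1--64;
#'   default 63).
#' @return A data frame with columns `start`, `end`, `edits`, `length`,
#'   one row per matching end position (possibly zero rows).
#' @examples
#' search_levenshtein("ACGT", "TTACGTTT", k = 1)
#' search_damerau("ACGT", "ACTG", k = 1)
#' search_hamming_bitap("ACGT", "AACGTT", k = 0)
#' @export
search_levenshtein <- function(pattern, text, k, overlap = "none",
                               min_overlap = 1L, wildcards = "N",
                               cutoff = TRUE, anchored = FALSE) {
  edit_search_df(pattern, text, k, FALSE, overlap, min_overlap, wildcards,
                 cutoff, anchored)
}

#' @rdname search_levenshtein
#' @export
search_damerau <- function(pattern, text, k, overlap = "none",
                           min_overlap = 1L, wildcards = "N",
                           cutoff = TRUE, anchored = FALSE) {
  edit_search_df(pattern, text, k, TRUE, overlap, min_overlap, wildcards,
                 cutoff, anchored)
}

edit_search_df <- function(pattern, text, k, transpositions, overlap,
                           min_overlap, wildcards, cutoff,
                           anchored = FALSE) {
  stopifnot(is.character(pattern), nchar(pattern) >= 1L, k >= 0L,
            min_overlap >= 1L)
  overlap <- match.arg(overlap, c("none", "start", "end", "both"))
  m <- cpp_edit_search(pattern, text, as.integer(k), transpositions,
                       overlap %in% c("start", "both"),
                       overlap %in% c("end", "both"),
                       as.integer(min_overlap), wildcards, cutoff, anchored)
  match_df(m)
}

#' @rdname search_levenshtein
#' @export
search_hamming_bitap <- function(pattern, text, k, word_width = 63L,
                                 wildcards = "N") {
  stopifnot(is.character(pattern), nchar(pattern) >= 1L, k >= 0L,
            word_width >= 1L, word_width <= 64L)
  m <- cpp_bitap_search(pattern, text, as.integer(k),
                        as.integer(word_width), wildcards)
  match_df(m)
}

match_df <- function(m, idx = FALSE) {
  col <- function(name) as.vector(m[, name])
  if (idx) {
    data.frame(subpattern_idx = col("idx"), start = col("start"),
               end = col("end"), edits = col("edits"),
               length = col("end") - col("start"))
  } else {
    data.frame(start = col("start"), end = col("end"), edits = col("edits"),
               length = col("end") - col("start"))
  }
}

#' Number of mask words used by the Bitap searcher
#'
#' @param pattern_len Subpattern length.
#' @param word_width Bits per machine word.
#' @return `ceiling(pattern_len / word_width)`.
#' @examples
#' bitap_word_count(100, 63)  # 2
#' @export
bitap_word_count <- function(pattern_len, word_width = 63L) {
  stopifnot(pattern_len >= 1L, word_width >= 1L)
  as.integer(ceiling(pattern_len / word_width))
}

#' n-gram pre-elimination of subpatterns
#'
#' Before running an edit-distance search, subpatterns that cannot possibly
#' match are eliminated by the q-gram argument: if a subpattern `P` occurs
#' in the text within `k` edits and `|P| > (k + 1)(n - 1) + k`, then at
#' least one of its overlapping n-grams occurs verbatim in the text (the
#' worst case spaces the k edits evenly, cutting the occurrence into pieces
#' one character short of an n-gram).  A subpattern is therefore dropped
#' only when that length inequality holds *and* none of its n-grams occurs
#' in the text; short subpatterns always survive, as do subpatterns and
#' texts containing wildcard characters (wildcards are not represented in
#' n-grams).
#'
#' `max_ngram_size()` gives the largest usable size for one subpattern,
#' i.e. the largest integer `n` with `n < (|P| - k)/(k + 1) + 1`; longer
#' n-grams are rarer in the text, so larger is better.  When several
#' subpatterns share a filter the minimum of their maximum sizes is used
#' (see [best_subpattern_match()]).
#'
#' @param pattern_len Subpattern length `|P|`.
#' @param k Maximum number of edits.
#' @return `max_ngram_size()`: the size, or 0 when no positive size
#'   qualifies (filter unusable).
#' @examples
#' max_ngram_size(30, 1)  # 15: the default for a 30-nt adapter at one edit
#' max_ngram_size(8, 1)   # 4
#' @export
max_ngram_size <- function(pattern_len, k) {
  pattern_len <- as.integer(pattern_len)
  k <- as.integer(k)
  stopifnot(pattern_len >= 1L, k >= 0L)
  # largest n with n < (|P| + 1) / (k + 1)
  n <- (pattern_len + 1L) %/% (k + 1L)
  if ((pattern_len + 1L) %% (k + 1L) == 0L) n <- n - 1L
  max(n, 0L)
}

#' @rdname max_ngram_size
#' @param subpatterns Character vector of subpattern sequences (or a
#'   subpattern list).
#' @param text Text line.
#' @param n n-gram size (>= 1).
#' @param wildcards Wildcard characters (subpatterns or texts containing
#'   them always survive).
#' @return `ngram_filter()`: the 0-based indices of surviving subpatterns.
#' @export
ngram_filter <- function(subpatterns, text, k, n, wildcards = "N") {
  if (inherits(subpatterns, "subpattern_list")) {
    subpatterns <- subpatterns$sequence
  }
  stopifnot(n >= 1L, k >= 0L)
  keep <- cpp_ngram_survivors(subpatterns, text, as.integer(k),
                              as.integer(n), wildcards)
  which(keep) - 1L
}

#' Candidate matches of a fuzzy pattern
#'
#' Runs the metric-appropriate searcher for every subpattern of a fuzzy
#' pattern over `text[from:]`, after n-gram pre-elimination, and returns all
#' candidate matches ordered by ascending end position, then ascending
#' edits, then ascending subpattern index -- the deterministic order in
#' which the greedy line matcher tries candidates.
#'
#' With `ngrams = "auto"` the filter size is the minimum over subpatterns of
#' [max_ngram_size()], so the one size is valid for every subpattern; auto
#' is disabled (size 0) when any subpattern contains a wildcard character.
#'
#' @param pattern A [fuzzy_pattern()] whose subpatterns are concrete (a
#'   resolved subpattern list, not an unresolved file reference).
#' @param text Text line.
#' @param from 0-based text index at which the search window starts.
#' @param anchored Constrain alignments to start exactly at `from` (see
#'   [search_levenshtein()]).
#' @return A data frame with columns `subpattern_idx` (0-based), `start`,
#'   `end`, `edits`, `length`.
#' @examples
#' p <- fuzzy_pattern(c("ACGTACGT", "TTGGCCAA"), edits = 1)
#' best_subpattern_match(p, "GGACGTACGTTT")
#' @export
best_subpattern_match <- function(pattern, text, from = 0L,
                                  anchored = FALSE) {
  stopifnot(inherits(pattern, "fuzzy_pattern"))
  subs <- pattern$subpatterns
  if (!inherits(subs, "subpattern_list")) {
    stop("fuzzy pattern subpatterns are not resolved; resolve the file ",
         "reference first (see resolve_value)", call. = FALSE)
  }
  from <- as.integer(from)
  stopifnot(from >= 0L, from <= nchar(text))
  win <- if (from > 0L) substr(text, from + 1L, nchar(text)) else text
  n <- auto_ngram_size(pattern)
  metric <- match(pattern$metric, c("hamming", "levenshtein", "damerau")) - 1L
  m <- cpp_multi_search(subs$sequence, win, pattern$k, metric, n,
                        pattern$overlap %in% c("start", "both"),
                        pattern$overlap %in% c("end", "both"),
                        pattern$min_overlap, pattern$word_width,
                        pattern$wildcards, TRUE, anchored)
  out <- match_df(m, idx = TRUE)
  if (from > 0L && nrow(out)) {
    out$start <- out$start + from
    out$end <- out$end + from
  }
  out
}

# Effective n-gram size for a fuzzy pattern (0 = filter disabled).
auto_ngram_size <- function(pattern) {
  if (!identical(pattern$ngrams, "auto")) return(as.integer(pattern$ngrams))
  seqs <- pattern$subpatterns$sequence
  if (nzchar(pattern$wildcards) &&
      any(grepl(paste0("[", gsub("([]\\^-])", "\\\\\\1", pattern$wildcards),
                       "]"), seqs))) {
    return(0L)
  }
  min(vapply(nchar(seqs), max_ngram_size, 1L, k = pattern$k))
}
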