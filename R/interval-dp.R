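#' Fixed-length wildcard matching
#'
#' A fixed-length wildcard pattern matches a window of exactly `length`
#' characters, all from the pattern's character class, by simulating a
#' sliding window; `match_fixed()` tests one window position.
#'
#' @param pattern A [fixed_wildcard()].
#' @param text Text line.
#' @param at 0-based window start.
#' @param vars,overlay Variable store (and in-flight bindings) used to
#'   resolve a `length = %name.length%` reference.
#' @return `TRUE` iff `at + length <= nchar(text)` and every character of
#'   the window is allowed.
#' @examples
#' match_fixed(fixed_wildcard(3), "abcd", 0)  # TRUE
#' match_fixed(fixed_wildcard(3), "abcd", 2)  # FALSE: window does not fit
#' match_fixed(fixed_wildcard(2, pattern = "0-9"), "a12b", 1)
#' @export
match_fixed <- function(pattern, text, at, vars = NULL, overlay = NULL) {
  stopifnot(inherits(pattern, "fixed_wildcard"))
  at <- as.integer(at)
  stopifnot(at >= 0L, at <= nchar(text))
  len <- resolve_fixed_length(pattern, vars, overlay)
  if (at + len > nchar(text)) return(FALSE)
  cc_allows(pattern$char_class, substr(text, at + 1L, at + len))
}

resolve_fixed_length <- function(pattern, vars = NULL, overlay = NULL) {
  len <- pattern$length
  if (is_value_expr(len)) {
    if (len$kind != "variable_ref") {
      stop("fixed-length wildcard length must be an integer or a variable ",
           "reference", call. = FALSE)
    }
    parts <- strsplit(len$payload, ".", fixed = TRUE)[[1]]
    len <- var_get(vars, parts[1], parts[2], overlay = overlay)
  }
  len <- as.integer(len)
  if (is.na(len) || len < 1L) {
    stop("fixed-length wildcard: resolved length must be >= 1, got ", len,
         call. = FALSE)
  }
  len
}

#' Interval-length wildcard chains: prefix-sum dynamic program
#'
#' A chain of interval-length wildcard patterns matches a text segment iff
#' the patterns can partition it into contiguous, non-overlapping, in-order
#' runs, each run's length within its pattern's `[min, max]` and all its
#' characters allowed by that pattern's class.  Writing `f(i, j)` for
#' "patterns `1..j` match the first `i` segment characters" gives the
#' recursion `f(0, 0) = 1`,
#' `f(i, j) = sum over s in [i - max_j, i - min_j] of f(s, j - 1) *
#' [characters s+1..i all allowed by pattern j]`.
#' Two precomputations reduce the naive cubic cost to `O(|patterns| * |T|)`:
#' `l(i, j)`, the longest allowed run ending at `i` for pattern `j`, limits
#' where pattern `j` can start, and per-pattern prefix sums
#' `p(i, j) = p(i-1, j) + f(i, j)` turn the window sum into
#' `f(i, j) = p(i - min_j, j-1) - p(max(i - max_j, i - l(i,j)) - 1, j-1)`
#' with out-of-range prefix indices contributing zero.  `f` is kept
#' saturated at 0/1 (only `f != 0` is ever queried, and saturation keeps
#' the counts from overflowing).
#'
#' The DP state is anchored at a text index and filled left to right; the
#' frontier can be *extended* without recomputing earlier cells, which is
#' what makes the greedy line matcher's interval-chunk cache work (the
#' chunk's start never moves, only the queried end grows).
#'
#' @param patterns List of [interval_wildcard()] patterns (may be empty:
#'   the empty chain matches only the empty segment).
#' @param text Text line.
#' @param anchor 0-based text index where the segment starts.
#' @return `interval_dp()` returns an `interval_dp_state` environment.
#' @examples
#' st <- interval_dp(list(interval_wildcard(0, 3, pattern = "A-Z")), "ABCD")
#' match_interval_chunk(st, 3)  # "ABC" -> TRUE
#' match_interval_chunk(st, 4)  # "ABCD" -> FALSE (longer than max)
#' @export
interval_dp <- function(patterns, text, anchor = 0L) {
  stopifnot(is.list(patterns),
            all(vapply(patterns, inherits, TRUE, "interval_wildcard")))
  anchor <- as.integer(anchor)
  n <- nchar(text)
  stopifnot(anchor >= 0L, anchor <= n)
  np <- length(patterns)
  cap <- n - anchor
  state <- new.env(parent = emptyenv())
  state$patterns <- patterns
  state$minv <- vapply(patterns, function(p) p$min_len, 1L)
  state$maxv <- vapply(patterns, function(p) {
    if (is.infinite(p$max_len)) NA_integer_ else as.integer(p$max_len)
  }, 1L)
  state$text <- text
  state$anchor <- anchor
  state$frontier <- 0L
  state$cells <- 0L  # computed-cell counter (complexity guard)
  # rows 1..cap+1 are segment offsets 0..cap; cols 1..np+1 are patterns 0..np
  state$f <- matrix(NA_integer_, nrow = cap + 1L, ncol = np + 1L)
  state$p <- matrix(NA_integer_, nrow = cap + 1L, ncol = np + 1L)
  state$l <- matrix(NA_integer_, nrow = cap + 1L, ncol = np + 1L)
  state$f[1L, ] <- c(1L, rep(0L, np))
  # pattern j matches the empty segment iff min_j == 0 and patterns 1..j-1
  # also match it, so f(0, j) cascades along zero-minimum prefixes
  if (np >= 1L) {
    for (j in seq_len(np)) {
      state$f[1L, j + 1L] <-
        if (state$minv[j] == 0L) state$f[1L, j] else 0L
    }
  }
  state$p[1L, ] <- state$f[1L, ]
  state$l[1L, ] <- 0L
  # per-pattern allowed-character lookup over the whole tail (computed once)
  if (cap > 0L && np > 0L) {
    seg <- substr(text, anchor + 1L, n)
    state$allow <- vapply(patterns,
                          function(p) cc_allow_vec(p$char_class, seg),
                          logical(cap))
    if (cap == 1L) state$allow <- matrix(state$allow, nrow = 1L)
  } else {
    state$allow <- matrix(logical(0), nrow = cap, ncol = np)
  }
  class(state) <- "interval_dp_state"
  state
}

#' @rdname interval_dp
#' @param state An `interval_dp_state`.
#' @param new_frontier Segment length (in characters past the anchor) up to
#'   which the tables must be filled; must not shrink and must not pass the
#'   end of the text.  Cells computed before an extension are never
#'   recomputed or changed.
#' @return `extend_frontier()` returns the state, invisibly.
#' @export
extend_frontier <- function(state, new_frontier) {
  stopifnot(inherits(state, "interval_dp_state"))
  new_frontier <- as.integer(new_frontier)
  if (new_frontier < state$frontier) {
    stop("frontier cannot shrink (", new_frontier, " < ", state$frontier,
         ")", call. = FALSE)
  }
  cap <- nchar(state$text) - state$anchor
  if (new_frontier > cap) {
    stop("frontier ", new_frontier, " exceeds the text end (segment length ",
         cap, ")", call. = FALSE)
  }
  if (new_frontier == state$frontier) return(invisible(state))
  np <- length(state$patterns)
  minv <- state$minv
  maxv <- state$maxv
  for (i in (state$frontier + 1L):new_frontier) {
    r <- i + 1L
    state$f[r, 1L] <- 0L
    state$p[r, 1L] <- state$p[r - 1L, 1L]
    state$l[r, 1L] <- 0L
    for (j in seq_len(np)) {
      cj <- j + 1L
      lv <- if (state$allow[i, j]) state$l[r - 1L, cj] + 1L else 0L
      state$l[r, cj] <- lv
      hi <- i - minv[j]                      # window top: p(i - min_j, j-1)
      lo <- max(if (is.na(maxv[j])) 0L else i - maxv[j], i - lv)
      fv <- 0L
      if (hi >= lo && hi >= 0L) {
        top <- state$p[hi + 1L, cj - 1L]
        bot <- if (lo >= 1L) state$p[lo, cj - 1L] else 0L
        fv <- if (top - bot > 0L) 1L else 0L
      }
      state$f[r, cj] <- fv
      state$p[r, cj] <- min(state$p[r - 1L, cj] + fv, .Machine$integer.max)
    }
    state$cells <- state$cells + np + 1L
  }
  state$frontier <- new_frontier
  invisible(state)
}

#' @rdname interval_dp
#' @param end 0-based text index (exclusive) of the queried segment end;
#'   `anchor <= end <= nchar(text)`.  The frontier is extended on demand;
#'   re-querying never grows the tables.
#' @return `match_interval_chunk()`: `TRUE` iff the whole pattern chain
#'   matches `text[anchor:end]`.
#' @export
match_interval_chunk <- function(state, end) {
  stopifnot(inherits(state, "interval_dp_state"))
  end <- as.integer(end)
  stopifnot(end >= state$anchor, end <= nchar(state$text))
  i <- end - state$anchor
  if (i > state$frontier) extend_frontier(state, i)
  state$f[i + 1L, length(state$patterns) + 1L] != 0L
}

#' @export
print.interval_dp_state <- function(x, ...) {
  cat("<interval_dp_state: ", length(x$patterns), " pattern(s), anchor ",
      x$anchor, ", frontier ", x$frontier, "/", nchar(x$text) - x$anchor,
      ">\n", sep = "")
  invisible(x)
}
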