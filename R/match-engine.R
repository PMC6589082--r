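#' Partition a line's patterns into alternating chunks
#'
#' The line matcher works on *chunks*: maximal runs of interval-length
#' patterns alternate with maximal runs of fixed-length patterns (fuzzy
#' patterns and fixed-length wildcards both have a determinable length, so
#' they share a chunk type).  An empty interval chunk is inserted in front
#' when the line starts with a fixed-length pattern, anchoring that chunk
#' at the line start; likewise the matcher treats a line that ends with a
#' fixed chunk as having an empty trailing interval chunk, anchoring it at
#' the line end.
#'
#' @param patterns Non-empty list of `template_pattern` objects.
#' @return A list of chunks, each `list(kind = "interval"|"fixed",
#'   idx = <0-based positions in `patterns`>)`, strictly alternating and
#'   starting with an interval chunk.
#' @examples
#' pats <- list(interval_wildcard(), fuzzy_pattern("ACGT"), interval_wildcard())
#' vapply(partition_chunks(pats), `[[`, "", "kind")
#' @export
partition_chunks <- function(patterns) {
  stopifnot(is.list(patterns), length(patterns) >= 1L)
  kinds <- vapply(patterns, function(p) p$kind, "")
  grp <- ifelse(kinds == "interval", "interval", "fixed")
  chunks <- list()
  if (grp[1] != "interval") {
    chunks[[1]] <- list(kind = "interval", idx = integer(0))
  }
  r <- rle(grp)
  pos <- 0L
  for (i in seq_along(r$lengths)) {
    idx <- pos + seq_len(r$lengths[i])
    chunks[[length(chunks) + 1L]] <- list(kind = r$values[i], idx = idx - 1L)
    pos <- pos + r$lengths[i]
  }
  chunks
}

#' Match one line of text against its template patterns
#'
#' Implements the greedy chunked algorithm.  For each (interval chunk,
#' fixed chunk) pair in order: candidate locations of a *starting pattern*
#' are searched in the text after the current cursor -- the starting
#' pattern iterates over the chunk's leading non-required patterns plus its
#' first required one.  For each candidate (in ascending end, then edits,
#' then subpattern index order) the remaining patterns of the chunk are
#' matched consecutively from the candidate's end (greedy, no backtracking;
#' a fuzzy pattern takes its lowest-edit candidate at that position), and
#' the candidate is accepted iff the preceding interval chunk matches the
#' text between the cursor and the candidate's start.  On acceptance the
#' cursor jumps to the chunk's end and never backtracks.  A fixed chunk
#' whose patterns are all optional and never match is skipped, its flanking
#' interval chunks merged.  After the last fixed chunk the trailing
#' interval chunk must match the remaining text.  Matching fails as soon as
#' a required pattern cannot be placed or a mandatory interval chunk fails.
#'
#' Greedy means not optimal by design: an early candidate can starve a
#' later chunk of text, in which case the line reports unmatched even
#' though an exhaustive segmentation would succeed.
#'
#' Two caches (both transparent to the result) speed up repeated work: the
#' outcome of matching each fixed-length pattern at each position, and the
#' interval-chunk DP state, which is extended rather than rebuilt as
#' candidate starts move right (the chunk's anchor never moves).
#'
#' Variables of named patterns are bound only if the whole line matches;
#' bindings become visible to later patterns on the same line while it is
#' being matched and are committed to `vars` on success.
#'
#' @param patterns List of `template_pattern` objects (one template line).
#' @param text The corresponding input line.
#' @param vars A [var_store()]; bindings from earlier lines are visible,
#'   and this line's bindings are committed into it on success.
#' @param lists Environment caching loaded list files.
#' @param base_dir Directory for relative list-file paths.
#' @param use_cache Disable to force fresh searches and DP states
#'   (results are identical; exposed for verification).
#' @return A `line_match` list: `matched`; `spans` (per pattern,
#'   0-based half-open `c(start, end)` or `NULL` for interval patterns and
#'   unmatched optionals); `chunk_spans` (per interval chunk: pattern
#'   indices and matched span); `trim_spans` (merged spans to delete);
#'   `bindings` (this line's new variable bindings).
#' @examples
#' pats <- parse_template(
#'   '{i}{f required, trim, name = "b", edits = 1, pattern = "ACGTACGT"}{i}'
#' )$lines[[1]]$patterns
#' vars <- var_store()
#' match_line(pats, "ACGTACGTGGGGTTTT", vars)$matched
#' var_get(vars, "b", "length")
#' @export
match_line <- function(patterns, text, vars = var_store(), lists = NULL,
                       base_dir = ".", use_cache = TRUE) {
  n <- nchar(text)
  npat <- length(patterns)
  if (isTRUE(attr(patterns, "trivial"))) {
    # a line of unrestricted {i} patterns matches anything
    return(structure(list(matched = TRUE, spans = vector("list", npat),
                          chunk_spans = list(list(idx = seq_len(npat) - 1L,
                                                  span = c(0L, n))),
                          trim_spans = matrix(integer(0), ncol = 2L),
                          bindings = list()),
                     class = "line_match"))
  }
  chunks <- attr(patterns, "partition")
  if (is.null(chunks)) chunks <- partition_chunks(patterns)
  unmatched <- structure(list(matched = FALSE,
                              spans = vector("list", npat),
                              chunk_spans = list(),
                              trim_spans = matrix(integer(0), ncol = 2L),
                              bindings = list()),
                         class = "line_match")

  st <- new.env(parent = emptyenv())
  st$overlay <- list()
  st$spans <- vector("list", npat)
  st$chunk_spans <- list()
  st$cursor <- 0L
  st$fixed_cache <- if (use_cache) new.env(parent = emptyenv()) else NULL
  st$use_cache <- use_cache

  pending <- integer(0)  # 0-based indices of interval patterns awaiting check
  for (ch in chunks) {
    if (ch$kind == "interval") {
      pending <- c(pending, ch$idx)
      next
    }
    res <- match_fixed_chunk(patterns, ch$idx, pending, text, st, vars,
                             lists, base_dir)
    if (identical(res, "fail")) return(unmatched)
    if (identical(res, "merge")) next  # all-optional chunk never matched
    pending <- integer(0)
  }
  # trailing interval chunk against the rest of the line
  if (!check_interval_chunk(patterns, pending, st$cursor, n, text, st)) {
    return(unmatched)
  }
  record_interval_span(patterns, pending, st$cursor, n, st)

  trim <- collect_trim_spans(patterns, st)
  for (nm in names(st$overlay)) bind_variables(nm, st$overlay[[nm]], vars)
  structure(list(matched = TRUE, spans = st$spans,
                 chunk_spans = st$chunk_spans, trim_spans = trim,
                 bindings = st$overlay),
            class = "line_match")
}

# One fixed chunk (indices `idx`) preceded by the interval patterns in
# `pending`.  Returns "fail", "merge", or "ok" (state updated in place).
match_fixed_chunk <- function(patterns, idx, pending, text, st, vars,
                              lists, base_dir) {
  n <- nchar(text)
  fp <- patterns[idx + 1L]
  req <- vapply(fp, function(p) isTRUE(p$required), TRUE)
  last_s <- if (any(req)) which(req)[1] else length(fp)

  anchored <- length(pending) == 0L
  for (s in seq_len(last_s)) {
    pat <- resolve_pattern(fp[[s]], vars, st$overlay, lists, base_dir)
    cands <- starting_candidates(pat, text, st$cursor, vars, st$overlay,
                                 anchored)
    for (ci in seq_len(nrow(cands))) {
      m_lo <- cands$start[ci]
      attempt <- match_chunk_remainder(patterns, idx, s, pat, cands[ci, ],
                                       text, st, vars, lists, base_dir)
      if (is.null(attempt)) next
      if (!check_interval_chunk(patterns, pending, st$cursor, m_lo, text,
                                st)) next
      # accept
      for (u in seq_along(attempt$spans)) {
        st$spans[[attempt$at[u]]] <- attempt$spans[[u]]
      }
      st$overlay <- attempt$overlay
      record_interval_span(patterns, pending, st$cursor, m_lo, st)
      st$cursor <- attempt$end
      return("ok")
    }
  }
  if (any(req)) "fail" else "merge"
}

# Match patterns s..end of the chunk: the starting candidate, then the rest
# consecutively from its end.  Returns NULL on failure, else
# list(end, spans, at (1-based pattern positions), overlay).
match_chunk_remainder <- function(patterns, idx, s, spat, cand, text, st,
                                  vars, lists, base_dir) {
  fp <- patterns[idx + 1L]
  overlay <- st$overlay
  spans <- list()
  at <- integer(0)
  pos <- cand$end
  add <- function(which_pat, span, binding) {
    spans[[length(spans) + 1L]] <<- span
    at[length(at) + 1L] <<- idx[which_pat] + 1L
    p <- fp[[which_pat]]
    if (!is.null(p$name)) {
      if (!is.null(overlay[[p$name]]) ||
          exists(p$name, envir = vars, inherits = FALSE)) {
        stop("variable '", p$name, "' is already bound in this record",
             call. = FALSE)
      }
      overlay[[p$name]] <<- binding
    }
  }
  add(s, c(cand$start, cand$end), candidate_binding(spat, cand))

  ni <- length(fp)
  if (s < ni) {
    for (u in (s + 1L):ni) {
      p <- fp[[u]]
      hit <- match_fixed_at(p, text, pos, st, vars, overlay, lists,
                            base_dir, idx[u])
      if (is.null(hit)) {
        if (isTRUE(p$required)) return(NULL)
        next  # unmatched optional: consumes nothing, binds nothing
      }
      add(u, c(hit$start, hit$end), candidate_binding(p, hit))
      pos <- hit$end
    }
  }
  list(end = pos, spans = spans, at = at, overlay = overlay)
}

# Match one fixed-length pattern anchored at `pos`.  Fuzzy patterns take
# their lowest-edit candidate among those starting exactly at `pos`.
# Returns list(start, end, ...) or NULL.  Cached per (pattern, position)
# when the pattern is static.
match_fixed_at <- function(p, text, pos, st, vars, overlay, lists,
                           base_dir, pat_idx0) {
  dynamic <- pattern_is_dynamic(p)
  key <- NULL
  if (!is.null(st$fixed_cache) && !dynamic) {
    key <- paste0(pat_idx0, ":", pos)
    if (exists(key, envir = st$fixed_cache, inherits = FALSE)) {
      return(get(key, envir = st$fixed_cache, inherits = FALSE))
    }
  }
  hit <- NULL
  if (p$kind == "fixed") {
    len <- resolve_fixed_length(p, vars, overlay)
    if (pos + len <= nchar(text) &&
        cc_allows(p$char_class, substr(text, pos + 1L, pos + len))) {
      hit <- list(start = pos, end = pos + len, edits = 0L,
                  subpattern_idx = NA_integer_)
    }
  } else {
    rp <- resolve_pattern(p, vars, overlay, lists, base_dir)
    cands <- best_subpattern_match(rp, text, from = pos, anchored = TRUE)
    if (nrow(cands)) {
      cands <- cands[order(cands$edits, cands$end, cands$subpattern_idx), ,
                     drop = FALSE]
      hit <- list(start = cands$start[1], end = cands$end[1],
                  edits = cands$edits[1],
                  subpattern_idx = cands$subpattern_idx[1],
                  resolved = rp)
    }
  }
  if (!is.null(key)) assign(key, hit, envir = st$fixed_cache)
  hit
}

# Candidate locations of a starting pattern in text[cursor:], ordered by
# ascending end, then edits, then subpattern index.  With `anchored` only
# alignments starting exactly at the cursor qualify.
starting_candidates <- function(pat, text, cursor, vars, overlay,
                                anchored = FALSE) {
  if (pat$kind == "fixed") {
    len <- resolve_fixed_length(pat, vars, overlay)
    n <- nchar(text)
    if (cursor + len > n) {
      return(data.frame(subpattern_idx = integer(0), start = integer(0),
                        end = integer(0), edits = integer(0)))
    }
    starts <- if (anchored) cursor else cursor:(n - len)
    if (!pat$char_class$universal) {
      bad <- cumsum(c(0L, !cc_allow_vec(pat$char_class, text)))
      ok <- bad[starts + len + 1L] - bad[starts + 1L] == 0L
      starts <- starts[ok]
    }
    data.frame(subpattern_idx = rep(NA_integer_, length(starts)),
               start = starts, end = starts + len,
               edits = rep(0L, length(starts)))
  } else {
    best_subpattern_match(pat, text, from = cursor, anchored = anchored)
  }
}

candidate_binding <- function(p, cand) {
  if (p$kind == "fixed") {
    list(length = cand$end - cand$start, pattern_idx = NA_integer_,
         pattern_name = NA_character_, edits = 0L)
  } else {
    rp <- if (!is.null(cand$resolved)) cand$resolved else p
    subs <- rp$subpatterns
    i0 <- cand$subpattern_idx
    offset <- attr(subs, "offset") %||% 0L
    list(length = cand$end - cand$start,
         pattern_idx = i0 + offset,
         pattern_name = if (inherits(subs, "data.frame")) subs$name[i0 + 1L]
                        else NA_character_,
         edits = cand$edits)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a fuzzy pattern's subpattern source (file references, possibly
# with a variable selector) into a concrete subpattern list.
resolve_pattern <- function(p, vars, overlay, lists, base_dir) {
  if (p$kind != "fuzzy" || !is_value_expr(p$subpatterns)) return(p)
  expr <- p$subpatterns
  if (expr$kind == "file_ref_selected" &&
      expr$selector$kind == "variable_ref") {
    parts <- strsplit(expr$selector$payload, ".", fixed = TRUE)[[1]]
    sel <- var_get(vars, parts[1], parts[2], overlay = overlay)
    lst <- load_list_file_cached(expr$payload, lists, base_dir)
    sel <- as.integer(sel)
    if (is.na(sel) || sel < 0L || sel >= nrow(lst)) {
      stop("selector ", sel, " out of range for list file '", expr$payload,
           "'", call. = FALSE)
    }
    out <- lst[sel + 1L, , drop = FALSE]
    attr(out, "offset") <- sel
    class(out) <- c("subpattern_list", "data.frame")
  } else {
    out <- resolve_value(expr, vars, lists, base_dir)
    if (expr$kind == "file_ref_selected") {
      attr(out, "offset") <- as.integer(resolve_value(expr$selector, vars,
                                                      lists, base_dir))
      class(out) <- c("subpattern_list", "data.frame")
    }
  }
  p$subpatterns <- out
  p
}

pattern_is_dynamic <- function(p) {
  if (p$kind == "fixed") return(is_value_expr(p$length))
  if (p$kind == "fuzzy") return(is_value_expr(p$subpatterns))
  FALSE
}

# Does the interval chunk `pending` (0-based pattern indices) match
# text[from:to]?  Uses the incremental DP state cached per chunk; chunks of
# unrestricted {i} patterns short-circuit.
check_interval_chunk <- function(patterns, pending, from, to, text, st) {
  if (to < from) return(FALSE)
  if (length(pending) == 0L) return(to == from)
  ip <- patterns[pending + 1L]
  if (all(vapply(ip, is_unbounded_universal, TRUE))) return(TRUE)
  key <- paste(pending, collapse = ",")
  state <- NULL
  if (st$use_cache) {
    if (is.null(st$interval_cache)) {
      st$interval_cache <- new.env(parent = emptyenv())
    }
    if (exists(key, envir = st$interval_cache, inherits = FALSE)) {
      state <- get(key, envir = st$interval_cache, inherits = FALSE)
      if (state$anchor != from) state <- NULL  # merged chunk moved anchors
    }
  }
  if (is.null(state)) {
    state <- interval_dp(ip, text, anchor = from)
    if (st$use_cache) assign(key, state, envir = st$interval_cache)
  }
  match_interval_chunk(state, to)
}

is_unbounded_universal <- function(p) {
  p$char_class$universal && p$min_len == 0L && is.infinite(p$max_len)
}

record_interval_span <- function(patterns, pending, from, to, st) {
  if (length(pending) == 0L) return(invisible())
  st$chunk_spans[[length(st$chunk_spans) + 1L]] <-
    list(idx = pending, span = c(from, to))
  if (length(pending) == 1L) {
    p <- patterns[[pending + 1L]]
    if (!is.null(p$name)) {
      if (!is.null(st$overlay[[p$name]])) {
        stop("variable '", p$name, "' is already bound in this record",
             call. = FALSE)
      }
      st$overlay[[p$name]] <- list(length = to - from,
                                   pattern_idx = NA_integer_,
                                   pattern_name = NA_character_,
                                   edits = 0L)
    }
  }
  invisible()
}

# Merge trim-flagged spans: fixed-kind pattern spans plus interval-chunk
# spans whose patterns are uniformly trim-flagged (a mixed chunk is
# rejected because individual interval patterns within a chunk have no
# identified span of their own).
collect_trim_spans <- function(patterns, st) {
  spans <- list()
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    if (p$kind != "interval" && isTRUE(p$trim) && !is.null(st$spans[[i]])) {
      spans[[length(spans) + 1L]] <- st$spans[[i]]
    }
  }
  for (cs in st$chunk_spans) {
    tr <- vapply(patterns[cs$idx + 1L], function(p) isTRUE(p$trim), TRUE)
    if (any(tr)) {
      if (!all(tr)) {
        stop("interval patterns within one chunk must either all carry ",
             "'trim' or none of them", call. = FALSE)
      }
      spans[[length(spans) + 1L]] <- cs$span
    }
  }
  if (!length(spans)) return(matrix(integer(0), ncol = 2L))
  m <- do.call(rbind, spans)
  m <- m[m[, 2L] > m[, 1L], , drop = FALSE]
  if (!nrow(m)) return(matrix(integer(0), ncol = 2L))
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L])) {
    stop("internal error: overlapping trim spans", call. = FALSE)
  }
  m
}

#' Remove trimmed spans from a line
#'
#' @param line The original text line.
#' @param result A matched `line_match` (see [match_line()]).
#' @return The line with every trim span deleted and the remaining
#'   characters concatenated in order.
#' @export
apply_trim <- function(line, result) {
  stopifnot(inherits(result, "line_match"))
  if (!result$matched) {
    stop("apply_trim needs a matched line result", call. = FALSE)
  }
  m <- result$trim_spans
  if (!nrow(m)) return(line)
  keep <- character(nrow(m) + 1L)
  pos <- 0L
  for (r in seq_len(nrow(m))) {
    keep[r] <- substr(line, pos + 1L, m[r, 1L])
    pos <- m[r, 2L]
  }
  keep[nrow(m) + 1L] <- substr(line, pos + 1L, nchar(line))
  paste(keep, collapse = "")
}

#' Match one record (a group of lines) against its templates
#'
#' Template lines are evaluated in processing order -- lines with an
#' explicit order index first (ascending), then unindexed lines in source
#' order -- sharing one variable store, so later lines (e.g. a quality line
#' trimming `%b.length%` characters, or a reverse-read template selecting
#' the barcode matched on the forward read) see earlier bindings.  The
#' record matches iff every line matches; trimming is applied only then,
#' and an unmatched record's output lines are the input lines, unmodified.
#'
#' @param templates A `template_spec`, or a list of them for multi-file
#'   (e.g. paired-end) input, order-aligned with `group`.
#' @param group A character vector of `group_size` lines, or a list of such
#'   vectors (one per input file).
#' @param vars Shared [var_store()] for the record.
#' @param lists List-file cache environment.
#' @param base_dir Directory for relative list-file paths.
#' @param use_cache See [match_line()].
#' @param schedule Precomputed processing order (internal; computed when
#'   `NULL`).
#' @return A `record_result` list: `matched`, `output_lines` (list per
#'   file), `line_results`, and `vars`.
#' @export
match_record <- function(templates, group, vars = var_store(),
                         lists = NULL, base_dir = ".", use_cache = TRUE,
                         schedule = NULL) {
  if (inherits(templates, "template_spec")) templates <- list(templates)
  if (!is.list(group) || is.character(group)) group <- list(group)
  stopifnot(length(templates) == length(group))
  for (fi in seq_along(templates)) {
    gs <- templates[[fi]]$group_size
    if (length(group[[fi]]) != gs) {
      stop("input ", fi, ": record has ", length(group[[fi]]),
           " line(s) but the template groups ", gs, call. = FALSE)
    }
  }
  sched <- schedule %||% line_schedule(templates)
  results <- lapply(templates, function(t) vector("list", t$group_size))
  matched <- TRUE
  for (r in seq_len(nrow(sched))) {
    fi <- sched$file[r]
    li <- sched$line[r]
    bd <- attr(templates[[fi]], "base_dir") %||% base_dir
    lr <- match_line(templates[[fi]]$lines[[li]]$patterns,
                     group[[fi]][li], vars, lists, bd, use_cache)
    results[[fi]][[li]] <- lr
    if (!lr$matched) { matched <- FALSE; break }
  }
  out <- group
  if (matched) {
    for (fi in seq_along(group)) {
      for (li in seq_along(group[[fi]])) {
        out[[fi]][li] <- apply_trim(group[[fi]][li], results[[fi]][[li]])
      }
    }
  }
  structure(list(matched = matched, output_lines = out,
                 line_results = results, vars = vars),
            class = "record_result")
}

# Processing order over all template lines of a set: explicit order indices
# ascending, then unindexed lines in (file, line) source order.
line_schedule <- function(templates) {
  rows <- do.call(rbind, lapply(seq_along(templates), function(fi) {
    t <- templates[[fi]]
    data.frame(file = fi, line = seq_len(t$group_size),
               ord = vapply(t$lines, function(l) {
                 if (is.na(l$order_index)) NA_integer_ else l$order_index
               }, 1L))
  }))
  withidx <- rows[!is.na(rows$ord), , drop = FALSE]
  if (anyDuplicated(withidx$ord)) {
    stop("duplicate order index across the template set", call. = FALSE)
  }
  rbind(withidx[order(withidx$ord), , drop = FALSE],
        rows[is.na(rows$ord), , drop = FALSE])
}

#' @export
print.line_match <- function(x, ...) {
  cat("<line_match: ", if (x$matched) "matched" else "unmatched", ">\n",
      sep = "")
  invisible(x)
}

#' @export
print.record_result <- function(x, ...) {
  cat("<record_result: ", if (x$matched) "matched" else "unmatched",
      ", ", length(x$output_lines), " file(s)>\n", sep = "")
  invisible(x)
}
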