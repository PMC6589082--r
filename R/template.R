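#' Parse a template file
#'
#' A template is a small declarative description of one record's layout:
#' one template line per input line, each line an ordered sequence of
#' brace-delimited patterns.  Because a template with `g` lines describes
#' `g` consecutive input lines, it is applied repeatedly to every group of
#' `g` lines of the input file (`g = 4` for FASTQ).
#'
#' Grammar (one line):
#'
#' ```
#' [order_index] {<kind> key = value, flag, ...}{<kind> ...}...
#' ```
#'
#' * `<kind>` is the first character of the token: `f` (fuzzy), `r`
#'   (fixed-length wildcard), `i` (interval-length wildcard).
#' * Parameters are comma-separated `key = value` pairs; `required` and
#'   `trim` are bare flags.  Values are integers, double-quoted strings,
#'   `f"path"` list-file references (optionally with a `[selector]`), or
#'   `%name.field%` variable references.
#' * A leading integer followed by whitespace is the line's processing
#'   order index; lines without an index are processed after all indexed
#'   lines, in source order.
#' * Lines starting with `#` are comments.
#'
#' Recognized keys -- `f`: `pattern` (mandatory), `edits`, `metric`
#' (`"hamming"`, `"levenshtein"`, `"damerau"`), `overlap` (`"start"`,
#' `"end"`, `"both"`, `"none"`), `min_overlap`, `ngrams` (`"auto"`, `"none"`
#' or a size), `words`, `wildcards`, `name`; `r`: `length` (mandatory),
#' `pattern` (a character-class range), `name`; `i`: `min`, `max`,
#' `pattern`, `name`.  Unknown keys and unknown pattern kinds are errors.
#'
#' @param text Template source as a single string or a character vector of
#'   lines.
#' @param path For `parse_template_file()`, a file to read.
#' @return A `template_spec`: list with `lines` (each a `template_line` with
#'   `order_index` and `patterns`) and `group_size` (number of template
#'   lines, i.e. input lines per record).
#' @examples
#' tpl <- parse_template(c(
#'   "{i}",
#'   '1 {f required, trim, name = "b", edits = 1, pattern = "ACGTACGT"}{i}',
#'   "{i}",
#'   "2 {r trim, length = %b.length%}{i}"))
#' tpl$group_size
#' @export
parse_template <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- sub("\r$", "", text)
  text <- text[!grepl("^\\s*#", text)]
  if (length(text) == 0L || all(!nzchar(trimws(text)))) {
    stop("empty template", call. = FALSE)
  }
  lines <- vector("list", length(text))
  for (li in seq_along(text)) {
    lines[[li]] <- parse_template_line(text[li], li)
  }
  idx <- vapply(lines, function(l) {
    if (is.na(l$order_index)) NA_integer_ else l$order_index
  }, 1L)
  dup <- idx[!is.na(idx)][duplicated(idx[!is.na(idx)])]
  if (length(dup)) {
    stop("duplicate order index ", dup[1], " in template", call. = FALSE)
  }
  structure(list(lines = lines, group_size = length(lines)),
            class = "template_spec")
}

#' @rdname parse_template
#' @export
parse_template_file <- function(path) {
  if (!file.exists(path)) stop("template file not found: ", path, call. = FALSE)
  spec <- parse_template(readLines(path, warn = FALSE))
  attr(spec, "base_dir") <- dirname(path)
  spec
}

parse_template_line <- function(line, lineno) {
  raw <- line
  order_index <- NA_integer_
  m <- regmatches(line, regexec("^\\s*([0-9]+)\\s+(.*)$", line))[[1]]
  if (length(m) == 3L) {
    order_index <- as.integer(m[2])
    line <- m[3]
  }
  tokens <- tokenize_braces(trimws(line), lineno)
  if (length(tokens) == 0L) {
    stop("template line ", lineno, " has no patterns: '", trimws(raw), "'",
         call. = FALSE)
  }
  patterns <- lapply(tokens, parse_pattern_token, lineno = lineno)
  structure(list(order_index = order_index, patterns = patterns),
            class = "template_line")
}

# Split a line into {...} tokens; '}' inside double quotes does not close a
# token.
tokenize_braces <- function(line, lineno) {
  chars <- strsplit(line, "")[[1]]
  tokens <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (grepl("^\\s$", chars[i])) { i <- i + 1L; next }
    if (chars[i] != "{") {
      stop("template line ", lineno, ": expected '{' at position ", i,
           " of '", line, "'", call. = FALSE)
    }
    j <- i + 1L
    in_quote <- FALSE
    while (j <= n && (in_quote || chars[j] != "}")) {
      if (chars[j] == '"') in_quote <- !in_quote
      j <- j + 1L
    }
    if (j > n) {
      stop("template line ", lineno, ": unterminated pattern token",
           call. = FALSE)
    }
    tokens <- c(tokens, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
    i <- j + 1L
  }
  tokens
}

# Split "key = value, flag, ..." on top-level commas (not inside quotes or
# selector brackets).
split_params <- function(body) {
  chars <- strsplit(body, "")[[1]]
  out <- character(0)
  buf <- character(0)
  in_quote <- FALSE
  depth <- 0L
  for (ch in chars) {
    if (ch == '"') in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
      if (ch == "," && depth == 0L) {
        out <- c(out, paste(buf, collapse = ""))
        buf <- character(0)
        next
      }
    }
    buf <- c(buf, ch)
  }
  out <- c(out, paste(buf, collapse = ""))
  trimws(out)
}

PATTERN_KEYS <- list(
  f = c("pattern", "edits", "metric", "overlap", "min_overlap", "ngrams",
        "words", "wildcards", "name", "required", "trim"),
  r = c("length", "pattern", "name", "required", "trim"),
  i = c("min", "max", "pattern", "name", "trim"))

parse_pattern_token <- function(token, lineno) {
  token <- trimws(token)
  if (!nzchar(token)) {
    stop("template line ", lineno, ": empty pattern token", call. = FALSE)
  }
  kind <- substr(token, 1L, 1L)
  if (!kind %in% names(PATTERN_KEYS)) {
    stop("template line ", lineno, ": unknown pattern type '", kind,
         "' (expected one of f, r, i)", call. = FALSE)
  }
  body <- trimws(substr(token, 2L, nchar(token)))
  params <- list()
  flags <- character(0)
  if (nzchar(body)) {
    for (piece in split_params(body)) {
      if (!nzchar(piece)) {
        stop("template line ", lineno, ": empty parameter in {", token, "}",
             call. = FALSE)
      }
      eq <- regmatches(piece,
                       regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$",
                               piece))[[1]]
      if (length(eq) == 3L) {
        key <- eq[2]
        check_key(key, kind, lineno)
        params[[key]] <- parse_value(eq[3])
      } else if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", piece)) {
        check_key(piece, kind, lineno)
        if (!piece %in% c("required", "trim")) {
          stop("template line ", lineno, ": parameter '", piece,
               "' needs a value", call. = FALSE)
        }
        flags <- c(flags, piece)
      } else {
        stop("template line ", lineno, ": malformed parameter '", piece, "'",
             call. = FALSE)
      }
    }
  }
  build_pattern(kind, params, flags, lineno)
}

check_key <- function(key, kind, lineno) {
  if (!key %in% PATTERN_KEYS[[kind]]) {
    stop("template line ", lineno, ": unknown parameter '", key,
         "' for pattern type '", kind, "'", call. = FALSE)
  }
}

lit_or_stop <- function(params, key, lineno, default = NULL) {
  v <- params[[key]]
  if (is.null(v)) return(default)
  if (v$kind != "literal") {
    stop("template line ", lineno, ": parameter '", key,
         "' must be a literal", call. = FALSE)
  }
  v$payload
}

build_pattern <- function(kind, params, flags, lineno) {
  required <- "required" %in% flags
  trim <- "trim" %in% flags
  name <- lit_or_stop(params, "name", lineno)
  if (kind == "f") {
    pat <- params$pattern
    if (is.null(pat)) {
      stop("template line ", lineno, ": fuzzy pattern needs 'pattern'",
           call. = FALSE)
    }
    pat <- if (pat$kind == "literal") as_subpattern_list(pat$payload) else pat
    ngrams <- lit_or_stop(params, "ngrams", lineno, "auto")
    fuzzy_pattern(
      pattern = pat,
      edits = lit_or_stop(params, "edits", lineno, 0L),
      metric = lit_or_stop(params, "metric", lineno, "levenshtein"),
      required = required, trim = trim, name = name,
      overlap = lit_or_stop(params, "overlap", lineno, "none"),
      min_overlap = lit_or_stop(params, "min_overlap", lineno, 1L),
      ngrams = ngrams,
      word_width = lit_or_stop(params, "words", lineno, 63L),
      wildcards = lit_or_stop(params, "wildcards", lineno, "N"))
  } else if (kind == "r") {
    len <- params$length
    if (is.null(len)) {
      stop("template line ", lineno,
           ": fixed-length wildcard needs 'length'", call. = FALSE)
    }
    len <- if (len$kind == "literal") len$payload else len
    fixed_wildcard(length = len,
                   pattern = lit_or_stop(params, "pattern", lineno),
                   required = required, trim = trim, name = name)
  } else {
    if (required) {
      stop("template line ", lineno,
           ": interval patterns cannot be 'required'", call. = FALSE)
    }
    maxv <- lit_or_stop(params, "max", lineno, Inf)
    interval_wildcard(min = lit_or_stop(params, "min", lineno, 0L),
                      max = maxv,
                      pattern = lit_or_stop(params, "pattern", lineno),
                      trim = trim, name = name)
  }
}

#' Serialize a template back to its source form
#'
#' Inverse of [parse_template()]: `parse_template(format_template(x))` is
#' equal to `x` for any parsed template.
#'
#' @param spec A `template_spec`.
#' @return A character vector of template lines.
#' @export
format_template <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  vapply(spec$lines, function(l) {
    pats <- vapply(l$patterns, format_pattern, "")
    prefix <- if (is.na(l$order_index)) "" else paste0(l$order_index, " ")
    paste0(prefix, paste(pats, collapse = ""))
  }, "")
}

format_pattern <- function(p) {
  q <- function(x) paste0('"', x, '"')
  parts <- character(0)
  if (isTRUE(p$required)) parts <- c(parts, "required")
  if (isTRUE(p$trim)) parts <- c(parts, "trim")
  if (!is.null(p$name)) parts <- c(parts, paste0("name = ", q(p$name)))
  if (p$kind == "fuzzy") {
    if (p$k != 0L) parts <- c(parts, paste0("edits = ", p$k))
    if (p$metric != "levenshtein") {
      parts <- c(parts, paste0("metric = ", q(p$metric)))
    }
    if (p$overlap != "none") parts <- c(parts, paste0("overlap = ", q(p$overlap)))
    if (p$min_overlap != 1L) {
      parts <- c(parts, paste0("min_overlap = ", p$min_overlap))
    }
    if (!identical(p$ngrams, "auto")) {
      parts <- c(parts, paste0("ngrams = ", p$ngrams))
    }
    if (p$word_width != 63L) parts <- c(parts, paste0("words = ", p$word_width))
    if (!identical(p$wildcards, "N")) {
      parts <- c(parts, paste0("wildcards = ", q(p$wildcards)))
    }
    pat <- if (is_value_expr(p$subpatterns)) {
      format_value(p$subpatterns)
    } else if (nrow(p$subpatterns) == 1L &&
               p$subpatterns$sequence[1] == p$subpatterns$name[1]) {
      q(p$subpatterns$sequence[1])
    } else {
      stop("cannot serialize an in-memory multi-subpattern list; ",
           "use a list-file reference", call. = FALSE)
    }
    parts <- c(parts, paste0("pattern = ", pat))
    paste0("{f ", paste(parts, collapse = ", "), "}")
  } else if (p$kind == "fixed") {
    len <- if (is_value_expr(p$length)) format_value(p$length) else p$length
    parts <- c(parts, paste0("length = ", len))
    if (!p$char_class$universal) {
      parts <- c(parts, paste0("pattern = ", q(p$char_class$source_spec)))
    }
    paste0("{r ", paste(parts, collapse = ", "), "}")
  } else {
    if (p$min_len != 0L) parts <- c(parts, paste0("min = ", p$min_len))
    if (!is.infinite(p$max_len)) parts <- c(parts, paste0("max = ", p$max_len))
    if (!p$char_class$universal) {
      parts <- c(parts, paste0("pattern = ", q(p$char_class$source_spec)))
    }
    if (length(parts)) {
      paste0("{i ", paste(parts, collapse = ", "), "}")
    } else {
      "{i}"
    }
  }
}

#' @export
print.template_spec <- function(x, ...) {
  cat("<template_spec: ", x$group_size, " line(s) per record>\n", sep = "")
  cat(paste0("  ", format_template(x)), sep = "\n")
  invisible(x)
}
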