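#' Pattern constructors
#'
#' The template language arranges three kinds of patterns on each line:
#'
#' * **fuzzy patterns** (`{f ...}`): one of several subpatterns (barcodes,
#'   adapters) matched approximately under an edit-distance metric; exactly
#'   one subpattern is chosen per successful match.
#' * **fixed-length wildcards** (`{r ...}`): a run of exactly `length`
#'   characters, all from a character class.
#' * **interval-length wildcards** (`{i ...}`): a run whose length lies in
#'   `[min, max]`, all characters from a class; `{i}` with defaults matches
#'   any number of any characters.
#'
#' These constructors build the same objects the template parser produces,
#' for programmatic use.
#'
#' @param pattern For `fuzzy_pattern()`: a character vector of subpattern
#'   sequences, a subpattern list (see [load_list_file()]), or a
#'   [value_expr()] (file reference, possibly with a selector).  For the
#'   wildcard constructors: a character-class range string (`NULL` =
#'   universal).
#' @param edits Maximum number of edits `k` (non-negative).
#' @param metric `"levenshtein"`, `"hamming"`, or `"damerau"` (restricted
#'   Damerau-Levenshtein, i.e. optimal string alignment).
#' @param required If a required pattern cannot be matched the whole line
#'   (and hence the record) is unmatched.
#' @param trim Delete the matched span from the output line.
#' @param name Variable namespace for the match statistics (see
#'   [var_store()]); `NULL` binds nothing.
#' @param overlap Allow the subpattern to hang past the text `"start"`,
#'   `"end"`, `"both"` ends, or `"none"`; overhanging characters cost
#'   nothing.
#' @param min_overlap Minimum number of pattern characters that must remain
#'   inside the text when an overlap is taken (default 1).
#' @param ngrams n-gram pre-elimination size: `"auto"` picks the largest
#'   size valid for every subpattern ([max_ngram_size()]), `0` or `"none"`
#'   disables the filter, a positive integer forces a size.
#' @param word_width Machine-word width in bits used by the Hamming (Bitap)
#'   searcher; correctness does not depend on it.
#' @param wildcards String of characters that match anything at zero cost in
#'   both pattern and text (default `"N"`, the undetermined nucleotide).
#' @return An object of class `fuzzy_pattern`, `fixed_wildcard`, or
#'   `interval_wildcard` (all also `template_pattern`).
#' @examples
#' fuzzy_pattern(c("ACGTACGT", "TTGGCCAA"), edits = 1, required = TRUE,
#'               trim = TRUE, name = "b")
#' fixed_wildcard(8, trim = TRUE)
#' interval_wildcard()          # {i}: any number of any characters
#' interval_wildcard(0, 3, pattern = "A-Z")
#' @export
fuzzy_pattern <- function(pattern, edits = 0L,
                          metric = c("levenshtein", "hamming", "damerau"),
                          required = FALSE, trim = FALSE, name = NULL,
                          overlap = c("none", "start", "end", "both"),
                          min_overlap = 1L, ngrams = "auto",
                          word_width = 63L, wildcards = "N") {
  metric <- match.arg(metric)
  overlap <- match.arg(overlap)
  edits <- as.integer(edits)
  stopifnot(edits >= 0L, min_overlap >= 1L,
            word_width >= 1L, word_width <= 64L)
  if (is.character(pattern)) pattern <- as_subpattern_list(pattern)
  if (!inherits(pattern, "subpattern_list") && !is_value_expr(pattern)) {
    stop("pattern must be subpattern sequences, a subpattern_list, ",
         "or a value_expr", call. = FALSE)
  }
  if (!identical(ngrams, "auto")) {
    if (identical(ngrams, "none")) ngrams <- 0L
    ngrams <- as.integer(ngrams)
    stopifnot(ngrams >= 0L)
  }
  structure(list(kind = "fuzzy", subpatterns = pattern, k = edits,
                 metric = metric, required = required, trim = trim,
                 name = name, overlap = overlap,
                 min_overlap = as.integer(min_overlap), ngrams = ngrams,
                 word_width = as.integer(word_width), wildcards = wildcards),
            class = c("fuzzy_pattern", "template_pattern"))
}

#' @rdname fuzzy_pattern
#' @param length Fixed window length: a positive integer or a [value_expr()]
#'   variable reference resolved at match time (e.g. `%b.length%`).
#' @export
fixed_wildcard <- function(length, pattern = NULL, required = FALSE,
                           trim = FALSE, name = NULL) {
  if (!is_value_expr(length)) {
    length <- as.integer(length)
    stopifnot(!is.na(length), length >= 1L)
  }
  structure(list(kind = "fixed", length = length,
                 char_class = parse_char_class(pattern),
                 required = required, trim = trim, name = name),
            class = c("fixed_wildcard", "template_pattern"))
}

#' @rdname fuzzy_pattern
#' @param min,max Length interval bounds; `max = Inf` is unbounded.
#' @export
interval_wildcard <- function(min = 0L, max = Inf, pattern = NULL,
                              trim = FALSE, name = NULL) {
  min <- as.integer(min)
  stopifnot(!is.na(min), min >= 0L)
  if (!is.infinite(max)) {
    max <- as.integer(max)
    if (min > max) {
      stop("interval pattern: min (", min, ") > max (", max, ")",
           call. = FALSE)
    }
  }
  structure(list(kind = "interval", min_len = min, max_len = max,
                 char_class = parse_char_class(pattern),
                 trim = trim, name = name),
            class = c("interval_wildcard", "template_pattern"))
}

#' @export
print.fuzzy_pattern <- function(x, ...) {
  cat(format_pattern(x), "\n")
  invisible(x)
}

#' @export
print.fixed_wildcard <- function(x, ...) {
  cat(format_pattern(x), "\n")
  invisible(x)
}

#' @export
print.interval_wildcard <- function(x, ...) {
  cat(format_pattern(x), "\n")
  invisible(x)
}
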