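#' Character classes for wildcard patterns
#'
#' A character class restricts which characters a fixed-length or
#' interval-length wildcard pattern accepts.  The class is described by a
#' range string such as `"a-z0-9"`: a concatenation of single characters and
#' `x-y` ranges (compared by byte value, so ASCII in practice).  An absent or
#' empty specification yields the universal class that accepts every
#' character.
#'
#' Classes are byte-oriented: the engine is format-agnostic and performs no
#' alphabet-specific validation.
#'
#' @param spec A range string, or `NULL` for the universal class.
#' @return An object of class `char_class` with fields `universal` (logical),
#'   `table` (a 256-long logical lookup indexed by byte value) and
#'   `source_spec` (the literal range string, or `NA` for universal).
#' @examples
#' cc <- parse_char_class("a-z0-9")
#' sum(cc$table)  # 36 characters
#' cc_allows(cc, "q")
#' cc_allows(cc, "Q")
#' @export
parse_char_class <- function(spec = NULL) {
  if (is.null(spec) || identical(spec, "") || all(is.na(spec))) {
    return(structure(
      list(universal = TRUE, table = rep(TRUE, 256), source_spec = NA_character_),
      class = "char_class"))
  }
  stopifnot(is.character(spec), length(spec) == 1L)
  bytes <- as.integer(charToRaw(spec))
  tab <- rep(FALSE, 256)
  i <- 1L
  n <- length(bytes)
  dash <- as.integer(charToRaw("-"))
  while (i <= n) {
    if (bytes[i] == dash) {
      stop("char class '", spec, "': dangling hyphen", call. = FALSE)
    }
    if (i + 2L <= n && bytes[i + 1L] == dash) {
      lo <- bytes[i]
      hi <- bytes[i + 2L]
      if (lo > hi) {
        stop("char class '", spec, "': descending range '",
             rawToChar(as.raw(lo)), "-", rawToChar(as.raw(hi)), "'",
             call. = FALSE)
      }
      tab[(lo:hi) + 1L] <- TRUE
      i <- i + 3L
    } else if (i + 1L == n && bytes[i + 1L] == dash) {
      stop("char class '", spec, "': dangling hyphen", call. = FALSE)
    } else {
      tab[bytes[i] + 1L] <- TRUE
      i <- i + 1L
    }
  }
  structure(list(universal = FALSE, table = tab, source_spec = spec),
            class = "char_class")
}

#' @rdname parse_char_class
#' @param cc A `char_class` object.
#' @param chars A character scalar; every character is tested.
#' @return `cc_allows()`: `TRUE` iff every character of `chars` is allowed.
#' @export
cc_allows <- function(cc, chars) {
  stopifnot(inherits(cc, "char_class"))
  if (cc$universal) return(TRUE)
  if (!nzchar(chars)) return(TRUE)
  all(cc$table[as.integer(charToRaw(chars)) + 1L])
}

# Per-character allowed vector for a whole line (used by the interval DP and
# the sliding-window matcher).
cc_allow_vec <- function(cc, text) {
  if (cc$universal) return(rep(TRUE, nchar(text)))
  if (!nzchar(text)) return(logical(0))
  cc$table[as.integer(charToRaw(text)) + 1L]
}

#' @export
print.char_class <- function(x, ...) {
  if (x$universal) {
    cat("<char_class: universal>\n")
  } else {
    cat("<char_class: \"", x$source_spec, "\" (", sum(x$table),
        " characters)>\n", sep = "")
  }
  invisible(x)
}

#' @export
format.char_class <- function(x, ...) {
  if (x$universal) NA_character_ else x$source_spec
}
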