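#' Load a list file of subpatterns
#'
#' List files hold the subpatterns of a fuzzy pattern (barcodes, adapters,
#' ...), one per line, with an optional TAB-separated name column.  Entries
#' keep file order; the subpattern index of entry i is i - 1 (indices are
#' 0-based everywhere in this package).  When no name is given the sequence
#' itself is the name.
#'
#' @param path Path to the list file (plain text, UTF-8/ASCII).
#' @param alphabet Optional string of permitted characters; entries using
#'   other characters trigger a warning (never an error -- the engine is
#'   byte-oriented and format-agnostic).
#' @return A data frame of class `subpattern_list` with columns `sequence`
#'   and `name`; row i corresponds to subpattern index i - 1.
#' @examples
#' f <- tempfile()
#' writeLines(c("ACGTACGT\tBC01", "TTGGCCAA\tBC02"), f)
#' load_list_file(f)
#' @export
load_list_file <- function(path, alphabet = NULL) {
  if (!file.exists(path)) {
    stop("list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0L) {
    stop("list file is empty: ", path, call. = FALSE)
  }
  blank <- which(!nzchar(trimws(lines)))
  if (length(blank)) {
    stop("blank line ", blank[1], " in list file: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  seqs <- vapply(parts, `[[`, "", 1L)
  nms <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else p[[1]], "")
  if (!is.null(alphabet)) {
    ok <- vapply(seqs, function(s) {
      all(strsplit(s, "")[[1]] %in% strsplit(alphabet, "")[[1]])
    }, TRUE)
    if (any(!ok)) {
      warning(sum(!ok), " entr", if (sum(!ok) == 1L) "y" else "ies",
              " in ", path, " contain characters outside '", alphabet, "'",
              call. = FALSE)
    }
  }
  structure(
    data.frame(sequence = seqs, name = nms, stringsAsFactors = FALSE),
    class = c("subpattern_list", "data.frame"))
}

# Cached loader keyed by normalized path; `lists` is an environment shared
# across a run so each list file is read once.
load_list_file_cached <- function(path, lists = NULL, base_dir = ".") {
  full <- if (grepl("^(/|~)", path)) path else file.path(base_dir, path)
  if (is.null(lists)) return(load_list_file(full))
  key <- full
  if (!exists(key, envir = lists, inherits = FALSE)) {
    assign(key, load_list_file(full), envir = lists)
  }
  get(key, envir = lists, inherits = FALSE)
}

# Build an in-memory subpattern list (no file involved).
as_subpattern_list <- function(sequences, names = sequences) {
  stopifnot(length(sequences) >= 1L, all(nchar(sequences) >= 1L))
  structure(
    data.frame(sequence = as.character(sequences),
               name = as.character(names), stringsAsFactors = FALSE),
    class = c("subpattern_list", "data.frame"))
}
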