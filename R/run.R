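#' Demultiplex and trim line-oriented read files
#'
#' The top-level driver: parses the template(s), streams records from the
#' input file(s), matches every record with [match_record()], and routes
#' trimmed matched records / untouched unmatched records to their output
#' files.  Matched output paths may reference match variables
#' (`"matched_%b.pattern_name%.fastq"`), which is what turns template
#' matching into demultiplexing.
#'
#' @param inputs Character vector of input paths (2 for paired-end).
#' @param templates Template file paths (or parsed `template_spec`s),
#'   order-aligned with `inputs`.  Relative list-file paths inside a
#'   template are resolved against the template file's directory.
#' @param matched Matched output path template(s), one per input (or one
#'   recycled); `NULL` discards matched records.
#' @param unmatched Unmatched output path(s); `NULL` discards unmatched
#'   records.
#' @param workers Parallel workers (forked; see [process_batches()]).
#' @param batch_size Records per batch.
#' @param preserve_order Force output order == input order even with
#'   several workers.
#' @param max_handles Cap on simultaneously open output files.
#' @param quiet Suppress the end-of-run summary message.
#' @return A `demux_summary`: records in, matched, unmatched, and
#'   per-destination record counts.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("ACGTACGT\tBC01", "TTGGCCAA\tBC02"), file.path(dir, "b.txt"))
#' writeLines(c(
#'   "{i}",
#'   '1 {f required, trim, name = "b", edits = 1, pattern = f"b.txt"}{i}',
#'   "{i}",
#'   "2 {r trim, length = %b.length%}{i}"), file.path(dir, "template.txt"))
#' writeLines(c("@r1", "ACGTACGTGGGG", "+", "IIIIIIIIIIII"),
#'            file.path(dir, "input.fastq"))
#' fuzzydemux(file.path(dir, "input.fastq"), file.path(dir, "template.txt"),
#'            matched = file.path(dir, "matched_%b.pattern_name%.fastq"),
#'            unmatched = file.path(dir, "unmatched.fastq"))
#' @export
fuzzydemux <- function(inputs, templates, matched = NULL, unmatched = NULL,
                       workers = 1L, batch_size = 256L,
                       preserve_order = workers == 1L, max_handles = 64L,
                       quiet = TRUE) {
  stopifnot(length(inputs) >= 1L)
  if (inherits(templates, "template_spec")) templates <- list(templates)
  if (is.character(templates)) templates <- lapply(templates, parse_template_file)
  if (length(templates) != length(inputs)) {
    stop("need one template per input file (", length(inputs), " input(s), ",
         length(templates), " template(s))", call. = FALSE)
  }
  lists <- new.env(parent = emptyenv())
  templates <- lapply(templates, compile_template, lists = lists)
  sched <- line_schedule(templates)  # validates order indices up front

  group_sizes <- vapply(templates, `[[`, 1L, "group_size")
  if (length(unique(group_sizes)) != 1L) {
    stop("templates with different group sizes per input are not supported",
         call. = FALSE)
  }
  reader <- group_reader(inputs, group_sizes[1])
  on.exit(reader_close(reader), add = TRUE)

  routes <- output_route(matched, unmatched, max_handles)
  on.exit(route_close(routes), add = TRUE)

  n_in <- 0L
  n_matched <- 0L
  handler <- function(group) {
    match_record(templates, group, vars = var_store(), lists = lists,
                 schedule = sched)
  }
  writer <- function(results) {
    for (res in results) {
      n_in <<- n_in + 1L
      if (res$matched) n_matched <<- n_matched + 1L
      route_record(res, routes)
    }
  }
  process_batches(reader, handler, writer, worker_count = workers,
                  batch_size = batch_size, preserve_order = preserve_order)

  summary <- structure(
    list(records = n_in, matched = n_matched,
         unmatched = n_in - n_matched, destinations = route_counts(routes)),
    class = "demux_summary")
  if (!quiet) message(paste(format(summary), collapse = "\n"))
  summary
}

# Pre-resolve what can be resolved once per run: static list-file
# references, chunk partitions, per-line trivial-match flags.  Also
# validates trim uniformity of interval chunks and interval variable names.
compile_template <- function(spec, lists = NULL) {
  stopifnot(inherits(spec, "template_spec"))
  base_dir <- attr(spec, "base_dir") %||% "."
  for (li in seq_along(spec$lines)) {
    pats <- spec$lines[[li]]$patterns
    for (pi in seq_along(pats)) {
      p <- pats[[pi]]
      if (p$kind == "fuzzy" && is_value_expr(p$subpatterns) &&
          p$subpatterns$kind == "file_ref") {
        p$subpatterns <- load_list_file_cached(p$subpatterns$payload, lists,
                                               base_dir)
        pats[[pi]] <- p
      }
    }
    part <- partition_chunks(pats)
    validate_line(pats, part)
    attr(pats, "partition") <- part
    attr(pats, "trivial") <- length(pats) >= 1L &&
      all(vapply(pats, function(p) {
        p$kind == "interval" && is_unbounded_universal(p) &&
          !isTRUE(p$trim) && is.null(p$name)
      }, TRUE))
    spec$lines[[li]]$patterns <- pats
  }
  attr(spec, "base_dir") <- base_dir
  spec
}

validate_line <- function(pats, part) {
  for (ch in part) {
    if (ch$kind != "interval" || length(ch$idx) == 0L) next
    ip <- pats[ch$idx + 1L]
    tr <- vapply(ip, function(p) isTRUE(p$trim), TRUE)
    if (any(tr) && !all(tr)) {
      stop("interval patterns within one chunk must either all carry ",
           "'trim' or none of them", call. = FALSE)
    }
    named <- vapply(ip, function(p) !is.null(p$name), TRUE)
    if (any(named) && length(ip) > 1L) {
      stop("a named interval pattern must be the only pattern of its ",
           "chunk (individual interval spans within a chunk are not ",
           "identified)", call. = FALSE)
    }
  }
  invisible()
}

#' @export
format.demux_summary <- function(x, ...) {
  c(sprintf("records in : %d", x$records),
    sprintf("matched    : %d", x$matched),
    sprintf("unmatched  : %d", x$unmatched),
    if (length(x$destinations)) "per-destination record counts:",
    sprintf("  %s: %d", names(x$destinations), x$destinations))
}

#' @export
print.demux_summary <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
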