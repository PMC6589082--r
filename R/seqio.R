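#' Read line groups from one or more input files
#'
#' Inputs are line-oriented: a record is a fixed-size group of consecutive
#' lines per file (`group_size = 4` for FASTQ).  Gzip compression is
#' detected by magic bytes, independent of the file extension.  Input
#' accepts both `\n` and `\r\n` line endings; output is always `\n`.
#'
#' `read_groups()` reads whole files; `group_reader()` returns a pull
#' function for streaming -- `reader(n)` yields up to `n` record groups
#' (each a list of per-file character vectors) and `NULL` at end of input.
#' A trailing partial group ("ragged tail") and paired files with unequal
#' record counts are errors.
#'
#' @param paths Character vector of input paths (one per file slot).
#' @param group_size Lines per record per file (>= 1).
#' @return `read_groups()`: a list of record groups in file order.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "TTTT", "+", "IIII"), f)
#' length(read_groups(f, 4))  # 2 records
#' @export
read_groups <- function(paths, group_size) {
  reader <- group_reader(paths, group_size)
  on.exit(reader_close(reader))
  out <- list()
  repeat {
    batch <- reader(1024L)
    if (is.null(batch)) break
    out <- c(out, batch)
  }
  out
}

#' @rdname read_groups
#' @export
group_reader <- function(paths, group_size) {
  group_size <- as.integer(group_size)
  stopifnot(group_size >= 1L, length(paths) >= 1L)
  cons <- lapply(paths, open_input)
  consumed <- integer(length(paths))
  done <- FALSE
  reader <- function(n) {
    if (done) return(NULL)
    per_file <- lapply(seq_along(cons), function(fi) {
      lines <- readLines(cons[[fi]], n = n * group_size, warn = FALSE)
      sub("\r$", "", lines)
    })
    counts <- lengths(per_file)
    if (all(counts == 0L)) {
      done <<- TRUE
      return(NULL)
    }
    if (length(unique(counts)) != 1L) {
      short <- which.min(counts)
      stop("paired input files have unequal record counts: '",
           paths[short], "' ends after ",
           (consumed[short] + counts[short]) %/% group_size, " record(s)",
           call. = FALSE)
    }
    nl <- counts[1]
    if (nl %% group_size != 0L) {
      stop("ragged tail: '", paths[1], "' line ", consumed[1] + nl,
           " ends a partial record (total lines not a multiple of ",
           group_size, ")", call. = FALSE)
    }
    consumed <<- consumed + nl
    ng <- nl %/% group_size
    lapply(seq_len(ng), function(g) {
      rows <- ((g - 1L) * group_size + 1L):(g * group_size)
      lapply(per_file, `[`, rows)
    })
  }
  attr(reader, "cons") <- cons
  reader
}

reader_close <- function(reader) {
  for (con in attr(reader, "cons")) try(close(con), silent = TRUE)
  invisible()
}

# gzip magic: 0x1f 0x8b
open_input <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) &&
      magic[2] == as.raw(0x8b)) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}

#' Interpolate variables into an output path
#'
#' Replaces `%name.field%` placeholders with values bound in a variable
#' store, so matched records can be routed to per-barcode files
#' (`"matched_%b.pattern_name%.fastq"`).  Substituted values are sanitized:
#' path separators inside them become `_`.
#'
#' @param template Path template, possibly containing placeholders.
#' @param vars A [var_store()].
#' @return The resolved path.  Unknown variables are an error listing the
#'   available names.
#' @examples
#' vars <- var_store()
#' bind_variables("b", list(length = 8, pattern_idx = 0,
#'                          pattern_name = "BC01", edits = 0), vars)
#' interpolate_filename("matched_%b.pattern_name%.fastq", vars)
#' @export
interpolate_filename <- function(template, vars) {
  m <- gregexpr("%[A-Za-z_][A-Za-z0-9_]*\\.[A-Za-z_]+%", template)[[1]]
  if (m[1] == -1L) return(template)
  refs <- regmatches(template, list(m))[[1]]
  out <- template
  for (ref in unique(refs)) {
    inner <- substr(ref, 2L, nchar(ref) - 1L)
    parts <- strsplit(inner, ".", fixed = TRUE)[[1]]
    val <- var_get(vars, parts[1], parts[2])
    val <- gsub("[/\\\\]", "_", as.character(val))
    out <- gsub(ref, val, out, fixed = TRUE)
  }
  out
}

#' Output routes
#'
#' An `output_route` appends each record to exactly one destination per
#' input file: the (variable-interpolated) matched path for matched
#' records, the unmatched path otherwise.  Unmatched records are written
#' byte-identically to their input lines -- they are never trimmed.  File
#' handles are kept open up to `max_handles` and reopened in append mode
#' beyond that (least recently used closed first), since barcode counts can
#' exceed the OS handle limit.  Paths ending in `.gz` are gzip-compressed.
#'
#' @param matched Character vector of matched path templates, one per input
#'   file (may contain `%name.field%` placeholders), or `NULL` to drop
#'   matched output.
#' @param unmatched Character vector of unmatched paths, one per input
#'   file, or `NULL` to drop unmatched output.
#' @param max_handles Open-handle cap.
#' @return An `output_route` environment.
#' @export
output_route <- function(matched, unmatched, max_handles = 64L) {
  rt <- new.env(parent = emptyenv())
  rt$matched <- matched
  rt$unmatched <- unmatched
  rt$max_handles <- as.integer(max_handles)
  rt$handles <- new.env(parent = emptyenv())
  rt$stamp <- 0L
  rt$counts <- new.env(parent = emptyenv())
  class(rt) <- "output_route"
  rt
}

#' @rdname output_route
#' @param result A `record_result` (see [match_record()]); its variable
#'   store resolves the matched path placeholders.
#' @param routes An `output_route`.
#' @export
route_record <- function(result, routes) {
  stopifnot(inherits(result, "record_result"),
            inherits(routes, "output_route"))
  tmpl <- if (result$matched) routes$matched else routes$unmatched
  for (fi in seq_along(result$output_lines)) {
    if (is.null(tmpl)) next
    path <- tmpl[min(fi, length(tmpl))]
    if (result$matched) path <- interpolate_filename(path, result$vars)
    route_write(routes, path, result$output_lines[[fi]])
  }
  invisible()
}

route_write <- function(routes, path, lines) {
  con <- route_handle(routes, path)
  writeLines(lines, con, sep = "\n")
  cnt <- routes$counts
  assign(path, (if (exists(path, envir = cnt)) get(path, envir = cnt)
                else 0L) + 1L, envir = cnt)
  invisible()
}

route_handle <- function(routes, path) {
  h <- routes$handles
  routes$stamp <- routes$stamp + 1L
  if (exists(path, envir = h, inherits = FALSE)) {
    entry <- get(path, envir = h, inherits = FALSE)
    entry$stamp <- routes$stamp
    assign(path, entry, envir = h)
    return(entry$con)
  }
  open_paths <- ls(h)
  if (length(open_paths) >= routes$max_handles) {
    stamps <- vapply(open_paths, function(p) {
      get(p, envir = h, inherits = FALSE)$stamp
    }, 1L)
    victim <- open_paths[which.min(stamps)]
    close(get(victim, envir = h, inherits = FALSE)$con)
    rm(list = victim, envir = h)
  }
  mode <- if (exists(path, envir = routes$counts, inherits = FALSE))
    "ab" else "wb"
  con <- if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
  assign(path, list(con = con, stamp = routes$stamp), envir = h)
  con
}

route_close <- function(routes) {
  for (p in ls(routes$handles)) {
    close(get(p, envir = routes$handles, inherits = FALSE)$con)
  }
  rm(list = ls(routes$handles), envir = routes$handles)
  invisible()
}

route_counts <- function(routes) {
  paths <- ls(routes$counts)
  stats::setNames(vapply(paths, function(p) {
    get(p, envir = routes$counts, inherits = FALSE)
  }, 1L), paths)
}

#' Batched (optionally parallel) record processing
#'
#' Producer-consumer processing: the reader pulls `worker_count` batches of
#' `batch_size` records at a time, workers transform each record
#' independently, and results are written out batch by batch, so in-flight
#' memory is bounded by `worker_count * batch_size` records.  Each record
#' is handled independently of every other, so per-destination output
#' content (as a multiset of records) is identical for any `worker_count`
#' and `batch_size`; with `worker_count = 1` (or `preserve_order`) output
#' order equals input order.  A worker error aborts the run.
#'
#' @param reader A [group_reader()] pull function (or any function with the
#'   same contract).
#' @param handler `function(group) -> result` applied to every record.
#' @param writer `function(results)` called with each batch's results, in
#'   batch order.
#' @param worker_count Number of parallel workers (forked processes via
#'   [parallel::mclapply()]; 1 = in-process).
#' @param batch_size Records per batch (>= 1).
#' @param preserve_order Force strictly sequential handling.
#' @return Number of records processed, invisibly.
#' @export
process_batches <- function(reader, handler, writer, worker_count = 1L,
                            batch_size = 256L, preserve_order = FALSE) {
  worker_count <- as.integer(worker_count)
  batch_size <- as.integer(batch_size)
  stopifnot(worker_count >= 1L, batch_size >= 1L)
  total <- 0L
  sequential <- worker_count == 1L || preserve_order
  repeat {
    pull <- if (sequential) batch_size else worker_count * batch_size
    groups <- reader(pull)
    if (is.null(groups)) break
    if (sequential) {
      results <- lapply(groups, handler)
    } else {
      batches <- split(groups,
                       ceiling(seq_along(groups) / batch_size))
      done <- parallel::mclapply(batches, function(b) lapply(b, handler),
                                 mc.cores = worker_count)
      err <- vapply(done, inherits, TRUE, "try-error")
      if (any(err)) {
        stop("worker failed: ",
             attr(done[[which(err)[1]]], "condition")$message,
             call. = FALSE)
      }
      results <- do.call(c, done)
      names(results) <- NULL
    }
    writer(results)
    total <- total + length(results)
  }
  invisible(total)
}
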