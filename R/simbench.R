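#' Synthetic benchmark datasets with ground truth
#'
#' Two generators emulate the standard read-preprocessing benchmarks:
#'
#' * `sim_adapter_dataset()` -- 3' adapter trimming.  One shared random
#'   adapter (default 30 nt).  Each read carries the adapter at its 3' end
#'   with probability `adapter_fraction` (default 0.75); a carried adapter
#'   has a 50% chance of no edits and 50% chance of exactly one edit.
#'   Reads without the adapter are `read_length` (default 130) random
#'   nucleotides; reads with it are `read_length - adapter_length` random
#'   nucleotides followed by the (possibly mutated) adapter, so totals stay
#'   around `read_length` (an indel shifts the length by one).
#'
#' * `sim_demux_dataset()` -- 5' barcode demultiplexing.  A set of
#'   `n_barcodes` (default 48) random barcodes with lengths uniform in
#'   `barcode_lengths` (default 8--15).  Each read has probability
#'   `barcode_fraction` (default 0.5) of starting with one of the barcodes
#'   (mutated with the same 0/1-edit profile) followed by `insert_length`
#'   (default 100) random nucleotides; other reads are just the random
#'   insert.
#'
#' Edits are drawn uniformly from `edit_kinds` and placed uniformly within
#' the feature; a substitution always changes the character.  All reads are
#' generated by a per-read sequence of RNG draws under [set.seed()], so the
#' same seed reproduces the dataset byte for byte and appending more reads
#' never changes earlier ones.
#'
#' `min_dist` optionally constrains the barcode set for controlled-recovery
#' experiments: candidate barcodes are rejection-sampled until every pair
#' keeps a *cross-prefix* Levenshtein distance of at least `min_dist`
#' (no barcode within `min_dist - 1` edits of any prefix of another).
#' Prefix-aware separation -- rather than plain full-length pairwise
#' distance -- is what guarantees unique assignment under prefix-anchored
#' matching when barcode lengths differ; see the package vignette.
#'
#' @param n_reads Number of reads.
#' @param fastq Output FASTQ path.
#' @param read_length,adapter_length,adapter_fraction Adapter recipe
#'   parameters (see above).
#' @param edit_probs Probabilities of 0 and 1 injected edits (must sum
#'   to 1).
#' @param edit_kinds Subset of `c("sub", "ins", "del")`.
#' @param alphabet Nucleotide alphabet.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return `sim_adapter_dataset()`: list with `fastq`, `adapter` (the
#'   sequence), `adapter_file` (a one-entry list file next to `fastq`), and
#'   `truth` (data frame: `read_id`, `with_feature`, `edits`).
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' d <- sim_adapter_dataset(50, f, seed = 7)
#' table(d$truth$with_feature)
#' @export
sim_adapter_dataset <- function(n_reads, fastq, read_length = 130L,
                                adapter_length = 30L,
                                adapter_fraction = 0.75,
                                edit_probs = c(0.5, 0.5),
                                edit_kinds = c("sub", "ins", "del"),
                                alphabet = c("A", "C", "G", "T"),
                                seed = NULL) {
  stopifnot(n_reads >= 1L, adapter_fraction >= 0, adapter_fraction <= 1,
            abs(sum(edit_probs) - 1) < 1e-9,
            all(edit_kinds %in% c("sub", "ins", "del")))
  if (adapter_length > read_length) {
    stop("adapter_length (", adapter_length, ") exceeds read_length (",
         read_length, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  adapter <- rand_seq(adapter_length, alphabet)
  pad <- read_length - adapter_length
  ids <- sprintf("read%06d", seq_len(n_reads))
  seqs <- character(n_reads)
  with_feature <- logical(n_reads)
  edits <- integer(n_reads)
  feature_len <- rep(NA_integer_, n_reads)
  for (i in seq_len(n_reads)) {
    if (runif(1) < adapter_fraction) {
      ne <- sample.int(length(edit_probs), 1L, prob = edit_probs) - 1L
      mut <- mutate_seq(adapter, ne, edit_kinds, alphabet)
      seqs[i] <- paste0(rand_seq(pad, alphabet), mut)
      with_feature[i] <- TRUE
      edits[i] <- ne
      feature_len[i] <- nchar(mut)
    } else {
      seqs[i] <- rand_seq(read_length, alphabet)
    }
  }
  write_fastq(fastq, ids, seqs)
  adapter_file <- paste0(tools::file_path_sans_ext(fastq), "_adapter.txt")
  writeLines(paste0(adapter, "\tadapter"), adapter_file)
  list(fastq = fastq, adapter = adapter, adapter_file = adapter_file,
       truth = data.frame(read_id = ids, with_feature = with_feature,
                          edits = edits, feature_len = feature_len,
                          stringsAsFactors = FALSE))
}

#' @rdname sim_adapter_dataset
#' @param n_barcodes,barcode_lengths,barcode_fraction,insert_length
#'   Demultiplexing recipe parameters (see above).
#' @param min_dist Optional minimum cross-prefix Levenshtein distance
#'   between every barcode pair (rejection sampling; an unreachable
#'   constraint is an error).
#' @param max_tries Sampling attempts per barcode before declaring the
#'   constraint infeasible.
#' @return `sim_demux_dataset()`: list with `fastq`, `barcodes` (data
#'   frame: `sequence`, `name`), `barcode_file` (TAB-separated list file),
#'   and `truth` (data frame: `read_id`, `barcode` (`NA` when absent),
#'   `edits`).
#' @export
sim_demux_dataset <- function(n_reads, fastq, n_barcodes = 48L,
                              barcode_lengths = c(8L, 15L),
                              barcode_fraction = 0.5,
                              insert_length = 100L,
                              edit_probs = c(0.5, 0.5),
                              edit_kinds = c("sub", "ins", "del"),
                              alphabet = c("A", "C", "G", "T"),
                              min_dist = NULL, max_tries = 100000L,
                              seed = NULL) {
  stopifnot(n_reads >= 1L, n_barcodes >= 1L,
            barcode_fraction >= 0, barcode_fraction <= 1,
            abs(sum(edit_probs) - 1) < 1e-9)
  if (!is.null(seed)) set.seed(seed)
  bc <- character(n_barcodes)
  for (b in seq_len(n_barcodes)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not sample barcode ", b, " under min_dist = ", min_dist,
             " after ", max_tries, " attempts; constraint infeasible",
             call. = FALSE)
      }
      len <- sample(barcode_lengths[1]:barcode_lengths[2], 1L)
      cand <- rand_seq(len, alphabet)
      if (is.null(min_dist) ||
          all(vapply(bc[seq_len(b - 1L)], prefix_separated, TRUE,
                     cand = cand, min_dist = min_dist))) {
        bc[b] <- cand
        break
      }
    }
  }
  names(bc) <- sprintf("BC%02d", seq_len(n_barcodes))

  ids <- sprintf("read%06d", seq_len(n_reads))
  seqs <- character(n_reads)
  barcode <- rep(NA_character_, n_reads)
  edits <- integer(n_reads)
  feature_len <- rep(NA_integer_, n_reads)
  for (i in seq_len(n_reads)) {
    if (runif(1) < barcode_fraction) {
      bi <- sample.int(n_barcodes, 1L)
      ne <- sample.int(length(edit_probs), 1L, prob = edit_probs) - 1L
      mut <- mutate_seq(bc[bi], ne, edit_kinds, alphabet)
      seqs[i] <- paste0(mut, rand_seq(insert_length, alphabet))
      barcode[i] <- names(bc)[bi]
      edits[i] <- ne
      feature_len[i] <- nchar(mut)
    } else {
      seqs[i] <- rand_seq(insert_length, alphabet)
    }
  }
  write_fastq(fastq, ids, seqs)
  barcode_file <- paste0(tools::file_path_sans_ext(fastq), "_barcodes.txt")
  writeLines(paste0(bc, "\t", names(bc)), barcode_file)
  list(fastq = fastq,
       barcodes = data.frame(sequence = unname(bc), name = names(bc),
                             stringsAsFactors = FALSE),
       barcode_file = barcode_file,
       truth = data.frame(read_id = ids, barcode = barcode, edits = edits,
                          feature_len = feature_len,
                          stringsAsFactors = FALSE))
}

# TRUE iff no prefix of either string is within min_dist - 1 edits of the
# other string (cross-prefix separation, used by the min_dist constraint).
prefix_separated <- function(existing, cand, min_dist) {
  k <- min_dist - 1L
  nrow(cpp_edit_search(cand, existing, k, FALSE, FALSE, FALSE, 1L, "",
                       TRUE)) == 0L &&
    nrow(cpp_edit_search(existing, cand, k, FALSE, FALSE, FALSE, 1L, "",
                         TRUE)) == 0L
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0L) return("")
  paste(alphabet[sample.int(length(alphabet), n, replace = TRUE)],
        collapse = "")
}

# Apply n_edits random edits (uniform kind and position; substitutions
# always change the character; an insertion inserts a random character).
mutate_seq <- function(seq, n_edits, kinds = c("sub", "ins", "del"),
                       alphabet = c("A", "C", "G", "T")) {
  if (n_edits == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (e in seq_len(n_edits)) {
    kind <- kinds[sample.int(length(kinds), 1L)]
    if (kind == "sub") {
      pos <- sample.int(length(chars), 1L)
      chars[pos] <- sample(setdiff(alphabet, chars[pos]), 1L)
    } else if (kind == "del") {
      pos <- sample.int(length(chars), 1L)
      chars <- chars[-pos]
    } else {
      pos <- sample.int(length(chars) + 1L, 1L)
      chars <- append(chars, alphabet[sample.int(length(alphabet), 1L)],
                      after = pos - 1L)
    }
  }
  paste(chars, collapse = "")
}

write_fastq <- function(path, ids, seqs) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Demultiplexing difference metric
#'
#' Scores an observed per-read barcode assignment against the ground
#' truth.  For each barcode b, `wrong_b` counts reads present in b's
#' output that do not belong there and `missing_b` counts reads that
#' belong to b but are absent from its output; the aggregate difference is
#'
#' \deqn{D = \frac{1}{\mathrm{with\_barcode}} \sum_b
#'       (\mathrm{wrong}_b + \mathrm{missing}_b)}
#'
#' where `with_barcode` is the number of reads that truly carry a barcode.
#' A read assigned to the wrong barcode counts twice (wrong there, missing
#' from its own); a barcode-free read that gets assigned counts once
#' (wrong only); an unassigned barcode-carrying read counts once
#' (missing only).
#'
#' @param truth Data frame with columns `read_id` and `barcode` (`NA` for
#'   reads without one), as produced by [sim_demux_dataset()].
#' @param assignments Observed assignment: a data frame with `read_id` and
#'   `barcode`, or a vector of barcodes named by read id (`NA` =
#'   unassigned).  Must cover the same read ids as `truth`.
#' @return A `difference_report`: per-barcode `wrong` / `missing` counts,
#'   `with_barcode`, and `D` (also as a percentage in `percent`).
#' @examples
#' truth <- data.frame(read_id = sprintf("r%d", 1:4),
#'                     barcode = c("BC1", "BC1", "BC2", NA))
#' obs <- c(r1 = "BC1", r2 = "BC2", r3 = "BC2", r4 = NA)
#' difference_metric(truth, obs)
#' @export
difference_metric <- function(truth, assignments) {
  stopifnot(is.data.frame(truth),
            all(c("read_id", "barcode") %in% names(truth)))
  if (is.data.frame(assignments)) {
    obs <- stats::setNames(as.character(assignments$barcode),
                           assignments$read_id)
  } else {
    obs <- assignments
  }
  if (!setequal(names(obs), truth$read_id) ||
      length(obs) != nrow(truth)) {
    stop("assignments must cover exactly the read ids in `truth`",
         call. = FALSE)
  }
  obs <- obs[truth$read_id]
  tru <- as.character(truth$barcode)
  with_barcode <- sum(!is.na(tru))
  if (with_barcode == 0L) {
    stop("no read in `truth` carries a barcode; D is undefined",
         call. = FALSE)
  }
  bcs <- sort(unique(c(tru[!is.na(tru)], obs[!is.na(obs)])))
  wrong <- vapply(bcs, function(b) {
    sum(!is.na(obs) & obs == b & (is.na(tru) | tru != b))
  }, 1L)
  missing <- vapply(bcs, function(b) {
    sum(!is.na(tru) & tru == b & (is.na(obs) | obs != b))
  }, 1L)
  D <- (sum(wrong) + sum(missing)) / with_barcode
  structure(list(per_barcode = data.frame(barcode = bcs, wrong = wrong,
                                          missing = missing,
                                          row.names = NULL,
                                          stringsAsFactors = FALSE),
                 with_barcode = with_barcode, wrong = sum(wrong),
                 missing = sum(missing), D = D, percent = 100 * D),
            class = "difference_report")
}

#' @export
print.difference_report <- function(x, ...) {
  cat("<difference_report>\n")
  cat(sprintf("  reads with a barcode : %d\n", x$with_barcode))
  cat(sprintf("  wrong assignments    : %d\n", x$wrong))
  cat(sprintf("  missing assignments  : %d\n", x$missing))
  cat(sprintf("  difference D         : %.4f (%.2f%%)\n", x$D, x$percent))
  invisible(x)
}
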