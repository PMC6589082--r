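# Fixture builders: everything is generated in code at test time.

# The canonical 4-line FASTQ barcode template (sequence line anchored at
# the 5' end), written next to its barcode list file.
write_fastq_template <- function(dir, list_file = "b.txt", name = "b",
                                 anchored = TRUE) {
  lead <- if (anchored) "" else "{i}"
  lines <- c(
    "{i}",
    sprintf('1 %s{f required, trim, name = "%s", edits = 1, pattern = f"%s"}{i}',
            lead, name, list_file),
    "{i}",
    sprintf("2 {r trim, length = %%%s.length%%}{i}", name))
  path <- file.path(dir, "template.txt")
  writeLines(lines, path)
  path
}

# A tiny deterministic FASTQ: reads constructed from given sequences.
write_reads <- function(path, seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

read_fastq_ids <- function(path) {
  lines <- readLines(path)
  sub("^@", "", lines[seq(1, length(lines), by = 4)])
}

read_fastq_seqs <- function(path) {
  lines <- readLines(path)
  lines[seq(2, length(lines), by = 4)]
}

# Observed per-read assignment from a directory of matched_<name>.fastq
# files produced by a demultiplexing run.
collect_assignments <- function(dir, prefix, all_ids) {
  obs <- rep(NA_character_, length(all_ids))
  names(obs) <- all_ids
  files <- list.files(dir, pattern = paste0("^", prefix), full.names = TRUE)
  for (f in files) {
    b <- sub("\\.fastq$", "", sub(paste0("^", prefix), "", basename(f)))
    obs[read_fastq_ids(f)] <- b
  }
  obs
}
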