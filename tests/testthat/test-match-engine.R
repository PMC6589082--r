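pats_of <- function(src) parse_template(src)$lines[[1]]$patterns

test_that("patterns partition into alternating anchored chunks", {
  kinds <- function(chunks) vapply(chunks, `[[`, "", "kind")
  sizes <- function(chunks) vapply(chunks, function(c) length(c$idx), 1L)

  ch <- partition_chunks(pats_of('{i}{f pattern = "AC"}{i}'))
  expect_equal(kinds(ch), c("interval", "fixed", "interval"))
  expect_equal(sizes(ch), c(1L, 1L, 1L))

  # a leading empty interval chunk anchors a line-initial fixed chunk
  ch <- partition_chunks(pats_of('{f pattern = "AC"}'))
  expect_equal(kinds(ch), c("interval", "fixed"))
  expect_equal(sizes(ch), c(0L, 1L))

  ch <- partition_chunks(pats_of(
    '{i}{f pattern = "AC"}{r length = 2}{i}{f pattern = "GT"}'))
  expect_equal(kinds(ch), c("interval", "fixed", "interval", "fixed"))
  expect_equal(sizes(ch), c(1L, 2L, 1L, 1L))
})

test_that("a line matches a 5' barcode with surrounding interval slack", {
  pats <- pats_of('{i}{f required, trim, name = "b", edits = 1, pattern = "ACGTACGT"}{i}')
  vars <- var_store()
  res <- match_line(pats, "ACGTACGTGGGGTT", vars)
  expect_true(res$matched)
  span <- res$spans[[2]]
  expect_equal(span[1], 0)  # leading interval chunk matched the empty prefix
  expect_equal(var_get(vars, "b", "edits") <= 1, TRUE)

  # {i} alone matches any line and binds nothing
  res <- match_line(pats_of("{i}"), "anything at all")
  expect_true(res$matched)
  expect_equal(res$trim_spans, matrix(integer(0), ncol = 2))

  # a required pattern beyond the edit radius fails the line
  line <- strrep("G", 20)
  expect_true(min(substring_scan_oracle("ACGTACGT", line, lev_dist)) > 1)
  res <- match_line(pats, line)
  expect_false(res$matched)
})

test_that("greedy chunk matching is deliberately not exhaustive", {
  # "ABAB": the first candidate of {f "AB"} is accepted with the leading
  # {i} matching the empty prefix; the trailing {i max = 0} then has two
  # characters left and the line fails, although placing the fuzzy match
  # at positions 2..4 would have succeeded.
  pats <- pats_of('{i}{f required, pattern = "AB"}{i max = 0}')
  expect_false(match_line(pats, "ABAB")$matched)

  # the later placement is genuinely valid: matched when forced
  forced <- pats_of('{i min = 2, max = 2}{f required, pattern = "AB"}{i max = 0}')
  expect_true(match_line(forced, "ABAB")$matched)

  # and the same greedy engine does succeed when the leftover text can be
  # absorbed
  pats2 <- pats_of('{i}{f required, pattern = "AB"}{i}')
  expect_true(match_line(pats2, "ABAB")$matched)
})

test_that("all-optional fixed chunks merge their flanking interval chunks", {
  pats <- pats_of('{i max = 2}{f pattern = "ZZZZ"}{i max = 2}')
  expect_true(match_line(pats, "AAAA")$matched)   # 4 <= 2 + 2 after merge
  expect_false(match_line(pats, "AAAAA")$matched) # 5 > 4: merge then fail
  # when the optional pattern does match, no merge happens
  res <- match_line(pats, "AZZZZA")
  expect_true(res$matched)
  expect_equal(res$spans[[2]], c(1, 5))
})

test_that("within a chunk, later patterns continue from the previous end", {
  pats <- pats_of('{i}{f required, name = "a", pattern = "ACGT"}{r required, length = 2, pattern = "0-9"}{i}')
  res <- match_line(pats, "GGACGT12TT")
  expect_true(res$matched)
  expect_equal(res$spans[[2]], c(2, 6))
  expect_equal(res$spans[[3]], c(6, 8))
  expect_false(match_line(pats, "GGACGTxxTT")$matched)

  # optional mid-chunk patterns are skipped without consuming text
  pats <- pats_of('{i}{f required, pattern = "ACGT"}{r length = 2, pattern = "0-9"}{f required, pattern = "TTTT"}{i}')
  res <- match_line(pats, "ACGTTTTT")
  expect_true(res$matched)
  expect_null(res$spans[[3]])
})

test_that("variables bind on line success with full statistics", {
  f <- tempfile()
  writeLines(c("AAAACCCC\tBC01", "GGGGTTTT\tBC02", "ACACACAC\tBC03"), f)
  pats <- pats_of(sprintf('{i}{f required, name = "b", edits = 1, pattern = f"%s"}{i}', f))
  vars <- var_store()
  res <- match_line(pats, "GGGGTTTAGGG", vars)
  expect_true(res$matched)
  expect_equal(var_get(vars, "b", "pattern_idx"), 1L)
  expect_equal(var_get(vars, "b", "pattern_name"), "BC02")
  expect_equal(var_get(vars, "b", "edits"), 1L)
  expect_equal(var_get(vars, "b", "length"), res$spans[[2]][2] - res$spans[[2]][1])

  # a failed line binds nothing
  vars2 <- var_store()
  res2 <- match_line(pats, strrep("G", 4), vars2)
  expect_false(res2$matched)
  expect_equal(length(var_names(vars2)), 0L)

  # unnamed patterns bind nothing
  vars3 <- var_store()
  match_line(pats_of('{i}{f pattern = "ACGT"}{i}'), "ACGT", vars3)
  expect_equal(length(var_names(vars3)), 0L)
})

test_that("trimming removes matched spans and keeps the rest in order", {
  pats <- pats_of('{i}{f required, trim, pattern = "ACGT"}{i}')
  line <- paste0(strrep("G", 4), "ACGT", strrep("T", 100))
  res <- match_line(pats, line)
  expect_true(res$matched)
  out <- apply_trim(line, res)
  expect_identical(out, paste0(strrep("G", 4), strrep("T", 100)))
  expect_equal(nchar(line) - nchar(out),
               res$trim_spans[1, 2] - res$trim_spans[1, 1])

  # no trim flags: line unchanged
  res2 <- match_line(pats_of('{i}{f pattern = "ACGT"}{i}'), line)
  expect_identical(apply_trim(line, res2), line)

  # trim-flagged interval chunk removes its whole span
  res3 <- match_line(pats_of('{i trim}{f required, pattern = "ACGT"}{i}'), line)
  expect_identical(apply_trim(line, res3), substr(line, 5, nchar(line)))
})

test_that("a record trims sequence and quality lines consistently", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c("AAAACCCC\tBC01", "GGGGTTTT\tBC02"), file.path(dir, "b.txt"))
  tpl <- parse_template_file(write_fastq_template(dir))

  grp <- c("@r1", paste0("AAAACCCC", strrep("G", 100)), "+", strrep("I", 108))
  res <- match_record(tpl, grp)
  expect_true(res$matched)
  out <- res$output_lines[[1]]
  # the bound match length is what both lines lose (the greedy candidate
  # order can settle on a one-shorter prefix of the barcode at one edit)
  blen <- var_get(res$vars, "b", "length")
  expect_true(blen %in% c(7L, 8L))
  expect_equal(nchar(out[2]), 108L - blen)
  expect_equal(nchar(out[2]), nchar(out[4]))
  expect_equal(out[1], "@r1")

  # no barcode within one edit: everything passes through untouched
  grp2 <- c("@r2", strrep("G", 50), "+", strrep("I", 50))
  res2 <- match_record(tpl, grp2)
  expect_false(res2$matched)
  expect_identical(res2$output_lines[[1]], grp2)
})

test_that("order indices sequence template lines so variables exist in time", {
  # the quality-line template (order 2) uses %b.length% bound by the
  # sequence line (order 1) although the quality line is line 4
  dir <- tempfile()
  dir.create(dir)
  writeLines("ACGTACGT\tBC01", file.path(dir, "b.txt"))
  tpl <- parse_template_file(write_fastq_template(dir))
  grp <- c("@r", paste0("ACGTACGT", strrep("A", 10)), "+", strrep("I", 18))
  res <- match_record(tpl, grp)
  expect_true(res$matched)
  expect_equal(nchar(res$output_lines[[1]][4]),
               nchar(res$output_lines[[1]][2]))

  expect_error(
    match_record(list(parse_template("1 {i}"), parse_template("1 {i}")),
                 list("x", "y")),
    "duplicate order index")
})

test_that("paired-end selection matches corresponding barcodes only", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c("AAAACCCC\tF01", "GGGGTTTT\tF02"), file.path(dir, "f.txt"))
  writeLines(c("TTTTGGGG\tR01", "CCCCAAAA\tR02"), file.path(dir, "r.txt"))
  fwd <- parse_template(c(
    "{i}",
    '1 {f required, trim, name = "f", edits = 1, pattern = f"f.txt"}{i}',
    "{i}",
    "2 {r trim, length = %f.length%}{i}"))
  attr(fwd, "base_dir") <- dir
  rev <- parse_template(c(
    "{i}",
    '3 {f required, trim, name = "r", edits = 1, pattern = f"r.txt"[%f.pattern_idx%]}{i}',
    "{i}",
    "4 {r trim, length = %r.length%}{i}"))
  attr(rev, "base_dir") <- dir

  mk <- function(seq) c("@p", seq, "+", strrep("I", nchar(seq)))
  concordant <- list(mk(paste0("GGGGTTTT", strrep("A", 20))),
                     mk(paste0("CCCCAAAA", strrep("G", 20))))
  res <- match_record(list(fwd, rev), concordant)
  expect_true(res$matched)
  expect_equal(var_get(res$vars, "f", "pattern_name"), "F02")
  expect_equal(var_get(res$vars, "r", "pattern_name"), "R02")

  # the reverse read carries the *other* pair's barcode: no match, and
  # both mates pass through unmodified
  discordant <- list(mk(paste0("GGGGTTTT", strrep("A", 20))),
                     mk(paste0("TTTTGGGG", strrep("G", 20))))
  res2 <- match_record(list(fwd, rev), discordant)
  expect_false(res2$matched)
  expect_identical(res2$output_lines, discordant)
})

test_that("caches are transparent to every record result", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c("AAAACCCC\tBC01", "GGGGTTTT\tBC02", "ACACACAC\tBC03"),
             file.path(dir, "b.txt"))
  tpl <- parse_template_file(write_fastq_template(dir, anchored = FALSE))
  set.seed(301)
  for (rep in 1:40) {
    seq <- if (runif(1) < 0.5) {
      paste0(rseq(sample(0:4, 1)), sample(c("AAAACCCC", "GGGGTTTT"), 1),
             rseq(20))
    } else {
      rseq(sample(5:30, 1))
    }
    grp <- c("@x", seq, "+", strrep("I", nchar(seq)))
    a <- match_record(tpl, grp, use_cache = TRUE)
    b <- match_record(tpl, grp, use_cache = FALSE)
    expect_equal(a$matched, b$matched)
    expect_identical(a$output_lines, b$output_lines)
  }
})

test_that("accepted chunk spans never move backwards", {
  pats <- pats_of('{i}{f required, pattern = "AC"}{i}{f required, pattern = "GT"}{i}')
  res <- match_line(pats, "TTACTTGTTT")
  expect_true(res$matched)
  spans <- do.call(rbind, Filter(Negate(is.null), res$spans))
  expect_true(all(diff(as.vector(t(spans))) >= 0))
})

test_that("rebinding one name within a record is rejected", {
  pats <- pats_of('{i}{f required, name = "b", pattern = "AC"}{i}{f required, name = "b", pattern = "GT"}{i}')
  expect_error(match_line(pats, "ACGT"), "already bound")
})
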