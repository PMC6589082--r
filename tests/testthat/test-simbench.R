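test_that("the adapter generator follows its recipe and seed contract", {
  dir <- tempfile()
  dir.create(dir)

  # degenerate fraction: no read carries the adapter
  d0 <- sim_adapter_dataset(50, file.path(dir, "none.fastq"),
                            adapter_fraction = 0, seed = 1)
  expect_true(all(!d0$truth$with_feature))
  expect_true(all(nchar(read_fastq_seqs(file.path(dir, "none.fastq"))) == 130))

  # identical seed, byte-identical output
  f1 <- file.path(dir, "a1.fastq")
  f2 <- file.path(dir, "a2.fastq")
  sim_adapter_dataset(200, f1, seed = 77)
  sim_adapter_dataset(200, f2, seed = 77)
  expect_identical(readLines(f1), readLines(f2))

  # carried fraction is close to 75% (binomial: 2000 draws, sd ~ 0.0097)
  d <- sim_adapter_dataset(2000, file.path(dir, "a.fastq"), seed = 5)
  frac <- mean(d$truth$with_feature)
  expect_true(abs(frac - 0.75) < 0.04)
  # edit profile ~ 50/50 among carriers
  e <- d$truth$edits[d$truth$with_feature]
  expect_true(abs(mean(e == 1) - 0.5) < 0.05)
  # read lengths stay around 130 (exactly 130 +- 1 from a single indel)
  lens <- nchar(read_fastq_seqs(file.path(dir, "a.fastq")))
  expect_true(all(lens >= 129 & lens <= 131))
  expect_true(all(lens[!d$truth$with_feature] == 130))

  # injected edits verified: the feature region is exactly `edits` away
  # from the source adapter
  seqs <- read_fastq_seqs(file.path(dir, "a.fastq"))
  idx <- which(d$truth$with_feature)[1:200]
  for (i in idx) {
    fl <- d$truth$feature_len[i]
    region <- substr(seqs[i], nchar(seqs[i]) - fl + 1, nchar(seqs[i]))
    expect_equal(lev_dist(d$adapter, region), d$truth$edits[i])
  }

  expect_error(sim_adapter_dataset(10, tempfile(), read_length = 20,
                                   adapter_length = 30),
               "exceeds")
})

test_that("the demultiplexing generator follows its recipe", {
  dir <- tempfile()
  dir.create(dir)
  d <- sim_demux_dataset(1000, file.path(dir, "d.fastq"), seed = 9)
  expect_equal(nrow(d$barcodes), 48L)
  expect_true(all(nchar(d$barcodes$sequence) >= 8 &
                  nchar(d$barcodes$sequence) <= 15))
  expect_equal(d$barcodes$name, sprintf("BC%02d", 1:48))
  # list file round-trips through the loader
  lst <- load_list_file(d$barcode_file)
  expect_equal(lst$sequence, d$barcodes$sequence)
  expect_equal(lst$name, d$barcodes$name)

  frac <- mean(!is.na(d$truth$barcode))
  expect_true(abs(frac - 0.5) < 0.06)

  # determinism
  f1 <- file.path(dir, "x1.fastq")
  f2 <- file.path(dir, "x2.fastq")
  sim_demux_dataset(100, f1, seed = 11)
  sim_demux_dataset(100, f2, seed = 11)
  expect_identical(readLines(f1), readLines(f2))

  # injected edits verified against the barcode source
  seqs <- read_fastq_seqs(file.path(dir, "d.fastq"))
  bcs <- stats::setNames(d$barcodes$sequence, d$barcodes$name)
  idx <- which(!is.na(d$truth$barcode))[1:200]
  for (i in idx) {
    region <- substr(seqs[i], 1, d$truth$feature_len[i])
    expect_equal(lev_dist(bcs[[d$truth$barcode[i]]], region),
                 d$truth$edits[i])
  }
})

test_that("min_dist rejection sampling yields cross-prefix separated sets", {
  dir <- tempfile()
  dir.create(dir)
  d <- sim_demux_dataset(10, file.path(dir, "s.fastq"), n_barcodes = 12,
                         min_dist = 4, seed = 13)
  bc <- d$barcodes$sequence
  # independent check with adist over prefixes, both directions
  prefdist <- function(a, b) {
    min(vapply(seq_len(nchar(b)), function(m) {
      lev_dist(a, substr(b, 1, m))
    }, 1))
  }
  for (i in seq_along(bc)) {
    for (j in seq_along(bc)) {
      if (i == j) next
      expect_true(prefdist(bc[i], bc[j]) >= 4,
                  info = sprintf("%s vs %s", bc[i], bc[j]))
    }
  }
  # an infeasible constraint is reported rather than looping forever
  expect_error(
    sim_demux_dataset(1, tempfile(), n_barcodes = 40,
                      barcode_lengths = c(2L, 2L), min_dist = 2,
                      max_tries = 200, seed = 1),
    "infeasible")
})

test_that("uniquely separated barcodes are perfectly recoverable", {
  # fraction 1, no injected edits, cross-prefix distance >= 4, k = 1:
  # every read must land on its true barcode
  dir <- tempfile()
  dir.create(dir)
  d <- sim_demux_dataset(300, file.path(dir, "r.fastq"), n_barcodes = 12,
                         barcode_fraction = 1, edit_probs = c(1, 0),
                         min_dist = 4, seed = 17)
  writeLines(c(
    "{i}",
    '1 {f required, trim, name = "b", edits = 1, pattern = f"r_barcodes.txt"}{i}',
    "{i}",
    "2 {r trim, length = %b.length%}{i}"), file.path(dir, "t.txt"))
  fuzzydemux(file.path(dir, "r.fastq"), file.path(dir, "t.txt"),
             matched = file.path(dir, "m_%b.pattern_name%.fastq"),
             unmatched = file.path(dir, "un.fastq"))
  obs <- collect_assignments(dir, "m_", d$truth$read_id)
  expect_true(all(!is.na(obs)))
  expect_equal(unname(obs), d$truth$barcode)
  rep <- difference_metric(d$truth, obs)
  expect_equal(rep$D, 0)
})

test_that("the difference metric counts wrong and missing reads per barcode", {
  truth <- data.frame(read_id = sprintf("r%02d", 1:12),
                      barcode = c(rep("BC1", 5), rep("BC2", 5), NA, NA))

  # perfect assignment
  perfect <- stats::setNames(truth$barcode, truth$read_id)
  expect_equal(difference_metric(truth, perfect)$D, 0)

  # hand-counted example: with_barcode = 10; BC1's file misses one true
  # read (r01 unassigned) and contains two foreign reads (r06 from BC2 --
  # which also counts as missing from BC2 -- and the barcode-free r11)
  obs <- perfect
  obs["r01"] <- NA          # missing_BC1 + 1
  obs["r06"] <- "BC1"       # wrong_BC1 + 1, missing_BC2 + 1
  obs["r11"] <- "BC1"       # wrong_BC1 + 1
  rep <- difference_metric(truth, obs)
  expect_equal(rep$with_barcode, 10L)
  pb <- rep$per_barcode
  expect_equal(pb$wrong[pb$barcode == "BC1"], 2L)
  expect_equal(pb$missing[pb$barcode == "BC1"], 1L)
  expect_equal(pb$missing[pb$barcode == "BC2"], 1L)
  expect_equal(rep$D, 4 / 10)

  # a smaller hand count: 1 missing + 2 wrong over 10 = 0.3
  obs2 <- perfect
  obs2["r01"] <- NA
  obs2["r11"] <- "BC1"
  obs2["r12"] <- "BC2"
  expect_equal(difference_metric(truth, obs2)$D, 3 / 10)

  # nothing assigned at all: D = 1
  none <- stats::setNames(rep(NA_character_, 12), truth$read_id)
  expect_equal(difference_metric(truth, none)$D, 1)

  # undefined without any barcode-bearing read
  t0 <- data.frame(read_id = "r1", barcode = NA_character_)
  expect_error(difference_metric(t0, c(r1 = NA_character_)), "undefined")
  # mismatched read universe
  expect_error(difference_metric(truth, perfect[1:5]), "cover")
})
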