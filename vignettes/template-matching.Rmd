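---
title: "Template matching for demultiplexing and trimming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template matching for demultiplexing and trimming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzydemux)
```

## The problem

Pooled sequencing runs interleave reads from many samples, each tagged with
a short sample-specific barcode, and reads frequently run through into
synthetic adapter sequence at their 3' end.  Before any analysis the reads
must be demultiplexed (split into per-sample files by barcode) and trimmed
(barcodes and adapters removed), tolerating the sequencer's errors --
substitutions and, on some platforms, insertions and deletions.

Dedicated tools hard-code a handful of read layouts.  `fuzzydemux` instead
describes the layout declaratively: a *template* mirrors the arrangement of
features on each line of a record, and one engine matches any such
arrangement.  A FASTQ record is simply a group of four lines, so a 4-line
template is applied to every four input lines; the same machinery handles
any line-oriented format.

## The template language

Three pattern kinds compose a template line:

* **Fuzzy patterns** `{f ...}` hold one or more *subpatterns* (barcodes,
  adapters, ...) and match when any subpattern occurs within `edits` errors
  under a chosen metric: Hamming (substitutions only), Levenshtein
  (substitutions, insertions, deletions), or restricted
  Damerau–Levenshtein (additionally, adjacent transpositions at unit cost).
  Exactly one subpattern is selected per match.
* **Fixed-length wildcards** `{r length = L, ...}` match exactly `L`
  characters from a character class.
* **Interval-length wildcards** `{i min = a, max = b, ...}` match a run
  whose length lies in `[a, b]`; `{i}` alone matches any number of any
  characters and provides the slack between features.

Named patterns bind `length`, `pattern_idx`, `pattern_name`, and `edits`
for the record; later patterns and output paths reference them as
`%name.field%`.  This is what couples the quality line to the sequence
line (`{r trim, length = %b.length%}` removes exactly as many quality
characters as the barcode match consumed) and what makes paired-end
combinatorial demultiplexing a one-line change (the reverse template
selects `f"r.txt"[%f.pattern_idx%]`, the list entry *corresponding to* the
forward barcode).  Writing matched output to
`matched_%b.pattern_name%.fastq` is demultiplexing.

## Matching machinery

**Fuzzy search.** Subpatterns are located with the classic semi-global
DP over pattern prefixes and text positions: `d(i, 0) = 0` (a match may
start anywhere), `d(0, j) = j`, unit-cost transitions, optionally the
restricted transposition move.  For every text end position within the
budget `k` one match is reported; its start is recovered by carrying
alignment origins forward under the move preference diagonal > vertical >
horizontal, which selects the longest text span among minimal-edit
alignments.  Retaining match spans is the reason this package uses the
banded DP rather than bit-vector distance algorithms, which give distances
but not spans.  Ukkonen's cutoff tracks the deepest DP row still within
budget and skips rows below it, bringing expected work to `O(k |T|)` per
subpattern; the results are provably (and, in the tests, verifiably)
identical to the full DP.  Hamming search instead uses the bit-parallel
Bitap recurrence with `k + 1` state vectors and masks split across
`ceiling(|P|/w)` words (the word width defaults to 63 bits; correctness
does not depend on it).  Wildcard characters (default `N`) match free in
either direction.

**n-gram elimination.** Before any DP, subpatterns that cannot match are
discarded: if a subpattern with `|P| > (k+1)(n-1) + k` occurs within `k`
edits, at least one of its overlapping n-grams occurs verbatim in the text,
so a subpattern none of whose n-grams occurs can be dropped.  The automatic
size is the largest `n` with `n < (|P|-k)/(k+1) + 1`, minimized over the
subpatterns sharing the filter (15 for a 30-nt adapter at one edit; 4 for
an 8-nt barcode).  Short subpatterns, and any subpattern or text containing
wildcards, always survive.

**Interval chains.** Consecutive interval-length wildcards are matched
together: `f(i, j)` says whether patterns `1..j` can partition the first
`i` segment characters into in-order runs, each run's length and characters
admissible.  Two precomputations reduce the naive cubic recursion to
`O(|patterns| × |T|)`: the longest admissible run ending at each position
(`l`), which bounds where a pattern can start, and per-pattern prefix sums
of `f` (`p`), which turn the start-window sum into two lookups with
out-of-range indices clamped to zero.  `f` is kept saturated at 0/1 --
only `f ≠ 0` is ever queried, and saturation cannot overflow.  The state is
anchored at a fixed text index and *extendable*: growing the frontier never
recomputes or changes existing cells.

**The greedy line matcher.** A line's patterns are partitioned into
maximal runs of interval patterns alternating with maximal runs of
fixed-length patterns (fuzzy + fixed wildcards), with empty interval chunks
inserted at the line ends so every fixed chunk is preceded and followed by
an interval chunk.  For each (interval chunk, fixed chunk) pair, candidate
locations of a starting pattern (the leading optional patterns plus the
first required one) are tried in ascending end position, then ascending
edit count, then ascending subpattern index; the rest of the fixed chunk is
matched consecutively from the candidate's end (each fuzzy pattern taking
its lowest-edit match), and the candidate is accepted iff the preceding
interval chunk matches the gap back to the cursor.  The cursor then jumps
and never backtracks.  An all-optional fixed chunk that never matches is
skipped and its flanking interval chunks merge.  Greedy means intentionally
not optimal: an early accepted candidate can starve a later chunk (the test
suite pins one such adversarial fixture); the exhaustive alternative was
rejected for its running time.  Two caches -- per-position fixed-pattern
results and the extendable interval DP state (valid because a chunk's
anchor never moves) -- change running time, never results.

**Anchored candidates.** When a pattern's start position is pinned -- an
empty interval chunk precedes it, or it continues a chunk from the previous
pattern's end -- candidates are generated by an *anchored* variant of the
DP (`d(i, 0) = i`) that reports alignments constrained to start exactly at
the pinned position.  This is a deliberate design choice rather than a
filter on the unanchored results: the unanchored scan reports one match per
end position, and a cheaper shifted alignment ending at the same position
would otherwise shadow a perfectly valid anchored alignment.  Concretely, a
5'-anchored barcode whose single sequencing error hits the first base
would be reported as a shifted exact match and rejected, and the read would
be lost; with anchored candidates it is recovered.  This is what makes
"every barcode within one edit is found" hold exactly in the recovery
experiments below.

## Determinism and parallelism

Records are independent, so the driver processes batches of records with a
producer–consumer scheme: the reader fills `workers` batches of
`batch_size` records, forked workers match records, and the writer appends
each batch's results in batch order.  Per-destination output content (as a
multiset of records) is invariant to `workers` and `batch_size`; with one
worker (or `preserve_order`) output order equals input order.  In-flight
memory is bounded by `workers × batch_size` records.  Unmatched records are
written byte-identical to their input and are never trimmed.

## The synthetic benchmarks

`sim_adapter_dataset()` emulates 3'-adapter read-through: one shared
random 30-nt adapter; 75% of reads carry it at the 3' end, half exact and
half with exactly one edit (kind uniform over substitution, insertion,
deletion; position uniform within the feature; a substitution always
changes the base); reads total ~130 nt -- exactly 130 without the adapter,
100 random + adapter (±1 after an indel) with it.  `sim_demux_dataset()`
emulates 5' demultiplexing: 48 random barcodes with lengths uniform in
8–15; each read starts with a barcode (probability 0.5, mutated with the
same 0/1-edit profile) followed by 100 random nucleotides, or is just the
100 random nucleotides.  Both draw all randomness read by read, so a seed
reproduces a dataset byte for byte and appending reads never perturbs
earlier ones.  Ground truth (feature presence, injected edit count, feature
length) is returned alongside.

What these generators do *not* emulate: position-dependent quality decay,
non-uniform error spectra, chimeras, or correlated errors.  Passing the
recovery experiments shows the matching machinery is exact under the
declared error model, not that real libraries are error-free.

**Barcode separation.** The controlled-recovery experiment constrains the
barcode set to a minimum pairwise distance of 4.  Because matching is
prefix-anchored and semi-global, the constraint is enforced on the
*cross-prefix* Levenshtein distance (no barcode within 3 edits of any
prefix of another), not on full-length distance: with mixed lengths 8–15, a
short barcode can lie within one or two edits of a longer barcode's prefix
even when the full-length distance is ≥ 4, and the greedy engine -- which
tries candidates in ascending end order -- would then assign the shorter
barcode first.  A wrong barcode can precede the true one only if it is
within 2 edits of a prefix of the true barcode (1 engine edit + 1 injected
edit), which cross-prefix separation ≥ 4 excludes with a one-edit margin.
This is why perfect recovery (difference 0) is a theorem under the
generator's conditions, and the experiment verifies the implementation
against it.  Sampling is incremental rejection (each candidate checked
against the accepted set); at these lengths the per-pair conflict rate is a
few percent, so 48 barcodes cost a few hundred candidate draws.

**The difference metric.** Demultiplexing output is scored as
`D = (Σ_b wrong_b + missing_b) / with_barcode`: per barcode, the reads
present in its file that do not belong plus the reads that belong but are
absent, normalized by the number of barcode-carrying reads.  A read
assigned to the wrong barcode counts twice (wrong there, missing from its
own file); an unassigned carrier counts once; an assigned non-carrier
counts once.

## Numerical and design choices

* **Coordinates** are 0-based, half-open `[start, end)` everywhere public,
  including subpattern indices (`pattern_idx` 0-based, matching the
  selection operator `f"file"[%x.pattern_idx%]`).  The DP internals use
  1-based prefix indices; fixing one public convention avoids off-by-one
  drift.
* **Damerau variant**: restricted / optimal string alignment (each
  character in at most one transposition) -- the standard choice for read
  error models, and it keeps the DP shape.
* **Traceback ties**: diagonal > vertical > horizontal (transposition
  last), i.e. the longest text span among minimal-edit alignments.
* **Unbounded interval maxima** are treated as the segment length, keeping
  the prefix-sum window finite; out-of-range prefix indices contribute
  zero.
* **Trim flags on interval patterns** must be uniform within a chunk (the
  chunk matches as a unit, so individual interval spans inside it are not
  identified); a named interval pattern must be alone in its chunk for the
  same reason.
* **Candidate order** (ascending end, then edits, then subpattern index)
  makes the greedy engine deterministic.  One visible consequence: with
  k = 1, an 8-nt barcode's 7-nt prefix (one deletion) ends earlier than
  the exact match and is accepted first, so trims can be one base shorter
  than the feature; sequence and quality stay consistent because both use
  the bound match length.
* **Degenerate inputs**: empty text lines match `{i}` and zero-length
  matches are representable (`d(0, j) = j` admits a zero-length match when
  `j ≤ k`); an empty interval chunk matches exactly the empty segment.
* **Problem sizes** in the shipped experiments -- 50,000 reads for adapter
  recovery, 20,000 for demultiplexing, 5,000 for the concurrency contract,
  exhaustive oracle sweeps over binary-alphabet strings up to |P| ≤ 3,
  |T| ≤ 4 plus seeded random draws up to |P| ≤ 6, |T| ≤ 10 -- were chosen
  so the full suite exercises every code path at statistically meaningful
  scale while staying comfortable to run on a laptop; the recovery
  properties they check are scale-free.

## Limitations

Binary formats (BAM) cannot be processed; records must be line-delimited,
which also excludes multi-line FASTA.  Quality scores are never
interpreted -- there is no quality trimming.  The greedy matcher can reject
lines an exhaustive segmentation would accept (by design).  Templates are
byte-oriented: multi-byte characters work in fuzzy subpatterns but
character classes compare single bytes.

## A worked example

```{r example}
dir <- tempfile()
dir.create(dir)
writeLines(c("ACGTACGT\tBC01", "TTGGCCAA\tBC02"), file.path(dir, "b.txt"))
writeLines(c(
  "{i}",
  '1 {f required, trim, name = "b", edits = 1, pattern = f"b.txt"}{i}',
  "{i}",
  "2 {r trim, length = %b.length%}{i}"), file.path(dir, "template.txt"))
writeLines(c("@r1", "ACGTACGTGGGGTTTT", "+", "IIIIIIIIIIIIIIII",
             "@r2", "CCCCCCCCCCCCCCCC", "+", "IIIIIIIIIIIIIIII"),
           file.path(dir, "input.fastq"))
fuzzydemux(file.path(dir, "input.fastq"), file.path(dir, "template.txt"),
           matched = file.path(dir, "matched_%b.pattern_name%.fastq"),
           unmatched = file.path(dir, "unmatched.fastq"))
readLines(file.path(dir, "matched_BC01.fastq"))
```
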