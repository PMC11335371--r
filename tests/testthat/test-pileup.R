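# Pileup geometry: time-scale, molecule-scale, clipping, track assembly.

sig_of <- function(n, id = "r") raw_signal(id, seq_len(n) * 10L, 1000, 0, 1000)

test_that("time-scale spaces samples uniformly and tracks base boundaries", {
  aln <- ss_alignment("r", ss_ops(rep("M", 2), c(4, 6)), 0, 10, 0, 2,
                      seq_kind = "read")
  g <- layout_time_scale(aln, sig_of(10))
  expect_equal(g$points$x, 0:9)
  expect_equal(g$boundaries, c(4, 10))       # cumulative MATCH lengths
  expect_equal(nrow(g$points), 10L)          # glyph sample count = signal span
})

test_that("molecule-scale packs each base's samples into an equal column", {
  aln <- ss_alignment("r", ss_ops(rep("M", 2), c(3, 6)), 0, 9, 0, 2,
                      seq_kind = "read")
  g <- layout_molecule_scale(aln, sig_of(9), base_width = 12)
  expect_equal(g$points$x[1:3], c(2, 6, 10))
  expect_equal(g$points$x[4:9], c(13, 15, 17, 19, 21, 23))
})

test_that("deletions produce labelled gap spans and insertions border markers", {
  aln <- ss_alignment("r", ss_ops(c("M", "D", "M"), c(3, 1, 3)), 0, 6, 0, 3,
                      seq_kind = "reference")
  g <- layout_molecule_scale(aln, sig_of(6), base_width = 10, seq = "ACG")
  expect_equal(nrow(g$gap_spans), 1L)
  expect_equal(g$gap_spans$x0, 10)
  expect_equal(g$gap_spans$x1, 20)
  expect_equal(g$gap_spans$label, "C")
  ins <- ss_alignment("r", ss_ops(c("M", "I", "M"), c(3, 2, 3)), 0, 8, 0, 2,
                      seq_kind = "reference")
  gi <- layout_molecule_scale(ins, sig_of(8), base_width = 10)
  expect_length(gi$insertion_markers, 1L)
  expect_equal(gi$insertion_markers[[1]]$x, 10)      # border of preceding base
  expect_length(gi$insertion_markers[[1]]$values, 2L)
})

test_that("every aligned sample appears exactly once in its glyph", {
  set.seed(606)
  for (i in 1:80) {
    ops <- rand_ss_ops(sample(1:15, 1))
    if (sum(ops$kind == "M") == 0L) next
    strand <- sample(c("+", "-"), 1)
    aln <- rand_ss_alignment(ops, strand = strand)
    nsamp <- aln$sig_end - aln$sig_start
    sig <- raw_signal("r1", seq_len(aln$sig_end + 5L), 1000, 0, 1000)
    g <- layout_molecule_scale(aln, sig, base_width = 10)
    got <- sort(c(g$points$y,
                  unlist(lapply(g$insertion_markers, `[[`, "values"))))
    want <- sort(signal_pA(sig)[(aln$sig_start + 1L):aln$sig_end])
    expect_equal(got, want)
    # molecule-scale column-width invariance: samples of base p stay inside
    # [(p - origin) * bw, (p - origin + 1) * bw]
    off <- g$points$x / 10 - (g$points$base_pos - aln$seq_start)
    expect_true(all(off > 0 & off < 1))
  }
})

test_that("clipping to a region preserves validity and drops outside samples", {
  set.seed(11317)
  for (i in 1:80) {
    case <- rand_cigar_case()
    s2r <- ss_alignment("r", ss_ops(rep("M", case$n), case$dwell), 0,
                        sum(case$dwell), 0, case$n, seq_kind = "read",
                        strand = case$strand)
    aln <- realign(s2r, read_record("r", strrep("A", case$n), "ref",
                                    case$ref_start, case$cigar, case$strand))
    lo <- aln$seq_start + sample(0:3, 1)
    hi <- max(lo + 1L, aln$seq_end - sample(0:3, 1))
    cl <- clip_to_region(aln, region("ref", lo, hi))
    if (is.null(cl)) next
    expect_length(ss_validate(cl), 0)
    expect_gte(cl$seq_start, lo)
    expect_lte(cl$seq_end, hi)
    expect_gte(cl$sig_start, aln$sig_start)
    expect_lte(cl$sig_end, aln$sig_end)
  }
})

test_that("pileups separate strands, share columns, and honor selection", {
  b <- simulate_dataset(tiny_model, ref_len = 120, depth = 8,
                        minus_fraction = 0.4, seed = 42)
  reg <- region("ref1", 30, 60)
  lay <- build_pileup(reg, b$truth$sig2ref, b$signals, b$reference)
  kinds <- vapply(lay$tracks, `[[`, "", "kind")
  strands <- vapply(lay$tracks, `[[`, "", "strand")
  expect_equal(kinds, c("pileup_overlay", "stacked_reads",
                        "pileup_overlay", "stacked_reads"))
  expect_equal(strands, c("+", "+", "-", "-"))
  expect_equal(lay$width, 30 * lay$base_width)
  expect_equal(nrow(lay$columns), 30L)
  expect_equal(unique(lay$columns$x1 - lay$columns$x0), lay$base_width)
  # minus glyph base columns coincide with plus columns
  for (tr in lay$tracks) for (g in tr$glyphs) {
    col <- floor(g$points$x / lay$base_width)
    expect_equal(col + reg$start, g$points$base_pos)
  }
  # stacked counts match strand split
  n_plus <- sum(vapply(b$reads, function(r) r$strand == "+", TRUE))
  expect_length(lay$tracks[[2]]$glyphs, n_plus)
  expect_length(lay$tracks[[4]]$glyphs, length(b$reads) - n_plus)
  # deselect all: overlays empty, stacks unchanged
  lay0 <- build_pileup(reg, b$truth$sig2ref, b$signals, b$reference,
                       selected = character(0))
  expect_length(lay0$tracks[[1]]$glyphs, 0)
  expect_length(lay0$tracks[[2]]$glyphs, n_plus)
})

test_that("annotation and simulated tracks come first, empty regions warn", {
  b <- simulate_dataset(tiny_model, ref_len = 100, depth = 4, seed = 5)
  bedf <- withr::local_tempfile(fileext = ".bed")
  writeLines("ref1\t40\t42\tCpG", bedf)
  sim <- simulate_dataset(tiny_model, reference = unname(b$reference),
                          depth = 2, seed = 6, read_prefix = "sim")
  lay <- build_pileup(region("ref1", 35, 55), b$truth$sig2ref, b$signals,
                      b$reference, bed = read_bed(bedf),
                      sim = list(alignments = sim$truth$sig2ref,
                                 signals = sim$signals))
  kinds <- vapply(lay$tracks, `[[`, "", "kind")
  expect_equal(kinds[1:2], c("annotation", "simulated"))
  expect_equal(nrow(lay$tracks[[1]]$intervals), 1L)
  expect_warning(
    build_pileup(region("ref1", 35, 55), list(), list(), b$reference),
    "no reads overlap")
})
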