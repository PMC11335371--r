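# I/O contracts: signal container, SAM/PAF tags, region queries, BED,
# pore models.

test_that("pA conversion applies the calibration elementwise", {
  s <- raw_signal("r1", c(0, 1, 2), digitisation = 8192, offset_pA = 0,
                  range_pA = 8192)
  expect_equal(signal_pA(s), c(0, 1, 2))
  s2 <- raw_signal("r2", 0, digitisation = 1000, offset_pA = 10,
                   range_pA = 1000)
  expect_equal(signal_pA(s2), 10)
})

test_that("signal container round-trips samples and calibration", {
  sigs <- list(
    a = raw_signal("a", sample.int(1000, 50), 8192, 10, 1200),
    b = raw_signal("b", sample.int(1000, 5), 4096, -3, 800, 3012))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signal_container(sigs, f, stamp = "test")
  back <- read_signal_container(f)
  expect_equal(back, sigs)
})

test_that("signal container rejects missing calibration and duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c('{"read_id":"x","digitisation":8192,"range_pA":1200,"sampling_rate":4000}',
               "1\t2\t3"), f)
  expect_error(read_signal_container(f), "read x.*offset_pA")
  sigs <- list(raw_signal("a", 1:3, 8192, 0, 1200),
               raw_signal("a", 4:6, 8192, 0, 1200))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_signal_container(sigs, f2)
  expect_error(read_signal_container(f2), "duplicate read_id.*a")
})

test_that("SAM round trip preserves tags byte-identically and coordinates", {
  recs <- list(
    read_record("r1", "ACGTACGT", "chr1", 41L, "3S5M", "+",
                tags = c("ss:Z:5,1I4,2D6,", "si:Z:9,25,41,48", "XY:i:7")),
    read_record("r2", "ACGTAACC", "chr1", 100L, "8M", "-",
                tags = "mv:B:c,5,1,0,1,1,0,1,1,0,1,1"))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, f, ref_lengths = c(chr1 = 500L))
  back <- read_sam(f)
  for (i in 1:2) {
    expect_identical(back[[i]]$tags, recs[[i]]$tags)
    expect_identical(back[[i]]$ref_start, recs[[i]]$ref_start)
    expect_identical(back[[i]]$sequence, recs[[i]]$sequence)
    expect_identical(back[[i]]$strand, recs[[i]]$strand)
  }
  # write(read(x)) is byte-stable
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(back, f2, header = attr(back, "header"))
  expect_identical(readLines(f), readLines(f2))
})

test_that("SAM parse errors carry line numbers", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               paste(c("r1", 0, "c", 1, 60, "3Q", "*", 0, 0, "ACG", "*"),
                     collapse = "\t")), f)
  expect_error(read_sam(f), "line 2")
})

test_that("PAF and SAM forms of one alignment agree", {
  truth <- read_record("r9", "ACGTACGTAA", "chr2", 77L, "4M2D6M", "-",
                       tags = c("ss:Z:4,2D6,", "si:Z:0,60,77,89"))
  fs <- withr::local_tempfile(fileext = ".sam")
  fp <- withr::local_tempfile(fileext = ".paf")
  write_sam(list(truth), fs)
  write_paf(list(truth), fp, ref_lengths = c(chr2 = 200L))
  a <- read_sam(fs)[[1]]; b <- read_paf(fp)[[1]]
  for (field in c("read_id", "ref_name", "ref_start", "cigar", "strand", "tags"))
    expect_identical(a[[field]], b[[field]])
})

test_that("region queries equal a full scan + overlap filter", {
  set.seed(99)
  n <- 80L
  recs <- lapply(seq_len(n), function(i)
    read_record(sprintf("r%02d", i), strrep("A", 10L), "chr1",
                sample.int(400L, 1L) - 1L, "10M",
                sample(c("+", "-"), 1L)))
  recs <- recs[order(vapply(recs, function(r) r$ref_start, 0L))]
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, f, ref_lengths = c(chr1 = 500L))
  for (trial in 1:20) {
    s <- sample.int(400L, 1L) - 1L
    reg <- region("chr1", s, s + sample.int(60L, 1L))
    got <- vapply(read_alignments(f, reg), function(r) r$read_id, "")
    want <- vapply(Filter(function(r)
      r$ref_start < reg$end && r$ref_start + 10L > reg$start, recs),
      function(r) r$read_id, "")
    expect_identical(got, want)
  }
  reg0 <- region("chrX", 0, 10)
  expect_length(read_alignments(f, reg0), 0)
})

test_that("BED reading sorts, labels and validates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t20\t25\tsiteB", "chr1\t5\t6\tCpG"), f)
  tr <- read_bed(f)
  expect_equal(tr$start, c(5L, 20L))
  expect_equal(tr$end, c(6L, 25L))
  expect_equal(tr$label, c("CpG", "siteB"))
  fe <- withr::local_tempfile(fileext = ".bed")
  file.create(fe)
  expect_equal(nrow(read_bed(fe)), 0L)
  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t10\tempty", fb)
  expect_error(read_bed(fb))
})

test_that("pore model I/O counts k-mers and rejects malformed tables", {
  m <- generate_pore_model(k = 3L, msb = 0L)
  expect_length(m$level_mean, 64L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pore_model(m, f, stamp = "0.1.0")
  back <- read_pore_model(f)
  expect_equal(back$k, 3L)
  expect_true(back$complete)
  expect_equal(back$level_mean, m$level_mean, tolerance = 1e-12)
  # duplicate k-mer
  lines <- readLines(f)
  writeLines(c(lines, lines[3]), f)
  expect_error(read_pore_model(f), "duplicate")
  # mixed k
  writeLines(c(lines, "ACGT\t91\t1"), f)
  expect_error(read_pore_model(f), "mixed")
  # incomplete model warns
  writeLines(lines[1:10], f)
  expect_warning(read_pore_model(f), "incomplete")
})

test_that("region strings parse 1-based inclusive and reject junk", {
  reg <- parse_region("ref1:100-250")
  expect_equal(c(reg$start, reg$end), c(99L, 250L))
  expect_error(parse_region("ref1:100"), "malformed region")
  expect_error(parse_region("ref1:0-5"), "malformed region")
})
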