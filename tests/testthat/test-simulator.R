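# The simulator: determinism, signal statistics, internal consistency,
# error injection.

test_that("zero-noise signal reproduces the model levels to DAC quantisation", {
  m <- generate_pore_model(k = 3L, msb = 1L, minor_weight = 0)
  b <- simulate_dataset(m, ref_len = 10, depth = 1, noise_multiplier = 0,
                        minus_fraction = 0, trim_len = 0, seed = 2)
  id <- names(b$signals)[1]
  sig <- b$signals[[id]]
  dwell <- b$truth$sig2read[[id]]$ops$len
  kmers <- substring(paste0(b$reference, strrep(substring(b$reference, 10, 10), 2)),
                     1:10, 3:12)
  want <- rep(unname(m$level_mean[kmers]), dwell)
  quant <- sig$range_pA / sig$digitisation
  expect_lt(max(abs(signal_pA(sig) - want)), quant / 2 + 1e-9)
})

test_that("the same seed reproduces the bundle byte for byte", {
  b1 <- simulate_dataset(tiny_model, ref_len = 60, depth = 3, seed = 123)
  b2 <- simulate_dataset(tiny_model, ref_len = 60, depth = 3, seed = 123)
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(b1, d1, stamp = "x"); write_dataset(b2, d2, stamp = "x")
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  b3 <- simulate_dataset(tiny_model, ref_len = 60, depth = 3, seed = 124)
  expect_false(identical(b1$signals, b3$signals))
})

test_that("bundle invariants: reform and realign recover the stored truth", {
  b <- simulate_dataset(tiny_model, ref_len = 90, depth = 5,
                        minus_fraction = 0.5, seed = 31)
  for (id in names(b$reads)) {
    s2r <- reform(b$move_tables[[id]], b$reads[[id]], b$signals[[id]])
    expect_equal(s2r$ops$len, b$truth$sig2read[[id]]$ops$len)
    s2f <- realign(s2r, b$reads[[id]])
    expect_equal(unclass(s2f)[-2], unclass(b$truth$sig2ref[[id]])[-2])
    expect_equal(s2f$ops$len, b$truth$sig2ref[[id]]$ops$len)
    expect_length(
      ss_validate(s2f, signal_len = length(b$signals[[id]]$samples),
                  seq_len = nchar(b$reference)), 0)
  }
})

test_that("degenerate simulation parameters are rejected", {
  expect_error(simulate_dataset(tiny_model, depth = 0), "depth")
  expect_error(simulate_dataset(tiny_model, dwell_mean = 0.5), "dwell mean")
})

test_that("a +8 pA modification on half the reads is recoverable at depth", {
  m <- generate_pore_model(k = 3L, msb = 0L)
  site <- 25L; delta <- 8
  b <- simulate_dataset(m, ref_len = 60, depth = 50, minus_fraction = 0,
                        seed = 55,
                        mods = data.frame(pos = site, delta_pA = delta,
                                          fraction = 0.5))
  per_read_mean <- vapply(names(b$reads), function(id) {
    aln <- b$truth$sig2ref[[id]]
    idx <- sigpile:::op_sample_indices(aln)[[site + 1L]]
    mean(signal_pA(b$signals[[id]])[idx])
  }, 0)
  mod <- b$truth$modified[names(b$reads)]
  expect_true(any(mod) && any(!mod))
  diff_hat <- mean(per_read_mean[mod]) - mean(per_read_mean[!mod])
  se <- sqrt(var(per_read_mean[mod]) / sum(mod) +
             var(per_read_mean[!mod]) / sum(!mod))
  expect_lt(abs(diff_hat - delta), 2 * se)
})

test_that("variants alter the molecule and its signal", {
  m <- generate_pore_model(k = 3L, msb = 1L, minor_weight = 0)
  ref <- strrep("A", 30)
  b <- simulate_dataset(m, reference = ref, depth = 2, minus_fraction = 0,
                        noise_multiplier = 0, trim_len = 0, seed = 9,
                        variants = data.frame(pos = 10L, base = "T",
                                              fraction = 1))
  id <- names(b$reads)[1]
  expect_equal(substring(b$reads[[id]]$sequence, 11, 11), "T")
  idx <- sigpile:::op_sample_indices(b$truth$sig2ref[[id]])[[9]]  # base 8: k-mer AAT
  expect_equal(mean(signal_pA(b$signals[[id]])[idx]),
               unname(m$level_mean[["AAT"]]), tolerance = 0.1)
})

test_that("inject_errors is the identity at zero rates and updates truth otherwise", {
  b <- simulate_dataset(tiny_model, ref_len = 80, depth = 4, seed = 71)
  expect_identical(inject_errors(b), b)
  eb <- inject_errors(b, sub_rate = 0.05, ins_rate = 0.05, del_rate = 0.05,
                      softclip_len = 2L, seed = 5)
  changed <- FALSE
  for (id in names(eb$reads)) {
    rec <- eb$reads[[id]]
    if (!identical(rec$cigar, b$reads[[id]]$cigar)) changed <- TRUE
    s2r <- reform(eb$move_tables[[id]], rec, eb$signals[[id]])
    expect_equal(s2r$ops$len, eb$truth$sig2read[[id]]$ops$len)
    s2f <- realign(s2r, rec)
    expect_length(
      ss_validate(s2f, signal_len = length(eb$signals[[id]]$samples),
                  seq_len = nchar(eb$reference)), 0)
    expect_equal(s2f$ops$len, eb$truth$sig2ref[[id]]$ops$len)
  }
  expect_true(changed)
  expect_error(inject_errors(b, sub_rate = 1.2), "rates")
})

test_that("deleting the only base of a read is rejected", {
  m <- tiny_model
  b <- simulate_dataset(m, reference = "ACGT", depth = 1, minus_fraction = 0,
                        trim_len = 0, seed = 1)
  # shrink to a single-base read by hand
  id <- names(b$reads)[1]
  d1 <- b$truth$sig2read[[id]]$ops$len[1]
  b$reads[[id]] <- read_record(id, "A", "ref1", 0L, "1M", "+")
  b$truth$sig2read[[id]] <- ss_alignment(id, ss_ops("M", d1), 0, d1, 0, 1,
                                         seq_kind = "read")
  b$signals[[id]] <- raw_signal(id, b$signals[[id]]$samples[1:d1],
                                8192, 10, 1200)
  expect_error(inject_errors(b, del_rate = 1), "empty")
})
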