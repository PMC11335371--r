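# K-mer-to-base shift correction: MSB scoring, shift application, offset
# recovery.

test_that("msb score is 1 for a pure positional model and 0 elsewhere", {
  m <- generate_pore_model(k = 4L, msb = 2L, minor_weight = 0)
  res <- msb_position(m)
  expect_equal(res$msb, 2L)
  expect_equal(res$scores[3], 1)
  expect_equal(res$scores[-3], rep(0, 3))
})

test_that("degenerate and incomplete models are rejected", {
  flat <- pore_model(2, c(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)),
                     rep(100, 16), rep(1, 16))
  expect_error(msb_position(flat), "degenerate model")
  expect_warning(part <- pore_model(3, c("AAA", "AAC"), c(1, 2), c(1, 1)),
                 "incomplete")
  expect_error(msb_position(part), "complete")
})

test_that("msb scoring matches a brute-force computation on a mixed model", {
  # level = 0.8*f(base at 1) + 0.2*f(base at 3) + noise
  set.seed(808)
  grid <- expand.grid(p4 = DNA_BASES_T(), p3 = DNA_BASES_T(),
                      p2 = DNA_BASES_T(), p1 = DNA_BASES_T(),
                      stringsAsFactors = FALSE)
  kmers <- paste0(grid$p1, grid$p2, grid$p3, grid$p4)
  f <- c(A = 80, C = 90, G = 100, T = 110)
  level <- 0.8 * f[grid$p2] + 0.2 * f[grid$p4] + rnorm(256, 0, 0.1)
  m <- pore_model(4, kmers, unname(level), rep(1, 256))
  res <- msb_position(m)
  expect_equal(res$msb, 1L)
  # brute force eta-squared per position on the same table
  for (p in 1:4) {
    key <- substring(kmers, p, p)
    gm <- tapply(level, key, mean); gn <- tapply(level, key, length)
    ssb <- sum(gn * (gm - mean(level))^2)
    sst <- sum((level - mean(level))^2)
    expect_equal(res$scores[p], ssb / sst, tolerance = 1e-12)
  }
})

test_that("apply_shift re-pairs ops and preserves conservation", {
  a <- ss_alignment("r", ss_ops(rep("M", 5), c(3, 4, 5, 6, 7)), 0, 25, 10, 15,
                    seq_kind = "reference", strand = "+")
  expect_equal(apply_shift(a, 0), a)
  s1 <- apply_shift(a, 1)
  expect_equal(nrow(s1$ops), 4L)
  expect_equal(c(s1$seq_start, s1$seq_end), c(11L, 15L))
  expect_equal(c(s1$sig_start, s1$sig_end), c(0L, 18L))  # last op's 7 samples dropped
  expect_length(ss_validate(s1), 0)
  # minus strand shifts in the opposite sequence direction
  am <- ss_alignment("r", ss_ops(rep("M", 5), c(3, 4, 5, 6, 7)), 0, 25, 10, 15,
                     seq_kind = "reference", strand = "-")
  m1 <- apply_shift(am, 2)
  expect_equal(c(m1$seq_start, m1$seq_end), c(10L, 13L))
  expect_equal(c(m1$sig_start, m1$sig_end), c(0L, 12L))
  expect_error(apply_shift(a, 5), "smaller than the number of MATCH ops")
})

test_that("apply_shift stays valid on fuzzed alignments with indels", {
  set.seed(2718)
  for (i in 1:120) {
    ops <- rand_ss_ops(sample(3:20, 1))
    n_match <- sum(ops$kind == "M")
    if (n_match < 2L) next
    a <- rand_ss_alignment(ops, strand = sample(c("+", "-"), 1))
    s <- sample.int(n_match - 1L, 1L)
    out <- apply_shift(a, s)
    expect_length(ss_validate(out), 0)
    expect_equal(out$seq_end - out$seq_start,
                 a$seq_end - a$seq_start - s)
  }
})

test_that("offset recovery finds the designated MSB and zero when pre-shifted", {
  msb <- 2L
  model <- generate_pore_model(k = 6L, msb = msb)
  b <- simulate_dataset(model, ref_len = 400, depth = 12, seed = 97)
  rep1 <- calculate_offset(b$truth$sig2ref, b$signals, b$reference, model)
  expect_equal(rep1$chosen_shift, msb)
  expect_true(all(rep1$separation_score >= 0 & rep1$separation_score <= 1,
                  na.rm = TRUE))
  shifted <- lapply(b$truth$sig2ref, apply_shift, msb)
  rep0 <- calculate_offset(shifted, b$signals, b$reference, model)
  expect_equal(rep0$chosen_shift, 0L)
})

test_that("a k = 1 model has the single trivial candidate", {
  m1 <- pore_model(1, DNA_BASES_T(), c(80, 90, 100, 110), rep(1, 4))
  b <- simulate_dataset(m1, ref_len = 80, depth = 4, seed = 3)
  rep <- calculate_offset(b$truth$sig2ref, b$signals, b$reference, m1)
  expect_equal(rep$candidate_shifts, 0L)
  expect_equal(rep$chosen_shift, 0L)
})

test_that("different protocols (MSB positions) yield different offsets", {
  mA <- generate_pore_model(k = 5L, msb = 1L)
  mB <- generate_pore_model(k = 5L, msb = 3L)
  bA <- simulate_dataset(mA, ref_len = 300, depth = 10, seed = 21)
  bB <- simulate_dataset(mB, ref_len = 300, depth = 10, seed = 22)
  rA <- calculate_offset(bA$truth$sig2ref, bA$signals, bA$reference, mA,
                         protocol_label = "protoA")
  rB <- calculate_offset(bB$truth$sig2ref, bB$signals, bB$reference, mB,
                         protocol_label = "protoB")
  expect_equal(rA$chosen_shift, 1L)
  expect_equal(rB$chosen_shift, 3L)
  expect_false(rA$protocol_label == rB$protocol_label)
})

test_that("calculate_offset rejects empty input and flags few-base data", {
  m <- generate_pore_model(k = 3L, msb = 1L)
  expect_error(calculate_offset(list(), list(), "ACGT", m), "no alignments")
  b <- simulate_dataset(m, reference = strrep("AC", 40), depth = 3, seed = 8)
  expect_warning(
    rep <- calculate_offset(b$truth$sig2ref, b$signals, b$reference, m),
    "low-confidence")
  expect_true(rep$low_confidence)
})
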