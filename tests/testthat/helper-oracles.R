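# Fixture builders and independent oracles used across the suite.

# random canonical ss op list (no I/D runs), lengths 1..20
rand_ss_ops <- function(n_ops) {
  if (n_ops == 0L) return(ss_ops())
  kinds <- character(n_ops)
  kinds[1L] <- sample(c("M", "I", "D"), 1L, prob = c(0.6, 0.2, 0.2))
  for (i in seq_len(n_ops)[-1L]) {
    allowed <- if (kinds[i - 1L] == "M") c("M", "I", "D")
               else setdiff(c("M", "I", "D"), kinds[i - 1L])
    kinds[i] <- sample(allowed, 1L)
  }
  ss_ops(kinds, sample.int(20L, n_ops, replace = TRUE))
}

# wrap an op list into a consistent ss_alignment with random offsets
rand_ss_alignment <- function(ops, strand = "+", seq_kind = "reference",
                              signal_direction = "forward") {
  sig0 <- sample.int(100L, 1L) - 1L
  seq0 <- sample.int(100L, 1L) - 1L
  sig_len <- sum(ops$len[ops$kind %in% c("M", "I")])
  seq_len <- sum(ops$kind == "M") + sum(ops$len[ops$kind == "D"])
  ss_alignment("r1", ops, sig0, sig0 + sig_len, seq0, seq0 + seq_len,
               seq_kind = seq_kind, strand = strand,
               signal_direction = signal_direction)
}

# random CIGAR + read-order dwell vector for realign fuzzing;
# body starts and ends with M; may include I, D, N and soft clips
rand_cigar_case <- function(max_blocks = 8L) {
  ops <- c("M")
  lens <- c(sample.int(4L, 1L))
  for (b in seq_len(sample.int(max_blocks, 1L))) {
    k <- sample(c("M", "I", "D", "N"), 1L, prob = c(0.55, 0.2, 0.2, 0.05))
    if (k != "M" && tail(ops, 1L) != "M") next      # keep runs apart
    ops <- c(ops, k); lens <- c(lens, sample.int(4L, 1L))
  }
  if (tail(ops, 1L) != "M") { ops <- c(ops, "M"); lens <- c(lens, 1L) }
  if (runif(1) < 0.4) { ops <- c("S", ops); lens <- c(sample.int(5L, 1L), lens) }
  if (runif(1) < 0.4) { ops <- c(ops, "S"); lens <- c(lens, sample.int(5L, 1L)) }
  cigar <- paste0(lens, ops, collapse = "")
  n <- sum(lens[ops %in% c("M", "I", "S")])
  strand <- sample(c("+", "-"), 1L)
  dwell <- sample(3:12, n, replace = TRUE)
  list(cigar = cigar, n = n, strand = strand, dwell = dwell,
       ref_start = sample.int(50L, 1L) - 1L)
}

# Brute-force projection oracle for realign: expands the CIGAR into
# per-unit records, assigns each query base its reference fate by cumulative
# coordinate arithmetic, and rebuilds the expected op list in reference
# order before converting to read (signal) order.
bf_realign <- function(dwell, cigar, strand, ref_start, sig_start, sig_end) {
  cg <- parse_cigar(cigar)
  units <- rep(cg$op, cg$len)
  q_consume <- units %in% c("M", "=", "X", "I", "S")
  r_consume <- units %in% c("M", "=", "X", "D", "N")
  qpos <- ifelse(q_consume, cumsum(q_consume) - 1L, NA_integer_)
  n <- length(dwell)
  dwell_q <- if (strand == "-") rev(dwell) else dwell
  kind <- character(0); len <- integer(0); skip <- logical(0)
  clipL <- 0L; clipR <- 0L; seen <- FALSE
  for (u in seq_along(units)) {
    op <- units[u]
    if (op == "S") {
      if (!seen) clipL <- clipL + dwell_q[qpos[u] + 1L]
      else clipR <- clipR + dwell_q[qpos[u] + 1L]
    } else if (op %in% c("M", "=", "X")) {
      seen <- TRUE
      kind <- c(kind, "M"); len <- c(len, dwell_q[qpos[u] + 1L])
      skip <- c(skip, FALSE)
    } else if (op == "I") {
      seen <- TRUE
      kind <- c(kind, "I"); len <- c(len, dwell_q[qpos[u] + 1L])
      skip <- c(skip, FALSE)
    } else {
      seen <- TRUE
      kind <- c(kind, "D"); len <- c(len, 1L); skip <- c(skip, op == "N")
    }
  }
  # merge I and D runs (per-unit expansion produces singletons); local
  # merge keeps the oracle independent of the package's canonicalizer
  mk <- character(0); ml <- integer(0); ms <- logical(0)
  for (i in seq_along(kind)) {
    j <- length(mk)
    if (j > 0L && kind[i] != "M" && mk[j] == kind[i]) {
      ml[j] <- ml[j] + len[i]; ms[j] <- ms[j] && skip[i]
    } else { mk <- c(mk, kind[i]); ml <- c(ml, len[i]); ms <- c(ms, skip[i]) }
  }
  ops <- ss_ops(mk, ml, ms)
  if (strand == "-") {
    idx <- rev(seq_len(nrow(ops)))
    ops <- ss_ops(ops$kind[idx], ops$len[idx], ops$skip[idx])
    lead <- clipR; trail <- clipL
  } else { lead <- clipL; trail <- clipR }
  list(ops = ops,
       sig_start = sig_start + lead, sig_end = sig_end - trail,
       seq_start = ref_start, seq_end = ref_start + sum(r_consume))
}

DNA_BASES_T <- function() c("A", "C", "G", "T")

# shared small test model/bundle (built once per test file load)
tiny_model <- generate_pore_model(k = 3L, msb = 1L)
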