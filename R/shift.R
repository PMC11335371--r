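# K-mer-to-base shift correction.
#
# Event-style signal alignments anchor signal to k-mers, not single bases:
# the samples labelled with base i are governed mostly by one position of
# the k-mer starting at i — the most significant base (MSB), at offset m
# within the k-mer, i.e. reference base i+m. Shifting every op forward by m
# bases re-pairs each base with the signal event that actually reflects it.
#
# The separation statistic is a one-way eta-squared: between-group variance
# of current levels grouped by base identity, divided by total variance.
# It is bounded in [0,1] and equals 1 iff the level is a pure function of
# the grouping base.

eta_squared <- function(values, groups) {
  tot <- sum((values - mean(values))^2)
  if (tot == 0) return(NA_real_)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssb / tot
}

#' Most significant base of a pore model
#'
#' For each position p in the k-mer, all 4^k model mean levels are
#' partitioned into 4 groups by the base at p and scored with eta-squared
#' (between-group / total variance). The MSB is the argmax position (ties
#' broken towards the smallest p). Position indices are 0-based.
#'
#' @param model a complete `pore_model`.
#' @return list with `msb` (0-based position) and `scores` (numeric vector
#'   of length k, one score per position).
#' @export
msb_position <- function(model) {
  stopifnot(inherits(model, "pore_model"))
  if (!model$complete)
    stop("msb_position requires a complete pore model (4^k k-mers)")
  means <- model$level_mean
  kmers <- names(means)
  if (sum((means - mean(means))^2) == 0)
    stop("degenerate model: all k-mer levels identical")
  scores <- vapply(seq_len(model$k), function(p)
    eta_squared(means, substring(kmers, p, p)), 0)
  list(msb = which.max(scores) - 1L, scores = scores)
}

#' Shift the base pairing of a signal-to-reference alignment
#'
#' Advances the base-to-op pairing by `shift` bases: the op previously
#' paired with base i pairs with base i+shift (plus strand). The last
#' `shift` sequence-units of ops lose their pairing and are dropped (their
#' samples leave the signal span) and the first `shift` bases become
#' unpaired (the seq span start advances). Minus-strand alignments shift in
#' the opposite sequence direction (seq_end retreats); in op order the drop
#' is again from the tail.
#'
#' @param aln an `ss_alignment` with `seq_kind = "reference"`.
#' @param shift non-negative integer, less than the number of MATCH ops.
#' @return the shifted alignment (conservation invariants preserved).
#' @export
apply_shift <- function(aln, shift) {
  stopifnot(inherits(aln, "ss_alignment"))
  if (aln$seq_kind != "reference")
    stop("apply_shift needs a signal-to-reference alignment")
  shift <- as.integer(shift)
  if (shift < 0L) stop("shift must be non-negative")
  if (shift == 0L) return(aln)
  n_match <- sum(aln$ops$kind == "M")
  if (shift >= n_match)
    stop("shift (", shift, ") must be smaller than the number of MATCH ops (",
         n_match, ")")
  ops <- aln$ops
  remaining <- shift          # sequence units still to remove from the tail
  removed_samples <- 0L
  while (remaining > 0L && nrow(ops) > 0L) {
    i <- nrow(ops)
    if (ops$kind[i] == "I") {
      removed_samples <- removed_samples + ops$len[i]
      ops <- ops[-i, , drop = FALSE]
    } else if (ops$kind[i] == "M") {
      removed_samples <- removed_samples + ops$len[i]
      ops <- ops[-i, , drop = FALSE]
      remaining <- remaining - 1L
    } else {                  # D
      take <- min(ops$len[i], remaining)
      remaining <- remaining - take
      if (take == ops$len[i]) ops <- ops[-i, , drop = FALSE]
      else ops$len[i] <- ops$len[i] - take
    }
  }
  class(ops) <- c("ss_ops", "data.frame")
  aln$ops <- ops
  # op-order tail sits at the signal end the direction points away from
  if (aln$signal_direction == "forward")
    aln$sig_end <- aln$sig_end - removed_samples
  else
    aln$sig_start <- aln$sig_start + removed_samples
  if (aln$strand == "+") aln$seq_start <- aln$seq_start + shift
  else aln$seq_end <- aln$seq_end - shift
  v <- ss_validate(aln)
  if (length(v) > 0L)
    stop("internal error: apply_shift produced an invalid alignment: ", v[[1L]])
  aln
}

# Per-MATCH-op mean pA and reference position, in op order.
match_op_stats <- function(aln, signal_pA_values) {
  ops <- aln$ops
  idx <- op_sample_indices(aln)
  is_m <- ops$kind == "M"
  means <- vapply(which(is_m), function(i) mean(signal_pA_values[idx[[i]]]), 0)
  # reference position of each op: walk in reference order, then map back
  ref_order <- if (aln$strand == "-") rev(seq_len(nrow(ops))) else
    seq_len(nrow(ops))
  pos <- integer(nrow(ops)); p <- aln$seq_start
  for (j in ref_order) {
    if (ops$kind[j] == "M") { pos[j] <- p; p <- p + 1L }
    else if (ops$kind[j] == "D") { pos[j] <- p; p <- p + ops$len[j] }
    else pos[j] <- p
  }
  list(mean = means, ref_pos = pos[is_m])
}

#' Measure the dataset-wide k-mer-to-base offset
#'
#' For every candidate shift s in [0, k), every MATCH op's mean current is
#' grouped by the base it would pair with after shifting by s (the base s
#' positions downstream on the plus strand, upstream on the minus strand,
#' complemented for minus-strand reads since the pore senses the read's own
#' sequence). The shift maximising the eta-squared separation of those
#' groups is the dataset's offset; applying it aligns each base with its
#' most relevant signal event.
#'
#' @param alignments list of `ss_alignment` with `seq_kind = "reference"`.
#' @param signals named list of `raw_signal`, keyed by read_id.
#' @param reference named character vector of reference sequences (only the
#'   sequence the alignments refer to is used), or a single sequence string.
#' @param model a `pore_model` (supplies k and the protocol identity).
#' @param ref_name reference to look up when `reference` is named.
#' @param max_ops subsample cap on MATCH ops (seeded) for speed; use
#'   `full_data = TRUE` to disable.
#' @param full_data logical; when TRUE all ops are used.
#' @param seed RNG seed for the subsample.
#' @param protocol_label recorded in the report so stored offsets are never
#'   cross-applied between protocols silently.
#' @return An `offset_report`: candidate shifts, separation score per shift,
#'   chosen shift (ties to the smallest), protocol label and a
#'   low-confidence flag when fewer than 4 distinct bases were observed.
#' @export
calculate_offset <- function(alignments, signals, reference, model,
                             ref_name = NULL, max_ops = 50000L,
                             full_data = FALSE, seed = 1L,
                             protocol_label = "default") {
  if (length(alignments) == 0L) stop("calculate_offset: no alignments given")
  stopifnot(inherits(model, "pore_model"))
  refseq <- if (length(reference) > 1L || !is.null(names(reference))) {
    if (is.null(ref_name)) reference[[1L]] else reference[[ref_name]]
  } else reference
  ref_bases <- strsplit(refseq, "", fixed = TRUE)[[1L]]

  means <- numeric(0); pos <- integer(0); strands <- character(0)
  for (aln in alignments) {
    if (aln$seq_kind != "reference")
      stop("calculate_offset needs signal-to-reference alignments")
    sig <- signals[[aln$read_id]]
    if (is.null(sig)) stop("no signal for read ", aln$read_id)
    st <- match_op_stats(aln, signal_pA(sig))
    means <- c(means, st$mean)
    pos <- c(pos, st$ref_pos)
    strands <- c(strands, rep(aln$strand, length(st$mean)))
  }
  if (!full_data && length(means) > max_ops) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    keep <- sample.int(length(means), max_ops)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    means <- means[keep]; pos <- pos[keep]; strands <- strands[keep]
  }

  shifts <- 0:(model$k - 1L)
  scores <- vapply(shifts, function(s) {
    # base paired with each op after shifting by s
    q <- ifelse(strands == "+", pos + s, pos - s)
    ok <- q >= 0L & q < length(ref_bases)
    if (!any(ok)) return(NA_real_)
    base <- ref_bases[q[ok] + 1L]
    base <- ifelse(strands[ok] == "-", complement_bases(base), base)
    eta_squared(means[ok], base)
  }, 0)

  observed <- unique(ref_bases[pmin(pmax(pos, 0L), length(ref_bases) - 1L) + 1L])
  low_conf <- length(observed) < 4L
  if (low_conf)
    warning("fewer than 4 distinct reference bases observed; ",
            "offset estimate is low-confidence")
  chosen <- shifts[which.max(scores)]   # which.max takes the first maximum
  structure(list(candidate_shifts = shifts, separation_score = scores,
                 chosen_shift = chosen, protocol_label = protocol_label,
                 low_confidence = low_conf, n_ops = length(means)),
            class = "offset_report")
}

#' @export
print.offset_report <- function(x, ...) {
  cat(sprintf("offset_report (%s): chosen shift %d over %d MATCH ops%s\n",
              x$protocol_label, x$chosen_shift, x$n_ops,
              if (x$low_confidence) " [low confidence]" else ""))
  for (i in seq_along(x$candidate_shifts))
    cat(sprintf("  shift %d: separation %.4f%s\n", x$candidate_shifts[i],
                x$separation_score[i],
                if (x$candidate_shifts[i] == x$chosen_shift) "  <- chosen" else ""))
  invisible(x)
}

#' Write an offset report as JSON
#' @param report an `offset_report`.
#' @param path output file.
#' @param stamp tool-version string stored in the report.
#' @return `path`, invisibly.
#' @export
write_offset_report <- function(report, path, stamp = SIGPILE_VERSION) {
  jsonlite::write_json(
    list(tool_version = stamp,
         protocol_label = report$protocol_label,
         chosen_shift = report$chosen_shift,
         candidate_shifts = report$candidate_shifts,
         separation_score = report$separation_score,
         low_confidence = report$low_confidence,
         n_ops = report$n_ops),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
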