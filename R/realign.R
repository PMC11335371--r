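# realign: project a signal-to-read alignment through the read's CIGAR into
# a signal-to-reference alignment.
#
# Each reference base consumed by M/=/X receives the samples of its read
# base; read-only bases (CIGAR I) contribute their samples as SIG_INS ops at
# their position in op order; reference-only bases (D, N) become BASE_DEL
# ops (N flagged as skip); soft-clipped bases have their samples trimmed
# from the signal span rather than emitted.
#
# Output ops are stored in signal (read sequencing) order: for minus-strand
# reads that is decreasing reference coordinate, and orient_for_reference()
# flips them into increasing reference order for layout.

#' Project a signal-to-read alignment onto the reference
#'
#' @param sig2read an `ss_alignment` with `seq_kind = "read"` covering the
#'   whole basecalled sequence with MATCH ops (as produced by [reform()]).
#' @param read the `read_record` carrying CIGAR, reference coordinates and
#'   strand.
#' @return an `ss_alignment` with `seq_kind = "reference"` over
#'   `[ref_start, ref_start + reference-consumed length)`.
#' @export
realign <- function(sig2read, read) {
  stopifnot(inherits(sig2read, "ss_alignment"), inherits(read, "read_record"))
  if (sig2read$seq_kind != "read")
    stop("realign needs a signal-to-read alignment (seq_kind 'read')")
  if (any(sig2read$ops$kind != "M"))
    stop("realign expects per-base MATCH ops only (reform output)")
  if (is.na(read$cigar)) stop("read ", read$read_id, " has no CIGAR")
  cg <- parse_cigar(read$cigar)
  n <- nrow(sig2read$ops)
  qlen <- sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S")])
  if (qlen != n)
    stop("CIGAR query length (", qlen, ") != signal-to-read base count (",
         n, ") for read ", read$read_id)
  if (sig2read$seq_start != 0L || sig2read$seq_end != n)
    stop("signal-to-read alignment must cover the whole read")
  if (any(cg$op == "H"))
    stop("hard-clipped read ", read$read_id,
         " cannot be realigned with signal present")

  dwell <- sig2read$ops$len                       # read sequencing order
  # query order = reference orientation of the read
  dwell_q <- if (read$strand == "-") rev(dwell) else dwell

  kind <- character(0); len <- integer(0); skip <- logical(0)
  q <- 0L
  clip_ref_left <- 0L; clip_ref_right <- 0L
  seen_body <- FALSE
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]; L <- cg$len[i]
    if (op == "S") {
      samp <- sum(dwell_q[(q + 1L):(q + L)])
      if (!seen_body) clip_ref_left <- clip_ref_left + samp
      else clip_ref_right <- clip_ref_right + samp
      q <- q + L
    } else if (op %in% c("M", "=", "X")) {
      seen_body <- TRUE
      kind <- c(kind, rep("M", L))
      len <- c(len, dwell_q[(q + 1L):(q + L)])
      skip <- c(skip, rep(FALSE, L))
      q <- q + L
    } else if (op == "I") {
      seen_body <- TRUE
      kind <- c(kind, "I")
      len <- c(len, sum(dwell_q[(q + 1L):(q + L)]))
      skip <- c(skip, FALSE)
      q <- q + L
    } else if (op %in% c("D", "N")) {
      seen_body <- TRUE
      kind <- c(kind, "D"); len <- c(len, L); skip <- c(skip, op == "N")
    } else stop("unsupported CIGAR op ", op)
  }
  ops_ref <- ss_canonicalize(ss_ops(kind, len, skip))
  ref_len <- sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])

  # map reference-end clips to signal-end clips through read order/direction
  if (read$strand == "-") {
    clip_lead <- clip_ref_right; clip_trail <- clip_ref_left
    idx <- rev(seq_len(nrow(ops_ref)))
    ops_out <- ss_ops(ops_ref$kind[idx], ops_ref$len[idx], ops_ref$skip[idx])
  } else {
    clip_lead <- clip_ref_left; clip_trail <- clip_ref_right
    ops_out <- ops_ref
  }
  if (sig2read$signal_direction == "forward") {
    sig_start <- sig2read$sig_start + clip_lead
    sig_end <- sig2read$sig_end - clip_trail
  } else {
    sig_start <- sig2read$sig_start + clip_trail
    sig_end <- sig2read$sig_end - clip_lead
  }

  out <- ss_alignment(read$read_id, ops_out, sig_start, sig_end,
                      seq_start = read$ref_start,
                      seq_end = read$ref_start + ref_len,
                      seq_kind = "reference", strand = read$strand,
                      signal_direction = sig2read$signal_direction)
  v <- ss_validate(out)
  if (length(v) > 0L)
    stop("internal error: realign produced an invalid alignment: ", v[[1L]])
  out
}

#' Orient a signal-to-reference alignment for display
#'
#' Minus-strand alignments store ops in read (signal) order, which runs
#' against the reference. This reverses the op order and flips the signal
#' direction so op order runs with increasing reference coordinate; plus
#' strand is unchanged. Applying the operation twice is the identity.
#'
#' @param aln an `ss_alignment` with `seq_kind = "reference"`.
#' @return the oriented alignment.
#' @export
orient_for_reference <- function(aln) {
  stopifnot(inherits(aln, "ss_alignment"))
  if (aln$seq_kind != "reference")
    stop("orient_for_reference needs a signal-to-reference alignment")
  if (aln$strand == "+") return(aln)
  idx <- rev(seq_len(nrow(aln$ops)))
  aln$ops <- ss_ops(aln$ops$kind[idx], aln$ops$len[idx], aln$ops$skip[idx])
  aln$signal_direction <-
    if (aln$signal_direction == "forward") "reverse" else "forward"
  aln
}

# Sample indices (1-based into the raw samples vector) for each op, in op
# order. Ops partition the signal window; direction decides which end op 1
# starts from.
op_sample_indices <- function(aln) {
  lens <- ifelse(aln$ops$kind == "D", 0L, aln$ops$len)
  ends <- cumsum(lens)
  starts <- ends - lens
  lapply(seq_along(lens), function(i) {
    if (lens[i] == 0L) return(integer(0))
    if (aln$signal_direction == "forward")
      (aln$sig_start + starts[i] + 1L):(aln$sig_start + ends[i])
    else
      (aln$sig_end - starts[i]):(aln$sig_end - ends[i] + 1L)
  })
}
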