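# The ss tag: a CIGAR-like encoding of signal-to-sequence alignments.
#
# Three op kinds:
#   M (match)    n samples aligned to exactly one base   -> "n,"
#   I (sig-ins)  n samples aligned to no base            -> "nI"
#   D (base-del) m bases with no signal                  -> "mD"
# Ops are concatenated with no other separators. Runs of I or D must be
# merged (canonical form); adjacent M ops are distinct one-base pairings and
# are always legal.

#' Construct an op list for a signal-to-sequence alignment
#'
#' @param kind character vector over `c("M","I","D")`.
#' @param len positive integer lengths (samples for M/I, bases for D).
#' @param skip logical; marks D ops that arise from CIGAR N (reference skip)
#'   so a renderer can draw them differently.
#' @return data.frame of class `ss_ops`.
#' @export
ss_ops <- function(kind = character(0), len = integer(0),
                   skip = rep(FALSE, length(kind))) {
  stopifnot(length(kind) == length(len))
  if (!all(kind %in% c("M", "I", "D"))) stop("ss op kind must be M, I or D")
  len <- as.integer(len)
  if (any(len < 1L)) stop("ss op length must be >= 1")
  out <- data.frame(kind = as.character(kind), len = len,
                    skip = as.logical(skip), stringsAsFactors = FALSE)
  class(out) <- c("ss_ops", "data.frame")
  out
}

#' A signal-to-sequence alignment
#'
#' One read's alignment of raw samples to bases of either its own basecalled
#' sequence (`seq_kind = "read"`) or a reference (`seq_kind = "reference"`).
#' Sample and base intervals are 0-based half-open. Ops are stored in signal
#' order: with `signal_direction = "forward"` the first op occupies samples
#' from `sig_start` upwards; with `"reverse"` it occupies samples from
#' `sig_end` downwards (RNA acquisition runs 3' to 5').
#'
#' @param read_id read identifier.
#' @param ops an `ss_ops` op list (see [ss_ops()]).
#' @param sig_start,sig_end sample interval covered, half-open.
#' @param seq_start,seq_end base interval covered, half-open.
#' @param seq_kind `"read"` or `"reference"`.
#' @param strand `"+"` or `"-"` (read-to-reference strand).
#' @param signal_direction `"forward"` or `"reverse"`.
#' @return An object of class `ss_alignment`.
#' @export
ss_alignment <- function(read_id, ops, sig_start, sig_end, seq_start, seq_end,
                         seq_kind = c("read", "reference"), strand = "+",
                         signal_direction = "forward") {
  seq_kind <- match.arg(seq_kind)
  stopifnot(strand %in% c("+", "-"),
            signal_direction %in% c("forward", "reverse"))
  if (!inherits(ops, "ss_ops")) ops <- ss_ops(ops$kind, ops$len)
  structure(
    list(read_id = read_id, ops = ops,
         sig_start = as.integer(sig_start), sig_end = as.integer(sig_end),
         seq_start = as.integer(seq_start), seq_end = as.integer(seq_end),
         seq_kind = seq_kind, strand = strand,
         signal_direction = signal_direction),
    class = "ss_alignment")
}

#' @export
print.ss_alignment <- function(x, ...) {
  cat(sprintf("ss_alignment %s: sig [%d,%d) -> %s [%d,%d) strand %s (%s)\n",
              x$read_id, x$sig_start, x$sig_end, x$seq_kind, x$seq_start,
              x$seq_end, x$strand, x$signal_direction))
  cat("  ss: ", ss_emit_ops(x$ops), "\n", sep = "")
  invisible(x)
}

#' Emit the ss string for an op list (no conservation checks)
#' @param ops an `ss_ops` op list.
#' @return the ss string.
#' @export
ss_emit_ops <- function(ops) {
  if (nrow(ops) == 0L) return("")
  glyph <- c(M = ",", I = "I", D = "D")[ops$kind]
  paste0(paste0(ops$len, glyph), collapse = "")
}

#' Emit the ss string for an alignment
#'
#' Validates the alignment's conservation and canonical-form invariants
#' first; a violation is a hard error naming the failing invariant.
#'
#' @param aln an `ss_alignment`.
#' @return the ss string.
#' @export
ss_emit <- function(aln) {
  stopifnot(inherits(aln, "ss_alignment"))
  v <- ss_validate(aln)
  if (length(v) > 0L)
    stop("invalid ss alignment for read ", aln$read_id, ": ", v[[1L]])
  ss_emit_ops(aln$ops)
}

#' Parse an ss string into an op list
#'
#' Inverse of [ss_emit()]. Stray characters, zero lengths and trailing
#' digits with no terminating glyph are hard errors reporting the 1-based
#' character offset of the fault.
#'
#' @param text the ss string.
#' @return an `ss_ops` op list.
#' @export
ss_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) stop("ss string is NA")
  if (text == "") return(ss_ops())
  m <- regexpr("^([0-9]+[,ID])*", text)
  ok_len <- attr(m, "match.length")
  if (ok_len < nchar(text)) {
    rest <- substring(text, ok_len + 1L)
    what <- if (grepl("^[0-9]+$", rest)) "trailing digits with no terminator"
            else "stray character"
    stop("bad ss string at offset ", ok_len + 1L, ": ", what)
  }
  toks <- regmatches(text, gregexpr("[0-9]+[,ID]", text))[[1L]]
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  glyph <- substring(toks, nchar(toks), nchar(toks))
  if (any(len == 0L)) {
    bad <- which(len == 0L)[1L]
    off <- if (bad == 1L) 1L else sum(nchar(toks[seq_len(bad - 1L)])) + 1L
    stop("bad ss string at offset ", off, ": zero-length op")
  }
  kind <- c("," = "M", "I" = "I", "D" = "D")[glyph]
  ss_ops(unname(kind), len)
}

#' Emit the si coordinate tag for an alignment
#'
#' The si tag is the coordinate companion of ss:
#' `"sig_start,sig_end,seq_start,seq_end"` as decimal integers.
#'
#' @param aln an `ss_alignment`.
#' @return the si string.
#' @export
si_emit <- function(aln) {
  stopifnot(inherits(aln, "ss_alignment"))
  if (aln$sig_end < aln$sig_start)
    stop("invalid coordinates: sig_end < sig_start")
  if (aln$seq_end < aln$seq_start)
    stop("invalid coordinates: seq_end < seq_start")
  sprintf("%d,%d,%d,%d", aln$sig_start, aln$sig_end, aln$seq_start,
          aln$seq_end)
}

#' Parse an si coordinate tag
#' @param text the si string.
#' @return list with `sig_start`, `sig_end`, `seq_start`, `seq_end`.
#' @export
si_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("^[0-9]+,[0-9]+,[0-9]+,[0-9]+$", text))
    stop("bad si string '", text, "': expected four non-negative integers")
  v <- as.integer(strsplit(text, ",", fixed = TRUE)[[1L]])
  if (v[2L] < v[1L]) stop("bad si string: sig_end < sig_start")
  if (v[4L] < v[3L]) stop("bad si string: seq_end < seq_start")
  list(sig_start = v[1L], sig_end = v[2L], seq_start = v[3L], seq_end = v[4L])
}

#' Validate an ss alignment
#'
#' Checks the two conservation invariants, canonical form, coordinate sanity
#' and (when lengths are supplied) bounds.
#'
#' @param aln an `ss_alignment`.
#' @param signal_len total samples in the read's signal, or NULL.
#' @param seq_len total bases in the read/reference sequence, or NULL.
#' @return character vector of violations; empty when valid.
#' @export
ss_validate <- function(aln, signal_len = NULL, seq_len = NULL) {
  v <- character(0)
  ops <- aln$ops
  if (nrow(ops) > 0L && any(ops$len < 1L))
    v <- c(v, "op length < 1")
  sig_samples <- sum(ops$len[ops$kind %in% c("M", "I")])
  if (sig_samples != aln$sig_end - aln$sig_start)
    v <- c(v, sprintf(
      "signal conservation: MATCH+SIG_INS samples (%d) != sig span (%d)",
      sig_samples, aln$sig_end - aln$sig_start))
  seq_bases <- sum(ops$kind == "M") + sum(ops$len[ops$kind == "D"])
  if (seq_bases != aln$seq_end - aln$seq_start)
    v <- c(v, sprintf(
      "sequence conservation: MATCH ops + BASE_DEL bases (%d) != seq span (%d)",
      seq_bases, aln$seq_end - aln$seq_start))
  if (nrow(ops) > 1L) {
    same <- ops$kind[-1L] == ops$kind[-nrow(ops)] & ops$kind[-1L] != "M"
    if (any(same))
      v <- c(v, "canonical form: adjacent ops of the same kind (I or D runs must be merged)")
  }
  if (aln$sig_start < 0L || aln$sig_end < aln$sig_start)
    v <- c(v, "signal coordinates out of order")
  if (aln$seq_start < 0L || aln$seq_end < aln$seq_start)
    v <- c(v, "sequence coordinates out of order")
  if (!is.null(signal_len) && aln$sig_end > signal_len)
    v <- c(v, sprintf("out of bounds: sig_end (%d) > signal length (%d)",
                      aln$sig_end, as.integer(signal_len)))
  if (!is.null(seq_len) && aln$seq_end > seq_len)
    v <- c(v, sprintf("out of bounds: seq_end (%d) > sequence length (%d)",
                      aln$seq_end, as.integer(seq_len)))
  v
}

#' Merge adjacent same-kind I/D ops into canonical form
#' @param ops an `ss_ops` op list.
#' @return canonical `ss_ops`.
#' @export
ss_canonicalize <- function(ops) {
  if (nrow(ops) < 2L) return(ops)
  keep_kind <- character(0); keep_len <- integer(0); keep_skip <- logical(0)
  for (i in seq_len(nrow(ops))) {
    n <- length(keep_kind)
    if (n > 0L && ops$kind[i] != "M" && keep_kind[n] == ops$kind[i]) {
      keep_len[n] <- keep_len[n] + ops$len[i]
      keep_skip[n] <- keep_skip[n] && ops$skip[i]
    } else {
      keep_kind <- c(keep_kind, ops$kind[i])
      keep_len <- c(keep_len, ops$len[i])
      keep_skip <- c(keep_skip, ops$skip[i])
    }
  }
  ss_ops(keep_kind, keep_len, keep_skip)
}

#' Auxiliary tag strings (ss/si plus bookkeeping) for an alignment
#' @param aln an `ss_alignment`.
#' @return character vector of tag strings to attach to a read record.
#' @export
ss_tags_for <- function(aln) {
  c(paste0("ss:Z:", ss_emit(aln)),
    paste0("si:Z:", si_emit(aln)),
    paste0("sk:Z:", aln$seq_kind),
    paste0("sd:Z:", aln$signal_direction))
}

#' Reconstruct an ss alignment from a read record's tags
#' @param record a `read_record` carrying ss:Z: and si:Z: tags.
#' @return an `ss_alignment`, or NULL if the record has no ss tag.
#' @export
ss_from_record <- function(record) {
  ss <- tag_value(record, "ss")
  si <- tag_value(record, "si")
  if (is.null(ss) || is.null(si)) return(NULL)
  co <- si_parse(si)
  sk <- tag_value(record, "sk"); if (is.null(sk)) sk <- "reference"
  sd <- tag_value(record, "sd"); if (is.null(sd)) sd <- "forward"
  ss_alignment(record$read_id, ss_parse(ss), co$sig_start, co$sig_end,
               co$seq_start, co$seq_end, seq_kind = sk,
               strand = record$strand, signal_direction = sd)
}
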