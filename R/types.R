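#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom rnbinom runif setNames var
#' @importFrom utils read.delim write.table head tail
NULL

SIGPILE_VERSION <- "0.1.0"

DNA_BASES <- c("A", "C", "G", "T")

#' Raw signal for one read
#'
#' Container for the raw current samples of a single nanopore read, in DAC
#' (digitiser) units, together with the calibration constants needed to
#' convert them to pico-amps.
#'
#' @param read_id read identifier.
#' @param samples integer vector of raw DAC values.
#' @param digitisation positive digitiser resolution (levels).
#' @param offset_pA calibration offset added to raw values.
#' @param range_pA positive calibration range in pA.
#' @param sampling_rate sampling rate in Hz.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(read_id, samples, digitisation, offset_pA, range_pA,
                       sampling_rate = 4000) {
  stopifnot(is.character(read_id), length(read_id) == 1L)
  if (!is.numeric(samples)) stop("samples must be numeric for read ", read_id)
  if (!is.numeric(digitisation) || digitisation <= 0)
    stop("digitisation must be positive for read ", read_id)
  if (!is.numeric(range_pA) || range_pA <= 0)
    stop("range_pA must be positive for read ", read_id)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive for read ", read_id)
  structure(
    list(read_id = read_id, samples = as.integer(round(samples)),
         digitisation = as.numeric(digitisation),
         offset_pA = as.numeric(offset_pA),
         range_pA = as.numeric(range_pA),
         sampling_rate = as.numeric(sampling_rate)),
    class = "raw_signal")
}

#' Convert raw signal samples to pico-amps
#'
#' Applies the calibration `pA = (raw + offset) * range / digitisation`
#' elementwise.
#'
#' @param x a `raw_signal` object.
#' @return numeric vector of pA values, one per sample.
#' @export
signal_pA <- function(x) {
  stopifnot(inherits(x, "raw_signal"))
  (x$samples + x$offset_pA) * x$range_pA / x$digitisation
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("raw_signal %s: %d samples, digitisation=%g, offset=%g, range=%g pA, %g Hz\n",
              x$read_id, length(x$samples), x$digitisation, x$offset_pA,
              x$range_pA, x$sampling_rate))
  invisible(x)
}

#' A basecalled, aligned read
#'
#' In-memory representation of one read: the basecalled sequence is stored in
#' sequencing direction (5' to 3' as the bases came off the pore), regardless
#' of strand; SAM files on disk store minus-strand sequences
#' reverse-complemented, and the conversion happens at the I/O boundary.
#'
#' @param read_id read identifier.
#' @param sequence basecalled sequence (sequencing direction), or NA.
#' @param ref_name reference name, or NA for unaligned reads.
#' @param ref_start 0-based reference start of the alignment.
#' @param cigar CIGAR string over M=XIDNSH, or NA.
#' @param strand "+" or "-".
#' @param tags character vector of auxiliary tags, each a full
#'   `TAG:TYPE:VALUE` string preserved verbatim.
#' @return An object of class `read_record`.
#' @export
read_record <- function(read_id, sequence = NA_character_,
                        ref_name = NA_character_, ref_start = 0L,
                        cigar = NA_character_, strand = "+",
                        tags = character(0)) {
  stopifnot(strand %in% c("+", "-"))
  if (!is.na(cigar) && !is.na(sequence)) {
    qlen <- cigar_query_length(cigar)
    if (qlen != nchar(sequence))
      stop("CIGAR query length (", qlen, ") != sequence length (",
           nchar(sequence), ") for read ", read_id)
  }
  structure(
    list(read_id = read_id, sequence = sequence, ref_name = ref_name,
         ref_start = as.integer(ref_start), cigar = cigar, strand = strand,
         tags = as.character(tags)),
    class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("read_record %s: %s:%d %s cigar=%s (%d tags)\n", x$read_id,
              x$ref_name, x$ref_start, x$strand, x$cigar, length(x$tags)))
  invisible(x)
}

#' Fetch an auxiliary tag value from a read record
#'
#' @param record a `read_record`.
#' @param tag two-letter tag name (e.g. "ss", "mv").
#' @return the raw value string after `TAG:TYPE:`, or NULL if absent.
#' @export
tag_value <- function(record, tag) {
  hit <- grep(paste0("^", tag, ":"), record$tags, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  sub("^..:.:", "", hit[[1L]])
}

#' Set or replace an auxiliary tag on a read record
#' @param record a `read_record`.
#' @param tag two-letter tag name.
#' @param type one-letter SAM tag type (e.g. "Z", "i").
#' @param value value, coerced to character.
#' @return the modified record.
#' @export
set_tag <- function(record, tag, type, value) {
  record$tags <- record$tags[!grepl(paste0("^", tag, ":"), record$tags)]
  record$tags <- c(record$tags, paste0(tag, ":", type, ":", value))
  record
}

#' Genomic region (0-based, half-open)
#'
#' @param ref_name reference name.
#' @param start 0-based inclusive start.
#' @param end exclusive end; must exceed `start`.
#' @return An object of class `region`.
#' @export
region <- function(ref_name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop("invalid region: start (", start, ") must be < end (", end, ")")
  if (start < 0L) stop("invalid region: negative start")
  structure(list(ref_name = ref_name, start = start, end = end),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region %s:[%d,%d)\n", x$ref_name, x$start, x$end))
  invisible(x)
}

#' Parse a CLI region string
#'
#' Accepts `name:start-end`, 1-based inclusive (browser convention), and
#' converts to the internal 0-based half-open form.
#'
#' @param text e.g. `"ref1:100-250"`.
#' @return a `region`.
#' @export
parse_region <- function(text) {
  m <- regmatches(text, regexec("^([^:]+):([0-9]+)-([0-9]+)$", text))[[1L]]
  if (length(m) != 4L)
    stop("malformed region string '", text, "': expected name:start-end")
  s1 <- as.integer(m[3L]); e1 <- as.integer(m[4L])
  if (s1 < 1L || e1 < s1)
    stop("malformed region string '", text, "': need 1 <= start <= end")
  region(m[2L], s1 - 1L, e1)
}

#' Basecaller move table
#'
#' The move table marks, at a fixed sample stride, the signal slots where a
#' new base starts. `trim_samples` counts samples (e.g. adapter) preceding
#' the first slot.
#'
#' @param stride positive integer, signal samples per move slot.
#' @param moves integer vector of 0/1 flags, one per slot; `moves[1]` must
#'   be 1.
#' @param trim_samples non-negative samples before the first slot.
#' @return An object of class `move_table`.
#' @export
move_table <- function(stride, moves, trim_samples = 0L) {
  stride <- as.integer(stride)
  moves <- as.integer(moves)
  trim_samples <- as.integer(trim_samples)
  if (stride < 1L) stop("stride must be a positive integer")
  if (length(moves) == 0L) stop("empty move table")
  if (!all(moves %in% c(0L, 1L))) stop("moves must be 0/1 flags")
  if (moves[1L] != 1L) stop("moves[1] must be 1: the first base starts at the first slot")
  if (trim_samples < 0L) stop("trim_samples must be non-negative")
  structure(list(stride = stride, moves = moves, trim_samples = trim_samples),
            class = "move_table")
}

#' Parse a CIGAR string
#' @param cigar CIGAR string.
#' @return data.frame with columns `op` (character) and `len` (integer).
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    return(data.frame(op = character(0), len = integer(0)))
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  data.frame(op = substring(toks, nchar(toks), nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

cigar_query_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S")])
}

cigar_ref_length <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
}

#' Reverse complement of a DNA string
#' @param x single character string over ACGTN.
#' @return reverse complement string.
#' @export
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), "", USE.NAMES = FALSE))
}

complement_bases <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)
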