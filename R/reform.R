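# reform: turn a basecaller move table into a signal-to-read alignment.
#
# The move table marks, at a fixed sample stride, the slots where a new base
# starts. Base i therefore occupies the samples between its slot and the next
# base's slot. Samples past the last slot (beyond stride * length(moves))
# are unmodelled and excluded rather than appended to the last base.

#' Per-base sample intervals from a move table
#'
#' Base i occupies samples `[trim + stride*slot_i, trim + stride*slot_{i+1})`
#' where `slot_i` is the index of the i-th 1 in `moves`; the last base ends
#' at `trim + stride*length(moves)`. Intervals are contiguous and tile
#' `[trim, trim + stride*length(moves))`.
#'
#' @param mt a `move_table`.
#' @return data.frame with columns `start`, `end` (0-based half-open sample
#'   indices), one row per base.
#' @export
moves_to_intervals <- function(mt) {
  stopifnot(inherits(mt, "move_table"))
  slots <- which(mt$moves == 1L) - 1L            # 0-based slot index per base
  starts <- mt$trim_samples + mt$stride * slots
  ends <- c(starts[-1L], mt$trim_samples + mt$stride * length(mt$moves))
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Convert a move table into a signal-to-read alignment
#'
#' Emits one MATCH op per basecalled base whose length is the base's dwell
#' (interval length in samples). The result always satisfies the ss
#' conservation invariants; reform never produces SIG_INS or BASE_DEL ops.
#'
#' @param mt a `move_table` for the read.
#' @param read the `read_record` (its sequence length must equal the number
#'   of moves).
#' @param signal optional `raw_signal`; when given, the alignment must fit
#'   within the signal.
#' @param rna logical; RNA is acquired 3' to 5', so the alignment is marked
#'   `signal_direction = "reverse"` for downstream layout.
#' @return an `ss_alignment` with `seq_kind = "read"`.
#' @export
reform <- function(mt, read, signal = NULL, rna = FALSE) {
  stopifnot(inherits(mt, "move_table"), inherits(read, "read_record"))
  nbase <- sum(mt$moves)
  if (!is.na(read$sequence) && nbase != nchar(read$sequence))
    stop("move table implies ", nbase, " bases but read ", read$read_id,
         " has ", nchar(read$sequence))
  iv <- moves_to_intervals(mt)
  sig_end <- mt$trim_samples + mt$stride * length(mt$moves)
  if (!is.null(signal) && sig_end > length(signal$samples))
    stop("move table extends to sample ", sig_end, " but signal of read ",
         read$read_id, " has only ", length(signal$samples))
  ss_alignment(read$read_id, ss_ops(rep("M", nrow(iv)), iv$end - iv$start),
               sig_start = mt$trim_samples, sig_end = sig_end,
               seq_start = 0L, seq_end = nbase, seq_kind = "read",
               strand = read$strand,
               signal_direction = if (rna) "reverse" else "forward")
}

#' Extract the move table from a read record's mv/ts tags
#'
#' Expects the common basecaller convention: `mv:B:c,<stride>,<m1>,<m2>,...`
#' and an optional `ts:i:<trim>` tag.
#'
#' @param record a `read_record`.
#' @return a `move_table`, or NULL if the record has no mv tag.
#' @export
move_table_from_record <- function(record) {
  mv <- tag_value(record, "mv")
  if (is.null(mv)) return(NULL)
  v <- as.integer(strsplit(sub("^c,", "", mv), ",", fixed = TRUE)[[1L]])
  ts <- tag_value(record, "ts")
  move_table(stride = v[1L], moves = v[-1L],
             trim_samples = if (is.null(ts)) 0L else as.integer(ts))
}

#' Encode a move table as mv/ts tag strings
#' @param mt a `move_table`.
#' @return character vector of two tag strings.
#' @export
move_table_tags <- function(mt) {
  c(paste0("mv:B:c,", mt$stride, ",", paste(mt$moves, collapse = ",")),
    paste0("ts:i:", mt$trim_samples))
}

#' Load move tables from a plain TSV (fixture fallback)
#'
#' Columns: `read_id`, `stride`, `trim`, `moves` (comma-separated 0/1).
#'
#' @param path TSV file.
#' @return named list of `move_table`.
#' @export
read_move_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   colClasses = c(moves = "character"))
  out <- lapply(seq_len(nrow(df)), function(i)
    move_table(df$stride[i],
               as.integer(strsplit(df$moves[i], ",", fixed = TRUE)[[1L]]),
               df$trim[i]))
  setNames(out, df$read_id)
}
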