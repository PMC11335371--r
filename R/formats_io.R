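# I/O for every external format the toolkit touches.
#
# Coordinates are 0-based half-open everywhere in memory; SAM's 1-based POS
# is converted at the boundary both ways. Minus-strand SAM SEQ fields are
# stored reverse-complemented on disk (SAM convention) and in sequencing
# direction in memory.

# ---- signal container --------------------------------------------------
#
# A documented plain-text stand-in for BLOW5: for each read, one JSON header
# line holding read_id + calibration, then one tab-separated line of raw DAC
# samples. Lines starting with '#' are comments.

#' Write a signal container
#' @param signals list of `raw_signal` objects.
#' @param path output file.
#' @param stamp optional tool-version string written as a comment header.
#' @return `path`, invisibly.
#' @export
write_signal_container <- function(signals, path, stamp = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(stamp))
    writeLines(paste0("# ", stamp), con, sep = "\n")
  writeLines("# sigpile signal container v1", con, sep = "\n")
  for (s in signals) {
    stopifnot(inherits(s, "raw_signal"))
    hdr <- jsonlite::toJSON(
      list(read_id = s$read_id, digitisation = s$digitisation,
           offset_pA = s$offset_pA, range_pA = s$range_pA,
           sampling_rate = s$sampling_rate, n_samples = length(s$samples)),
      auto_unbox = TRUE, digits = NA)
    writeLines(as.character(hdr), con, sep = "\n")
    writeLines(paste(s$samples, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a signal container
#'
#' @param path container file written by [write_signal_container()] (or by
#'   hand, following the same schema).
#' @return named list of `raw_signal`, keyed by read_id (O(1) lookup).
#' @export
read_signal_container <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) %% 2L != 0L)
    stop("malformed signal container: odd number of data lines")
  out <- list()
  for (i in seq(1L, length(lines), by = 2L)) {
    hdr <- jsonlite::fromJSON(lines[i])
    need <- c("read_id", "digitisation", "offset_pA", "range_pA",
              "sampling_rate")
    miss <- setdiff(need, names(hdr))
    if (length(miss) > 0L)
      stop("signal container record ", (i + 1L) %/% 2L,
           if (!is.null(hdr$read_id)) paste0(" (read ", hdr$read_id, ")"),
           ": missing calibration field(s) ", paste(miss, collapse = ", "))
    if (!is.null(out[[hdr$read_id]]))
      stop("duplicate read_id in signal container: ", hdr$read_id)
    samples <- as.integer(strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]])
    if (!is.null(hdr$n_samples) && hdr$n_samples != length(samples))
      stop("signal container read ", hdr$read_id, ": declared ",
           hdr$n_samples, " samples, found ", length(samples))
    out[[hdr$read_id]] <- raw_signal(hdr$read_id, samples, hdr$digitisation,
                                     hdr$offset_pA, hdr$range_pA,
                                     hdr$sampling_rate)
  }
  out
}

# ---- SAM ---------------------------------------------------------------

sam_flag <- function(strand) if (strand == "-") 16L else 0L

#' Read a plain-text SAM file
#'
#' Auxiliary tags are preserved verbatim. Minus-strand sequences are
#' converted to sequencing direction in memory.
#'
#' @param path SAM file.
#' @return list of `read_record`; header lines kept in attribute `"header"`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  recs <- vector("list", length(body_idx))
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("malformed SAM line ", i, ": fewer than 11 fields")
    flag <- as.integer(f[2L])
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    cigar <- f[6L]
    if (cigar != "*" && !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
      stop("malformed CIGAR at SAM line ", i, ": ", cigar)
    seq <- f[10L]
    if (seq == "*") seq <- NA_character_
    else if (strand == "-") seq <- revcomp(seq)
    recs[[j]] <- read_record(
      read_id = f[1L], sequence = seq,
      ref_name = if (f[3L] == "*") NA_character_ else f[3L],
      ref_start = as.integer(f[4L]) - 1L,
      cigar = if (cigar == "*") NA_character_ else cigar,
      strand = strand,
      tags = if (length(f) > 11L) f[12:length(f)] else character(0))
  }
  attr(recs, "header") <- hdr
  recs
}

#' Write read records as plain-text SAM
#'
#' @param records list of `read_record`.
#' @param path output file.
#' @param header character vector of header lines (passed through verbatim);
#'   when NULL, a minimal header is synthesised from `ref_lengths`.
#' @param ref_lengths named integer vector of reference lengths for @SQ
#'   lines (used only when `header` is NULL).
#' @param stamp optional tool-version string emitted as a @PG line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, header = NULL, ref_lengths = NULL,
                      stamp = NULL) {
  if (is.null(header)) {
    header <- "@HD\tVN:1.6\tSO:coordinate"
    if (!is.null(ref_lengths))
      header <- c(header, sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                                  as.integer(ref_lengths)))
  }
  if (!is.null(stamp))
    header <- c(header, paste0("@PG\tID:sigpile\tPN:sigpile\tVN:", stamp))
  body <- vapply(records, function(r) {
    seq <- r$sequence
    if (is.na(seq)) seq <- "*"
    else if (r$strand == "-") seq <- revcomp(seq)
    paste(c(r$read_id, sam_flag(r$strand),
            if (is.na(r$ref_name)) "*" else r$ref_name,
            r$ref_start + 1L, 60L,
            if (is.na(r$cigar)) "*" else r$cigar,
            "*", 0L, 0L, seq, "*", r$tags), collapse = "\t")
  }, "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

# ---- PAF ---------------------------------------------------------------
#
# Standard PAF columns; signal information travels in typed tags (ss:Z:,
# si:Z:, ...), and the CIGAR in cg:Z:. PAF carries no sequence.

#' Read a PAF file into read records
#' @param path PAF file.
#' @return list of `read_record` (sequence is NA; CIGAR from cg:Z: if present).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recs <- vector("list", length(lines))
  for (j in seq_along(lines)) {
    f <- strsplit(lines[j], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) stop("malformed PAF line ", j, ": fewer than 12 fields")
    tags <- if (length(f) > 12L) f[13:length(f)] else character(0)
    cg <- grep("^cg:Z:", tags, value = TRUE)
    cigar <- if (length(cg) > 0L) sub("^cg:Z:", "", cg[[1L]]) else NA_character_
    if (!is.na(cigar) && !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
      stop("malformed CIGAR at PAF line ", j, ": ", cigar)
    recs[[j]] <- read_record(
      read_id = f[1L], sequence = NA_character_, ref_name = f[6L],
      ref_start = as.integer(f[8L]), cigar = cigar, strand = f[5L],
      tags = tags[!startsWith(tags, "cg:Z:")])
  }
  recs
}

#' Write read records as PAF
#' @param records list of `read_record`.
#' @param path output file.
#' @param ref_lengths named integer vector of reference lengths.
#' @param stamp optional version comment line.
#' @return `path`, invisibly.
#' @export
write_paf <- function(records, path, ref_lengths = NULL, stamp = NULL) {
  body <- vapply(records, function(r) {
    qlen <- if (!is.na(r$sequence)) nchar(r$sequence)
            else if (!is.na(r$cigar)) cigar_query_length(r$cigar) else 0L
    rlen <- if (!is.na(r$cigar)) cigar_ref_length(r$cigar) else 0L
    tlen <- if (!is.null(ref_lengths) && !is.na(r$ref_name) &&
                r$ref_name %in% names(ref_lengths))
      as.integer(ref_lengths[[r$ref_name]]) else r$ref_start + rlen
    tags <- r$tags
    if (!is.na(r$cigar)) tags <- c(tags, paste0("cg:Z:", r$cigar))
    paste(c(r$read_id, qlen, 0L, qlen, r$strand,
            if (is.na(r$ref_name)) "*" else r$ref_name,
            tlen, r$ref_start, r$ref_start + rlen, rlen, rlen, 60L, tags),
          collapse = "\t")
  }, "")
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# sigpile ", stamp), con, sep = "\n")
  writeLines(body, con, sep = "\n")
  invisible(path)
}

# ---- region-filtered alignment access ----------------------------------

record_ref_span <- function(r) {
  rlen <- if (!is.na(r$cigar)) cigar_ref_length(r$cigar) else 0L
  c(r$ref_start, r$ref_start + rlen)
}

record_overlaps <- function(r, reg) {
  if (is.na(r$ref_name) || r$ref_name != reg$ref_name) return(FALSE)
  sp <- record_ref_span(r)
  sp[1L] < reg$end && sp[2L] > reg$start
}

#' Read alignments, optionally filtered to a region
#'
#' Dispatches on extension (`.sam` / `.paf`). With a region, returns exactly
#' the records whose reference span overlaps it. Files below 10k records are
#' scanned linearly; larger coordinate-sorted files use a binary search on
#' start coordinate.
#'
#' @param path SAM or PAF file.
#' @param region optional `region` filter.
#' @return list of `read_record`.
#' @export
read_alignments <- function(path, region = NULL) {
  ext <- tolower(tools::file_ext(path))
  recs <- switch(ext, sam = read_sam(path), paf = read_paf(path),
                 stop("unknown alignment format: .", ext))
  if (is.null(region)) return(recs)
  hdr <- attr(recs, "header")
  if (length(recs) > 10000L) {
    starts <- vapply(recs, function(r) r$ref_start, 0L)
    if (is.unsorted(starts))
      stop("region queries on files above 10k records require coordinate-sorted input")
    maxlen <- max(vapply(recs, function(r) diff(record_ref_span(r)), 0L))
    lo <- findInterval(region$start - maxlen, starts) + 1L # earlier records cannot overlap
    hi <- findInterval(region$end - 1L, starts)            # later records start past the region
    cand <- if (hi >= lo) recs[lo:hi] else list()
    out <- Filter(function(r) record_overlaps(r, region), cand)
  } else {
    out <- Filter(function(r) record_overlaps(r, region), recs)
  }
  attr(out, "header") <- hdr
  out
}

# ---- BED ---------------------------------------------------------------

#' Read a BED annotation track
#'
#' 3+ column BED, 0-based half-open. The result is sorted by
#' (ref_name, start).
#'
#' @param path BED file.
#' @return data.frame of class `annotation_track` with columns `ref_name`,
#'   `start`, `end`, `label`, `color`.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("BED file not found: ", path)
  empty <- data.frame(ref_name = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      color = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("annotation_track", "data.frame")
  if (info$size == 0L) return(empty)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("failed to parse BED ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr) == 0L) return(empty)
  df <- data.frame(
    ref_name = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    label = if (!is.null(gr$name)) as.character(gr$name) else "",
    color = if (!is.null(gr$itemRgb)) as.character(gr$itemRgb) else
      NA_character_,
    stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    stop("BED interval with start >= end at line ",
         which(df$start >= df$end)[1L])
  df <- df[order(df$ref_name, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_track", "data.frame")
  df
}

# ---- pore model --------------------------------------------------------

#' Read a k-mer pore model
#'
#' TSV with a header and columns `kmer`, `level_mean`, `level_stdv`. A model
#' with all 4^k k-mers is complete; missing k-mers give a warning and an
#' incomplete model.
#'
#' @param path model TSV.
#' @return An object of class `pore_model`: list with `k`, named numeric
#'   `level_mean` and `level_stdv`, and logical `complete`.
#' @export
read_pore_model <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("kmer", "level_mean", "level_stdv")
  if (!all(need %in% names(df)))
    stop("pore model must have columns kmer, level_mean, level_stdv")
  klens <- unique(nchar(df$kmer))
  if (length(klens) != 1L)
    stop("mixed k-mer lengths in pore model: ", paste(klens, collapse = ", "))
  if (anyDuplicated(df$kmer))
    stop("duplicate k-mer in pore model: ", df$kmer[duplicated(df$kmer)][1L])
  pore_model(k = klens, kmers = df$kmer, level_mean = df$level_mean,
             level_stdv = df$level_stdv)
}

#' Construct a pore model object
#' @param k k-mer length.
#' @param kmers character vector of k-mers.
#' @param level_mean,level_stdv numeric vectors parallel to `kmers` (pA).
#' @return a `pore_model`.
#' @export
pore_model <- function(k, kmers, level_mean, level_stdv) {
  complete <- length(kmers) == 4L^k
  if (!complete)
    warning("incomplete pore model: ", length(kmers), " of ", 4L^k,
            " ", k, "-mers present")
  structure(list(k = as.integer(k),
                 level_mean = setNames(as.numeric(level_mean), kmers),
                 level_stdv = setNames(as.numeric(level_stdv), kmers),
                 complete = complete, msb = NA_integer_),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("pore_model: k=%d, %d k-mers%s%s\n", x$k, length(x$level_mean),
              if (x$complete) " (complete)" else " (incomplete)",
              if (!is.na(x$msb)) paste0(", MSB position ", x$msb) else ""))
  invisible(x)
}

#' Write a pore model TSV
#' @param model a `pore_model`.
#' @param path output file.
#' @param stamp optional version comment line.
#' @return `path`, invisibly.
#' @export
write_pore_model <- function(model, path, stamp = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# sigpile ", stamp), con, sep = "\n")
  writeLines("kmer\tlevel_mean\tlevel_stdv", con, sep = "\n")
  writeLines(sprintf("%s\t%s\t%s", names(model$level_mean),
                     format(model$level_mean, trim = TRUE, digits = 15),
                     format(model$level_stdv, trim = TRUE, digits = 15)),
             con, sep = "\n")
  invisible(path)
}

# ---- FASTA -------------------------------------------------------------

#' Read a FASTA reference
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write a FASTA reference
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Extract the sequence of a region from a reference
#' @param ref named character vector of reference sequences.
#' @param reg a `region`.
#' @return character string of length `reg$end - reg$start`.
#' @export
ref_region_seq <- function(ref, reg) {
  if (!reg$ref_name %in% names(ref))
    stop("reference ", reg$ref_name, " not found")
  s <- ref[[reg$ref_name]]
  if (reg$end > nchar(s))
    stop("region end ", reg$end, " beyond reference length ", nchar(s))
  substring(s, reg$start + 1L, reg$end)
}
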