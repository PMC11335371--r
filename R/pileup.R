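# Pileup geometry: where every sample of every read goes on screen.
#
# Two horizontal layouts:
#   time-scale:     consecutive samples are spaced uniformly; base columns
#                   fall wherever the alignment puts them.
#   molecule-scale: every base column has equal width; a base's n samples
#                   are re-packed evenly inside its column.
# All geometry is computed here; the renderer only draws it.

BASE_COLORS <- c(A = "#4daf4a", C = "#377eb8", G = "#ff7f00", T = "#e41a1c",
                 U = "#e41a1c", N = "#999999")
BASE_COLORS_CB <- c(A = "#009E73", C = "#0072B2", G = "#E69F00", T = "#D55E00",
                    U = "#D55E00", N = "#999999")

empty_points <- function() {
  data.frame(x = numeric(0), y = numeric(0), base_pos = integer(0),
             kind = character(0), stringsAsFactors = FALSE)
}

read_glyph <- function(read_id, points, boundaries = numeric(0),
                       gap_spans = NULL, insertion_markers = NULL,
                       strand = "+") {
  if (is.null(gap_spans))
    gap_spans <- data.frame(x0 = numeric(0), x1 = numeric(0),
                            pos = integer(0), label = character(0),
                            skip = logical(0), stringsAsFactors = FALSE)
  if (is.null(insertion_markers))
    insertion_markers <- list()
  structure(list(read_id = read_id, points = points, boundaries = boundaries,
                 gap_spans = gap_spans, insertion_markers = insertion_markers,
                 strand = strand),
            class = "read_glyph")
}

#' Time-scale layout of one aligned read
#'
#' Samples are placed at `x = i * unit` in op order; base boundaries fall at
#' cumulative MATCH/SIG_INS sample counts.
#'
#' @param aln an `ss_alignment`.
#' @param signal the read's `raw_signal`.
#' @param unit display units per sample.
#' @return a `read_glyph` whose points carry x, pA, the aligned sequence
#'   position (NA for SIG_INS samples) and the op kind.
#' @export
layout_time_scale <- function(aln, signal, unit = 1) {
  stopifnot(inherits(aln, "ss_alignment"), inherits(signal, "raw_signal"))
  pA <- signal_pA(signal)
  idx <- op_sample_indices(aln)
  ops <- aln$ops
  x0 <- 0; pts <- vector("list", nrow(ops)); bounds <- numeric(0)
  p <- aln$seq_start
  for (i in seq_len(nrow(ops))) {
    k <- ops$kind[i]
    if (k == "D") { p <- p + ops$len[i]; next }
    n <- ops$len[i]
    xs <- x0 + (seq_len(n) - 1) * unit
    pts[[i]] <- data.frame(x = xs, y = pA[idx[[i]]],
                           base_pos = if (k == "M") p else NA_integer_,
                           kind = k, stringsAsFactors = FALSE)
    x0 <- x0 + n * unit
    if (k == "M") { bounds <- c(bounds, x0); p <- p + 1L }
  }
  points <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
  if (is.null(points)) points <- empty_points()
  read_glyph(aln$read_id, points, boundaries = bounds, strand = aln$strand)
}

#' Molecule-scale layout of one aligned read
#'
#' Every base column has width `base_width`; a base's n samples sit at
#' `x = base_left + base_width * (j + 0.5)/n`. Deleted bases produce a gap
#' span over their columns, labelled with the missing bases; inserted
#' samples are stacked at the border of the preceding base's column.
#'
#' @param aln an `ss_alignment` (minus-strand reference alignments are
#'   oriented internally so columns run with the reference).
#' @param signal the read's `raw_signal`.
#' @param base_width display units per base column.
#' @param seq the sequence the alignment refers to (read or reference),
#'   used for gap labels; optional.
#' @param origin sequence position mapped to x = 0 (defaults to the
#'   alignment's own start; a pileup passes the region start so all glyphs
#'   share columns).
#' @return a `read_glyph`.
#' @export
layout_molecule_scale <- function(aln, signal, base_width = 20, seq = NULL,
                                  origin = NULL) {
  stopifnot(inherits(aln, "ss_alignment"), inherits(signal, "raw_signal"))
  if (aln$seq_kind == "reference" && aln$strand == "-") {
    ops_ref_order <- ops_in_ref_order(aln)
    aln2 <- aln
    aln2$ops <- ops_ref_order$ops
    aln2$signal_direction <- ops_ref_order$signal_direction
    aln <- aln2
  }
  if (is.null(origin)) origin <- aln$seq_start
  pA <- signal_pA(signal)
  idx <- op_sample_indices(aln)
  ops <- aln$ops
  p <- aln$seq_start
  pts <- vector("list", nrow(ops))
  gaps <- list(); ins <- list()
  for (i in seq_len(nrow(ops))) {
    k <- ops$kind[i]; n <- ops$len[i]
    left <- (p - origin) * base_width
    if (k == "M") {
      xs <- left + base_width * (seq_len(n) - 0.5) / n
      pts[[i]] <- data.frame(x = xs, y = pA[idx[[i]]], base_pos = p,
                             kind = "M", stringsAsFactors = FALSE)
      p <- p + 1L
    } else if (k == "D") {
      labels <- if (!is.null(seq))
        substring(seq, p + 1L, p + n) else paste(rep("?", n), collapse = "")
      gaps[[length(gaps) + 1L]] <- data.frame(
        x0 = left, x1 = left + n * base_width, pos = p,
        label = labels, skip = ops$skip[i], stringsAsFactors = FALSE)
      p <- p + n
    } else {                                    # SIG_INS
      ins[[length(ins) + 1L]] <- list(x = left, pos = p,
                                      values = pA[idx[[i]]])
    }
  }
  points <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
  if (is.null(points)) points <- empty_points()
  bounds <- ((aln$seq_start:aln$seq_end) - origin) * base_width
  read_glyph(aln$read_id, points, boundaries = bounds,
             gap_spans = if (length(gaps) > 0L) do.call(rbind, gaps) else NULL,
             insertion_markers = ins, strand = aln$strand)
}

# Reverse a minus-strand alignment's ops into reference order without
# touching coordinates (the op list/direction pair used for layout).
ops_in_ref_order <- function(aln) {
  idx <- rev(seq_len(nrow(aln$ops)))
  list(ops = ss_ops(aln$ops$kind[idx], aln$ops$len[idx], aln$ops$skip[idx]),
       signal_direction = if (aln$signal_direction == "forward") "reverse"
                          else "forward")
}

#' Clip a signal-to-reference alignment to a region
#'
#' Ops outside the region are dropped (their samples leave the signal span);
#' BASE_DEL ops straddling a boundary are split. Insertions keep their
#' position at the border of the preceding base and are retained only when
#' that base lies inside the region.
#'
#' @param aln an `ss_alignment` with `seq_kind = "reference"`.
#' @param reg a `region`.
#' @return the clipped alignment, or NULL when there is no overlap.
#' @export
clip_to_region <- function(aln, reg) {
  stopifnot(inherits(aln, "ss_alignment"), inherits(reg, "region"))
  if (aln$seq_kind != "reference")
    stop("clip_to_region needs a signal-to-reference alignment")
  if (aln$seq_start >= reg$end || aln$seq_end <= reg$start) return(NULL)
  if (aln$seq_start >= reg$start && aln$seq_end <= reg$end) return(aln)

  rev_in <- aln$strand == "-"
  ops <- aln$ops
  order_idx <- if (rev_in) rev(seq_len(nrow(ops))) else seq_len(nrow(ops))
  p <- aln$seq_start
  head_samples <- 0L; tail_samples <- 0L
  keep_kind <- character(0); keep_len <- integer(0); keep_skip <- logical(0)
  for (j in order_idx) {
    k <- ops$kind[j]; L <- ops$len[j]
    if (k == "M") {
      inside <- p >= reg$start && p < reg$end
      if (!inside) {
        if (p < reg$start) head_samples <- head_samples + L
        else tail_samples <- tail_samples + L
      } else {
        keep_kind <- c(keep_kind, "M"); keep_len <- c(keep_len, L)
        keep_skip <- c(keep_skip, FALSE)
      }
      p <- p + 1L
    } else if (k == "D") {
      lo <- max(p, reg$start); hi <- min(p + L, reg$end)
      if (hi > lo) {
        keep_kind <- c(keep_kind, "D"); keep_len <- c(keep_len, hi - lo)
        keep_skip <- c(keep_skip, ops$skip[j])
      }
      p <- p + L
    } else {                                    # I: border of base p-1
      inside <- p > reg$start && p <= reg$end
      if (!inside) {
        if (p <= reg$start) head_samples <- head_samples + L
        else tail_samples <- tail_samples + L
      } else {
        keep_kind <- c(keep_kind, "I"); keep_len <- c(keep_len, L)
        keep_skip <- c(keep_skip, FALSE)
      }
    }
  }
  new_ops <- ss_ops(keep_kind, keep_len, keep_skip)
  if (rev_in) {
    ridx <- rev(seq_len(nrow(new_ops)))
    new_ops <- ss_ops(new_ops$kind[ridx], new_ops$len[ridx],
                      new_ops$skip[ridx])
  }
  # head (reference-left) ops map to the op-order head for +, tail for -
  lead <- if (rev_in) tail_samples else head_samples
  trail <- if (rev_in) head_samples else tail_samples
  out <- aln
  out$ops <- new_ops
  if (aln$signal_direction == "forward") {
    out$sig_start <- aln$sig_start + lead
    out$sig_end <- aln$sig_end - trail
  } else {
    out$sig_start <- aln$sig_start + trail
    out$sig_end <- aln$sig_end - lead
  }
  out$seq_start <- max(aln$seq_start, reg$start)
  out$seq_end <- min(aln$seq_end, reg$end)
  v <- ss_validate(out)
  if (length(v) > 0L)
    stop("internal error: clip_to_region produced an invalid alignment: ",
         v[[1L]])
  out
}

#' Build the pileup layout for a region
#'
#' Assembles, in track order: annotation (if given), simulated data (if
#' given), plus-strand overlay, plus-strand stacked reads, minus-strand
#' overlay, minus-strand stacked reads. Minus-strand glyphs are built in
#' reverse signal orientation so their base columns coincide with the plus
#' track's columns. Reads are clipped to the region.
#'
#' @param reg a `region`.
#' @param alignments list of signal-to-reference `ss_alignment`.
#' @param signals named list of `raw_signal` keyed by read_id.
#' @param reference named character vector of reference sequences.
#' @param base_width display units per base column (molecule-scale).
#' @param bed optional `annotation_track`.
#' @param sim optional simulated-data track: list with elements
#'   `alignments` and `signals` shaped like the main arguments.
#' @param selected read ids shown in the overlay tracks (default: all).
#' @return An object of class `pileup_layout`.
#' @export
build_pileup <- function(reg, alignments, signals, reference,
                         base_width = 20, bed = NULL, sim = NULL,
                         selected = NULL) {
  stopifnot(inherits(reg, "region"))
  refseq <- ref_region_seq(reference, region(reg$ref_name, 0L, reg$end))
  cols <- data.frame(
    pos = reg$start:(reg$end - 1L),
    x0 = (0:(reg$end - reg$start - 1L)) * base_width,
    x1 = (1:(reg$end - reg$start)) * base_width,
    base = strsplit(substring(refseq, reg$start + 1L, reg$end), "")[[1L]],
    stringsAsFactors = FALSE)

  make_glyphs <- function(alns, sigs) {
    out <- list()
    for (aln in alns) {
      if (is.null(aln) || aln$seq_kind != "reference") next
      if (aln$seq_start >= reg$end || aln$seq_end <= reg$start) next
      cl <- clip_to_region(aln, reg)
      if (is.null(cl) || sum(cl$ops$kind == "M") == 0L) next
      sig <- sigs[[cl$read_id]]
      if (is.null(sig)) stop("no signal for read ", cl$read_id)
      out[[cl$read_id]] <- layout_molecule_scale(cl, sig, base_width,
                                                 seq = refseq,
                                                 origin = reg$start)
    }
    out
  }

  glyphs <- make_glyphs(alignments, signals)
  if (length(glyphs) == 0L)
    warning("no reads overlap region ", reg$ref_name, ":[", reg$start, ",",
            reg$end, ")")
  if (is.null(selected)) selected <- names(glyphs)
  strands <- vapply(glyphs, function(g) g$strand, "")
  plus <- glyphs[strands == "+"]; minus <- glyphs[strands == "-"]

  tracks <- list()
  if (!is.null(bed)) {
    ann <- bed[bed$ref_name == reg$ref_name & bed$start < reg$end &
                 bed$end > reg$start, , drop = FALSE]
    tracks[[length(tracks) + 1L]] <-
      list(kind = "annotation", strand = "both", intervals = ann)
  }
  if (!is.null(sim)) {
    sim_glyphs <- make_glyphs(sim$alignments, sim$signals)
    tracks[[length(tracks) + 1L]] <-
      list(kind = "simulated", strand = "both", glyphs = sim_glyphs)
  }
  if (length(plus) > 0L) {
    tracks[[length(tracks) + 1L]] <-
      list(kind = "pileup_overlay", strand = "+",
           glyphs = plus[names(plus) %in% selected])
    tracks[[length(tracks) + 1L]] <-
      list(kind = "stacked_reads", strand = "+", glyphs = plus)
  }
  if (length(minus) > 0L) {
    tracks[[length(tracks) + 1L]] <-
      list(kind = "pileup_overlay", strand = "-",
           glyphs = minus[names(minus) %in% selected])
    tracks[[length(tracks) + 1L]] <-
      list(kind = "stacked_reads", strand = "-", glyphs = minus)
  }
  structure(list(region = reg, base_width = base_width, tracks = tracks,
                 columns = cols, selected = selected,
                 width = (reg$end - reg$start) * base_width),
            class = "pileup_layout")
}

#' @export
print.pileup_layout <- function(x, ...) {
  cat(sprintf("pileup_layout %s:[%d,%d): %d tracks, width %g\n",
              x$region$ref_name, x$region$start, x$region$end,
              length(x$tracks), x$width))
  for (tr in x$tracks)
    cat(sprintf("  %s (%s): %d members\n", tr$kind, tr$strand,
                if (!is.null(tr$glyphs)) length(tr$glyphs)
                else nrow(tr$intervals)))
  invisible(x)
}
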