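# Seeded pore-model signal simulator.
#
# Generates an internally consistent bundle: reference, per-read signal
# (Gaussian per-k-mer current levels, truncated-negative-binomial dwells,
# trimmed adapter samples, both strands), move tables, perfect-CIGAR read
# records, and ground-truth signal-to-read / signal-to-reference
# alignments. All randomness flows from one explicit seed and the global
# RNG state is restored afterwards.
#
# Conventions: the samples of read base i are drawn from the k-mer of the
# *read's own* sequence starting at i (padded at the tail by repeating the
# terminal base), so a minus-strand read is governed by the complement of
# the reference — exactly what the pore senses.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  force(code)
}

#' Generate a synthetic pore model with a designated most significant base
#'
#' Current level of a k-mer is dominated by the base at position `msb`
#' (0-based): A=80, C=90, G=100, T=110 pA by default, plus small
#' deterministic contributions from the other positions that decay
#' geometrically with distance from the MSB. With `minor_weight = 0` the
#' level is a pure function of the MSB base.
#'
#' @param k k-mer length.
#' @param msb 0-based designated MSB position, in `[0, k)`.
#' @param base_levels named main-effect levels in pA.
#' @param minor_weight geometric decay factor of the secondary positions'
#'   contributions (0 disables them).
#' @param level_stdv per-k-mer noise sd in pA.
#' @return a complete `pore_model` with its `msb` field set.
#' @export
generate_pore_model <- function(k = 6L, msb = 2L,
                                base_levels = c(A = 80, C = 90, G = 100, T = 110),
                                minor_weight = 0.4, level_stdv = 1.0) {
  k <- as.integer(k); msb <- as.integer(msb)
  if (msb < 0L || msb >= k) stop("msb must lie in [0, k)")
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, DNA_BASES, simplify = FALSE)),
                    stringsAsFactors = FALSE))
  grid <- grid[, rev(seq_len(k)), drop = FALSE]   # column p = position p
  kmers <- do.call(paste0, grid)
  minor <- c(A = -1.5, C = -0.5, G = 0.5, T = 1.5)
  level <- base_levels[grid[[msb + 1L]]]
  if (minor_weight > 0) for (p in seq_len(k)) {
    if (p == msb + 1L) next
    w <- 2 * minor_weight^abs(p - 1L - msb)
    level <- level + w * minor[grid[[p]]]
  }
  m <- pore_model(k, kmers, unname(level), rep(level_stdv, length(kmers)))
  m$msb <- msb
  m
}

# k-mer starting at each base of seq, tail-padded by the terminal base.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  padded <- paste0(seq, strrep(substring(seq, n, n), k - 1L))
  substring(padded, 1:n, 1:n + k - 1L)
}

#' Simulate a fully consistent signal dataset
#'
#' Each read covers the whole reference on one strand. Per base, dwell is
#' drawn from a truncated negative binomial (minimum 1 sample, or 1 slot
#' when `stride > 1`); per sample, current is Gaussian around the covering
#' k-mer's model mean (plus any modification offset), with sd equal to the
#' model sd times `noise_multiplier`. A trimmed adapter segment precedes
#' the first base. Identical seed, identical bundle.
#'
#' @param model a `pore_model` (see [generate_pore_model()]).
#' @param reference reference sequence string, or NULL to draw a random one
#'   of length `ref_len`.
#' @param ref_len length of the random reference when `reference` is NULL.
#' @param depth number of reads (each spans the full reference).
#' @param dwell_mean,dwell_dispersion mean and dispersion (negative
#'   binomial `size`) of the per-base dwell, in samples.
#' @param noise_multiplier scales the model sd (0 gives noise-free signal).
#' @param trim_len adapter samples before the first base.
#' @param stride move-table stride; with `stride > 1` dwells are quantised
#'   to whole slots.
#' @param minus_fraction probability a read is minus-strand.
#' @param seed the single RNG seed for the whole bundle.
#' @param variants optional data.frame(pos, base, fraction): substitutions
#'   applied to a read's molecule (sequence *and* signal) with the given
#'   per-read probability; `pos` is 0-based on the reference.
#' @param mods optional data.frame(pos, delta_pA, fraction): current-level
#'   offsets at marked reference positions, applied to a read with the
#'   given probability (emulating base modifications such as 5mC);
#'   modification status is per read.
#' @param ref_name reference name used throughout the bundle.
#' @param read_prefix read-id prefix.
#' @return a dataset bundle: list with `reference`, `ref_name`, `model`,
#'   `reads`, `signals`, `move_tables`, `truth` (sig2read, sig2ref,
#'   dwells, modified, variant status) and `params`.
#' @export
simulate_dataset <- function(model, reference = NULL, ref_len = 500L,
                             depth = 20L, dwell_mean = 9, dwell_dispersion = 3,
                             noise_multiplier = 1, trim_len = 50L, stride = 1L,
                             minus_fraction = 0.5, seed = 1L,
                             variants = NULL, mods = NULL,
                             ref_name = "ref1", read_prefix = "read") {
  stopifnot(inherits(model, "pore_model"))
  if (depth <= 0L) stop("depth must be positive")
  if (dwell_mean < 1) stop("dwell mean must be at least 1 sample")
  stride <- as.integer(stride)
  with_seed(seed, {
    if (is.null(reference))
      reference <- paste(sample(DNA_BASES, ref_len, replace = TRUE),
                         collapse = "")
    L <- nchar(reference)
    k <- model$k
    digitisation <- 8192; range_pA <- 1200; offset_pA <- 10
    reads <- list(); signals <- list(); mts <- list()
    t_s2r <- list(); t_s2f <- list()
    modified <- logical(0); varied <- logical(0)
    for (r in seq_len(depth)) {
      id <- sprintf("%s_%03d", read_prefix, r)
      strand <- if (runif(1) < minus_fraction) "-" else "+"
      mol <- reference                      # the molecule actually sequenced
      has_var <- FALSE
      if (!is.null(variants)) for (i in seq_len(nrow(variants))) {
        frac <- if ("fraction" %in% names(variants)) variants$fraction[i] else 1
        if (runif(1) < frac) {
          substring(mol, variants$pos[i] + 1L, variants$pos[i] + 1L) <-
            variants$base[i]
          has_var <- TRUE
        }
      }
      read_seq <- if (strand == "-") revcomp(mol) else mol
      n <- nchar(read_seq)
      # dwell: truncated negative binomial, minimum one slot
      if (stride == 1L) {
        dwell <- 1L + rnbinom(n, size = dwell_dispersion,
                              mu = dwell_mean - 1)
      } else {
        mu_slots <- max(dwell_mean / stride - 1, 1e-3)
        dwell <- stride * (1L + rnbinom(n, size = dwell_dispersion,
                                        mu = mu_slots))
      }
      level <- unname(model$level_mean[seq_kmers(read_seq, k)])
      sdv <- unname(model$level_stdv[seq_kmers(read_seq, k)]) *
        noise_multiplier
      is_mod <- FALSE
      if (!is.null(mods) && nrow(mods) > 0L) {
        frac <- if ("fraction" %in% names(mods)) mods$fraction[1L] else 1
        is_mod <- runif(1) < frac
        if (is_mod) for (i in seq_len(nrow(mods))) {
          ref_pos <- mods$pos[i]
          ri <- if (strand == "-") L - 1L - ref_pos else ref_pos  # read index
          if (ri >= 0L && ri < n)
            level[ri + 1L] <- level[ri + 1L] + mods$delta_pA[i]
        }
      }
      body <- rnorm(sum(dwell), mean = rep(level, dwell),
                    sd = rep(sdv, dwell))
      adapter <- rnorm(trim_len, mean = 75, sd = 3)
      pA <- c(adapter, body)
      raw <- round(pA * digitisation / range_pA - offset_pA)
      signals[[id]] <- raw_signal(id, raw, digitisation, offset_pA, range_pA)
      moves <- integer(sum(dwell) %/% stride)
      moves[c(0L, cumsum(dwell[-n]))[seq_len(n)] %/% stride + 1L] <- 1L
      mts[[id]] <- move_table(stride, moves, trim_len)
      reads[[id]] <- read_record(id, sequence = read_seq,
                                 ref_name = ref_name, ref_start = 0L,
                                 cigar = paste0(n, "M"), strand = strand,
                                 tags = move_table_tags(mts[[id]]))
      sig_end <- trim_len + sum(dwell)
      t_s2r[[id]] <- ss_alignment(id, ss_ops(rep("M", n), dwell),
                                  trim_len, sig_end, 0L, n,
                                  seq_kind = "read", strand = strand)
      t_s2f[[id]] <- ss_alignment(id, ss_ops(rep("M", n), dwell),
                                  trim_len, sig_end, 0L, n,
                                  seq_kind = "reference", strand = strand)
      modified <- c(modified, setNames(is_mod, id))
      varied <- c(varied, setNames(has_var, id))
    }
    list(reference = setNames(reference, ref_name), ref_name = ref_name,
         model = model, reads = reads, signals = signals, move_tables = mts,
         truth = list(sig2read = t_s2r, sig2ref = t_s2f,
                      modified = modified, varied = varied),
         params = list(depth = depth, dwell_mean = dwell_mean,
                       dwell_dispersion = dwell_dispersion,
                       noise_multiplier = noise_multiplier,
                       trim_len = trim_len, stride = stride,
                       minus_fraction = minus_fraction, seed = seed))
  })
}

#' Inject basecall/alignment errors into a simulated bundle
#'
#' Substitutions change the basecalled sequence only (the signal keeps the
#' molecule's level). Deletions drop a base from the basecall and merge its
#' samples into the neighbouring base's dwell. Insertions invent a base
#' that steals half of the preceding base's samples. Soft clips append
#' extra basecalled bases (with fresh adapter-like samples) at both read
#' ends, marked S in the CIGAR. Move tables, CIGARs and ground truth are
#' re-derived consistently. All rates zero and no clipping returns the
#' bundle unchanged.
#'
#' @param bundle a bundle from [simulate_dataset()] (stride 1 only).
#' @param sub_rate,ins_rate,del_rate per-base error probabilities in [0,1].
#' @param softclip_len bases soft-clipped at each end (0 disables).
#' @param seed RNG seed.
#' @return the mutated bundle.
#' @export
inject_errors <- function(bundle, sub_rate = 0, ins_rate = 0, del_rate = 0,
                          softclip_len = 0L, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("error rates must lie in [0, 1]")
  if (all(rates == 0) && softclip_len == 0L) return(bundle)
  if (bundle$params$stride != 1L)
    stop("inject_errors requires a stride-1 bundle")
  with_seed(seed, {
    trim <- bundle$params$trim_len
    for (id in names(bundle$reads)) {
      rec <- bundle$reads[[id]]
      strand <- rec$strand
      # work in reference orientation
      qseq <- if (strand == "-") revcomp(rec$sequence) else rec$sequence
      dwell <- bundle$truth$sig2read[[id]]$ops$len
      if (strand == "-") dwell <- rev(dwell)
      bases <- strsplit(qseq, "", fixed = TRUE)[[1L]]
      n <- length(bases)
      out_base <- character(0); out_dwell <- integer(0); out_op <- character(0)
      for (j in seq_len(n)) {
        b <- bases[j]; d <- dwell[j]
        if (runif(1) < del_rate) {                    # basecaller missed it
          if (length(out_dwell) > 0L) {
            # merge into the previous emitted base's dwell
            last_sig <- max(which(out_op != "D"))
            out_dwell[last_sig] <- out_dwell[last_sig] + d
            out_base <- c(out_base, NA_character_)
            out_dwell <- c(out_dwell, 0L)
            out_op <- c(out_op, "D")
          } else {
            out_base <- c(out_base, NA_character_)    # merge forward later
            out_dwell <- c(out_dwell, -d)             # carry samples forward
            out_op <- c(out_op, "D")
          }
          next
        }
        carry <- 0L
        if (length(out_op) > 0L && all(out_op == "D")) {
          carry <- -sum(out_dwell)                    # leading deletions
          out_dwell[out_dwell < 0L] <- 0L
        }
        if (runif(1) < sub_rate)
          b <- sample(setdiff(DNA_BASES, b), 1L)
        out_base <- c(out_base, b)
        out_dwell <- c(out_dwell, d + carry)
        out_op <- c(out_op, "M")
        if (runif(1) < ins_rate && (d + carry) >= 2L) {
          steal <- (d + carry) %/% 2L
          out_dwell[length(out_dwell)] <- out_dwell[length(out_dwell)] - steal
          out_base <- c(out_base, sample(DNA_BASES, 1L))
          out_dwell <- c(out_dwell, steal)
          out_op <- c(out_op, "I")
        }
      }
      if (!any(out_op == "M"))
        stop("inject_errors would leave read ", id, " empty")
      sig <- bundle$signals[[id]]
      clipL_samp <- integer(0); clipR_samp <- integer(0)
      if (softclip_len > 0L) {
        cl_d <- 2L + rnbinom(2L * softclip_len, size = 2, mu = 4)
        cl_b <- sample(DNA_BASES, 2L * softclip_len, replace = TRUE)
        dL <- cl_d[seq_len(softclip_len)]; dR <- cl_d[-seq_len(softclip_len)]
        raw_clip <- function(nsamp) {
          pa <- rnorm(nsamp, 85, 4)
          as.integer(round(pa * sig$digitisation / sig$range_pA - sig$offset_pA))
        }
        clipL_samp <- raw_clip(sum(dL)); clipR_samp <- raw_clip(sum(dR))
        out_base <- c(cl_b[seq_len(softclip_len)], out_base,
                      cl_b[-seq_len(softclip_len)])
        out_dwell <- c(dL, out_dwell, dR)
        out_op <- c(rep("S", softclip_len), out_op, rep("S", softclip_len))
      }
      keep <- out_op != "D"
      new_qseq <- paste(out_base[keep], collapse = "")
      new_dwell_ref <- out_dwell[keep]
      # CIGAR in reference orientation
      cg_ops <- rle(out_op)
      cigar <- paste0(cg_ops$lengths, cg_ops$values, collapse = "")
      # back to sequencing order
      new_seq <- if (strand == "-") revcomp(new_qseq) else new_qseq
      new_dwell <- if (strand == "-") rev(new_dwell_ref) else new_dwell_ref
      # splice clip samples into the signal at the read-order ends of the body
      body <- sig$samples[(trim + 1L):length(sig$samples)]
      lead_clip <- if (strand == "-") clipR_samp else clipL_samp
      trail_clip <- if (strand == "-") clipL_samp else clipR_samp
      new_samples <- c(sig$samples[seq_len(trim)], lead_clip, body, trail_clip)
      bundle$signals[[id]] <- raw_signal(id, new_samples, sig$digitisation,
                                         sig$offset_pA, sig$range_pA,
                                         sig$sampling_rate)
      nb <- length(new_dwell)
      moves <- integer(sum(new_dwell))
      moves[c(0L, cumsum(new_dwell[-nb]))[seq_len(nb)] + 1L] <- 1L
      mt <- move_table(1L, moves, trim)
      bundle$move_tables[[id]] <- mt
      rec2 <- read_record(id, sequence = new_seq, ref_name = rec$ref_name,
                          ref_start = rec$ref_start, cigar = cigar,
                          strand = strand, tags = move_table_tags(mt))
      bundle$reads[[id]] <- rec2
      s2r <- reform(mt, rec2, bundle$signals[[id]])
      bundle$truth$sig2read[[id]] <- s2r
      bundle$truth$sig2ref[[id]] <- realign(s2r, rec2)
    }
    bundle
  })
}

#' Write a simulated bundle to disk
#'
#' Emits `ref.fa`, `signal.tsv` (signal container), `reads.sam` (mv/ts
#' tags), `sig2ref.sam` (ground-truth ss/si tags) and `model.tsv`.
#'
#' @param bundle a dataset bundle.
#' @param outdir output directory (created if needed).
#' @param stamp tool-version string written into file headers.
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(bundle, outdir, stamp = SIGPILE_VERSION) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- c(ref = file.path(outdir, "ref.fa"),
         signal = file.path(outdir, "signal.tsv"),
         reads = file.path(outdir, "reads.sam"),
         sig2ref = file.path(outdir, "sig2ref.sam"),
         model = file.path(outdir, "model.tsv"))
  write_fasta(bundle$reference, p[["ref"]])
  write_signal_container(bundle$signals, p[["signal"]], stamp = stamp)
  ref_lengths <- setNames(nchar(bundle$reference), bundle$ref_name)
  write_sam(bundle$reads, p[["reads"]], ref_lengths = ref_lengths,
            stamp = stamp)
  tagged <- lapply(names(bundle$reads), function(id) {
    rec <- bundle$reads[[id]]
    rec$tags <- c(rec$tags, ss_tags_for(bundle$truth$sig2ref[[id]]))
    rec
  })
  write_sam(tagged, p[["sig2ref"]], ref_lengths = ref_lengths, stamp = stamp)
  write_pore_model(bundle$model, p[["model"]], stamp = stamp)
  invisible(p)
}
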