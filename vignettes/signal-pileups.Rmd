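---
title: "Anchoring nanopore raw signal to bases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring nanopore raw signal to bases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigpile)
```

## The problem

A nanopore read is a time series of current measurements; basecalling turns
it into a sequence, but many analyses (modified-base detection, variant
inspection, method development) need to look at the raw samples *in
register with* the bases they were measured over. `sigpile` maintains that
register at three levels: an encoding (the ss tag), converters that produce
it (reform from move tables, realign through read alignments), and a layout
engine that turns registered alignments into pileup graphics. This vignette
records the models, conventions and tunable parameters, and what the test
suite does and does not establish.

## The ss encoding and its invariants

A signal-to-sequence alignment is an ordered op list over three kinds:
MATCH (*n* samples on exactly one base, written `n,`), SIG_INS (*n* samples
on no base, `nI`) and BASE_DEL (*m* bases with no samples, `mD`), plus a
coordinate quadruple (signal and sequence intervals, both 0-based
half-open). Two conservation laws tie the op list to the coordinates:

* signal: MATCH + SIG_INS sample counts sum to `sig_end - sig_start`;
* sequence: MATCH-op count + BASE_DEL lengths sum to `seq_end - seq_start`.

`ss_validate()` checks both plus bounds; every producer in the package
(reform, realign, the simulator, shift application, region clipping)
guarantees its output validates. Canonical form forbids *runs* of SIG_INS
or BASE_DEL ops (producers merge them), which makes string equality a
usable equality test. Adjacent MATCH ops are the normal case — each binds a
different base — so they are exempt from the run rule.

Ops are stored in signal order. A `signal_direction` field records whether
op order runs with raw acquisition order (`forward`) or against it
(`reverse`): RNA is acquired 3'→5' while its basecall is stored 5'→3', and
minus-strand alignments flip once oriented to the reference, so the
direction must be explicit rather than inferred.

## reform: move tables to per-base dwells

The basecaller emits, at a fixed sample stride, a 0/1 flag per slot marking
where a new base starts; base *i* therefore owns the samples between its
slot and the next base's slot. Two conventions are normative here:

* samples beyond the last slot (`stride * length(moves)`) are unmodelled
  and excluded, not appended to the last base — visualization should not
  attribute samples no one aligned;
* the `ts` trim (adapter samples) offsets the whole alignment; trimmed
  samples are never shown as aligned.

reform output is all-MATCH by construction (a move table is surjective onto
bases), which realign relies on.

## realign: projecting through the CIGAR

Each reference base consumed by M/=/X receives its read base's samples;
read-only bases (I) become SIG_INS ops kept *between* their flanking MATCH
ops, i.e. at the border of the preceding reference base, matching how the
renderer stacks inserted samples; reference-only bases (D, N) become
BASE_DEL ops, with N flagged so a renderer can draw skips differently;
soft-clipped samples are trimmed off the signal span rather than emitted
(clipped signal is not reference-anchored). Minus-strand output keeps ops
in signal order; `orient_for_reference()` reverses them into reference
order for layout and is an involution.

The implementation is a single CIGAR walk, and is checked against an
independent per-unit projection oracle (expand the CIGAR, assign every
query base its fate by cumulative coordinate arithmetic, rebuild ops) on
hundreds of fuzzed CIGARs including I/D/N/S on both strands.

## K-mer-to-base shift correction

Event-style alignments anchor signal to k-mers: the samples labelled with
base *i* are drawn while the pore reads the k-mer starting at *i*, and the
current level is dominated by one position of that k-mer — the most
significant base (MSB), at offset *m*. Three choices are normative in this
package:

* **Separation statistic.** One-way eta-squared: between-group variance of
  levels grouped by base identity divided by total variance. It is bounded
  in [0, 1], equals 1 iff the level is a pure function of the grouping
  base, and is trivially brute-forceable, which makes the implementation
  checkable. `msb_position()` applies it to the 4^k model means per k-mer
  position; `calculate_offset()` applies the same statistic to empirical
  per-op mean currents.
* **Shift direction.** Applying shift *s* advances the pairing: the op
  previously paired with base *i* pairs with base *i + s* on the plus
  strand (the first *s* bases become unpaired, the last *s*
  sequence-units of ops are dropped along with their samples). This is the
  direction under which the offset of an unshifted event alignment equals
  the MSB position: base *j*'s most relevant event is the one labelled
  *j − m*, whose k-mer has its MSB at *j*. Minus-strand alignments shift in
  the opposite sequence direction, because the pore reads the complement
  strand with reversed geometry; in op order the drop is again from the
  tail. For minus-strand reads the grouping base is the *complement* of the
  reference base — the base the pore actually senses.
* **Ties and caps.** Ties break to the smallest shift (determinism);
  `calculate_offset()` subsamples to 50,000 MATCH ops with a seeded sample
  (`full_data = TRUE` disables this). Fewer than four observed base
  identities flags the report low-confidence.

The offset is protocol-specific (flow cell, basecall model, aligner), so
the report carries a `protocol_label`; two simulated datasets built from
models with different MSB positions yield different chosen shifts, and the
label prevents silently cross-applying one to the other.

## The simulator

The simulator is the package's ground-truth generator and its stand-in for
an expected-signal track. What it emulates, with defaults:

| feature | law | default |
|---|---|---|
| current level | Normal(model mean of the read-sequence k-mer starting at the base, model sd × multiplier) | multiplier 1, model sd 1 pA |
| dwell | 1 + NegBinomial(mu = mean − 1, size = dispersion), i.e. truncated at 1 | mean 9 samples, dispersion 3 |
| adapter | `trim_len` Gaussian samples before the first base, trimmed by `ts` | 50 samples |
| strand | Bernoulli per read; minus reads carry the reverse complement, signal generated along their own sequence | 50% minus |
| calibration | integer DAC samples, pA = (raw + offset) × range / digitisation | digitisation 8192, range 1200 pA, offset 10 |
| modifications | +Δ pA added to the samples of marked positions, per-read status | off |
| variants | substitutions applied to the molecule (sequence *and* signal) | off |

The default synthetic pore model gives the four bases at the designated MSB
position levels 80/90/100/110 pA, with contributions from the other
positions decaying geometrically (factor 0.4, amplitude 2 pA) so the MSB is
dominant but not exclusive — a pure-position model is available with
`minor_weight = 0`. Reads span the full reference; depth is therefore the
read count. The default stride is 1 so the move table represents the true
dwells exactly and `reform` must reproduce the stored truth bit for bit;
larger strides quantise dwells to whole slots.

With `noise_multiplier = 0` the signal reproduces the model levels *up to
DAC quantisation*: samples are integers, so one half quantisation step
(range/digitisation/2 ≈ 0.073 pA at the defaults) is the attainable
accuracy; the tests assert exactly that bound.

What it does **not** emulate: amplitude drift and stalls, adapter
waveforms, event-boundary blur, dwell–sequence dependence, or any specific
instrument's noise spectrum. Passing the recovery tests therefore shows the
estimators are correct under the stated generative model, not that they are
robust to every artefact of real flow cells.

`inject_errors()` adds basecall-style corruption on top (substitutions
leave signal untouched; deletions merge the lost base's samples into a
neighbour; insertions steal half the preceding base's samples; soft clips
append extra basecalled bases with fresh samples), re-deriving move tables,
CIGARs and ground truth consistently. It requires stride 1, since sample
stealing breaks slot quantisation.

## Layout and rendering

Molecule-scale places the *n* samples of a base at
`x = left + width * (j + 0.5) / n` — columns have identical width by
construction, which is what lets independent reads with different
translocation speeds overlay into a pileup. Time-scale places samples
uniformly. Deletions leave labelled gaps; insertions collapse to a marker
at the preceding base's right border, revealed by the "show signal points"
toggle. Tracks are ordered annotation, simulated, + overlay, + stack,
− overlay, − stack; minus-strand glyphs are oriented so their columns
coincide with the plus track's.

The renderer is deliberately dumb: all geometry is computed in R, embedded
as one JSON payload at full precision (the renderer never rounds a pA
value), and drawn by a small inline SVG viewer. One HTML file, no network,
and byte-identical output for a fixed build stamp — determinism is an
asserted property, not an aspiration. A static SVG exporter covers figure
export.

## Numerical and boundary conventions

* All in-memory coordinates are 0-based half-open; SAM POS (1-based) and
  the CLI region syntax (`name:start-end`, 1-based inclusive) convert at
  the boundary.
* SAM stores minus-strand SEQ reverse-complemented (the SAM convention);
  the in-memory record always holds the basecalled sequence in sequencing
  direction.
* Region clipping drops ops outside the window (splitting BASE_DEL ops as
  needed) and keeps an insertion only when its preceding base is inside.
* `apply_shift` refuses shifts at or beyond the MATCH-op count; degenerate
  (constant) pore models are a hard error in `msb_position` since the
  statistic is undefined at zero total variance.
* Region queries scan linearly below 10k records and binary-search sorted
  starts above; both paths are property-tested against a full scan.

## Validation scale

The suite validates with fuzzed cases at fixed seeds: 1000 codec round
trips, 500 move tables, 500 CIGAR projections, and 100 simulated replicates
(500-base reference, 20× depth) for shift recovery, requiring ≥ 95/100
correct recoveries and correct zero-offsets on pre-shifted input. The
modification use case injects +8 pA at one site on half of 50× reads and
requires the group-mean difference to land within two standard errors.
These sizes keep the whole suite in a couple of minutes on one CPU while
leaving the estimators no room to be systematically wrong.

## Known limitations

* No binary container support (FAST5/POD5/BLOW5, BAM, CRAM): the signal
  container is a documented plain-text format behind a small reader
  interface, and SAM/PAF are plain text. Desk-scale by design.
* The offset search assumes one global shift per dataset; per-read or
  position-dependent offsets are out of scope.
* `inject_errors` models basecall errors phenomenologically, not a real
  basecaller's error process.
* The interactive viewer implements the named controls (pan/zoom,
  select/deselect, show signal points) and nothing more.
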