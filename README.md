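# sigpile

Signal-to-sequence alignment and pileup visualization for nanopore raw
current data, in R.

Nanopore sequencers record a time series of ionic current (a "squiggle") as
each DNA/RNA molecule translocates a pore. The signal carries more than the
base sequence — base modifications such as 5mC, secondary structure, and
other molecular features distort it — but inspecting it requires anchoring
every raw sample to the base it was measured over, either in the basecalled
read or in a reference genome. `sigpile` provides that anchoring and the
visualization on top of it:

* **ss codec** — a compact CIGAR-like encoding of signal-to-sequence
  alignments carried as SAM/PAF auxiliary tags (`ss:Z:`, `si:Z:`).
* **reform** — converts the basecaller move table (`mv:B:c`/`ts:i` tags)
  into a per-base signal-to-read alignment.
* **realign** — projects a signal-to-read alignment through the read's
  CIGAR into a signal-to-reference alignment, with insertion stacking,
  deletion gaps, soft-clip trimming and strand reversal.
* **shift correction** — finds the most significant base (MSB) of a k-mer
  pore model and the dataset-wide k-mer-to-base offset, and shifts all
  alignments so each base lines up with the signal event that actually
  reflects it.
* **pileup layout + renderer** — stacks and overlays many reads over a
  reference region in time-scale or molecule-scale and writes one
  self-contained interactive HTML browser view (pan/zoom, per-read
  select/deselect, "show signal points").
* **simulator** — a fully seeded pore-model signal simulator producing
  internally consistent fixtures (reference, signals, move tables,
  ground-truth alignments) for testing and simulated comparison tracks.

## The ss encoding

An alignment is an ordered list of three op kinds, written with three
glyphs:

| op | meaning | text |
|----|---------|------|
| MATCH of n samples | n samples aligned to exactly one base | `n,` |
| SIG_INS of n samples | n samples aligned to no base (e.g. inserted bases) | `nI` |
| BASE_DEL of m bases | m bases with no signal | `mD` |

So `8,5I4,2D6,` reads: 8 samples on one base, 5 inserted samples, 4 samples
on the next base, 2 deleted bases, 6 samples on the last base. Two
invariants make the encoding checkable: MATCH+SIG_INS sample counts equal
the signal span, and MATCH-op count plus BASE_DEL lengths equals the
sequence span. The companion tag `si:Z:sig_start,sig_end,seq_start,seq_end`
carries the 0-based half-open coordinates.

## K-mer-to-base shift correction

Event-style alignments anchor signal to k-mers, not bases: the samples
labelled with base *i* are governed mostly by one position of the k-mer
starting at *i* — the MSB, at offset *m* < *k*. For each candidate shift
*s*, `calculate_offset()` groups every MATCH op's mean current by the base
it would pair with after shifting by *s* and scores the grouping with a
one-way eta-squared (between-group variance / total variance, in [0, 1]).
The maximising shift is the dataset's offset; it is protocol-specific and
recorded with a protocol label so it is never silently reused.

## Worked example

```r
library(sigpile)

model <- generate_pore_model(k = 6, msb = 2)
msb_position(model)$scores
#> [1] 0.0010 0.0063 0.9852 0.0063 0.0010 0.0002
```

Position 2 explains 98.5% of the variance of the 4096 k-mer levels — the
designated MSB.

```r
bundle <- simulate_dataset(model, ref_len = 300, depth = 12, seed = 42)
id <- names(bundle$reads)[1]
s2r <- reform(bundle$move_tables[[id]], bundle$reads[[id]], bundle$signals[[id]])
s2r
#> ss_alignment read_001: sig [50,2824) -> read [0,300) strand - (forward)
#>   ss: 10,11,2,5,13,7,8,11,10,7,10,6,6,12,16,16,...
```

The move table put 10 samples on the first base, 11 on the second, and so
on; 50 adapter samples were trimmed. Projecting through the (here perfect)
CIGAR gives the reference-anchored alignment, and the dataset-wide offset
recovers the model's MSB:

```r
s2f <- realign(s2r, bundle$reads[[id]])
report <- calculate_offset(bundle$truth$sig2ref, bundle$signals,
                           bundle$reference, model)
report
#> offset_report (default): chosen shift 2 over 3600 MATCH ops
#>   shift 0: separation 0.0063
#>   shift 1: separation 0.0119
#>   shift 2: separation 0.9854  <- chosen
#>   shift 3: separation 0.0095
#>   ...
```

Shift-correct, lay out a region, and render the browser view:

```r
corrected <- lapply(bundle$truth$sig2ref, apply_shift, report$chosen_shift)
lay <- build_pileup(region("ref1", 100, 140), corrected, bundle$signals,
                    bundle$reference)
lay
#> pileup_layout ref1:[100,140): 4 tracks, width 800
#>   pileup_overlay (+): 6 members
#>   stacked_reads (+): 6 members
#>   pileup_overlay (-): 6 members
#>   stacked_reads (-): 6 members
render_html(lay, "view.html")
```

The same pipeline is available from the shell via the installed `sigpile`
script (`exec/sigpile`):

```sh
sigpile simulate --ref-len 300 --depth 12 --seed 42 --outdir fx
sigpile reform   --bam fx/reads.sam --signal fx/signal.tsv -o s2r.sam
sigpile realign  --sig2read s2r.sam -o s2f.sam
sigpile calculate-offsets --sam s2f.sam --signal fx/signal.tsv \
        --ref fx/ref.fa --model fx/model.tsv -o offsets.json
sigpile plot --region ref1:101-140 --sam s2f.sam --signal fx/signal.tsv \
        --ref fx/ref.fa --model fx/model.tsv -o view.html
```

`plot` auto-runs shift correction when a model is given; `--no-shift` or
`--shift N` override it.

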