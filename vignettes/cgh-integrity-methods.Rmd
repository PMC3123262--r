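---
title: "Methods: CNV calling and artifact triage for array CGH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV calling and artifact triage for array CGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghintegrity)
```

## The measurement model

Array comparative genomic hybridization (CGH) co-hybridizes fluorescently
labelled test and reference DNA onto a dense oligonucleotide array and
reports, per probe, the log2 ratio of test to reference intensity. Under a
diploid baseline a true single-copy gain shifts the local log2 ratio by
about +0.58 and a single-copy loss by about -1; in practice attenuation
(cell mixtures, hybridization kinetics) compresses these shifts, which is
why event calling thresholds sit near 0.5 rather than at the theoretical
values.

`cghintegrity` treats a hybridization as a probe-ordered signal

\[ y_i \;=\; \beta \;+\; w\,\big(g_i - \bar g\big) \;+\; \sum_k \delta_k\,
   \mathbf 1[\text{probe } i \in \text{CNV}_k] \;+\; \varepsilon_i , \]

where \(\beta\) is a global dye-bias offset (Cy3 vs Cy5), \(g_i\) is the
local GC fraction around probe \(i\), \(\bar g\) the genome average,
\(w\) the "genomic wave" coupling of baseline to GC content, \(\delta_k\)
the log2 shift of a true copy-number variant, and \(\varepsilon_i\)
independent Gaussian noise. The package's generator
(`simulate_hybridization()`) simulates exactly this model; the analysis
stages try to undo it term by term: `median_center()` removes \(\beta\),
`gc_wave_correct()` can remove the \(w\) term, segmentation plus calling
estimates the \(\delta_k\), and the cohort/GC stages flag calls that look
like residual \(w\) artifacts.

A self-self hybridization (test DNA = reference DNA) has all
\(\delta_k = 0\) by construction, so *every* event called on it is a false
positive. That makes self tracks a null calibration set for the calling
criterion, and it is the core design idea the package reproduces.

## Segmentation

`segment_track()` fits a piecewise-constant mean to each chromosome by
penalized least squares: minimize within-segment squared error plus a
penalty \(\lambda\) per change point. The search is a recursive *interval
carve*: within each current segment the best candidate sub-interval is
located by scanning a geometric ladder of window widths (1, 2, 4, ...)
for the largest standardized mean deviation, candidate boundaries are then
refined by exact coordinate-wise search, and the carve is accepted only if
its exact SSE reduction exceeds \(\lambda\) per new change point. Accepted
carves split the segment into at most three parts, which are searched
recursively.

Two properties motivated this design over classic single-split binary
segmentation:

* a short CNV (say 10 probes) embedded in a long chromosome (hundreds of
  thousands of probes) has a vanishing single-split SSE gain — the
  statistic is diluted by the flanking probes — whereas its interval-carve
  gain is \(k\,\delta^2\) regardless of chromosome length;
* the procedure is deterministic: no random intervals, ties broken toward
  fewer segments and then the leftmost boundary, so identical inputs give
  identical segmentations.

The default penalty is \(\lambda = z^2\hat\sigma^2/2\) with \(z = 4.5\)
and \(\hat\sigma = \mathrm{mad}(\Delta y)/\sqrt 2\), a robust
difference-based noise estimate that ignores CNVs. This controls spurious
carves at roughly the 4.5-sigma level across the multiscale scan of a
whole genome; on noise-free input \(\hat\sigma = 0\), the penalty
vanishes, and segmentation is exact. The penalty is exposed as an argument
because the artifact analyses deliberately run it far looser (see below).

On a masked (missing) probe the track is split: masked stretches form
their own `NA` segments, runs are never fused across them, and a
qualifying run must contain the minimum probe count of *observed* probes.

## Event calling and the criterion

`call_events()` applies a `cgh_criterion(min_abs_shift, min_probes)` to
segment means: qualifying segments have \(|\bar y| \ge\) `min_abs_shift`
over at least `min_probes` probes; adjacent qualifying segments of the
same sign are fused (pooled mean). Event intervals run from the first to
the last probe of the qualifying run, without extension into flanking
probe gaps — conservative and reproducible. Gain/loss is the sign of the
event mean.

The package default, 0.5 log2 units over 5 probes, is not arbitrary: it is
what `select_criterion()` picks when `calibration_sweep()` is run over
self-self tracks simulated at the package's default noise (sd 0.2) on a
dense (1.2 kb pitch) design. The sweep counts false-positive events per
criterion cell; counts are necessarily non-increasing in both thresholds
(asserted after every sweep — event fusion could in contrived cases break
this, so the assertion is a real check, not decoration). Selection takes
the least-stringent cell — smallest shift, then smallest probe count —
whose false-positive total fits a budget, falling back to the grid
minimum. Preferring the least-stringent qualifying cell keeps the
criterion at the resolution limit instead of the most conservative corner.

Two quantities deserve explicit definitions:

* *Resolution*: `resolution()` returns `(min_probes - 1) * mean_spacing`,
  the minimum genomic span that `min_probes` consecutive probes cover at
  the array's average pitch — 4.8 kb for (0.5, 5) at 1.2 kb.
* *False-positive budget*: self tracks carry no true events, so a false
  discovery *rate* is undefined on them; the sweep reports counts. In the
  packaged calibration experiments the budget is 0.05 false calls per
  null hybridization — effectively "minimal false positives" — and
  `fdr_proxy()` offers mean-self over mean-comparative counts as a rough
  cohort-level FDR stand-in.

The calibration experiment in the test suite and acceptance script uses
100 null hybridizations of ~600,000 probes each (three 240 Mb chromosomes
at 1.2 kb pitch, sizes-only, no sequence needed since the wave term is
off). That scale was chosen by a power calculation, not tuned afterwards:
with iid Gaussian noise the expected false-call count drops roughly
thirty-fold per additional required probe at a 0.5 threshold, so ~6x10^7
pooled probes is the scale at which cells more lenient than (0.5, 5)
reliably overshoot the budget while (0.5, 5) reliably meets it. At desk
scale (thousands of probes) the whole grid is zero and the selection is
uninformative.

## Cross-hybridization triage

True, independent copy-number differences should not recur at the same
locus across unrelated comparisons. `classify_shared()` flags an event as
*shared* when it overlaps an event from a different hybridization —
deliberately ignoring sign, because a recurrent artifact locus can surface
as a gain in one comparison and a loss in another depending on which
channel the wave perturbs; sign agreement is reported separately as
`same_type`. "Nearby" defaults to at least one shared base (`max_gap = 0`);
a gap tolerance is exposed but was not needed to reproduce the packaged
event table's shared column. `unique_loci()` merges the pooled events into
maximal disjoint loci with member lists; `size_filter()` implements the
strict "larger than 10 kb" size class; `summarize_cohort()` and
`summarize_counts()` produce the per-hybridization and per-role summaries.

## GC artifact analysis

`windowed_gc()` computes browser-style tiling GC tracks (default 5 bp
windows); `region_vs_genome()` scores each event's sequence GC against the
genome average computed from the supplied FASTA — never a hard-coded
constant — and reports the per-event excess and the count of events above
average. The packaged mechanistic check is: with a positive wave
coefficient, self-track calls concentrate on GC-rich sequence (positive
excess in at least 90% of them), while wave-free null calls, provoked by
running the caller with a deliberately loose penalty and criterion, show
mean excess near zero (within ±0.02). That is the level at which
"recurrent calls sit in high-GC regions because of genomic waves" is
testable on synthetic data.

`gc_wave_correct()` (local linear regression of signal on probe GC, one
robust reweighting pass, span 0.4) is provided but **off by default**: the
reference analysis style flags GC-driven calls post hoc rather than
pre-correcting the signal, and keeping the default faithful lets users
quantify how much of the shared-call artifact a correction would remove.

## The synthetic genome and what it does not emulate

`make_genome()` draws each base independently from a position-dependent GC
propensity: an AT-richer baseline plus Gaussian GC-rich bumps (default one
per 200 kb, height 0.25, width 4 kb), renormalized so the expected
genome-wide GC equals the target (default 0.417, the documented cattle
genome average; 0.535 is a useful high-GC scenario). The bump landscape
mirrors the isolated GC peaks that sit near probes at recurrent artifact
loci, and makes wave-driven false calls *gains at GC-rich sites* — the
directionality the artifact analysis expects. Local probe GC is computed
over a 500 bp window centered on the probe, since neighborhood GC rather
than probe-sequence GC drives hybridization artifacts.

Defaults are desk-scale: 5 chromosomes x 2 Mb, ~8,300 probes at 1.2 kb
pitch; the full ~2.1-million-probe, 1.2 kb design the package models is
reachable by passing larger sizes (the calibration experiments use
~600,000-probe layouts). Deliberately *not* modelled: two-channel raw
intensities and their normalization, on-chip spatial effects, repeats and
segmental duplications, probe-specific affinity, correlated (AR) noise,
and dye-swap replicate designs. Passing tests on this generator therefore
demonstrates correctness of the calling/triage machinery under the stated
model, not performance on real arrays.

All randomness flows from explicit integer seeds through an isolated RNG
stream, so simulations are reproducible and never disturb the caller's
random state; seeds are recorded in track metadata and in the
`write_config_snapshot()` YAML that pipeline runs emit.

## Interval conventions and remapping

Coordinates are 0-based half-open throughout (BED convention), so an
event's printed `Length` equals `End - Start`; published tables are
ingested as printed, with comma thousand-separators stripped, and no
1-based shift is applied — the length identity, which holds on every
packaged row, fixes the span convention but not the absolute offset, and
guessing a shift would falsify the printed coordinates. Overlap is strict
(abutting intervals do not overlap); merging fuses abutting intervals
(their union is contiguous).

`read_chain()`/`remap_interval()` implement a minimal assembly-migration
tool over block-structured chain alignments: an interval maps through the
best-scoring chain aligning at least `min_match` (default 0.95) of its
bases, negative-strand targets are flipped to plus-strand coordinates, and
failures are reported as `unmapped` (no chain), `deleted_in_target`
(covered by a chain but mostly in gaps) or `split` (partial coverage over
several chains). Multi-chain stitching and sub-interval mapping of split
intervals are out of scope. `invert_chain()` exists chiefly so tests can
assert exact round-trips.

## Known limitations

* Segmentation is greedy (recursive carving), not globally optimal; it is
  deterministic and exact on noise-free input, but no optimality claim is
  made for noisy input, and no bit-compatibility with any vendor
  segmentation tool is intended.
* Event fusion can, in adversarial segmentations, make event counts
  non-monotone in the criterion; the sweep asserts monotonicity rather
  than assuming it.
* The generator's independence assumptions (per-base, per-probe) make
  synthetic noise better behaved than real array noise; calibration
  results transfer to real data only to the extent the noise model does.
* `gc_wave_correct()` assumes a smooth monotone signal-GC relationship;
  waves driven by features other than GC are untouched.
* Balanced events (inversions, translocations) and events below the probe
  pitch are invisible to array CGH and hence to this package.
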