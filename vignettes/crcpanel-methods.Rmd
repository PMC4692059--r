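---
title: "Methods behind crcpanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind crcpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crcpanel` implements the analysis chain used to characterise a panel of
colorectal cancer cell lines on several molecular levels and to integrate
them into a list of candidate predictive biomarkers.  This vignette is the
package's account of the underlying models, the tunable parameters, the
synthetic data the tests rely on, and the places where a design decision
had to be made.

## Dose-response and sensitivity

Cell viability is expressed as a percentage of untreated control wells:
`100 × mean(treated RFU) / mean(control RFU)`, with the replicate-well SD
carried onto the same scale.  The dose-response model is the
four-parameter logistic (4PL)

$$v(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
        {1 + (c/\mathrm{IC_{50}})^{h}},$$

fitted by least squares on log10 concentration.  Parameters and bounds:
`top` ∈ [80, 120] %, `bottom` ∈ [0, 40] %, `hill` > 0 — the bounds encode
the assumptions that untreated viability is near 100 % and that full
curves approach a low plateau.  Start values come from the data (extreme
observed viabilities; linear interpolation of the 50 % crossing).  The
optimiser is Levenberg–Marquardt followed by a bounded quasi-Newton
(L-BFGS-B) polish; both are run because L-M alone can stop on a singular
gradient at near-perfect fits, and a coarse grid over
(log IC50, hill, top, bottom) rescues the rare pathological curve (it is
only consulted when the local fits leave an RMSE above five viability
points).

The **reported IC50 is the fitted 50 %-of-control crossing**, not the 4PL
midpoint; the two coincide when `top = 100`, `bottom = 0`.  No
extrapolation is performed: when the crossing lies above the top tested
dose, or the fitted curve never reaches 50 % in range (`top` and `bottom`
both above 50), the IC50 is reported *censored at the maximum tested
concentration*.  Censored values enter downstream analyses (profile
clustering, genotype comparisons) imputed at that maximum, mirroring
">100 µM"-style reporting.

Sensitivity calls are pure threshold functions per drug; the defaults are
IC50 ≤ 30 µM (5-FU), ≤ 10 µM (oxaliplatin) and < 80 nM (BEZ235) — note
the deliberate mix of inclusive and strict comparisons, which the
boundary tests pin down.  Censored curves are never called sensitive.

An optional studentised-residual outlier exclusion (|t| > 3, refit) is
available but **off by default**: the upstream description of outlier
handling in commercial fitters is ambiguous, so the package does nothing
silently.

The default concentration grid uses eight log-spaced points from 2.5 to
100 µM for the cytotoxics (the wider of the two printed ranges; the grid
is configurable, the narrower 5–100 µM reading is not guessed at) and
2.5–80 nM for BEZ235, with six replicate wells per concentration.

## Copy-number segmentation and recurrence

Marker-level log2 ratios are assumed already ratio-scale (tumour versus
reference).  True intensity-level loess normalisation needs the raw
two-channel intensities, which ratio-level inputs do not carry; the
default stand-in subtracts the per-sample global median, and a
lowess-versus-mean-intensity mode is available when an intensity column
exists.

Segmentation is CBS-style recursive binary splitting.  Within an
interval, the candidate breakpoint maximises the pooled two-sample t
statistic over all admissible cuts; a split is accepted only if

1. its permutation p-value (marker shuffles within the interval, default
   1000, with early exit once rejection is certain) is ≤ `alpha`
   (default 0.001),
2. both children have at least `min_markers` (default 10) markers, and
3. the children's mean difference is at least `snr` (default 0.03) times
   the robust marker noise SD.

The three defaults are the segmentation settings reported for the
original analysis, mapped onto this algorithm's knobs: minimum genomic
markers → minimum child size, p-value → split acceptance level,
signal-to-noise → standardised mean-difference floor.  The proprietary
"Genomic Segmentation" implementation is not public, so this mapping is
an interpretation, not a re-implementation.  Noise is estimated robustly
as `mad(diff(x))/√2` from lag-1 marker differences so genuine steps do
not inflate it.  After recursion, adjacent segments violating the snr
floor are merged.  A single-cut statistic has limited power for short
interior segments flanked by long neutral stretches (the classic argument
for the circular statistic); at the panel's noise level this only affects
low-amplitude events near the detection limit, and the synthetic defaults
place the dosage-bearing amplicons well above it.

Segments tile each chromosome's marker span; boundaries between adjacent
segments fall midway between the flanking markers, so gene-level lookups
always find full coverage.  Internally intervals are manipulated
half-open, but **every file and reported table is 1-based inclusive**.

Calls use strict inequalities — gain above 0.15, loss below −0.3 — and an
inclusive high-level amplification flag at ≥ 1.0 (which implies gain).
Recurrent regions are maximal runs, over the union of all samples'
breakpoints, of elementary intervals altered in at least `min_support`
samples (default 7, the at-least-7-of-15 rule).  The supporting-sample
set is the intersection over the whole run — the stricter reading, under
which a listed line is altered across the entire region.  The finder is
property-tested against a per-base brute-force counter.

Sample-level clustering of segment profiles resamples each sample's
segment means onto the breakpoint-union grid (one coordinate per
elementary interval, unweighted) and agglomerates with Euclidean
distance/average linkage; IC50 profiles use 1 − Pearson r with complete
linkage; protein profiles use centred correlation with average linkage.
Items are sorted by id before clustering so ties resolve
deterministically.

## Expression and protein matrices

Quantile normalisation (via limma, ties averaged), detection-p filtering
(keep a probe detected at p ≤ 0.05 in **at least one** sample — the
all-samples variant is a switch; the permissive default was chosen
because nothing in the source states the stricter rule), log2 transform
and per-feature mean centring.

SAM-style differential expression uses the moderated statistic
`d = (m₁ − m₂)/(s + s₀)` with `s` the pooled standard error and the fudge
factor `s₀` set to the **median of `s` over features** — the simplest
published choice; the percentile-optimising variant is out of scope.
The null distribution of |d| comes from permuted class labels with `s₀`
held at its observed value; when at most 500 distinct label assignments
exist they are enumerated exhaustively, making p and q exact (with 15
samples this is always the case).  q-values are expected-false-positive
counts over observed-positive counts at each |d|, made monotone along the
|d| ranking from the bottom up (shrinking, never inflating).  Reported
features must additionally pass a 1.5 linear fold-change gate, the floor
implied by the supplementary gene lists.

Mann-Whitney U tests are exact (full enumeration, via `wilcox.test`) when
both groups have ≤ 8 untied observations, and use the tie-corrected
normal approximation with continuity correction otherwise; the
continuity-corrected form agrees with the exact test to within 0.02 at
the panel's 7-versus-8 group sizes, which the suite verifies by
simulation.  Treatment-association p-values are deliberately
**unadjusted** (matching per-gene reporting practice); an FDR mode exists
behind a flag.

RPPA triplicate spots are collapsed by the median (robust to one aberrant
spot), log2-transformed and mean-centred per antibody; pairs with fewer
than two usable spots are flagged low-confidence rather than dropped.

## The integration ledger

The stepwise chain is: genes overlapping recurrent gains (any-overlap,
≥ 1 bp) → per-gene copy number as the overlap-length-weighted mean of
overlapping segment means → Pearson correlation between gene copy number
and expression with two-sided t-transform p-values and Bonferroni
adjustment over the **family of genes actually tested** (recorded in the
output) → "passes" requires adjusted p ≤ 0.05 **and r > 0**, the
amplified-and-over-expressed direction (the sign gate is this package's
operationalisation of "significantly correlated over-expressed"; the
source never states it explicitly) → per-drug Mann-Whitney association of
the passing genes with sensitivity classes → exact set algebra (union,
pairwise and three-way intersections, alphabetically ordered).

`build_ledger()` enforces that each per-drug list is a subset of the
correlated set and accepts an alias map for printed synonyms; the
packaged fixtures carry one such pair (CASC8 printed in a drug list,
LOC727677 in the correlated-gene column — the same locus under two
symbols).

Hotspot substitution calls translate the affected codon before and after
a single-base change against a reference CDS (the packaged fixture
stores the first 30 codons of the KRAS CDS, enough to cover codons 12 and
13); a reference-base mismatch is an error, which guards the fixture
transcription itself.  The published variant coordinates use an
undisclosed reference numbering, so the fixtures store the equivalent CDS
positions (c.34, c.35, c.38), which the codon table verifies directly.

## FISH and the protein network

A core's score is the ratio of summed red to summed green signals over at
most `max_nuclei` (20) nuclei, taken in input order because no selection
rule is stated for over-scored cores; cores with fewer than `min_nuclei`
(10) scorable nuclei, or zero green signal, are not evaluable.
Amplification is **inclusive** at 1.8 ("less than 1.8 is negative"
implies the boundary is positive).  Cohort summaries use
linear-interpolation quantiles.  Probe-pair correlation defaults to
Spearman (the method attached to the figure carrying the published
result; Pearson is a switch), exact for n ≤ 9.  The protein network
correlates all marker pairs (pairwise-complete), Bonferroni-corrects over
the number of pairs tested, and keeps edges at adjusted p ≤ 0.05.

## The synthetic panel: what it emulates, and what it does not

`panel_spec()` defaults describe a 15-line panel:

- six chromosomes of 400 markers at 100 kb spacing (a desk-scale stand-in
  for a 135k-marker tiling array; the real array's geometry is not
  emulated);
- planted copy-number segments with marker noise SD 0.2: two recurrent
  gains at log2 level 1.2 carried by 8 and 7 lines (amplicon-like levels,
  within the 0.2–4.2 range seen for real recurrent gains, and high
  enough that a unit-slope dosage effect is detectable through a
  Bonferroni screen over ~500 genes — planting effects at the detection
  floor would make every downstream property a coin flip), one recurrent
  loss at −0.5, one weak 0.4 gain near the single-cut detection limit,
  and one focal 1.5 high-level amplification in three lines;
- twenty dosage genes with slope 1 and expression noise SD 0.3 inside the
  two strong gains, plus 500 null genes with zero slope placed at random;
  the first gain's carriers coincide with the 5-FU-sensitive class, so
  its dosage genes are both copy-number-driven and response-associated —
  the configuration the end-to-end ledger property needs;
- true IC50s spanning the sensitive and resistant ranges per drug
  (5-FU 3.1 to > 100 µM with two censored lines, oxaliplatin 3–31.1 µM,
  BEZ235 13.4 nM to censored-above-80 for eight lines), 4PL shape
  top = 100, bottom = 0, hill = 1, well CV 5 %, six replicate wells;
- a 118-core FISH cohort at 15 % planted amplification prevalence, 20
  nuclei per core, Poisson counts; amplified cores are planted at ratio
  3 (red mean 6, green mean 2) — clearly above the 1.8 cutoff, so the
  cohort prevalence estimate is limited by sampling noise rather than by
  borderline misclassification;
- 31 antibodies × 15 samples spotted in triplicate with log-normal spot
  noise.

Every generator draws from an independent substream derived from the one
spec seed (keyed by module name), so regenerating any layer is
bit-reproducible and adding a generator never perturbs another's output.
The truth set (realised segments, per-gene dosage slopes and copy-number
values, true IC50s, true FISH ratios) serialises to JSON and round-trips
unchanged.

What the generator does **not** emulate: bead-level array artefacts,
two-channel intensity bias (hence the loess stand-in), probe
cross-hybridisation, cell-line heterogeneity, plate spatial effects, and
image-level FISH/AQUA artefacts.  Passing tests therefore demonstrate
that the algorithms recover planted structure under honest noise of the
stated magnitude — not that they would be robust to every artefact of
the real platforms.

## Numerical choices and degenerate inputs

- 4PL optimiser tolerances: L-BFGS-B `factr 1e3`; exact curves are
  recovered to ~1e-6 relative on the IC50.
- Zero pooled variance in a t statistic: identical children give t = 0
  (no split), a clean step gives an infinite statistic (always split,
  subject to the permutation test).
- Constant features: Mann-Whitney returns U at its null mean with p = 1;
  SAM returns d = 0 and an empty result on a fully constant matrix;
  correlation records with zero variance get missing r and never pass.
- Zero-variance profiles are dropped with a warning before
  correlation-distance clustering.
- Bonferroni adjustments are capped at 1; q-value monotonisation only
  shrinks.
- Fixture files are checksum-verified (MD5) at load, so silent edits to
  the transcriptions fail loudly.

## Problem sizes

The test suite and the acceptance script run the panel at the default
sizes above: 45 dose-response curves per pipeline run, 200 curves for the
IC50 recovery property, 2,400 markers × 15 samples per segmentation run,
50 random instances for the recurrence oracle, 50 seeded simulations for
SAM sensitivity, 20 panel seeds for the integration recovery property,
and 500 cores for the FISH coverage check.  These sizes were chosen so
each property is estimated with useful precision by a few minutes of
computation on one core.

## Known limitations

- Binary (non-circular) splitting has reduced power for short interior
  segments; very low-amplitude events (≈ 0.4 log2 over tens of markers)
  are detected in some samples and missed in others at α = 0.001.
- The per-gene copy number is an overlap-weighted segment mean; it does
  not model intra-gene breakpoints separately.
- The SAM fudge factor is the median-`s` choice; results can differ from
  percentile-optimised implementations on matrices with strong
  variance-mean trends.
- Probe-to-gene collapsing is "first annotated probe wins"; no
  alternative collapse rules are provided.
- No ploidy estimation, allele-specific copy number, or sex chromosomes;
  no pathway enrichment; no survival analysis.
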