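---
title: "Designing allele-selective antisense oligonucleotides from differential RNA accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing allele-selective antisense oligonucleotides from differential RNA accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Dominant mutations that trigger in-frame exon skipping produce a mutant
mRNA that differs from the wild-type transcript only by a missing exon.
Silencing the mutant allele with a gapmer antisense oligonucleotide (ASO)
— a central phosphorothioate-DNA "gap" that recruits RNase H, flanked by
modified-ribonucleotide wings — is attractive because the novel exon–exon
junction is a mutant-specific sequence. In practice the two alleles are
so similar that classical gapmers silence both. `asodesign` implements a
design strategy that recovers selectivity from two additional signals:

1. **Differential secondary-structure accessibility.** Positions that are
   single-stranded (accessible) in the mutant transcript but sequestered
   in the wild type receive high-affinity RNA chemistry in the ASO,
   converting the gapmer into a *mixmer* whose binding is biased toward
   the mutant allele.
2. **A deliberate single-nucleotide mismatch** at a position accessible
   in both alleles, which trims binding affinity across the board but —
   because the mutant duplex operates far above its dissociation constant
   while the wild-type duplex does not — de-represses the wild type far
   more than the mutant.

The package covers the full path: transcript modelling, structure-ensemble
prediction or import, ss-count accessibility profiling, differential
mapping, gapmer enumeration, mixmer conversion, mismatch scanning,
physicochemical annotation, and the dose-response analytics (2^-ddCt,
four-parameter-logistic IC50, selectivity indices) used to rank designs.

## Transcript model

Exons are concatenated into a wild-type transcript; skipping an internal
exon yields the mutant and its novel junction. Coordinates are 0-based
and half-open throughout, and junctions are inter-residue offsets — the
boundary between positions `j-1` and `j`. A total, strictly increasing
coordinate map (identity left of the junction, shifted by the skipped
length right of it) reconciles mutant and wild-type positions.

Analysis windows are cut per allele with the junction centred at
`floor(L/2)` (the tie-break for odd lengths is ours; nothing forces the
other rounding). Windows near a transcript end truncate with a flag
rather than erroring, because centred windows presume long transcripts.
The default length set is 200, 500, 1000, 1500, 2000 and 2500 nt.

## Structure ensembles and the ss-count

The *ss-count* of a position is the number of structures in an ensemble
in which it is unpaired; dividing by the ensemble size gives
`ss_fraction`, the comparison currency across ensembles of different
sizes. The package computes ensembles with a deliberately transparent
baseline energy model and also imports externally computed ensembles
(CT/connect or dot-bracket files), so any folding engine can be
substituted.

The baseline model scores base pairs GC = −3, AU = −2, GU = −1 (score
units), forbids pseudoknots and hairpin loops under 3 nt, and:

* **exhaustive mode** (≤ 25 nt): enumerates *every* valid nested
  structure within ε = 2 units of the optimum, via band-limited
  traceback of the minimum-energy dynamic program. A brute-force
  recursive enumerator in the test suite independently reproduces the
  structure sets on randomized sequences up to 15 nt.
* **sampled mode** (longer sequences): draws `n_samples = 30` seeded
  Boltzmann-weighted samples (temperature kT = 1 unit) from the nested
  partition function and prepends the optimum if it was not drawn. The
  30-structure default matches the ensemble scale at which ss-counts are
  conventionally read. The seed is recorded in the ensemble object.

The ss-count logic, not folding physics, is the point: the model captures
"a helix sequesters these positions" without nearest-neighbor loop
thermodynamics. Thermodynamic engines can be plugged in through
`import_ensemble()`.

Accessibility classes are symmetric tertiles of `ss_fraction`: open at
≥ 2/3, closed at ≤ 1/3, semi-open between. No principled thresholds are
published for the three-color (green/yellow/red) heatmap semantics;
tertiles reproduce them and are configurable. The heatmap export
reconciles several window lengths by majority class, with ties resolved
to semi-open — a conservative construction, since nothing specifies how
profiles from different window lengths were combined.

The **differential map** reports, in mutant coordinates, positions open
or semi-open in the mutant whose wild-type image (through the exon
coordinate map) is closed — the mixmer RNA placement set — and positions
open in both alleles — the mismatch candidate set. Because the mutant
allele is a pure deletion, every mutant position has a wild-type image;
alignment of the two (differently centred) windows is done through the
coordinate map rather than by sequence alignment.

## The oligonucleotide model

Designs are per-residue (base, sugar, backbone) lists. The bracket
notation — `[..]` 2′-OMe, `<..>` 2′-MOE, `{..}` LNA, `*`-starred bases
PS-DNA — parses to and serializes from this representation losslessly.
The star is treated as a sugar marker: wing backbones are unstated in the
notation, and all residues default to phosphorothioate, the standard for
therapeutic gapmers (configurable). DNA residues are written T,
2′-OMe/2′-MOE residues U; LNA may carry either.

Category is inferred from the run pattern: one internal DNA run flanked
by non-DNA is a gapmer, two or more DNA runs a mixmer; declared mismatch
positions make a mismatch-mixmer. The packaged 28-design reference table
carries its published category separately, because one interleaved-LNA
entry is published as a gapmer yet has four DNA runs, and three rows have
printed length/gap values that disagree with their printed sequences —
the loader flags these conflicts rather than correcting them.

Melting temperature is a model-based analogue (nearest-neighbor two-state
Tm with salt correction, Wallace rule under 8 nt) plus additive
per-residue increments for modified sugars (LNA +3.0, 2′-MOE +1.0,
2′-OMe +0.7 °C). Published Tm columns come from external calculators with
undisclosed settings, so the package asserts only orderings and
monotonicity properties, never equality. Off-target scanning is ungapped
Hamming-distance search (≤ 2 substitutions, T/U-equivalent) of the
design's reverse complement against a transcript set, with the intended
site excluded.

## Design engine

`enumerate_gapmers()` walks the constraint box (defaults: lengths 13–23,
gaps 7–11, wings 3–7) and keeps every placement whose DNA gap straddles
the junction with at least one gap base on each side; candidates are the
exact reverse complements of their mutant footprints, in deterministic
(length, gap, offset) order.

`place_mixmer_chemistry()` recolors the design from the differential map:
RNA opposite mutant-open/wild-type-closed positions, PS-DNA elsewhere.
Singleton RNA assignments extend to blocks of ≥ 2 toward the neighbor
with the larger accessibility margin (mutant-minus-wild-type
ss-fraction), echoing the 3-nt block rhythm of published mixmers; if no
DNA run of ≥ 4 survives — the minimum for RNase-H competence — RNA
assignments are revoked most-3′-first until one does. The assignment is a
pure function of the differential map, so the operation is idempotent.

`generate_mismatch_variants()` swaps one base at a time for its
Watson–Crick complement at ASO positions opposite open-in-both sites
within a named exon. The complement swap generalizes the three distinct
substitutions observable in the packaged mismatch designs and guarantees
a non-pairing apposition on either allele; a substitution matrix hook
allows other choices.

### Binding annotation and predicted selectivity

`annotate_affinity()` scores each allele as
`dG_total = dG_hybrid + dG_open`: the hybrid term sums pair scores plus a
per-residue chemistry bonus (2′-OMe −0.5, 2′-MOE −1.0, LNA −1.5 units)
over complementary appositions, with +1 per mismatch; the opening term
charges each paired position `|score| × w × (1 − ss_fraction)` of its
target, so demanding affinity from a structured region costs
proportionally (with w = 1 this is exactly an availability-weighted
duplex score). It is always non-negative. The wild-type alignment is the
best ungapped offset over the profiled window — for a junction-spanning
design one half necessarily mismatches; modelling the skipped exon as a
bulge loop (gapped alignment) is out of scope. `discrimination =
dG_total_wt − dG_total_mut` is positive when the mutant is favored.

Raw score differences do not capture what a mismatch does, however. In
the packaged reference table the mismatch variants have *smaller*
mutant-vs-wild-type affinity gaps than their parent mixmer, yet the
corresponding measured IC50 ratios improve several-fold. The resolution
is saturation: at a working dose `c`, fractional engagement is
`c / (c + Kd)`, so `predict_selectivity()` maps scores to dissociation
constants (`Kd = exp((dG_total − dG_ref)/kT)`, defaults `dG_ref = −25`,
`kT = 2` units, dose 100 nM) and reports the engagement ratio
`(c + Kd_wt)/(c + Kd_mut)`. A symmetric affinity loss then provably
*raises* the ratio whenever `Kd_wt > Kd_mut` — the mechanism by which a
mismatch improves functional selectivity while lowering both affinities.
The calibration constants set the score-to-nanomolar scale of the
synthetic exercises; the gapmer < mixmer < mismatch-mixmer ordering is
insensitive to them. Ranking sorts by clean off-target status,
discrimination, then mutant affinity, with a stable name tie-break.

## Assay analytics

* `ddct_fold_change()` is the standard 2^-ddCt quantification against a
  reference gene and untreated control.
* `screen_selective()` passes a design when residual mutant expression is
  at most `1 − threshold` of residual wild-type expression (default
  threshold 0.75, i.e. mutant suppressed by more than 75% relative to
  wild type).
* `fit_dose_response()` fits a 4PL on log10 dose by bounded
  Levenberg–Marquardt (`minpack.lm`), replicates averaged per dose first
  (per-point fitting is a switch). Bounds — top ∈ [0.5, 1.5], bottom ∈
  [−0.2, 0.5], hill ∈ [0.2, 5] — and extremes-based initialization are
  our choices; no fitting software or constraints are published for the
  reference curves. Amplitude collapse (top − bottom < 0.1) or
  non-convergence yields a flagged result, never a silent failure.
* `selectivity_report()` is the wild-type/mutant IC50 quotient. The
  reported-IC50 fixture reproduces the headline quotients: 261/8 ≈ 32.6,
  261/25.5 ≈ 10.2 and 261/83 ≈ 3.1. (The prose figure of "around 8-fold"
  that accompanies the 83/7 pair is inconsistent with its own quotient of
  11.9; the package computes quotients and does not special-case prose.)

## Synthetic data: what it emulates and what it does not

`generate_synthetic_locus()` builds a three-exon construct whose middle
(skippable, 54-nt by default, hence in-frame) exon carries the reverse
complement of an *occlusion span* in the upstream exon: the wild type
folds that span into a helix (closed), the exon-skipped mutant leaves it
single-stranded (open). The background is deliberately pairing-inert
(adenines; the occlusion span is G-only with a C-only partner and a 3-nt
spacer satisfying the minimum loop), so under the baseline model the
engineered helix is the *only* possible structure and the intended
differential positions are known exactly — a positive-control construct,
not a realistic transcript. Consequences worth being explicit about:
passing the ground-truth recovery test shows the pipeline's coordinate
logic and classification are correct, not that the baseline energy model
predicts real COL6A3 structure. Real transcripts have competing helices,
wobble-rich context and comparable accessibility in both alleles over
most positions; for those, import thermodynamic ensembles and expect the
differential map to be sparse and threshold-sensitive. The real
transcript is deliberately not bundled; a FASTA loader accepts it for
anyone rerunning the original windows.

An oracle-mode locus (8 + 8 + 6 nt, 5-nt occlusion) is used wherever
exhaustive folding must certify the whole front half of the pipeline.

`generate_dose_response()` draws seeded 4PL curves plus Gaussian noise on
a dose grid defaulting to the working concentrations 10–100 nM. The
estimator-characterization protocol used by the tests and the acceptance
script is a 24-concentration quarter-log ladder spanning ±2 decades
around the true IC50, 3 replicates, 5% noise: dense enough that the
four-parameter fit resolves the inflection. Under that protocol 100
seeded fits at IC50 = 7 nM show |bias| < 5% and ≥ 95% of estimates within
15% of truth. On the sparse 5-point default grid the same estimator is
unbiased but roughly twice as variable — a fact about assay design, not
about the fitter.

## Known limitations

* The baseline folding model has no loop entropies, dangles or
  coaxial stacking; its ensembles are calibration objects. Pseudoknots
  and chemical-probing restraints are out of scope.
* Binding annotation is a transparent analogue of
  accessibility-corrected hybridization, not a reproduction of any
  specific thermodynamic server's decomposition; only sign patterns and
  orderings are asserted against published values.
* Off-target search is substitution-only (no gaps) over supplied
  transcripts.
* Predicted selectivity depends on the score-to-Kd calibration for its
  absolute scale; use it to order candidate designs, not to forecast
  cellular IC50s.
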