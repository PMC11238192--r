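# asodesign

Design toolkit for **allele-selective antisense oligonucleotides (ASOs)**
against transcripts carrying an in-frame exon-skipping mutation. The
mutant mRNA differs from wild type only by a missing exon, so a gapmer
ASO aimed at the novel exon–exon junction tends to silence both alleles.
`asodesign` implements the design strategy that restores selectivity:

1. model the wild-type / exon-skipped transcript pair and its novel
   junction;
2. compute (or import) secondary-structure ensembles per allele and
   summarize them as per-nucleotide **ss-counts** — the number of
   structures in which a position is single-stranded;
3. map **differential accessibility**: positions open in the mutant but
   closed in the wild type;
4. enumerate junction-straddling **gapmers** (PS-DNA gap, modified-RNA
   wings), convert them to **mixmers** by placing RNA chemistry opposite
   the differential positions, and scan **single-mismatch variants** at
   positions open in both alleles;
5. annotate every design (GC%, model Tm, DNA-run architecture /
   RNase-H competence, off-target hits, accessibility-corrected binding
   scores per allele) and rank;
6. analyze the supporting assays: 2^-ddCt expression fold changes, the
   75%-relative-suppression screen, four-parameter-logistic (4PL) IC50
   fits and wild-type/mutant selectivity indices.

At the core is the per-allele binding score
`dG_total = dG_hybrid + dG_open`, with `dG_open = Σ |s_i| · w · (1 −
ss_fraction_i)` charging affinity demanded from structured positions, and
the saturation-aware selectivity `(c + Kd_wt)/(c + Kd_mut)` with
`Kd = exp((dG_total − dG_ref)/kT)` — which explains why a deliberate
mismatch that weakens binding to *both* alleles still improves
discrimination: the mutant duplex operates far above its Kd, the
wild-type one does not.

A packaged 28-design reference table (gapmers, mixmers and
mismatch-mixmers in bracket/asterisk notation, with published length /
gap / GC% / Tm / off-target / per-allele binding-affinity columns) and
seeded synthetic generators make every stage testable offline.

## Worked example

A small synthetic locus whose middle exon occludes the tail of the first
exon — closed in wild type, open in the exon-skipped mutant:

```r
library(asodesign)

loc  <- generate_synthetic_locus(synthetic_locus_spec(
  exon15_length = 8, exon16_length = 8, exon17_length = 6,
  occlusion_span = c(3, 8), spacer = 3))
pair <- loc$pair
pm <- compute_ss_count(fold_ensemble(pair$mut_sequence), allele = "mut")
pw <- compute_ss_count(fold_ensemble(pair$wt_sequence),  allele = "wt")
dm <- differential_accessibility(classify_accessibility(pm),
                                 classify_accessibility(pw), pair)
dm$mut_accessible_wt_closed
#> [1] 3 4 5 6 7

cons <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                           wing_range = c(3, 3))
g    <- enumerate_gapmers(pair, cons)
mix  <- place_mixmer_chemistry(g[[2]], dm, pair, cons)
vars <- generate_mismatch_variants(mix, dm, pair, region = "exon15")
all  <- c(g[2], list(mix), vars)
anns <- lapply(all, annotate_affinity, pair = pair,
               profile_mut = pm, profile_wt = pw)
rank_designs(all, anns)[, c("rank", "name", "category", "discrimination")]
#>   rank                         name        category discrimination
#> 1    1      G_L13_g07_w3.3_s001.mix          mixmer           22.5
#> 2    2 G_L13_g07_w3.3_s001.mix.mm12 mismatch_mixmer           22.5
#> 3    3 G_L13_g07_w3.3_s001.mix.mm13 mismatch_mixmer           22.5
#> 4    4          G_L13_g07_w3.3_s001          gapmer           20.5

sort(vapply(anns, function(a) predict_selectivity(a)$selectivity, 1))
#> 4.14 11.96 50.12 50.12
```

The differential map recovers exactly the occluded span (mutant positions
3–7). The mixmer beats the gapmer on the raw score gap (`discrimination`,
wild-type minus mutant total score: 22.5 vs 20.5), and the predicted
engagement selectivity at 100 nM orders the three architectures
gapmer (4.1) < mixmer (12.0) < mismatch-mixmer (50.1) — note the mismatch
leaves the score gap unchanged (it costs both alleles equally) yet
quadruples the functional selectivity through saturation.

The packaged reference designs load with `load_table1()`; e.g. the lead
mixmer parses to 23 residues, GC 69.6%, DNA runs 4+3+3:

```r
t1 <- load_table1()
d  <- attr(t1, "designs")[["M-7"]]
serialize_oligo(d)
#> [1] "[GAC] C*A*C*G* [CUC] A*C*C* [CUUU] G*G*C* [CCG]"
gc_content(d); dna_run_profile(d)$runs
#> [1] 69.6
#> [1] 4 3 3
```

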