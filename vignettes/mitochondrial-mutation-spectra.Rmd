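---
title: "Comparing mitochondrial DNA mutation spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing mitochondrial DNA mutation spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitospectra)
```

## The scientific question

Somatic mitochondrial DNA (mtDNA) point mutations accumulate and clonally
expand in ageing mitotic tissues such as colonic crypts. In the germline,
purifying selection — amplified by the mitochondrial bottleneck — removes
deleterious variants; whether any comparable constraint acts on somatic
mutations is a different question. If somatic mutations arise and expand
free of selection, then (i) their positions should be indistinguishable from
uniform placement over the genome, (ii) the fraction that change an amino
acid, shift the reading frame, or create a premature stop should be *higher*
than among rare germline population variants (which have survived selection),
and (iii) their predicted pathogenicity distribution should match that of
*all possible* amino-acid changes rather than a selected subset.

`mitospectra` implements the complete analytical chain for this comparison:
consequence annotation on rCRS coordinates, random-placement goodness-of-fit
tests, cross-cohort spectrum contingency tests with Bonferroni thresholds,
and Wilcoxon rank-sum comparisons of precomputed pathogenicity scores,
together with a seeded synthetic-cohort generator so that every stage is
testable end to end without external downloads.

## Coordinate system and reference

All coordinates are 1-based inclusive on the rCRS (NC_012920.1) numbering,
matching m.-notation; the genome is circular and the control region
(16024–576) wraps the origin. The gene annotation is a versioned TSV
transcribed from the NC_012920.1 feature table: 13 protein-coding genes,
22 tRNAs, 2 rRNAs; MT-ND6 and eight tRNAs lie on the light strand; the
ATP8/ATP6, ND4L/ND4, ATP6/CO3, TI/TQ and TC/TY pairs overlap. Genes whose
stop codon is completed by polyadenylation carry an `incomplete_stop_len`
of 1–2 bases (ND1, ND2, CO3, ND3, ND4, CYB), chosen so that every CDS length
minus that value is divisible by 3.

The package does **not** bundle the rCRS base string. Instead
`synthetic_reference()` generates, as a pure function of a seed, a fully
synthetic 16,569-bp genome that is structurally faithful to the real
molecule: real gene coordinates, `ATG` initiators, stop-free reading frames
in *every* protein gene including both frames of the overlap regions and the
light-strand MT-ND6, correct complete (`TAA`) and incomplete (`T`/`TA`)
terminators, the historical placeholder `N` at position 3107, and a
heavy-strand-like base composition (A/C-rich, G-poor). Everything
coordinate-level (gene queries, occupancy expectations, region classes,
binning) is therefore exact with respect to the real annotation, while
residue-level outputs (which amino acid a specific variant produces) are
exact with respect to the synthetic sequence and illustrative with respect
to the real one. Analyses of real data should load the true rCRS FASTA with
`load_reference()`; every downstream function is agnostic to which genome
object it receives.

## Consequence annotation

For a substitution in a protein gene the affected codon is rebuilt from the
reference: the codon index is `ceiling(offset / 3)` where `offset` is the
1-based position within the CDS (read descending and complemented for
light-strand genes, while `ref`/`alt` stay in rCRS orientation), the
alternate base is spliced in, and both codons are translated with NCBI
translation table 2 (vertebrate mitochondrial: `TGA`=Trp, `ATA`=Met,
`AGA`/`AGG`=stop). Classes:

* `synonymous` — same residue;
* `non_synonymous` — different residue;
* `premature_termination` — the alternate codon is a stop;
* `stop_loss` — the reference codon was the terminator (or the variant hits
  the 1–2 polyadenylation-completed terminal bases, whose disruption
  destroys the completed stop);
* `frameshift` / `in_frame_indel` — indel length not divisible / divisible
  by 3;
* `tRNA`, `rRNA`, `noncoding` — located classes for RNA-gene and intergenic
  changes (no structural scoring is attempted; RNA mutations are classified
  by location only).

Non-standard initiator codons are reported as Met in whole-protein
translations (`translate_gene(init_met = TRUE)`), but codon-1 variants are
classified from the raw table-2 translation of both codons, which keeps the
classification a pure codon-level function. The test suite verifies the
codon-level caller against an independent oracle that mutates the whole
genome, re-translates the entire protein with Biostrings, and diffs
residues, for 1,000 random substitutions per run.

A substitution inside a gene overlap receives one consequence per gene; for
single-count tabulation the most severe wins, ordered
`premature_termination > frameshift > stop_loss > non_synonymous >
in_frame_indel > synonymous`, and within equal severity the gene earlier in
genome order. Position-to-type tabulation uses the precedence
protein > tRNA > rRNA > noncoding, so that every base has exactly one class
and spectrum totals equal cohort sizes. For the three-category reporting
spectrum (`consequence_spectrum()`), stop-losses are pooled with
frameshift/premature-termination because all three disrupt termination or
reading frame; in-frame indels (absent from the motivating datasets) stay
separate unless `pool_in_frame = TRUE`.

## Enumeration of all possible protein variants

`enumerate_protein_variants()` generates the 3 possible substitutions at
every complete codon of every protein gene. The terminator codon of
complete-stop genes is excluded (variants there are stop-losses, not
amino-acid variations, and whole-proteome pathogenicity tables score residue
substitutions only), as are incomplete terminal bases. Overlap regions are
enumerated once per gene, since the same base change is a different protein
variant in each frame. Two totals are reported for the amino-acid-changing
count: nucleotide substitution *events*, and *distinct*
`(gene, aa_pos, aa_ref, aa_alt)` tuples (different third-position changes can
yield the same residue change, so events ≥ distinct). Published whole-
proteome counts do not state their convention unambiguously; the package
defaults to the event count and always reports both. On the synthetic
reference the identity `records = 3 × enumerated CDS bases` (34,101 records
over 11,367 enumerated bases) is asserted in the tests.

## Statistical methods

**Positional goodness of fit.** Mutations are binned in fixed 2,000-bp
windows starting at position 1. Expected counts are proportional to each
bin's overlap with the analyzed region (default: the coding region 577–16023,
15,447 bp, configurable), with an equal-per-bin mode available because a
"every window equally likely" reading of the null is also defensible. The
trailing window overlaps the coding region by only 23 bp; an expected count
of ~0.2 would invalidate the chi-squared approximation, so by default a
trailing bin with less than half a window of overlap is pooled with its
neighbour (standard sparse-cell practice), giving 8 bins of widths
1424, 2000 × 6, 2023. The statistic is Pearson
`X² = Σ (O − E)² / E` with `df = bins − 1`; the implementation is the
one-line closed form (cross-checked against `chisq.test` in the unit tests)
so that the null-calibration simulation can evaluate 10,000 replicates in
vector form.

**Gene-type goodness of fit.** Observed counts per gene type
(protein/tRNA/rRNA) are tested against expectations proportional to the
bases each type occupies in the analyzed region (11,341 / 1,504 / 2,513 of
15,447). The 89 intergenic bases inside the coding span are too few to
support an expected cell at study sample sizes; mutations there are excluded
from this test and their count reported.

**Cross-cohort contingency.** `contingency_compare()` runs Pearson
chi-squared tests without continuity correction (the multi-category tables
that dominate this analysis take no correction; a Yates flag exists for 2×2
sensitivity checks), overall and for every pair of cohorts. Bonferroni
correction over the k pairwise tests is represented as fixed significance
thresholds `0.05/k, 0.01/k, 0.001/k` — for three cohorts 0.017, 0.003,
0.0003 — with Bonferroni-inflated p-values emitted alongside. No automatic
fallback to Fisher's exact test is attempted.

**Score comparisons.** Pathogenicity scores are consumed from a table keyed
by `(gene, aa_pos, aa_ref, aa_alt)`; reproducing any predictor is out of
scope. Non-synonymous substitutions are looked up; synonymous changes are
scored 0 and included when the `synonymous_as_zero` convention is on (they
change no residue); frameshift/premature-termination/stop-loss changes are
always unscored because residue-substitution predictors cannot analyse them;
lookup misses are flagged data, not errors, and are excluded from summaries
(a `collapse_duplicates` flag additionally counts recurrent variants once —
both behaviours exist because either can explain a scored n smaller than the
non-synonymous count). Summaries report mean, sample (n−1) standard
deviation, and n, to 3 decimals. Distributions are compared with the
two-sided Wilcoxon rank-sum test: exact enumeration when both samples have
≤ 12 observations and no ties (verified exhaustively against a brute-force
enumeration oracle for all n₁+n₂ ≤ 10), otherwise the normal approximation
with tie and continuity correction (within 0.01 of exact for tie-free
samples of 8–12).

## The synthetic cohort generator

`generate_cohort()` emulates the structure of single-cell mutation tables,
with every default chosen once from the study conditions the analysis
assumes:

| parameter | default | rationale |
|---|---|---|
| `n_cells` | 156 | sequenced cells in the motivating ageing dataset |
| `count_probs` | 0:67, 1:61, 2:20, 3:5, 4:3 (/156) | published burden histogram; zero class = cells without clonal mutations |
| `type_mix` | transition 0.90, transversion 0.04, insertion 0.02, deletion 0.04 | ~90% transitions; indels present at a few percent |
| `transition_pairs` | C:G>T:A 0.65, T:A>C:G 0.35 | 65% of transitions are C:G>T:A (replication error / cytosine deamination signature) |
| `homoplasmic_prob` | 0.39 | 39% of mutations homoplasmic |
| `het_range` | 15–95% | detectable clonal expansions below homoplasmy |
| `cox_model` | base 0.20, high-load 0.85 at ≥80% | COX deficiency requires high mutant load |

Substitution sampling draws the target strand-symmetric pair first and then
a position whose reference base participates, so pair proportions are
matched while positions stay conditionally uniform under the positional
model (`uniform_coding` by default). With `transition_pairs = NULL` the
position is drawn first, unconditionally, and the transition partner of the
reference base is used — this is the exact uniform-placement null, and it is
the configuration the calibration experiments use, because it *is* the null
hypothesis the goodness-of-fit tests address. Reference bases are read from
the genome so every generated record passes validation; all public
generators take an explicit seed and restore the caller's RNG state.

What the generator does **not** emulate: mutational hotspots and context
effects (positions are exchangeable given the pair label), linkage of
mutations within a cell, phylogenetic structure among population variants,
realistic per-gene selection in the disease spectrum, and electropherogram-
level heteroplasmy measurement error. Passing tests therefore demonstrate
correctness of the analytical machinery under its own null and calibrated
alternatives — not that real tissues obey the generator's model.

`generate_score_table()` draws one Beta(5.58, 3.11) score per distinct
missense variant of the enumeration (moment-matched to a mean of 0.642 and
sd of 0.154, the marginal shape of published whole-proteome tables);
`spike_selection()` thins non-synonymous mutations binomially to mimic
purifying selection for power experiments.

## Numerical choices and problem sizes

* Percentages are reported to 1 decimal, score means/sds to 3, matching the
  precision conventions of the literature the outputs are compared against.
* `gof_null_calibration()` uses 10,000 replicates at cohort size 117; both
  tests reject at 0.050 ± 0.003 in our runs (band checked in tests: ± 0.01).
* `selection_power()` uses 1,000 replicate pairs at protein-gene cohort
  sizes 81 vs 155; power to detect 50% non-synonymous depletion is ~0.65
  and stable across seeds.
* Parameter-recovery checks run at n = 10,000 mutations with 3-binomial-sd
  acceptance bands.
* The test suite and the acceptance script each complete in about a minute
  on one CPU; these sizes were chosen as the smallest that make the binomial
  bands meaningfully tight.

## Known limitations

* The bundled genome is synthetic: residue-level identities (e.g. which
  amino acid change m.8993T>G produces) match the synthetic sequence, not
  the rCRS. Coordinate-level behaviour is exact. Real analyses should load
  the true rCRS.
* Gene boundaries follow one annotation build; curations differing by 1–2 bp
  at a handful of boundaries could move single mutations between classes.
* Indels are located by their first affected base; an indel spanning a gene
  boundary is assigned to the gene containing that base.
* The disease-cohort curation process (pathogenicity criteria for inclusion)
  and heteroplasmy quantification are upstream of this package: mutation
  tables and score tables are inputs, taken at face value after validation.
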