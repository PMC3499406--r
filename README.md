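# mitospectra

Comparative analysis of mitochondrial DNA (mtDNA) point-mutation spectra in
R. The package asks whether a cohort of mutations — somatic mutations from
ageing tissue, rare germline population variants, or disease-causing
mutations — shows the imprint of purifying selection, by testing three
predictions of the selection-free null:

1. **Random placement.** Under uniform placement, the count `O_i` of
   mutations in genomic window *i* (or gene type *i*) follows expectations
   `E_i ∝ L_i`, the bases that window or gene type occupies; Pearson
   `X² = Σ (O_i − E_i)² / E_i` with `df = k − 1` tests the fit.
2. **Consequence spectrum.** The proportions of synonymous,
   non-synonymous, and frameshift/premature-termination changes in
   protein-coding genes are compared across cohorts by r×c chi-squared
   contingency tests, with Bonferroni-corrected significance thresholds
   `0.05/k, 0.01/k, 0.001/k` over the k pairwise tests.
3. **Pathogenicity.** Precomputed per-residue-substitution pathogenicity
   scores in [0, 1] are attached to non-synonymous changes (synonymous
   changes scored 0 under the inclusive convention; truncating changes are
   unscorable) and cohorts are compared with two-sided Wilcoxon rank-sum
   tests, including against the distribution over *all* possible
   amino-acid-changing substitutions in the 13 protein genes, which the
   package enumerates (3 substitutions × every complete codon, overlap
   genes counted per frame).

Annotation runs on rCRS (NC_012920.1) coordinates with the vertebrate
mitochondrial genetic code (`TGA`=Trp, `ATA`=Met, `AGA`/`AGG`=stop),
strand-aware for MT-ND6 and the light-strand tRNAs, and
overlap-aware for ATP8/ATP6 and ND4L/ND4. A seeded synthetic-data module
generates reference genomes, mutation cohorts, and score tables with the
statistical structure the analysis assumes, so the entire pipeline is
testable offline; the bundled genome is *synthetic* (structurally faithful
to the rCRS — real gene coordinates, stop-free frames, N at 3107 — but not
the real base string; see the methods vignette).

Intended users: researchers analysing single-cell or clonal mtDNA mutation
tables who need consequence calls, spectrum statistics, and score
comparisons in one reproducible chain.

## Worked example

```r
library(mitospectra)
genome <- synthetic_reference(seed = 42)   # or load_reference("rCRS.fa")
ann <- mito_annotation(genome)

ageing <- generate_cohort(cohort_spec(), ann, seed = 1, cohort = "ageing")
population <- generate_cohort(
  cohort_spec(n_cells = 180, count_probs = c(`1` = 1),
              type_mix = c(transition = 0.94, transversion = 0.05,
                           insertion = 0.005, deletion = 0.005)),
  ann, seed = 2, cohort = "population")

enum <- enumerate_protein_variants(ann)
scores <- generate_score_table(enum, seed = 3)
report <- run_full_analysis(list(ageing = ageing, population = population),
                            ann, score_table = scores)
print(report)
```

```
Mitochondrial mutation-spectrum report
Cohort funnel:
     cohort n_input n_coding n_excluded_control_region
     ageing     129      129                         0
 population     180      180                         0

[ageing] consequence spectrum (protein genes):
                            class  n  pct
                       synonymous 30 30.6
                   non_synonymous 60 61.2
 frameshift_premature_termination  8  8.2
  positional GOF p = 0.731; gene-type GOF p = 0.137

[population] consequence spectrum (protein genes):
                            class  n  pct
                       synonymous 42 34.4
                   non_synonymous 72 59.0
 frameshift_premature_termination  8  6.6
  positional GOF p = 0.699; gene-type GOF p = 0.174

Pairwise consequence-class contingency:
                 pair statistic df   p_value p_bonferroni stars
 ageing vs population 0.4784209  2 0.7872492    0.7872492

Pathogenicity score summaries (non-synonymous only):
  ageing: 0.651 +/- 0.164 (sd), n = 60
  population: 0.629 +/- 0.133 (sd), n = 72
```

Reading the output: both synthetic cohorts were generated without
positional structure, and both goodness-of-fit p-values are accordingly
non-significant — the mutations look randomly placed. The 129 ageing
mutations funnel into 98 protein-gene changes, 61.2% of them
non-synonymous; the pairwise contingency test finds no spectrum difference
between these two particular synthetic cohorts (p = 0.79, far above the
k-corrected threshold 0.017). Score summaries report mean ± sample sd over
scored (non-synonymous) changes only.

The same functions serve as standalone stages: `annotate_mutations()`
(annotate), `consequence_spectrum()` and the per-cohort tables in the
report (spectrum), `contingency_compare()` and `wilcoxon_rank_sum()`
(compare), `enumerate_protein_variants()` (enumerate),
`generate_cohort()` (simulate), and `run_full_analysis()` with
`outdir=` (report: TSV tables plus a JSON results bundle). Cohort tables
are read and written with `read_mutation_table()` /
`write_mutation_table()` (TSV/CSV, schema `cohort, subject_id, cell_id,
position, ref, alt, kind, heteroplasmy_percent, cox_status, inheritance,
reported_gene`), with minimal VCF export via `write_vcf()`.

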