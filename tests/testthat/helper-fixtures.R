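# Shared fixtures: one synthetic reference genome + annotation per run.
ref_genome <- synthetic_reference(seed = 42)
rcrs_ann <- mito_annotation(ref_genome)
mito_code2 <- Biostrings::getGeneticCode("2")

# Independent whole-protein oracle: extract a protein gene (strand-aware),
# translate the full CDS with Biostrings, return residue vector.
oracle_protein <- function(sequence, g) {
  s <- substring(sequence, g$start, g$end)
  if (g$strand == "L")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s <- substring(s, 1, nchar(s) - g$incomplete_stop_len)
  strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(s), genetic.code = mito_code2,
    no.init.codon = TRUE)), "")[[1]]
}

# Consequence of a substitution by brute force: mutate the whole genome,
# re-translate every overlapped protein gene, and diff residues.
oracle_consequence <- function(ann, pos, alt) {
  mutseq <- ann$genome$sequence
  substr(mutseq, pos, pos) <- alt
  hits <- genes_at(ann, pos)
  hits <- hits[hits$gene_type == "protein", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    g <- hits[i, ]
    aaref <- oracle_protein(ann$genome$sequence, g)
    aaalt <- oracle_protein(mutseq, g)
    d <- which(aaref != aaalt)
    out[[g$symbol]] <- list(
      class = if (length(d) == 0L) "synonymous"
      else if (aaalt[d[1L]] == "*") "premature_termination"
      else if (aaref[d[1L]] == "*") "stop_loss"
      else "non_synonymous",
      aa_pos = if (length(d)) d[1L] else NA_integer_,
      aa_ref = if (length(d)) aaref[d[1L]] else NA_character_,
      aa_alt = if (length(d)) aaalt[d[1L]] else NA_character_)
  }
  out
}

# All enumerated (complete-codon) positions of the protein genes: inside the
# CDS but outside incomplete terminal bases, so substitutions there have a
# codon-level consequence the oracle can diff.
protein_cds_positions <- function(ann) {
  pro <- ann$genes[ann$genes$gene_type == "protein", ]
  unlist(lapply(seq_len(nrow(pro)), function(i) {
    g <- pro[i, ]
    if (g$strand == "H") seq.int(g$start, g$end - g$incomplete_stop_len)
    else seq.int(g$start + g$incomplete_stop_len, g$end)
  }))
}

# Minimal single-cohort MutationSet from bare columns.
make_ms <- function(position, ref, alt, kind = NULL, cell_id = NULL,
                    het = 50, cohort = "test", ...) {
  n <- length(position)
  if (is.null(kind)) kind <- rep("substitution", n)
  if (is.null(cell_id)) cell_id <- sprintf("c%03d", seq_len(n))
  MutationSet(data.frame(position = position, ref = ref, alt = alt,
                         kind = kind, cell_id = cell_id,
                         subject_id = "s1",
                         heteroplasmy_percent = het,
                         cox_status = "unknown",
                         inheritance = "not_applicable",
                         reported_gene = "",
                         stringsAsFactors = FALSE, ...),
              cohort = cohort)
}

# Random valid substitutions at protein CDS positions.
random_protein_substitutions <- function(ann, n, seed) {
  withr::with_seed(seed, {
    pos <- sample(protein_cds_positions(ann), n, replace = TRUE)
    refb <- ref_base(ann$genome, pos)
    alt <- vapply(refb, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1L))
    data.frame(position = pos, ref = refb, alt = alt,
               stringsAsFactors = FALSE)
  })
}

# Brute-force exact two-sided Wilcoxon rank-sum p-value by enumeration of
# all group assignments (tie-free samples).
wilcoxon_brute_force <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n1 + n2, n1)
  w_all <- apply(subsets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  p <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  p
}
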