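test_that("change-type classification splits transitions and transversions", {
  expect_equal(classify_change_type("A", "G"), "transition")
  expect_equal(classify_change_type("C", "T"), "transition")
  expect_equal(classify_change_type("C", "A"), "transversion")
  expect_equal(classify_change_type("G", "T"), "transversion")
  expect_equal(classify_change_type("A", "", kind = "deletion"), "deletion")
  expect_equal(classify_change_type("", "A", kind = "insertion"), "insertion")
  expect_error(classify_change_type("A", "A", kind = "substitution"),
               "ref equal to alt")
})

test_that("strand-symmetric labels collapse complements onto 6 pairs", {
  expect_equal(strand_symmetric_label("G", "A"), "C:G>T:A")
  expect_equal(strand_symmetric_label("C", "T"), "C:G>T:A")
  expect_equal(strand_symmetric_label("C", "A"), "C:G>A:T")
  expect_equal(strand_symmetric_label("T", "C"), "T:A>C:G")
  expect_error(strand_symmetric_label("AC", "A"))
  # exactly 6 labels across all 12 substitutions
  bases <- c("A", "C", "G", "T")
  all12 <- expand.grid(r = bases, a = bases, stringsAsFactors = FALSE)
  all12 <- all12[all12$r != all12$a, ]
  expect_equal(length(unique(strand_symmetric_label(all12$r, all12$a))), 6L)
})

test_that("classification is invariant under joint complementation", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in bases) for (a in setdiff(bases, r)) {
    expect_equal(classify_change_type(r, a),
                 classify_change_type(comp[[r]], comp[[a]]))
    expect_equal(strand_symmetric_label(r, a),
                 strand_symmetric_label(comp[[r]], comp[[a]]))
  }
})

test_that("codon-level annotation matches the whole-protein oracle", {
  subs <- random_protein_substitutions(rcrs_ann, 250L, seed = 9)
  ms <- make_ms(subs$position, subs$ref, subs$alt,
                cell_id = sprintf("c%04d", seq_len(nrow(subs))))
  res <- annotate_mutations(ms, rcrs_ann, all_overlaps = TRUE)
  res <- res[res$gene_type == "protein", ]
  for (i in seq_len(nrow(res))) {
    orc <- oracle_consequence(rcrs_ann, res$position[i], res$alt[i])
    exp <- orc[[res$gene[i]]]
    expect_equal(res$change_class[i], exp$class,
                 label = paste("class at", res$position[i], res$gene[i]))
    if (exp$class == "non_synonymous") {
      expect_equal(res$aa_pos[i], exp$aa_pos)
      expect_equal(res$aa_ref[i], exp$aa_ref)
      expect_equal(res$aa_alt[i], exp$aa_alt)
    }
  }
})

test_that("synonymous calls never change the translated protein", {
  subs <- random_protein_substitutions(rcrs_ann, 400L, seed = 10)
  ms <- make_ms(subs$position, subs$ref, subs$alt,
                cell_id = sprintf("c%04d", seq_len(nrow(subs))))
  res <- annotate_mutations(ms, rcrs_ann, all_overlaps = TRUE)
  syn <- res[res$change_class == "synonymous" & res$gene_type == "protein", ]
  expect_gt(nrow(syn), 0L)
  for (i in seq_len(nrow(syn))) {
    orc <- oracle_consequence(rcrs_ann, syn$position[i], syn$alt[i])
    expect_equal(orc[[syn$gene[i]]]$class, "synonymous")
  }
})

test_that("L-strand genes are annotated in complemented orientation", {
  # an MT-ND6 (L-strand) substitution: codon read descending with complement
  g <- rcrs_ann$genes[rcrs_ann$genes$symbol == "MT-ND6", ]
  pos <- g$end - 10L  # inside codon 4 on the L strand
  refb <- ref_base(ref_genome, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  ms <- make_ms(pos, refb, alt)
  res <- annotate_mutations(ms, rcrs_ann)
  expect_equal(res$gene, "MT-ND6")
  expect_equal(res$aa_pos, (g$end - pos) %/% 3L + 1L)
  orc <- oracle_consequence(rcrs_ann, pos, alt)
  expect_equal(res$change_class, orc[["MT-ND6"]]$class)
})

test_that("indels in protein genes are frameshift unless length % 3 == 0", {
  g <- rcrs_ann$genes[rcrs_ann$genes$symbol == "MT-ND1", ]
  p <- g$start + 30L
  one <- make_ms(p, ref_base(ref_genome, p), "", kind = "deletion")
  expect_equal(annotate_mutations(one, rcrs_ann)$change_class, "frameshift")
  three <- make_ms(p, substring(ref_genome$sequence, p, p + 2L), "",
                   kind = "deletion")
  expect_equal(annotate_mutations(three, rcrs_ann)$change_class,
               "in_frame_indel")
  ins <- make_ms(p, "", "AC", kind = "insertion")
  expect_equal(annotate_mutations(ins, rcrs_ann)$change_class, "frameshift")
})

test_that("RNA-gene and intergenic mutations are classified by location", {
  ms <- make_ms(c(3243L, 1555L, 100L),
                ref_base(ref_genome, c(3243L, 1555L, 100L)), c("", "", ""),
                kind = rep("deletion", 3))
  res <- annotate_mutations(ms, rcrs_ann)
  expect_equal(res$change_class, c("tRNA", "rRNA", "noncoding"))
  expect_equal(res$gene, c("MT-TL1", "MT-RNR1", NA))
  expect_true(all(is.na(res$aa_change)))
})

test_that("overlap substitutions get one consequence per gene, most severe wins", {
  # find an ATP8/ATP6 overlap substitution that differs in class between genes
  found <- FALSE
  for (pos in 8527:8569) {
    refb <- ref_base(ref_genome, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      ms <- make_ms(pos, refb, alt)
      both <- annotate_mutations(ms, rcrs_ann, all_overlaps = TRUE)
      expect_equal(nrow(both), 2L)
      expect_setequal(both$gene, c("MT-ATP8", "MT-ATP6"))
      primary <- annotate_mutations(ms, rcrs_ann)
      expect_equal(nrow(primary), 1L)
      sev <- c("premature_termination", "frameshift", "stop_loss",
               "non_synonymous", "in_frame_indel", "synonymous")
      expect_equal(primary$change_class,
                   sev[min(match(both$change_class, sev))])
      if (length(unique(both$change_class)) > 1L) found <- TRUE
    }
    if (found) break
  }
  expect_true(found)
})

test_that("consequence spectrum pools truncating classes over protein genes", {
  p <- rcrs_ann$genes$start[rcrs_ann$genes$symbol == "MT-CO1"] + c(10L, 40L)
  subs <- random_protein_substitutions(rcrs_ann, 120L, seed = 12)
  ms <- make_ms(c(subs$position, p),
                c(subs$ref, ref_base(ref_genome, p)),
                c(subs$alt, "", ""),
                kind = c(rep("substitution", nrow(subs)),
                         "deletion", "deletion"),
                cell_id = sprintf("c%04d", seq_len(nrow(subs) + 2L)))
  res <- annotate_mutations(ms, rcrs_ann)
  spec <- consequence_spectrum(res)
  expect_setequal(spec$class, c("synonymous", "non_synonymous",
                                "frameshift_premature_termination"))
  expect_equal(sum(spec$n), sum(res$gene_type == "protein"))
  n_trunc <- sum(res$change_class %in%
                   c("frameshift", "premature_termination", "stop_loss"))
  expect_equal(spec$n[spec$class == "frameshift_premature_termination"],
               n_trunc)
  expect_equal(spec$pct,
               round(100 * spec$n / sum(spec$n), 1))
  # all-synonymous set reports 100%
  syn <- res[res$change_class == "synonymous", ][1, , drop = FALSE]
  expect_equal(consequence_spectrum(syn)$pct[1], 100)
})
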