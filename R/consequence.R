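PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

CHANGE_CLASSES <- c("premature_termination", "frameshift", "stop_loss",
                    "non_synonymous", "in_frame_indel", "synonymous",
                    "tRNA", "rRNA", "noncoding")

#' Classify the nucleotide change type of mutations
#'
#' Splits substitutions into transitions (purine-purine or
#' pyrimidine-pyrimidine) and transversions (cross-class); indels are
#' labelled by their kind.
#'
#' @param ref,alt Character vectors of reference/alternate alleles (empty
#'   string for the missing side of an indel).
#' @param kind Character vector `substitution`/`insertion`/`deletion`;
#'   inferred from `ref`/`alt` when `NULL`.
#' @return Character vector over `transition`, `transversion`, `insertion`,
#'   `deletion`.
#' @examples
#' classify_change_type(c("A", "C"), c("G", "A"))
#' @export
classify_change_type <- function(ref, alt, kind = NULL) {
  if (is.null(kind)) kind <- infer_kind(ref, alt)
  out <- kind
  sub <- which(kind == "substitution")
  if (length(sub)) {
    r <- ref[sub]; a <- alt[sub]
    if (any(r == a)) stop("ref equal to alt in substitution")
    same <- (r %in% PURINES & a %in% PURINES) |
      (r %in% PYRIMIDINES & a %in% PYRIMIDINES)
    out[sub] <- ifelse(same, "transition", "transversion")
  }
  out
}

#' Strand-symmetric substitution labels
#'
#' Collapses each substitution and its complement onto one of the six
#' canonical base-pair change labels (pyrimidine written first), e.g. both
#' `G>A` and `C>T` map to `"C:G>T:A"`.
#'
#' @param ref,alt Single-base character vectors.
#' @return Character vector of pair labels, one of `C:G>T:A`, `T:A>C:G`,
#'   `C:G>A:T`, `C:G>G:C`, `T:A>A:T`, `T:A>G:C`.
#' @export
strand_symmetric_label <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("strand_symmetric_label applies to substitutions only")
  flip <- ref %in% PURINES
  r <- ifelse(flip, complement_base(ref), ref)
  a <- ifelse(flip, complement_base(alt), alt)
  paste0(r, ":", complement_base(r), ">", a, ":", complement_base(a))
}

## consequence of a single-base substitution within one protein gene;
## scalar coordinates to keep the hot path free of data-frame access
protein_substitution_consequence <- function(sequence, g_start, g_end,
                                             g_strand, g_inc, position, alt,
                                             code) {
  cds_len <- g_end - g_start + 1L - g_inc
  offset <- if (g_strand == "H") position - g_start + 1L
            else g_end - position + 1L
  if (offset > cds_len) {
    ## the 1-2 terminal bases completed to a stop by polyadenylation
    return(list(change_class = "stop_loss", aa_ref = NA_character_,
                aa_alt = NA_character_, aa_pos = NA_integer_))
  }
  codon_idx <- (offset - 1L) %/% 3L + 1L
  within <- (offset - 1L) %% 3L + 1L
  pos3 <- if (g_strand == "H") g_start + 3L * (codon_idx - 1L) + 0:2
          else g_end - 3L * (codon_idx - 1L) - 0:2
  ref_bases <- substring(sequence, pos3, pos3)
  if (g_strand == "L") ref_bases <- complement_base(ref_bases)
  alt_bases <- ref_bases
  alt_bases[within] <- if (g_strand == "L") complement_base(alt) else alt
  aa_ref <- translate_codons(paste(ref_bases, collapse = ""), code)
  aa_alt <- translate_codons(paste(alt_bases, collapse = ""), code)
  cls <- if (aa_ref == "*") {
    if (aa_alt == "*") "synonymous" else "stop_loss"
  } else if (aa_alt == "*") {
    "premature_termination"
  } else if (aa_ref == aa_alt) "synonymous" else "non_synonymous"
  list(change_class = cls, aa_ref = aa_ref, aa_alt = aa_alt,
       aa_pos = codon_idx)
}

#' Annotate mutations with their genetic consequence
#'
#' For every mutation, rebuilds the affected codon from the reference
#' (strand-aware: L-strand genes are read in complemented orientation while
#' ref/alt stay in rCRS coordinates), translates reference and alternate
#' codons with the vertebrate mitochondrial code, and assigns a consequence
#' class: `synonymous`, `non_synonymous`, `premature_termination` (a
#' stop-creating substitution), `stop_loss`, `frameshift` (indel of length
#' not divisible by 3 in a protein gene), `in_frame_indel`, or the locating
#' classes `tRNA`, `rRNA`, `noncoding`. A substitution in a gene-overlap
#' region is evaluated once per gene; the reported (primary) consequence is
#' the most severe one, with severity ordered
#' `premature_termination > frameshift > stop_loss > non_synonymous >
#' in_frame_indel > synonymous > tRNA > rRNA > noncoding`.
#'
#' @param ms A `MutationSet` (validated against the same reference).
#' @param ann A `MitoAnnotation`.
#' @param all_overlaps If `TRUE`, return one row per (mutation, gene) pair
#'   instead of the per-mutation primary consequence.
#' @return Data frame: the mutation columns plus `change_type` (transition /
#'   transversion / insertion / deletion), `gene`, `gene_type`,
#'   `change_class`, `aa_ref`, `aa_pos`, `aa_alt`, `aa_change`
#'   (`p.RefPosAlt` one-letter notation, `NA` outside protein substitutions).
#' @export
annotate_mutations <- function(ms, ann, all_overlaps = FALSE) {
  df <- as.data.frame(ms)
  code <- mito_genetic_code()
  sequence <- ann$genome$sequence
  ## flat gene vectors keep the per-mutation loop off data-frame accessors
  gt <- ann$genes[ann$genes$gene_type != "noncoding", ]
  g_sym <- gt$symbol; g_type <- gt$gene_type
  g_start <- gt$start; g_end <- gt$end
  g_strand <- gt$strand; g_inc <- gt$incomplete_stop_len
  g_wraps <- g_start > g_end
  n <- nrow(df)
  acc <- vector("list", n)
  for (i in seq_len(n)) {
    p <- df$position[i]
    hit <- which((!g_wraps & g_start <= p & p <= g_end) |
                   (g_wraps & (p >= g_start | p <= g_end)))
    if (length(hit) == 0L) {
      acc[[i]] <- list(i, NA_character_, "noncoding", "noncoding",
                       NA_character_, NA_character_, NA_integer_)
      next
    }
    m <- length(hit)
    cls <- character(m); aar <- rep(NA_character_, m)
    aaa <- rep(NA_character_, m); aap <- rep(NA_integer_, m)
    for (k in seq_len(m)) {
      j <- hit[k]
      if (g_type[j] != "protein") {
        cls[k] <- g_type[j]
      } else if (df$kind[i] == "substitution") {
        cons <- protein_substitution_consequence(
          sequence, g_start[j], g_end[j], g_strand[j], g_inc[j], p,
          df$alt[i], code)
        cls[k] <- cons$change_class
        aar[k] <- cons$aa_ref; aaa[k] <- cons$aa_alt; aap[k] <- cons$aa_pos
      } else {
        indel_len <- max(nchar(df$ref[i]), nchar(df$alt[i]))
        cls[k] <- if (indel_len %% 3L == 0L) "in_frame_indel" else "frameshift"
      }
    }
    keep <- if (all_overlaps || m == 1L) seq_len(m)
            else order(match(cls, CHANGE_CLASSES))[1L]
    ## severity first; genome order (earlier gene) breaks ties
    acc[[i]] <- list(rep.int(i, length(keep)), g_sym[hit[keep]],
                     g_type[hit[keep]], cls[keep], aar[keep], aaa[keep],
                     aap[keep])
  }
  pull <- function(k, how) how(lapply(acc, `[[`, k))
  rows <- pull(1L, function(x) unlist(x, use.names = FALSE))
  out <- df[rows, , drop = FALSE]
  out$gene <- pull(2L, function(x) unlist(x, use.names = FALSE))
  out$gene_type <- pull(3L, function(x) unlist(x, use.names = FALSE))
  out$change_class <- pull(4L, function(x) unlist(x, use.names = FALSE))
  out$aa_ref <- pull(5L, function(x) unlist(x, use.names = FALSE))
  out$aa_alt <- pull(6L, function(x) unlist(x, use.names = FALSE))
  out$aa_pos <- pull(7L, function(x) unlist(x, use.names = FALSE))
  out$change_type <- classify_change_type(out$ref, out$alt, out$kind)
  out$aa_change <- ifelse(is.na(out$aa_ref), NA_character_,
                          paste0("p.", out$aa_ref, out$aa_pos, out$aa_alt))
  rownames(out) <- NULL
  out
}

#' Consequence-class spectrum of protein-gene mutations
#'
#' Tabulates annotated mutations falling in protein-coding genes into the
#' three reporting categories used for cross-cohort comparison:
#' `synonymous`, `non_synonymous`, and `frameshift_premature_termination`
#' (frameshifts, stop-creating substitutions and stop-losses pooled, as all
#' three disrupt translation termination or reading frame). In-frame indels
#' are kept separate unless `pool_in_frame = TRUE`.
#'
#' @param annotated Data frame from [annotate_mutations()].
#' @param pool_in_frame Pool `in_frame_indel` with the frameshift category.
#' @return Data frame with `class`, `n`, `pct` (percentages of protein-gene
#'   mutations, 1 decimal).
#' @export
consequence_spectrum <- function(annotated, pool_in_frame = FALSE) {
  pro <- annotated[annotated$gene_type == "protein", , drop = FALSE]
  pooled <- ifelse(pro$change_class %in%
                     c("frameshift", "premature_termination", "stop_loss") |
                     (pool_in_frame & pro$change_class == "in_frame_indel"),
                   "frameshift_premature_termination", pro$change_class)
  lev <- c("synonymous", "non_synonymous",
           "frameshift_premature_termination")
  if (!pool_in_frame && any(pooled == "in_frame_indel"))
    lev <- c(lev, "in_frame_indel")
  counts <- table(factor(pooled, levels = lev))
  data.frame(class = lev, n = as.integer(counts),
             pct = round(100 * as.integer(counts) / max(1L, nrow(pro)), 1L),
             stringsAsFactors = FALSE)
}

#' Enumerate every possible substitution in the protein-coding genes
#'
#' Generates all single-base substitutions at every codon of each of the 13
#' protein genes, classified as `synonymous`, `missense`, or `stop_gain` by
#' codon translation under the vertebrate mitochondrial code. Enumeration
#' covers complete annotated codons only: the terminator codon of
#' complete-stop genes is excluded (changes there are stop-losses, not
#' amino-acid variations), as are the 1-2 polyadenylation-completed
#' terminal bases of incomplete-stop genes. Overlap regions are enumerated
#' once per gene, so a base inside the ATP8/ATP6 overlap contributes records
#' to both genes.
#'
#' Two counting conventions for the amino-acid-changing total are reported:
#' `missense_events` counts nucleotide substitution events, and
#' `missense_distinct` counts distinct `(gene, aa_pos, aa_ref, aa_alt)`
#' tuples (two different third-position changes can produce the same residue
#' change). `missense_events` is the default convention used by
#' [generate_score_table()] keys via the distinct tuples it maps onto.
#'
#' @param ann A `MitoAnnotation`.
#' @return A `VariantEnumeration`: list with `records` (data.frame: gene,
#'   nt_pos, ref, alt, aa_pos, aa_ref, aa_alt, class; `ref`/`alt` in rCRS
#'   H-strand orientation), `class_totals`, `per_gene` summary,
#'   `missense_events`, `missense_distinct`.
#' @export
enumerate_protein_variants <- function(ann) {
  code <- mito_genetic_code()
  bases <- c("A", "C", "G", "T")
  pro <- ann$genes[ann$genes$gene_type == "protein", ]
  recs <- lapply(seq_len(nrow(pro)), function(i) {
    g <- pro[i, ]
    pm <- codon_position_matrix(g)
    if (g$incomplete_stop_len == 0L) pm <- pm[-nrow(pm), , drop = FALSE]
    ncod <- nrow(pm)
    cod <- read_codons(substring_vec(ann$genome$sequence), g, pm)
    aa_ref <- translate_codons(cod, code)
    ## expand: codon x within-position x 3 alternates
    idx <- rep(seq_len(ncod), each = 9L)
    within <- rep(rep(1:3, each = 3L), times = ncod)
    cod_mat <- matrix(unlist(strsplit(cod, "")), ncol = 3L, byrow = TRUE)
    ref_gene <- cod_mat[cbind(idx, within)]          # gene-orientation ref
    altn <- rep(1:3, times = 3L * ncod)
    alt_tab <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                     G = c("A", "C", "T"), T = c("A", "C", "G"))
    alt_gene <- alt_tab[cbind(match(ref_gene, bases), altn)]
    alt_codon <- cod[idx]
    substr(alt_codon, within, within) <- alt_gene
    aa_alt <- translate_codons(alt_codon, code)
    ref_here <- aa_ref[idx]
    class <- ifelse(aa_alt == "*", "stop_gain",
                    ifelse(aa_alt == ref_here, "synonymous", "missense"))
    nt_pos <- pm[cbind(idx, within)]
    if (g$strand == "L") {
      ref_out <- complement_base(ref_gene)
      alt_out <- complement_base(alt_gene)
    } else {
      ref_out <- ref_gene
      alt_out <- alt_gene
    }
    data.frame(gene = g$symbol, nt_pos = nt_pos, ref = ref_out,
               alt = alt_out, aa_pos = idx, aa_ref = ref_here,
               aa_alt = aa_alt, class = class, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  mis <- records[records$class == "missense", ]
  per_gene <- as.data.frame.matrix(table(records$gene, records$class))
  per_gene$gene <- rownames(per_gene)
  rownames(per_gene) <- NULL
  structure(
    list(records = records,
         class_totals = table(records$class),
         per_gene = per_gene,
         missense_events = nrow(mis),
         missense_distinct = nrow(unique(mis[, c("gene", "aa_pos", "aa_ref",
                                                 "aa_alt")]))),
    class = "VariantEnumeration")
}

## read_codons expects a base vector; cache the split genome
substring_vec <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1L]]
}

#' @export
print.VariantEnumeration <- function(x, ...) {
  cat("VariantEnumeration: ", nrow(x$records), " substitutions (",
      paste(names(x$class_totals), as.integer(x$class_totals),
            sep = "=", collapse = ", "),
      "); missense events = ", x$missense_events,
      ", distinct residue changes = ", x$missense_distinct, "\n", sep = "")
  invisible(x)
}
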