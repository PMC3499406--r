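#' Specification for a synthetic mutation cohort
#'
#' Describes the generative model used to emulate single-cell mtDNA mutation
#' tables. Defaults reproduce the headline marginal structure of published
#' ageing-colon cohorts: 156 sequenced cells of which 67 carry no clonally
#' expanded mutation and the rest carry 1/2/3/4 mutations in proportions
#' 61/20/5/3; ~90% of changes are transitions with 65% of transitions being
#' C:G>T:A; 39% of mutations homoplasmic; COX deficiency more likely in
#' cells carrying a high-heteroplasmy mutation.
#'
#' @param n_cells Number of cells sequenced.
#' @param count_probs Named probability vector over mutations-per-cell
#'   (names are counts, `"0"` allowed: the zero-inflation component).
#' @param positional_model `"uniform_coding"` (uniform over 577-16023),
#'   `"uniform_genome"`, or `"per_gene_weights"`.
#' @param gene_weights Named per-gene weights (required for
#'   `per_gene_weights`); positions are drawn uniformly within the weighted
#'   gene.
#' @param type_mix Probabilities over
#'   `transition`/`transversion`/`insertion`/`deletion`.
#' @param transition_pairs Probabilities over the two transition pair labels
#'   (`C:G>T:A`, `T:A>C:G`), or `NULL` to let the pair mix follow the base
#'   composition of the sampled positions (the pure uniform-placement null).
#' @param transversion_pairs Probabilities over the four transversion pair
#'   labels, or `NULL` as above.
#' @param homoplasmic_prob Point mass at 100% heteroplasmy.
#' @param het_range Range of the continuous heteroplasmy component
#'   (detectable clonal expansions; levels drawn uniformly and rounded).
#' @param cox_model List with `base`, `high_load`, `threshold`:
#'   P(COX-deficient) is `high_load` for cells whose maximum mutation
#'   heteroplasmy is at least `threshold` percent, else `base`.
#' @param n_subjects Cells are assigned round-robin to this many subjects.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_cells = 156L,
                        count_probs = c(`0` = 67, `1` = 61, `2` = 20,
                                        `3` = 5, `4` = 3) / 156,
                        positional_model = c("uniform_coding",
                                             "uniform_genome",
                                             "per_gene_weights"),
                        gene_weights = NULL,
                        type_mix = c(transition = 0.90, transversion = 0.04,
                                     insertion = 0.02, deletion = 0.04),
                        transition_pairs = c(`C:G>T:A` = 0.65,
                                             `T:A>C:G` = 0.35),
                        transversion_pairs = c(`C:G>A:T` = 0.25,
                                               `C:G>G:C` = 0.25,
                                               `T:A>A:T` = 0.25,
                                               `T:A>G:C` = 0.25),
                        homoplasmic_prob = 0.39,
                        het_range = c(15, 95),
                        cox_model = list(base = 0.2, high_load = 0.85,
                                         threshold = 80),
                        n_subjects = 9L) {
  positional_model <- match.arg(positional_model)
  check_probs <- function(p, what) {
    if (!is.null(p) && abs(sum(p) - 1) > 1e-9)
      stop(what, " probabilities must sum to 1")
  }
  check_probs(count_probs, "count")
  check_probs(type_mix, "type_mix")
  check_probs(transition_pairs, "transition pair")
  check_probs(transversion_pairs, "transversion pair")
  if (positional_model == "per_gene_weights" && is.null(gene_weights))
    stop("gene_weights required for per_gene_weights model")
  structure(list(n_cells = as.integer(n_cells), count_probs = count_probs,
                 positional_model = positional_model,
                 gene_weights = gene_weights, type_mix = type_mix,
                 transition_pairs = transition_pairs,
                 transversion_pairs = transversion_pairs,
                 homoplasmic_prob = homoplasmic_prob, het_range = het_range,
                 cox_model = cox_model, n_subjects = as.integer(n_subjects)),
            class = "CohortSpec")
}

## support positions for a positional model
position_support <- function(spec, ann) {
  switch(spec$positional_model,
         uniform_coding = seq.int(CODING_REGION[1L], CODING_REGION[2L]),
         uniform_genome = seq_len(ann$genome$length),
         per_gene_weights = {
           g <- ann$genes[match(names(spec$gene_weights),
                                ann$genes$symbol), ]
           if (anyNA(g$start)) stop("unknown gene in gene_weights")
           unlist(lapply(seq_len(nrow(g)), function(i)
             interval_positions(g$start[i], g$end[i], ann$genome$length)))
         })
}

## per-position sampling weights implementing the per_gene_weights model
position_weights <- function(spec, support, ann) {
  if (spec$positional_model != "per_gene_weights")
    return(rep(1, length(support)))
  g <- ann$genes[match(names(spec$gene_weights), ann$genes$symbol), ]
  w <- rep(spec$gene_weights / (g$end - g$start + 1L),
           times = g$end - g$start + 1L)
  w
}

PAIR_REF <- list(`C:G>T:A` = c(C = "T", G = "A"),
                 `T:A>C:G` = c(T = "C", A = "G"),
                 `C:G>A:T` = c(C = "A", G = "T"),
                 `C:G>G:C` = c(C = "G", G = "C"),
                 `T:A>A:T` = c(T = "A", A = "T"),
                 `T:A>G:C` = c(T = "G", A = "C"))

#' Generate a synthetic mutation cohort
#'
#' Draws a reproducible cohort of point mutations under a `CohortSpec`.
#' Reference bases are read from the genome, so every generated record
#' passes [validate_mutations()]. For substitutions with a pair mix, the
#' target strand-symmetric pair is drawn first and a position whose
#' reference base participates in that pair is then drawn from the
#' positional model, so the requested pair proportions are matched while
#' positions stay (conditionally) uniform; with `transition_pairs = NULL`
#' the position is drawn unconditionally and the transition partner of the
#' reference base is used, giving the exact uniform-placement null.
#'
#' @param spec A `CohortSpec`.
#' @param ann A `MitoAnnotation` (supplies genome and gene coordinates).
#' @param seed Integer seed; the cohort is a pure function of (spec, seed).
#' @param cohort Cohort label for the resulting `MutationSet`.
#' @return A validated `MutationSet`. Cells with zero mutations contribute
#'   no rows; the number of mutation-free cells is recorded in the
#'   `n_cells_without_mutations` attribute.
#' @export
generate_cohort <- function(spec, ann, seed, cohort = "synthetic") {
  genome <- ann$genome
  withr::with_seed(as.integer(seed), {
    counts <- sample(as.integer(names(spec$count_probs)), spec$n_cells,
                     replace = TRUE, prob = spec$count_probs)
    n_mut <- sum(counts)
    support <- position_support(spec, ann)
    w <- position_weights(spec, support, ann)
    ref_all <- ref_base(genome, support)
    kind4 <- sample(names(spec$type_mix), n_mut, replace = TRUE,
                    prob = spec$type_mix)
    position <- integer(n_mut)
    ref <- character(n_mut)
    alt <- character(n_mut)
    kind <- character(n_mut)
    draw_pos <- function(n, ok = TRUE) {
      idx <- which(ok & ref_all != "N")
      idx[sample.int(length(idx), n, replace = TRUE,
                     prob = w[idx] / sum(w[idx]))]
    }
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    for (k in c("transition", "transversion")) {
      which_k <- which(kind4 == k)
      if (!length(which_k)) next
      pairs <- if (k == "transition") spec$transition_pairs
               else spec$transversion_pairs
      if (is.null(pairs)) {
        ## pure placement null: position first, alt follows the ref base
        j <- draw_pos(length(which_k))
        r <- ref_all[j]
        a <- if (k == "transition") unname(ts_partner[r])
             else {
               pick <- ifelse(r %in% PURINES, 1L, 2L)
               cross <- rbind(PYRIMIDINES, PURINES)
               cross[cbind(pick, sample.int(2L, length(r), replace = TRUE))]
             }
      } else {
        ## target pair first, then a position whose ref participates
        pair <- sample(names(pairs), length(which_k), replace = TRUE,
                       prob = pairs)
        j <- integer(length(which_k))
        r <- a <- character(length(which_k))
        for (pl in unique(pair)) {
          grp <- which(pair == pl)
          map <- PAIR_REF[[pl]]
          jj <- draw_pos(length(grp), ref_all %in% names(map))
          j[grp] <- jj
          r[grp] <- ref_all[jj]
          a[grp] <- unname(map[r[grp]])
        }
      }
      position[which_k] <- support[j]
      ref[which_k] <- r
      alt[which_k] <- a
      kind[which_k] <- "substitution"
    }
    dels <- which(kind4 == "deletion")
    if (length(dels)) {
      j <- draw_pos(length(dels))
      position[dels] <- support[j]; ref[dels] <- ref_all[j]
      alt[dels] <- ""; kind[dels] <- "deletion"
    }
    inss <- which(kind4 == "insertion")
    if (length(inss)) {
      j <- draw_pos(length(inss))
      position[inss] <- support[j]; ref[inss] <- ""
      alt[inss] <- sample(c("A", "C", "G", "T"), length(inss),
                          replace = TRUE)
      kind[inss] <- "insertion"
    }
    het <- ifelse(runif(n_mut) < spec$homoplasmic_prob, 100,
                  round(runif(n_mut, spec$het_range[1L],
                              spec$het_range[2L])))
    cell_of <- rep(seq_len(spec$n_cells), times = counts)
    ## unique (cell, position, alt) keys: redraw clashing positions
    for (tries in seq_len(25L)) {
      key <- paste(cell_of, position, alt)
      dup <- which(duplicated(key))
      if (!length(dup)) break
      for (i in dup) {
        j <- draw_pos(1L, if (kind[i] == "substitution" && nzchar(ref[i]))
          ref_all == ref[i] else TRUE)
        position[i] <- support[j]
        if (kind[i] != "insertion") ref[i] <- ref_all[j]
      }
    }
    max_het <- tapply(het, cell_of, max)
    cox_p <- ifelse(max_het[as.character(seq_len(spec$n_cells))] >=
                      spec$cox_model$threshold,
                    spec$cox_model$high_load, spec$cox_model$base)
    cox_p[is.na(cox_p)] <- spec$cox_model$base
    cox_cell <- ifelse(runif(spec$n_cells) < cox_p, "deficient", "positive")
    df <- data.frame(
      cohort = cohort,
      subject_id = sprintf("S%02d", ((cell_of - 1L) %% spec$n_subjects) + 1L),
      cell_id = sprintf("cell%04d", cell_of),
      position = position, ref = ref, alt = alt, kind = kind,
      heteroplasmy_percent = het,
      cox_status = cox_cell[cell_of],
      inheritance = "not_applicable",
      reported_gene = "",
      stringsAsFactors = FALSE)
    ms <- MutationSet(df, cohort = cohort,
                      provenance = sprintf("synthetic cohort, seed %d", seed))
    validate_mutations(ms, genome)
    attr(ms, "n_cells_without_mutations") <- sum(counts == 0L)
    ms
  })
}

#' Generate a synthetic pathogenicity score table
#'
#' Draws one Beta-distributed score per distinct amino-acid variant of a
#' protein-variant enumeration, emulating the marginal structure of
#' published whole-proteome pathogenicity tables (scores in \[0, 1\],
#' unimodal, mean near 0.64). Defaults Beta(5.58, 3.11) match a mean of
#' 0.642 and sd of 0.154.
#'
#' @param enumeration A `VariantEnumeration` from
#'   [enumerate_protein_variants()].
#' @param seed Integer seed.
#' @param shape1,shape2 Beta parameters.
#' @return A `PathogenicityTable` keyed by every distinct missense
#'   `(gene, aa_pos, aa_ref, aa_alt)` of the enumeration.
#' @export
generate_score_table <- function(enumeration, seed, shape1 = 5.58,
                                 shape2 = 3.11) {
  mis <- enumeration$records[enumeration$records$class == "missense",
                             c("gene", "aa_pos", "aa_ref", "aa_alt")]
  mis <- unique(mis)
  rownames(mis) <- NULL
  withr::with_seed(as.integer(seed), {
    mis$score <- rbeta(nrow(mis), shape1, shape2)
  })
  pathogenicity_table(mis)
}

#' Thin non-synonymous mutations to mimic purifying selection
#'
#' Independently retains each non-synonymous protein-gene mutation with the
#' given probability, leaving all other mutations untouched. Used to build
#' power curves for the cross-cohort consequence-spectrum comparison.
#'
#' @param ms A `MutationSet`.
#' @param ann A `MitoAnnotation` (to classify consequences).
#' @param retention Retention probability in \[0, 1\] (1 = no selection,
#'   0 = complete removal of non-synonymous changes).
#' @param seed Integer seed.
#' @return A `MutationSet` with the thinned record set.
#' @export
spike_selection <- function(ms, ann, retention, seed) {
  if (!is.numeric(retention) || retention < 0 || retention > 1)
    stop("retention must be in [0, 1]")
  annotated <- annotate_mutations(ms, ann)
  withr::with_seed(as.integer(seed), {
    nonsyn <- annotated$change_class == "non_synonymous"
    drop <- nonsyn & runif(nrow(annotated)) >= retention
    out <- ms
    out$mutations <- ms$mutations[!drop, , drop = FALSE]
    rownames(out$mutations) <- NULL
    out
  })
}
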