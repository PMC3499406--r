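#' Null calibration of the goodness-of-fit tests
#'
#' Simulates cohorts of `n` mutations placed uniformly over the coding
#' region (the random-placement null of [generate_cohort()] with
#' unconditional position draws) and computes, for each replicate, the
#' positional-bin and gene-type goodness-of-fit p-values. Used to verify
#' that both tests reject at their nominal rate under the null.
#'
#' @param ann A `MitoAnnotation`.
#' @param n Mutations per replicate (cohort size).
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param bin_size Positional bin width.
#' @param alpha Nominal significance level for the reported rejection rates.
#' @return List with `positional_p`, `gene_type_p` (vectors of length
#'   `reps`) and `rejection_rates` (named, at `alpha`).
#' @export
gof_null_calibration <- function(ann, n = 117L, reps = 10000L, seed = 1L,
                                 bin_size = 2000L, alpha = 0.05) {
  support <- seq.int(CODING_REGION[1L], CODING_REGION[2L])
  ## positional bins (merged trailing bin, as in positional_bins)
  template <- positional_bins(
    MutationSet(data.frame(position = support[1L], ref = "A", alt = "G",
                           kind = "substitution", cell_id = "c1",
                           stringsAsFactors = FALSE)),
    bin_size = bin_size)
  starts <- as.integer(sub("-.*", "", template$category))
  bin_prob <- template$expected / sum(template$expected)
  lens <- gene_type_lengths(ann, CODING_REGION)[c("protein", "tRNA", "rRNA")]
  withr::with_seed(as.integer(seed), {
    pos <- matrix(sample(support, n * reps, replace = TRUE), nrow = reps)
    ## positional GOF, vectorized across replicates
    bin_idx <- matrix(findInterval(pos, starts), nrow = reps)
    nb <- length(starts)
    obs_b <- matrix(tabulate(bin_idx + nb * (row(bin_idx) - 1L),
                             nbins = nb * reps),
                    nrow = reps, byrow = TRUE)
    exp_b <- matrix(n * bin_prob, nrow = reps, ncol = nb, byrow = TRUE)
    x2_b <- rowSums((obs_b - exp_b)^2 / exp_b)
    p_pos <- pchisq(x2_b, nb - 1L, lower.tail = FALSE)
    ## gene-type GOF: classify positions, drop intra-coding gaps
    cls <- matrix(ann$class_map[pos], nrow = reps)
    obs_t <- vapply(1:3, function(k) rowSums(cls == k), numeric(reps))
    tot <- rowSums(obs_t)
    exp_t <- outer(tot, as.numeric(lens) / sum(lens))
    x2_t <- rowSums((obs_t - exp_t)^2 / exp_t)
    p_type <- pchisq(x2_t, 2L, lower.tail = FALSE)
  })
  list(positional_p = p_pos, gene_type_p = p_type,
       rejection_rates = c(positional = mean(p_pos < alpha),
                           gene_type = mean(p_type < alpha)))
}

#' Power of the consequence-spectrum comparison under purifying selection
#'
#' Estimates the power of [contingency_compare()] to detect a depletion of
#' non-synonymous mutations (binomial thinning with the given retention) by
#' comparing a thinned cohort of size about `n1` against an unthinned
#' cohort of size `n2`, over `reps` simulated pairs.
#'
#' @param ann A `MitoAnnotation`.
#' @param enumeration A `VariantEnumeration` (supplies the per-class
#'   substitution pool the cohorts are drawn from).
#' @param retention Non-synonymous retention probability under selection.
#' @param n1,n2 Protein-gene cohort sizes of the two groups.
#' @param reps Number of simulated pairs.
#' @param seed Integer seed.
#' @param alpha Significance level of the pairwise test.
#' @return List with `power` and the per-replicate p-values.
#' @export
selection_power <- function(ann, enumeration, retention = 0.5, n1 = 81L,
                            n2 = 155L, reps = 1000L, seed = 1L,
                            alpha = 0.05) {
  cls <- enumeration$records$class
  base_p <- c(non_synonymous = mean(cls == "missense" | cls == "stop_gain"),
              synonymous = mean(cls == "synonymous"))
  sel_p <- base_p
  sel_p["non_synonymous"] <- sel_p["non_synonymous"] * retention
  sel_p <- sel_p / sum(sel_p)
  base_p <- base_p / sum(base_p)
  withr::with_seed(as.integer(seed), {
    p <- vapply(seq_len(reps), function(i) {
      o1 <- stats::rbinom(1L, n1, sel_p["non_synonymous"])
      o2 <- stats::rbinom(1L, n2, base_p["non_synonymous"])
      tab <- rbind(non_synonymous = c(o1, o2),
                   synonymous = c(n1 - o1, n2 - o2))
      colnames(tab) <- c("selected", "unselected")
      contingency_compare(tab)$overall$p_value
    }, numeric(1L))
  })
  list(power = mean(p < alpha), p_values = p)
}

## change-type and gene-type categorizers used by the pipeline
categorize_change_type <- function(ms) {
  df <- as.data.frame(ms)
  ct <- classify_change_type(df$ref, df$alt, df$kind)
  ifelse(ct %in% c("insertion", "deletion"), "indel", ct)
}

#' Run the full comparative mutation-spectrum analysis
#'
#' Orchestrates the complete analysis over one or more cohorts: validation
#' and coding-region filtering (with a before/after audit log), per-cohort
#' spectrum tables (gene-type, change-type, consequence-class percentages),
#' positional and gene-type goodness-of-fit tests per cohort, pairwise
#' cross-cohort contingency comparisons with Bonferroni thresholds, and -
#' when a score table is supplied - pathogenicity summaries and pairwise
#' Wilcoxon rank-sum comparisons (with and without the synonymous-as-zero
#' convention), an all-possible-variants comparison, and an
#' inherited-versus-sporadic comparison for cohorts carrying inheritance
#' labels. Without a score table, score stages are skipped with a warning
#' and the spectrum stages still run.
#'
#' @param cohorts Named list of `MutationSet`s.
#' @param ann A `MitoAnnotation`.
#' @param score_table Optional `PathogenicityTable`.
#' @param bin_size Positional bin width (default 2000).
#' @param coding_bounds Analyzed region (default 577-16023).
#' @param synonymous_as_zero Convention for the inclusive score analysis.
#' @param outdir Optional directory: TSV/JSON result files are written there.
#' @return A `mito_spectrum_report` list with elements `log`, `spectra`,
#'   `gof`, `contingency`, `scores`.
#' @export
run_full_analysis <- function(cohorts, ann, score_table = NULL,
                              bin_size = 2000L,
                              coding_bounds = CODING_REGION,
                              synonymous_as_zero = TRUE, outdir = NULL) {
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    stop("cohorts must be a named list")
  log <- list()
  filtered <- list()
  annotated <- list()
  for (nm in names(cohorts)) {
    ms <- cohorts[[nm]]
    validate_mutations(ms, ann$genome)
    fc <- filter_coding_region(ms, coding_bounds)
    log[[nm]] <- data.frame(cohort = nm, n_input = length(ms),
                            n_coding = length(fc),
                            n_excluded_control_region = attr(fc, "excluded"))
    filtered[[nm]] <- fc
    annotated[[nm]] <- annotate_mutations(fc, ann)
  }
  log <- do.call(rbind, log)

  spectra <- lapply(names(filtered), function(nm) {
    ann_df <- annotated[[nm]]
    gene_type <- table(factor(region_class(ann, ann_df$position),
                              levels = REGION_CLASSES))
    change_type <- table(factor(categorize_change_type(filtered[[nm]]),
                                levels = c("transition", "transversion",
                                           "indel")))
    list(cohort = nm,
         gene_type = data.frame(
           type = names(gene_type), n = as.integer(gene_type),
           pct = round(100 * as.integer(gene_type) /
                         max(1L, sum(gene_type)), 1L)),
         change_type = data.frame(
           type = names(change_type), n = as.integer(change_type),
           pct = round(100 * as.integer(change_type) /
                         max(1L, sum(change_type)), 1L)),
         consequence = consequence_spectrum(ann_df))
  })
  names(spectra) <- names(filtered)

  gof <- lapply(names(filtered), function(nm) {
    ms <- filtered[[nm]]
    if (length(ms) == 0L) return(NULL)
    list(positional = chisq_goodness_of_fit(
           positional_bins(ms, bin_size = bin_size, region = coding_bounds)),
         gene_type = gene_type_gof(ms, ann, region = coding_bounds))
  })
  names(gof) <- names(filtered)

  contingency <- NULL
  if (length(filtered) >= 2L) {
    contingency <- list(
      gene_type = contingency_compare(
        filtered, function(ms)
          region_class(ann, as.data.frame(ms)$position)),
      change_type = contingency_compare(filtered, categorize_change_type),
      consequence = contingency_compare(
        lapply(annotated, function(a)
          a[a$gene_type == "protein", , drop = FALSE]),
        function(a) ifelse(a$change_class %in%
                             c("frameshift", "premature_termination",
                               "stop_loss"),
                           "frameshift_premature_termination",
                           a$change_class)))
  }

  scores <- NULL
  if (is.null(score_table)) {
    warning("no score table supplied; pathogenicity stages skipped")
  } else {
    scored_strict <- lapply(annotated, score_mutations, table = score_table,
                            synonymous_as_zero = FALSE)
    scored_incl <- lapply(annotated, score_mutations, table = score_table,
                          synonymous_as_zero = synonymous_as_zero)
    summaries <- lapply(scored_strict, function(s)
      tryCatch(summarize_scores(s), error = function(e) NULL))
    pairwise_wilcoxon <- function(scored) {
      nms <- names(scored)
      pairs <- utils::combn(length(nms), 2L)
      k <- ncol(pairs)
      thr <- bonferroni_thresholds(k)
      do.call(rbind, lapply(seq_len(k), function(j) {
        a <- retained_scores(scored[[pairs[1L, j]]])
        b <- retained_scores(scored[[pairs[2L, j]]])
        if (!length(a) || !length(b)) return(NULL)
        r <- wilcoxon_rank_sum(a, b)
        data.frame(pair = paste(nms[pairs[, j]], collapse = " vs "),
                   statistic = r$statistic, p_value = r$p_value,
                   stars = star_label(r$p_value, thr))
      }))
    }
    scores <- list(
      summaries = summaries,
      wilcoxon_nonsynonymous = if (length(annotated) >= 2L)
        pairwise_wilcoxon(scored_strict),
      wilcoxon_with_synonymous = if (length(annotated) >= 2L)
        pairwise_wilcoxon(scored_incl))
    ## each cohort against the full table of all possible variants
    scores$vs_all_possible <- do.call(rbind, lapply(names(scored_strict),
      function(nm) {
        a <- retained_scores(scored_strict[[nm]])
        if (!length(a)) return(NULL)
        r <- wilcoxon_rank_sum(a, score_table$score)
        data.frame(cohort = nm, statistic = r$statistic,
                   p_value = r$p_value)
      }))
    ## inherited vs sporadic within cohorts that carry the labels
    inh <- lapply(names(annotated), function(nm) {
      a <- scored_strict[[nm]]
      grp <- a$inheritance
      if (!any(grp %in% c("inherited", "sporadic"))) return(NULL)
      xi <- retained_scores(a[grp == "inherited", , drop = FALSE])
      xs <- retained_scores(a[grp == "sporadic", , drop = FALSE])
      if (!length(xi) || !length(xs)) return(NULL)
      r <- wilcoxon_rank_sum(xs, xi)
      data.frame(cohort = nm, n_sporadic = length(xs),
                 n_inherited = length(xi),
                 mean_sporadic = mean(xs), mean_inherited = mean(xi),
                 p_value = r$p_value)
    })
    scores$inherited_vs_sporadic <- do.call(rbind, inh)
  }

  report <- structure(list(log = log, spectra = spectra, gof = gof,
                           contingency = contingency, scores = scores),
                      class = "mito_spectrum_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.mito_spectrum_report <- function(x, ...) {
  cat("Mitochondrial mutation-spectrum report\n")
  cat("Cohort funnel:\n")
  print(x$log, row.names = FALSE)
  for (nm in names(x$spectra)) {
    s <- x$spectra[[nm]]
    cat("\n[", nm, "] consequence spectrum (protein genes):\n", sep = "")
    print(s$consequence, row.names = FALSE)
    if (!is.null(x$gof[[nm]]))
      cat("  positional GOF p = ",
          signif(x$gof[[nm]]$positional$p_value, 3),
          "; gene-type GOF p = ",
          signif(x$gof[[nm]]$gene_type$p_value, 3), "\n", sep = "")
  }
  if (!is.null(x$contingency)) {
    cat("\nPairwise consequence-class contingency:\n")
    print(x$contingency$consequence$pairwise, row.names = FALSE)
  }
  if (!is.null(x$scores) && !is.null(x$scores$summaries)) {
    cat("\nPathogenicity score summaries (non-synonymous only):\n")
    for (nm in names(x$scores$summaries))
      if (!is.null(x$scores$summaries[[nm]])) {
        cat("  ", nm, ": ", sep = ""); print(x$scores$summaries[[nm]])
      }
  }
  invisible(x)
}

## flat TSV/JSON emission of a report bundle
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$log, file.path(outdir, "filter_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(report$spectra)) {
    s <- report$spectra[[nm]]
    for (part in c("gene_type", "change_type", "consequence"))
      write.table(s[[part]],
                  file.path(outdir, paste0(nm, "_", part, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- list(
    gof = lapply(report$gof, function(g) if (!is.null(g)) list(
      positional = list(statistic = g$positional$statistic,
                        df = g$positional$df, p = g$positional$p_value),
      gene_type = list(statistic = g$gene_type$statistic,
                       df = g$gene_type$df, p = g$gene_type$p_value))),
    contingency = lapply(report$contingency, function(cc) list(
      overall_p = cc$overall$p_value, pairwise = cc$pairwise,
      thresholds = as.list(cc$thresholds))),
    scores = if (!is.null(report$scores)) list(
      summaries = lapply(report$scores$summaries, function(s)
        if (!is.null(s)) list(mean = s$mean, sd = s$sd, n = s$n)),
      wilcoxon_nonsynonymous = report$scores$wilcoxon_nonsynonymous,
      wilcoxon_with_synonymous = report$scores$wilcoxon_with_synonymous,
      vs_all_possible = report$scores$vs_all_possible,
      inherited_vs_sporadic = report$scores$inherited_vs_sporadic))
  jsonlite::write_json(json, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(outdir)
}
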