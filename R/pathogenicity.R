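#' Load a precomputed pathogenicity score table
#'
#' Reads a tab- or comma-separated table of per-residue-substitution
#' pathogenicity scores (one row per amino-acid variant, as published for
#' MutPred-style predictors) with columns `gene`, `aa_pos`, `aa_ref`,
#' `aa_alt`, `score`. Scores are probabilities in \[0, 1\]; higher means more
#' likely pathogenic. Scores are consumed, never computed here.
#'
#' @param path Path to the delimited file.
#' @return A `PathogenicityTable` (data.frame with a lookup key).
#' @export
load_score_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  pathogenicity_table(df)
}

#' Construct a PathogenicityTable from a data frame
#'
#' @param df Data frame with columns `gene`, `aa_pos`, `aa_ref`, `aa_alt`,
#'   `score`.
#' @return A validated `PathogenicityTable`.
#' @export
pathogenicity_table <- function(df) {
  need <- c("gene", "aa_pos", "aa_ref", "aa_alt", "score")
  if (!all(need %in% names(df)))
    stop("score table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[, need]
  df$aa_pos <- as.integer(df$aa_pos)
  df$score <- as.numeric(df$score)
  if (any(is.na(df$score) | df$score < 0 | df$score > 1))
    stop("scores outside [0, 1] in rows: ",
         paste(which(is.na(df$score) | df$score < 0 | df$score > 1),
               collapse = ", "))
  key <- variant_key(df$gene, df$aa_pos, df$aa_ref, df$aa_alt)
  if (anyDuplicated(key))
    stop("duplicate variant keys in rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  attr(df, "key") <- key
  class(df) <- c("PathogenicityTable", "data.frame")
  df
}

variant_key <- function(gene, aa_pos, aa_ref, aa_alt) {
  paste(gene, aa_pos, aa_ref, aa_alt, sep = "|")
}

#' @export
print.PathogenicityTable <- function(x, ...) {
  cat("PathogenicityTable: ", nrow(x), " amino-acid variants, score range [",
      if (nrow(x)) round(min(x$score), 3) else NA, ", ",
      if (nrow(x)) round(max(x$score), 3) else NA, "]\n", sep = "")
  invisible(x)
}

#' Attach pathogenicity scores to annotated mutations
#'
#' Looks up each protein-gene non-synonymous substitution in the score table
#' by its amino-acid change. Synonymous substitutions are scored 0 when
#' `synonymous_as_zero` is on (they do not change a residue and are very
#' unlikely to have a functional effect), otherwise excluded. Frameshift,
#' premature-termination and stop-loss changes are always unscored (the
#' predictors behind these tables analyse residue substitutions only), as
#' are RNA-gene and noncoding mutations. Lookup misses are flagged, not
#' errors.
#'
#' @param annotated Data frame from [annotate_mutations()].
#' @param table A `PathogenicityTable`.
#' @param synonymous_as_zero Score synonymous changes as 0 and include them.
#' @param collapse_duplicates Count each distinct (gene, aa_change) variant
#'   once even if observed in several cells (default `FALSE`: every observed
#'   mutation contributes).
#' @return A `ScoredSet`: the annotated rows plus `score` and `score_status`
#'   (`scored` / `synonymous_zero` / `unscored_missing` /
#'   `excluded_<reason>`), with the convention recorded in attributes.
#' @export
score_mutations <- function(annotated, table, synonymous_as_zero = TRUE,
                            collapse_duplicates = FALSE) {
  df <- annotated
  if (collapse_duplicates) {
    k <- variant_key(df$gene, df$aa_pos, df$aa_ref, df$aa_alt)
    k[is.na(df$aa_ref)] <- paste0("row", which(is.na(df$aa_ref)))
    df <- df[!duplicated(k), , drop = FALSE]
  }
  df$score <- NA_real_
  df$score_status <- "excluded_not_protein_substitution"
  is_nonsyn <- df$gene_type == "protein" & df$change_class == "non_synonymous"
  is_syn <- df$gene_type == "protein" & df$change_class == "synonymous"
  trunc <- df$change_class %in% c("frameshift", "premature_termination",
                                  "stop_loss")
  df$score_status[trunc] <- "excluded_truncating"
  hit <- match(variant_key(df$gene, df$aa_pos, df$aa_ref, df$aa_alt),
               attr(table, "key"))
  df$score[is_nonsyn] <- table$score[hit[is_nonsyn]]
  df$score_status[is_nonsyn] <-
    ifelse(is.na(df$score[is_nonsyn]), "unscored_missing", "scored")
  if (synonymous_as_zero) {
    df$score[is_syn] <- 0
    df$score_status[is_syn] <- "synonymous_zero"
  } else {
    df$score_status[is_syn] <- "excluded_synonymous"
  }
  structure(df, synonymous_as_zero = synonymous_as_zero,
            collapse_duplicates = collapse_duplicates,
            class = c("ScoredSet", "data.frame"))
}

#' Scores retained for analysis from a ScoredSet
#'
#' @param scored A `ScoredSet`.
#' @return Numeric vector of the scored values (lookup misses and excluded
#'   classes dropped).
#' @export
retained_scores <- function(scored) {
  scored$score[scored$score_status %in% c("scored", "synonymous_zero")]
}

#' Summarize a score distribution
#'
#' Mean, sample standard deviation (n - 1 denominator) and count over the
#' scored entries only, matching the mean +/- sd (n) convention used when
#' reporting pathogenicity-score comparisons.
#'
#' @param scored A `ScoredSet` or a bare numeric vector of scores.
#' @return List with `mean`, `sd`, `n` (class `SummaryStats`).
#' @export
summarize_scores <- function(scored) {
  x <- if (is.numeric(scored)) scored else retained_scores(scored)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no scored entries to summarize")
  structure(list(mean = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else 0,
                 n = length(x)),
            class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("%.3f +/- %.3f (sd), n = %d\n", x$mean, x$sd, x$n))
  invisible(x)
}
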