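MUTATION_COLUMNS <- c("cohort", "subject_id", "cell_id", "position", "ref",
                      "alt", "kind", "heteroplasmy_percent", "cox_status",
                      "inheritance", "reported_gene")

#' Construct a MutationSet
#'
#' A `MutationSet` is the container for one cohort of mitochondrial point
#' mutations (substitutions and small indels) on rCRS coordinates.
#'
#' @param mutations Data frame in the mutation-table schema (see
#'   [read_mutation_table()]).
#' @param cohort Cohort label, e.g. `"ageing"`, `"population"`, `"disease"`,
#'   `"other_tissue"`.
#' @param provenance Free-text provenance note.
#' @return A `MutationSet` object.
#' @export
MutationSet <- function(mutations, cohort = "unlabelled",
                        provenance = "") {
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  key <- paste(mutations$cell_id, mutations$position, mutations$alt, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cell_id, position, alt) records: rows ",
         paste(which(duplicated(key)), collapse = ", "))
  mutations$cohort <- rep(cohort, nrow(mutations))
  structure(list(mutations = mutations, cohort = cohort,
                 provenance = provenance),
            class = "MutationSet")
}

#' @export
print.MutationSet <- function(x, ...) {
  cat("MutationSet [", x$cohort, "]: ", nrow(x$mutations), " mutations in ",
      length(unique(x$mutations$cell_id)), " cells\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.MutationSet <- function(x, ...) x$mutations

#' Number of mutations in a MutationSet
#' @param x A `MutationSet`.
#' @export
length.MutationSet <- function(x) nrow(x$mutations)

## classify a ref/alt pair into substitution/insertion/deletion
infer_kind <- function(ref, alt) {
  ref <- ifelse(is.na(ref) | ref %in% c("-", "."), "", ref)
  alt <- ifelse(is.na(alt) | alt %in% c("-", "."), "", alt)
  kind <- rep(NA_character_, length(ref))
  kind[nchar(ref) >= 1L & nchar(alt) == 0L] <- "deletion"
  kind[nchar(ref) == 0L & nchar(alt) >= 1L] <- "insertion"
  kind[nchar(ref) == 1L & nchar(alt) == 1L] <- "substitution"
  kind
}

#' Read a cohort mutation table
#'
#' Parses a delimited mutation table (comma or tab, sniffed from the header
#' line) with at least the columns `position`, `ref`, `alt`. The full schema
#' is `cohort, subject_id, cell_id, position, ref, alt, kind,
#' heteroplasmy_percent, cox_status, inheritance, reported_gene`; absent
#' columns are filled with defaults, unknown columns are preserved.
#' `"."` or an empty field marks unknown heteroplasmy; `"-"`, `"."` or empty
#' marks the missing side of an indel. When a genome is supplied, `ref` of
#' every substitution and deletion is checked against the reference and
#' mismatches are reported with their row numbers.
#'
#' @param path Path to the delimited file.
#' @param cohort Cohort label stamped on every record.
#' @param genome Optional `MitoGenome` for reference validation.
#' @return A validated `MutationSet`.
#' @export
read_mutation_table <- function(path, cohort = "unlabelled", genome = NULL) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("position", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("mutation table missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$position <- suppressWarnings(as.integer(df$position))
  if (anyNA(df$position))
    stop("unparseable position in rows: ",
         paste(which(is.na(df$position)), collapse = ", "))
  df$ref <- toupper(ifelse(df$ref %in% c("-", ".", NA), "", df$ref))
  df$alt <- toupper(ifelse(df$alt %in% c("-", ".", NA), "", df$alt))
  n <- nrow(df)
  if (is.null(df$kind) || all(!nzchar(df$kind))) df$kind <- infer_kind(df$ref, df$alt)
  if (is.null(df$heteroplasmy_percent))
    df$heteroplasmy_percent <- rep(NA_real_, n)
  df$heteroplasmy_percent <- suppressWarnings(as.numeric(
    ifelse(df$heteroplasmy_percent %in% c(".", ""), NA,
           df$heteroplasmy_percent)))
  for (col in c("subject_id", "cell_id", "reported_gene"))
    if (is.null(df[[col]])) df[[col]] <- rep("", n)
  if (is.null(df$cox_status) || all(!nzchar(df$cox_status)))
    df$cox_status <- rep("unknown", n)
  if (is.null(df$inheritance) || all(!nzchar(df$inheritance)))
    df$inheritance <- rep("not_applicable", n)
  ms <- MutationSet(df, cohort = cohort, provenance = path)
  validate_mutations(ms, genome)
  ms
}

#' Validate a MutationSet against its invariants
#'
#' Checks positional bounds, the substitution/insertion/deletion shape
#' invariants, heteroplasmy range, and (when a genome is given) agreement of
#' `ref` with the reference base at `position`. All violations are collected
#' and reported together with row numbers.
#'
#' @param ms A `MutationSet`.
#' @param genome Optional `MitoGenome`.
#' @return `ms` invisibly; errors on any violation.
#' @export
validate_mutations <- function(ms, genome = NULL) {
  df <- ms$mutations
  bad <- character()
  row_msg <- function(rows, what)
    if (length(rows)) paste0(what, " in rows: ", paste(rows, collapse = ", "))
  L <- if (is.null(genome)) GENOME_LENGTH else genome$length
  bad <- c(bad, row_msg(which(df$position < 1L | df$position > L),
                        "position out of range"))
  bad <- c(bad, row_msg(which(is.na(df$kind)), "unclassifiable ref/alt"))
  sub <- which(df$kind == "substitution")
  bad <- c(bad, row_msg(sub[nchar(df$ref[sub]) != 1L |
                              nchar(df$alt[sub]) != 1L |
                              df$ref[sub] == df$alt[sub]],
                        "invalid substitution"))
  bad <- c(bad, row_msg(which(df$kind == "deletion" &
                                (!nzchar(df$ref) | nzchar(df$alt))),
                        "invalid deletion"))
  bad <- c(bad, row_msg(which(df$kind == "insertion" &
                                (nzchar(df$ref) | !nzchar(df$alt))),
                        "invalid insertion"))
  het <- df$heteroplasmy_percent
  bad <- c(bad, row_msg(which(!is.na(het) & (het < 0 | het > 100)),
                        "heteroplasmy outside 0-100"))
  if (!is.null(genome)) {
    chk <- which(df$kind %in% c("substitution", "deletion") &
                   df$position >= 1L & df$position <= L)
    if (length(chk)) {
      want <- substring(genome$sequence, df$position[chk],
                        df$position[chk] + nchar(df$ref[chk]) - 1L)
      bad <- c(bad, row_msg(chk[df$ref[chk] != want],
                            "ref does not match reference"))
    }
  }
  bad <- bad[nzchar(bad)]
  if (length(bad)) stop("mutation table validation failed:\n  ",
                        paste(bad, collapse = "\n  "))
  invisible(ms)
}

#' Write a MutationSet to a tab-separated table
#'
#' Emits the canonical column schema (plus any extra columns present) so
#' that reading the file back reproduces the set.
#'
#' @param ms A `MutationSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(ms, path) {
  df <- ms$mutations
  first <- intersect(MUTATION_COLUMNS, names(df))
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Restrict a MutationSet to the coding region
#'
#' Keeps mutations whose position lies inside the coding span of the genome
#' (default 577-16023, i.e. everything outside the control region), in the
#' original order. The number excluded is recorded in the `excluded`
#' attribute.
#'
#' @param ms A `MutationSet`.
#' @param bounds Inclusive `c(start, end)` of the analyzed region.
#' @return Filtered `MutationSet`.
#' @export
filter_coding_region <- function(ms, bounds = CODING_REGION) {
  keep <- ms$mutations$position >= bounds[1L] &
    ms$mutations$position <= bounds[2L]
  out <- ms
  out$mutations <- ms$mutations[keep, , drop = FALSE]
  rownames(out$mutations) <- NULL
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Per-cell mutation burden and homoplasmy profile
#'
#' Summarizes a cohort by cell: mutation count per cell, homoplasmic count
#' (homoplasmy defined as a recorded heteroplasmy of exactly 100%), the
#' count histogram, and the homoplasmic fraction of all mutations.
#'
#' @param ms A `MutationSet` with `cell_id` populated.
#' @return List with `cells` (data.frame: cell_id, n_mutations,
#'   n_homoplasmic), `count_histogram` (table of mutations per cell),
#'   `homoplasmic_fraction`.
#' @export
cell_mutation_profile <- function(ms) {
  df <- ms$mutations
  if (nrow(df) == 0L)
    return(list(cells = data.frame(cell_id = character(),
                                   n_mutations = integer(),
                                   n_homoplasmic = integer()),
                count_histogram = table(integer()),
                homoplasmic_fraction = NaN))
  if (any(!nzchar(df$cell_id))) stop("cell_id must be populated")
  homo <- !is.na(df$heteroplasmy_percent) & df$heteroplasmy_percent == 100
  n <- tapply(rep(1L, nrow(df)), df$cell_id, sum)
  h <- tapply(homo, df$cell_id, sum)
  cells <- data.frame(cell_id = names(n), n_mutations = as.integer(n),
                      n_homoplasmic = as.integer(h[names(n)]),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(cells = cells,
       count_histogram = table(cells$n_mutations),
       homoplasmic_fraction = mean(homo))
}

#' Export a MutationSet as a minimal VCF
#'
#' Writes a minimal VCF 4.2 file (`CHROM = chrMT`), using the anchor-base
#' convention for indels: a deletion of bases at `position` is emitted at
#' `position - 1` with the preceding reference base as anchor, an insertion
#' before `position` likewise.
#'
#' @param ms A `MutationSet`.
#' @param genome A `MitoGenome` (supplies anchor bases).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ms, genome, path) {
  df <- ms$mutations
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=chrMT,length=", genome$length, ">"),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(df)) {
    pos <- df$position
    ref <- df$ref
    alt <- df$alt
    anchor_at <- pmax(pos - 1L, 1L)
    anchor <- ref_base(genome, anchor_at)
    is_del <- df$kind == "deletion"
    is_ins <- df$kind == "insertion"
    out_pos <- ifelse(is_del | is_ins, anchor_at, pos)
    out_ref <- ifelse(is_del, paste0(anchor, ref), ifelse(is_ins, anchor, ref))
    out_alt <- ifelse(is_del, anchor, ifelse(is_ins, paste0(anchor, alt), alt))
    ord <- order(out_pos)
    lines <- c(lines, paste("chrMT", out_pos[ord], ".", out_ref[ord],
                            out_alt[ord], ".", "PASS", ".", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
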