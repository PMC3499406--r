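#' @importFrom stats pchisq rbeta runif setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

GENOME_LENGTH <- 16569L
CODING_REGION <- c(577L, 16023L)
REGION_CLASSES <- c("protein", "tRNA", "rRNA", "noncoding")

#' The vertebrate mitochondrial genetic code
#'
#' Returns the codon-to-amino-acid map for NCBI translation table 2
#' (vertebrate mitochondrial), in which `TGA` encodes tryptophan, `ATA`
#' encodes methionine, and `AGA`/`AGG` are stop codons, giving exactly four
#' stops (`TAA`, `TAG`, `AGA`, `AGG`).
#'
#' @return Named character vector of length 64 mapping codons (DNA alphabet)
#'   to one-letter amino acids, with `"*"` for stop.
#' @examples
#' code <- mito_genetic_code()
#' code[c("TGA", "ATA", "AGA")]
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("2")
  stopifnot(length(code) == 64L, sum(code == "*") == 4L)
  code
}

#' Load a mitochondrial reference genome from FASTA
#'
#' Reads a single-record FASTA file holding a circular mitochondrial genome
#' on rCRS-style 1-based coordinates. The historical placeholder base `N`
#' (position 3107 in the rCRS) is retained so that coordinates match
#' m.-notation.
#'
#' @param path Path to a single-record FASTA file.
#' @return A `MitoGenome` object: list with `name`, `sequence` (single
#'   character string over A/C/G/T/N), `length`, and `circular = TRUE`.
#' @export
load_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("reference FASTA must contain exactly one record, found ", length(set))
  seq <- toupper(as.character(set[[1L]]))
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop("reference contains non-nucleotide characters: ",
         paste(unique(strsplit(bad, "")[[1L]]), collapse = ", "))
  MitoGenome(names(set)[1L], seq)
}

#' Construct a MitoGenome object
#'
#' @param name Sequence name.
#' @param sequence Single character string over A/C/G/T/N.
#' @return A `MitoGenome` object.
#' @export
MitoGenome <- function(name, sequence) {
  structure(
    list(name = name, sequence = sequence,
         length = nchar(sequence), circular = TRUE),
    class = "MitoGenome")
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat("MitoGenome <", x$name, ">: ", x$length,
      " bp, circular\n", sep = "")
  invisible(x)
}

#' Write a MitoGenome to FASTA
#'
#' @param genome A `MitoGenome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reference base(s) at given positions
#'
#' @param genome A `MitoGenome`.
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(genome, positions) {
  positions <- as.integer(positions)
  if (any(is.na(positions)) || any(positions < 1L | positions > genome$length))
    stop("positions out of range 1..", genome$length)
  substring(genome$sequence, positions, positions)
}

## wrap-aware expansion of an interval to a position vector
interval_positions <- function(start, end, genome_length) {
  if (start <= end) seq.int(start, end)
  else c(seq.int(start, genome_length), seq.int(1L, end))
}

#' Load a gene annotation for a mitochondrial genome
#'
#' Reads a tab-separated gene table (columns `symbol`, `gene_type`, `start`,
#' `end`, `strand`, `incomplete_stop_len`) and binds it to a genome. The
#' bundled default transcribes the NC_012920.1 (rCRS) feature table: 13
#' protein-coding genes, 22 tRNAs, 2 rRNAs, and the control region, which
#' wraps the origin (16024-576). Coordinates are 1-based inclusive on the
#' heavy strand; L-strand genes carry `strand = "L"`.
#'
#' @param genome A `MitoGenome` of matching length.
#' @param path Path to the annotation TSV; defaults to the bundled rCRS table.
#' @return A `MitoAnnotation`: list with `genes` (data.frame), `genome`, and a
#'   precomputed per-position `class_map` used for region classification.
#' @export
mito_annotation <- function(genome, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rcrs_genes.tsv", package = "mitospectra",
                        mustWork = TRUE)
  genes <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "gene_type", "start", "end", "strand",
            "incomplete_stop_len")
  if (!all(need %in% names(genes)))
    stop("annotation table missing columns: ",
         paste(setdiff(need, names(genes)), collapse = ", "))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$incomplete_stop_len <- as.integer(genes$incomplete_stop_len)
  if (!all(genes$gene_type %in% REGION_CLASSES))
    stop("unknown gene_type values")
  if (!all(genes$strand %in% c("H", "L")))
    stop("strand must be H or L")
  pro <- genes[genes$gene_type == "protein", ]
  cds_len <- pro$end - pro$start + 1L - pro$incomplete_stop_len
  if (any(cds_len %% 3L != 0L))
    stop("protein gene length minus incomplete stop not divisible by 3: ",
         paste(pro$symbol[cds_len %% 3L != 0L], collapse = ", "))
  ann <- structure(list(genes = genes, genome = genome), class = "MitoAnnotation")
  ann$class_map <- build_class_map(ann)
  ann
}

#' @export
print.MitoAnnotation <- function(x, ...) {
  tt <- table(x$genes$gene_type)
  cat("MitoAnnotation: ", nrow(x$genes), " records (",
      paste(names(tt), tt, sep = "=", collapse = ", "),
      ") on ", x$genome$length, " bp genome\n", sep = "")
  invisible(x)
}

## one class per base under the precedence protein > tRNA > rRNA > noncoding
build_class_map <- function(ann) {
  L <- ann$genome$length
  cls <- rep.int(4L, L)  # noncoding
  prec <- c(protein = 1L, tRNA = 2L, rRNA = 3L, noncoding = 4L)
  for (type in c("rRNA", "tRNA", "protein")) {
    rows <- ann$genes[ann$genes$gene_type == type, ]
    for (i in seq_len(nrow(rows))) {
      pos <- interval_positions(rows$start[i], rows$end[i], L)
      cls[pos] <- pmin(cls[pos], prec[[type]])
    }
  }
  cls
}

#' Genes overlapping a position
#'
#' Returns every annotated gene whose (wrap-aware) interval contains the
#' position, in genome order. Intergenic and control-region positions return
#' zero gene rows (the control-region record itself is not a gene).
#'
#' @param ann A `MitoAnnotation`.
#' @param position Single 1-based position.
#' @return Data frame of gene records (possibly zero rows).
#' @export
genes_at <- function(ann, position) {
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > ann$genome$length)
    stop("position must be a single coordinate in 1..", ann$genome$length)
  g <- ann$genes[ann$genes$gene_type != "noncoding", ]
  wraps <- g$start > g$end
  hit <- (!wraps & g$start <= position & position <= g$end) |
    (wraps & (position >= g$start | position <= g$end))
  g[hit, , drop = FALSE]
}

#' Single-class region label for positions
#'
#' Resolves each position to one of `protein`, `tRNA`, `rRNA`, `noncoding`
#' under the overlap precedence protein > tRNA > rRNA > noncoding, so that
#' every base of the genome receives exactly one class and spectrum tables
#' have totals equal to cohort sizes.
#'
#' @param ann A `MitoAnnotation`.
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of region classes.
#' @export
region_class <- function(ann, positions) {
  positions <- as.integer(positions)
  if (any(is.na(positions)) ||
      any(positions < 1L | positions > ann$genome$length))
    stop("positions out of range 1..", ann$genome$length)
  REGION_CLASSES[ann$class_map[positions]]
}

#' Base counts per gene type over a region
#'
#' Counts, under the single-class overlap rule, how many bases of the query
#' interval belong to each gene type. These counts are the length-proportional
#' expectations used by the gene-type goodness-of-fit test.
#'
#' @param ann A `MitoAnnotation`.
#' @param region Integer vector `c(start, end)`, 1-based inclusive; may wrap
#'   the origin (start > end). Defaults to the whole genome.
#' @return Named integer vector over `protein`, `tRNA`, `rRNA`, `noncoding`;
#'   values sum to the region length.
#' @export
gene_type_lengths <- function(ann, region = c(1L, ann$genome$length)) {
  region <- as.integer(region)
  if (length(region) != 2L || any(is.na(region)))
    stop("region must be c(start, end)")
  if (any(region < 1L | region > ann$genome$length))
    stop("region out of genome bounds")
  pos <- interval_positions(region[1L], region[2L], ann$genome$length)
  if (length(pos) == 0L) stop("empty region")
  counts <- tabulate(ann$class_map[pos], nbins = 4L)
  setNames(counts, REGION_CLASSES)
}

#' Extract and translate an annotated protein gene
#'
#' Pulls the coding sequence of a protein gene from the reference (reverse
#' complemented for L-strand genes), drops any incomplete terminal stop
#' bases, and translates with the vertebrate mitochondrial code. With
#' `init_met = TRUE` the first residue is reported as Met regardless of the
#' (possibly non-standard) initiator codon.
#'
#' @param ann A `MitoAnnotation`.
#' @param symbol Gene symbol, e.g. `"MT-ND5"`.
#' @param init_met Report codon 1 as Met (default `TRUE`).
#' @return Single character string of one-letter residues; a complete-stop
#'   gene ends in `"*"`.
#' @export
translate_gene <- function(ann, symbol, init_met = TRUE) {
  g <- ann$genes[ann$genes$symbol == symbol, ]
  if (nrow(g) != 1L || g$gene_type != "protein")
    stop(symbol, " is not an annotated protein gene")
  cds <- gene_cds(ann, g)
  aa <- translate_codons(codon_split(cds))
  if (init_met) aa[1L] <- "M"
  paste(aa, collapse = "")
}

## coding sequence in reading orientation, incomplete stop bases dropped
gene_cds <- function(ann, g) {
  seq <- substring(ann$genome$sequence, g$start, g$end)
  if (g$strand == "L") seq <- revcomp(seq)
  substring(seq, 1L, nchar(seq) - g$incomplete_stop_len)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

codon_split <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  substring(cds, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}

translate_codons <- function(codons, code = mito_genetic_code()) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  aa
}
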