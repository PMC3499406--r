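## H-strand positions of each codon of a protein gene, in reading order.
## Row j = the three genomic positions of codon j; for L-strand genes the
## positions descend and bases must be complemented to read the codon.
codon_position_matrix <- function(g) {
  ncod <- (g$end - g$start + 1L - g$incomplete_stop_len) %/% 3L
  j <- seq_len(ncod)
  if (g$strand == "H") {
    first <- g$start + 3L * (j - 1L)
    cbind(first, first + 1L, first + 2L, deparse.level = 0)
  } else {
    first <- g$end - 3L * (j - 1L)
    cbind(first, first - 1L, first - 2L, deparse.level = 0)
  }
}

## read codons of a protein gene from a base vector (reading orientation)
read_codons <- function(bases, g, pos_mat = codon_position_matrix(g)) {
  b <- matrix(bases[pos_mat], ncol = 3L)
  if (g$strand == "L") b[] <- complement_base(b)
  paste0(b[, 1L], b[, 2L], b[, 3L])
}

#' Generate a synthetic rCRS-like reference genome
#'
#' Builds a synthetic 16,569-bp circular mitochondrial genome that is
#' structurally faithful to the rCRS without reproducing its base string:
#' gene coordinates follow the bundled NC_012920.1 feature-table transcript,
#' every protein gene starts with `ATG` and translates without internal stop
#' codons under the vertebrate mitochondrial code (including both reading
#' frames of the ATP8/ATP6 and ND4L/ND4 overlaps and the L-strand gene
#' MT-ND6), complete-stop genes terminate with `TAA`, incomplete-stop genes
#' end in the `T`/`TA` completed by polyadenylation, and the historical
#' placeholder `N` sits at position 3107. Base composition approximates the
#' heavy strand of the human molecule. Intended as a fully synthetic test
#' reference; it is not the NC_012920.1 sequence.
#'
#' @param seed Integer RNG seed; the genome is a pure function of it.
#' @param ann_path Optional path to an alternative annotation TSV.
#' @return A `MitoGenome` named `"chrM_synthetic"`.
#' @examples
#' g <- synthetic_reference(seed = 1)
#' g$length
#' @export
synthetic_reference <- function(seed = 1L, ann_path = NULL) {
  if (is.null(ann_path))
    ann_path <- system.file("extdata", "rcrs_genes.tsv",
                            package = "mitospectra", mustWork = TRUE)
  genes <- read.delim(ann_path, stringsAsFactors = FALSE)
  pro <- genes[genes$gene_type == "protein", ]
  withr::with_seed(as.integer(seed), {
    bases <- sample(c("A", "C", "G", "T"), GENOME_LENGTH, replace = TRUE,
                    prob = c(0.31, 0.31, 0.13, 0.25))
    locked <- logical(GENOME_LENGTH)
    ## lock initiator and terminator bases of every protein gene
    for (i in seq_len(nrow(pro))) {
      g <- pro[i, ]
      if (g$strand == "H") {
        start_pos <- g$start + 0:2
        start_bases <- c("A", "T", "G")
      } else {
        start_pos <- (g$end - 2L):g$end
        start_bases <- c("C", "A", "T")  # revcomp(ATG)
      }
      bases[start_pos] <- start_bases
      locked[start_pos] <- TRUE
      if (g$incomplete_stop_len == 0L) {
        if (g$strand == "H") {
          term_pos <- (g$end - 2L):g$end
          term_bases <- c("T", "A", "A")
        } else {
          term_pos <- g$start + 0:2
          term_bases <- c("T", "T", "A")  # revcomp(TAA)
        }
      } else {
        ## trailing bases of a polyadenylation-completed TAA (H genes only)
        term_pos <- (g$end - g$incomplete_stop_len + 1L):g$end
        term_bases <- c("T", "A")[seq_len(g$incomplete_stop_len)]
      }
      bases[term_pos] <- term_bases
      locked[term_pos] <- TRUE
    }
    ## iteratively resample unlocked bases of any internal stop codon until
    ## every protein frame (overlaps included) is stop-free
    code <- mito_genetic_code()
    stops <- names(code)[code == "*"]
    pos_mats <- lapply(seq_len(nrow(pro)), function(i)
      codon_position_matrix(pro[i, ]))
    for (pass in seq_len(200L)) {
      dirty <- FALSE
      for (i in seq_len(nrow(pro))) {
        g <- pro[i, ]
        pm <- pos_mats[[i]]
        codons <- read_codons(bases, g, pm)
        internal <- seq_len(nrow(pm))
        if (g$incomplete_stop_len == 0L)
          internal <- internal[-length(internal)]  # keep the terminator
        bad <- internal[codons[internal] %in% stops]
        for (j in bad) {
          free <- pm[j, ][!locked[pm[j, ]]]
          if (length(free) == 0L)
            stop("unsatisfiable codon constraint at ", g$symbol, " codon ", j)
          bases[free] <- sample(c("A", "C", "G", "T"), length(free),
                                replace = TRUE)
          dirty <- TRUE
        }
      }
      if (!dirty) break
      if (pass == 200L) stop("synthetic genome generation did not converge")
    }
    bases[3107L] <- "N"
    MitoGenome("chrM_synthetic", paste(bases, collapse = ""))
  })
}
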