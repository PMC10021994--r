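#' @keywords internal
"_PACKAGE"

# Genotype call codes. Calls are stored as an integer matrix (markers x
# samples); NA encodes a missing call. P1 is the allele carried by the
# sequenced parental homokaryon wherever the parent is called and homozygous.
GT_P1 <- 1L
GT_P2 <- 2L
GT_HET <- 3L

#' Construct a genotype matrix for a haploid mapping population
#'
#' The central call table of the package: markers (rows) by samples (columns),
#' with calls coded `1` (P1, the parental-homokaryon allele), `2` (P2, the
#' other allele), `3` (heterozygous, i.e. a suspected heterokaryon call) and
#' `NA` (missing). Markers are kept sorted by (contig, pos) and carry their
#' physical coordinates, alleles and phasing status.
#'
#' @param calls integer matrix, markers x samples, values in \{1, 2, 3, NA\}.
#' @param markers data.frame with columns `id`, `contig`, `pos`, `ref`, `alt`,
#'   `phased` (logical), `triallelic` (logical). One row per row of `calls`.
#' @param parent name of the parental homokaryon sample used as phase anchor,
#'   or `NA` if the matrix was built already phased (e.g. by the simulator).
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers, parent = NA_character_) {
  stopifnot(is.matrix(calls), nrow(calls) == nrow(markers))
  calls <- matrix(as.integer(calls), nrow = nrow(calls),
                  dimnames = dimnames(calls))
  need <- c("id", "contig", "pos")
  if (!all(need %in% names(markers)))
    stop("markers must have columns id, contig, pos")
  if (is.null(markers$ref)) markers$ref <- NA_character_
  if (is.null(markers$alt)) markers$alt <- NA_character_
  if (is.null(markers$phased)) markers$phased <- TRUE
  if (is.null(markers$triallelic)) markers$triallelic <- FALSE
  ord <- order(markers$contig, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  if (anyDuplicated(markers[c("contig", "pos")]))
    stop("duplicate (contig, pos) marker coordinates")
  bad <- calls[!is.na(calls) & !(calls %in% c(GT_P1, GT_P2, GT_HET))]
  if (length(bad)) stop("invalid call codes: ", paste(unique(bad), collapse = ","))
  rownames(calls) <- markers$id
  rownames(markers) <- NULL
  structure(list(calls = calls, markers = markers, parent = parent),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d samples on %d contigs\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$markers$contig))))
  cat(sprintf("  parent: %s; unphased markers: %d; het calls: %d; missing: %.1f%%\n",
              x$parent, sum(!x$markers$phased),
              sum(x$calls == GT_HET, na.rm = TRUE),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

# Subset a geno_matrix by marker index and/or sample index, keeping the
# marker table in step.
subset_geno <- function(m, markers = NULL, samples = NULL) {
  if (!is.null(markers)) {
    m$calls <- m$calls[markers, , drop = FALSE]
    m$markers <- m$markers[markers, , drop = FALSE]
    rownames(m$markers) <- NULL
  }
  if (!is.null(samples)) {
    m$calls <- m$calls[, samples, drop = FALSE]
  }
  m
}

#' Assembly coordinate index
#'
#' Holds contig lengths and, when constructed from a FASTA file, the contig
#' sequences themselves (as a [Biostrings::DNAStringSet]).
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param sequences optional `DNAStringSet` whose names match
#'   `names(contig_lengths)`.
#' @return object of class `assembly_index`.
#' @export
assembly_index <- function(contig_lengths, sequences = NULL) {
  if (is.null(names(contig_lengths)) || anyDuplicated(names(contig_lengths)))
    stop("contig lengths must be uniquely named")
  if (any(contig_lengths < 1)) stop("contig lengths must be >= 1")
  structure(list(contig_lengths = contig_lengths, sequences = sequences),
            class = "assembly_index")
}

#' @export
print.assembly_index <- function(x, ...) {
  cat(sprintf("assembly_index: %d contigs, %.2f Mb total, sequences %s\n",
              length(x$contig_lengths), sum(x$contig_lengths) / 1e6,
              if (is.null(x$sequences)) "absent" else "present"))
  invisible(x)
}

#' Gene interval set
#'
#' Per-contig gene intervals, 1-based inclusive as in GFF3, sorted by start.
#' Overlapping genes are allowed (they are common in gene-dense fungal
#' genomes) and are merged only where an operation requires coverage.
#'
#' @param genes data.frame with columns `contig`, `start`, `end` and
#'   optionally `strand`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(genes) {
  if (nrow(genes) == 0) {
    genes <- data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character())
  }
  if (is.null(genes$strand)) genes$strand <- "+"
  stopifnot(all(genes$start >= 1), all(genes$start <= genes$end))
  genes <- genes[order(genes$contig, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes on %d contigs\n",
              nrow(x$genes), length(unique(x$genes$contig))))
  invisible(x)
}
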