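#' Load a VCF of biallelic SNP calls into a genotype matrix
#'
#' Reads the GT field of a VCF (haploid `0`/`1` and diploid `0/0`, `1/1`,
#' `0/1` dialects are both accepted), drops non-SNP records (indels, MNPs,
#' symbolic alleles) with a message, and resolves phase against the sequenced
#' parental homokaryon: wherever the parent is called and homozygous its
#' allele becomes P1. Markers where the parent is missing or heterozygous
#' keep raw REF-as-P1 orientation and are flagged `phased = FALSE`. SNP
#' records with more than one alternate allele are kept but flagged
#' `triallelic`; calls to a second alternate allele are set missing.
#'
#' @param vcf_path path to a VCF 4.x file (plain text or bgzipped).
#' @param parent_sample sample name of the parental homokaryon; must be
#'   present in the VCF header.
#' @param drop_parent drop the parent's own column from the call table
#'   after phase resolution (default TRUE): the parent is the phase
#'   anchor, not a member of the mapping population.
#' @return a [geno_matrix()].
#' @export
load_genotype_matrix <- function(vcf_path, parent_sample,
                                 drop_parent = TRUE) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  samples <- colnames(vcf)
  if (!parent_sample %in% samples)
    stop("parent sample '", parent_sample, "' absent from VCF header")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_list <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt_chr <- suppressWarnings(as(alt_list, "CharacterList"))
  alt1 <- vapply(alt_chr, function(a) if (length(a)) a[[1]] else NA_character_,
                 character(1))
  is_snp <- nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message("load_genotype_matrix: skipped ", n_skip, " non-SNP record(s)")
  gt <- VariantAnnotation::geno(vcf)$GT
  gt <- gt[is_snp, , drop = FALSE]
  contig <- as.character(GenomicRanges::seqnames(rr))[is_snp]
  pos <- GenomicRanges::start(rr)[is_snp]
  ref <- ref[is_snp]; alt1 <- alt1[is_snp]; n_alt <- n_alt[is_snp]

  # allele index per call: 0 = REF, 1 = first ALT, >=2 = further ALTs,
  # -1 = heterozygous, NA = missing
  idx <- gt_allele_index(gt)
  par_idx <- idx[, samples == parent_sample]
  phased <- !is.na(par_idx) & par_idx %in% c(0L, 1L)
  p1_is_ref <- ifelse(phased, par_idx == 0, TRUE)

  calls <- matrix(NA_integer_, nrow = nrow(idx), ncol = ncol(idx))
  calls[which(idx == -1)] <- GT_HET
  a0 <- !is.na(idx) & idx == 0
  a1 <- !is.na(idx) & idx == 1
  calls[a0] <- ifelse(p1_is_ref[row(calls)[a0]], GT_P1, GT_P2)
  calls[a1] <- ifelse(p1_is_ref[row(calls)[a1]], GT_P2, GT_P1)
  # allele index >= 2 (third allele) stays NA; the record keeps its flag
  colnames(calls) <- samples
  markers <- data.frame(
    id = paste0(contig, ":", pos), contig = contig, pos = pos,
    ref = ref, alt = alt1, phased = phased,
    triallelic = n_alt > 1L | apply(idx, 1, function(z) any(z >= 2, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  if (drop_parent)
    calls <- calls[, samples != parent_sample, drop = FALSE]
  geno_matrix(calls, markers, parent = parent_sample)
}

# Parse GT strings into allele indices: haploid "0"/"1"/"2"/"." and diploid
# "a/b" (or "a|b"); homozygous diploid -> allele, heterozygous -> -1,
# missing -> NA.
gt_allele_index <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)[[1]]
    parts <- parts[parts != ""]
    if (length(parts) == 0 || all(parts == ".")) return(NA_integer_)
    if (any(parts == ".")) parts <- parts[parts != "."]
    v <- suppressWarnings(as.integer(parts))
    if (anyNA(v)) return(NA_integer_)
    if (length(unique(v)) == 1L) unique(v) else -1L
  }, integer(1))
  matrix(map[match(as.vector(gt), u)], nrow = nrow(gt),
         dimnames = dimnames(gt))
}

#' Load an assembly index from FASTA or a length index
#'
#' @param path a FASTA file (sequences retained) or a samtools `.fai` /
#'   two-column `contig<TAB>length` file (lengths only).
#' @return an [assembly_index()].
#' @export
load_assembly <- function(path) {
  if (file.info(path)$size == 0) stop("empty assembly file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs))) stop("duplicate contig names in FASTA")
    lens <- Biostrings::width(seqs)
    names(lens) <- names(seqs)
    assembly_index(lens, sequences = seqs)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(tab[[1]])) stop("duplicate contig names in index")
    lens <- as.numeric(tab[[2]])
    names(lens) <- as.character(tab[[1]])
    assembly_index(lens)
  }
}

#' Load gene intervals from a GFF3 file
#'
#' Only rows whose feature type is exactly `"gene"` are retained (the
#' annotation convention that excludes UTR-level features). Records with
#' start > end are rejected with a message before parsing.
#'
#' @param gff_path path to a GFF3 file.
#' @return a [gene_set()].
#' @export
load_gene_set <- function(gff_path) {
  lines <- readLines(gff_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  ok_len <- vapply(fields, length, integer(1)) >= 8
  bad_coord <- vapply(fields, function(f) {
    length(f) >= 5 && suppressWarnings(as.numeric(f[4]) > as.numeric(f[5]))
  }, logical(1))
  if (any(bad_coord, na.rm = TRUE))
    message("load_gene_set: rejected ", sum(bad_coord, na.rm = TRUE),
            " record(s) with start > end")
  keep <- lines
  keep[body][!ok_len | bad_coord %in% TRUE] <- NA
  keep <- keep[!is.na(keep)]
  if (!any(!startsWith(keep, "#") & nzchar(keep)))
    return(gene_set(data.frame(contig = character(), start = integer(),
                               end = integer())))
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  writeLines(keep, tf)
  gr <- rtracklayer::import(tf, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  gene_set(data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE))
}

#' Load a binary trait table
#'
#' Two-column TSV (`sample`, `value`) with values 0, 1 or NA; used to place a
#' scored phenotype (e.g. mating type) on the map as an extra marker.
#'
#' @param path TSV path.
#' @return named integer vector with values in \{0, 1, NA\}.
#' @export
load_trait_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- as.integer(tab[[2]])
  if (!all(v %in% c(0L, 1L, NA)))
    stop("trait values must be 0, 1 or NA")
  stats::setNames(v, as.character(tab[[1]]))
}

#' Write a genetic map as TSV
#'
#' One row per placed marker: `marker`, `contig`, `pos`, `linkage_group`,
#' `cm`, `junction` (whether the marker opens a new contig within its chain).
#' [read_map_tsv()] restores an equivalent map object.
#'
#' @param map a `genetic_map`.
#' @param path output path.
#' @export
write_map_tsv <- function(map, path) {
  rows <- map_marker_table(map)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a genetic map to a marker table
#' @param map a `genetic_map`.
#' @return data.frame with one row per placed marker.
#' @export
map_marker_table <- function(map) {
  do.call(rbind, lapply(names(map$groups), function(g) {
    d <- map$groups[[g]]
    data.frame(marker = d$id, contig = d$contig, pos = d$pos,
               linkage_group = g, cm = d$cm, junction = d$junction,
               stringsAsFactors = FALSE)
  }))
}

#' Read a genetic map written by [write_map_tsv()]
#' @param path TSV path.
#' @param assembly optional [assembly_index()] used to recompute per-group
#'   physical lengths.
#' @return a `genetic_map`.
#' @export
read_map_tsv <- function(path, assembly = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  groups <- lapply(split(tab, factor(tab$linkage_group,
                                     levels = unique(tab$linkage_group))),
                   function(d) data.frame(id = d$marker, contig = d$contig,
                                          pos = d$pos, cm = d$cm,
                                          junction = d$junction,
                                          stringsAsFactors = FALSE))
  new_genetic_map(groups, assembly)
}

#' Write a statistics table as TSV (round-trippable)
#' @param df data.frame (e.g. landscape results or a window track).
#' @param path output path.
#' @export
write_stats_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a statistics TSV written by [write_stats_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_stats_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so a 1-based interval \[1, 30000\] becomes `0 30000`.
#'
#' @param df data.frame with columns `contig`, `start`, `end` and optionally
#'   `name` and `score`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$contig, start = df$start - 1L, end = df$end,
                    name = if (is.null(df$name)) "." else df$name,
                    score = if (is.null(df$score)) 0 else df$score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#' @param path BED path.
#' @return data.frame with columns `contig`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(contig = tab[[1]], start = tab[[2]] + 1L, end = tab[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- tab[[4]]
  if (ncol(tab) >= 5) out$score <- tab[[5]]
  out
}
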