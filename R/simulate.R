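#' Simulation configuration for a haploid mapping population
#'
#' The stated world of the generator mirrors the mapping design the
#' analysis assumes: ~10 chromosomes of a few Mb fragmented into contigs,
#' GBS-like markers every ~37 kb on average, 88 haploid offspring from one
#' heterokaryotic parent segregating 1:1, an obligate crossover per
#' chromosome plus a Poisson number of extras, optional recombination
#' hotspots, viability-driven segregation distortion, heterokaryon
#' (two-gamete) contaminant samples, and missing/error call noise.
#'
#' @param n_chromosomes number of chromosomes (default 10).
#' @param chromosome_length length(s) in bp, recycled (default 7e6).
#' @param contigs_per_chromosome contigs each chromosome is split into
#'   (default 3).
#' @param marker_spacing mean marker spacing in bp, exponential inter-marker
#'   distances (default 37000).
#' @param n_offspring haploid offspring count (default 88).
#' @param obligate at least one crossover per chromosome per meiosis
#'   (default TRUE).
#' @param xo_lambda Poisson mean of extra crossovers per chromosome
#'   (default 0.5).
#' @param hotspots data.frame (`chrom`, `start`, `end`, `multiplier`) of
#'   crossover intensity multipliers, or NULL.
#' @param distortion data.frame (`chrom`, `pos`, `coef`) of viability
#'   selection loci: an offspring carrying the disfavoured (P2) allele at
#'   the locus is rejected and redrawn with probability `coef`.
#' @param heterokaryon_fraction fraction of samples that are unions of two
#'   sibling gametes (default 0).
#' @param missing_rate per-call missing probability (default 0.05).
#' @param error_rate per-call allele flip probability (default 0.002).
#' @param with_sequence generate nucleotide sequences (default FALSE).
#' @param telomeres write telomere motif runs onto chromosome-end contigs
#'   when sequences are generated (default TRUE).
#' @param gc genome GC fraction for generated sequence (default 0.53).
#' @param seed integer seed; all `simulate_*` functions derive their
#'   streams from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10, chromosome_length = 7e6,
                       contigs_per_chromosome = 3, marker_spacing = 37000,
                       n_offspring = 88, obligate = TRUE, xo_lambda = 0.5,
                       hotspots = NULL, distortion = NULL,
                       heterokaryon_fraction = 0, missing_rate = 0.05,
                       error_rate = 0.002, with_sequence = FALSE,
                       telomeres = TRUE, gc = 0.53, seed = 1) {
  stopifnot(n_chromosomes >= 1, all(chromosome_length > 0),
            contigs_per_chromosome >= 1, marker_spacing > 0,
            n_offspring >= 1, xo_lambda >= 0,
            heterokaryon_fraction >= 0, heterokaryon_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1, gc > 0, gc < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a fragmented assembly with markers
#'
#' Chromosomes are cut into contigs at random positions (each contig at
#' least three mean marker spacings long); markers are placed along each
#' chromosome with exponential spacing of the configured mean. With
#' `with_sequence`, random nucleotide sequence is generated and telomere
#' motif runs (4-21 copies) are written onto the terminal contig ends of
#' every chromosome.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_genome`: `assembly` ([assembly_index()]),
#'   `contig_map` (contig, chrom, chrom_start, chrom_end), `markers`
#'   (contig, pos, chrom, chrom_pos), `chrom_lengths`, `cfg`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  chrom_lengths <- rep_len(cfg$chromosome_length, cfg$n_chromosomes)
  min_len <- 3 * cfg$marker_spacing
  contig_map <- list(); idx <- 0
  for (i in seq_len(cfg$n_chromosomes)) {
    L <- chrom_lengths[i]; k <- cfg$contigs_per_chromosome
    if (k * min_len > L)
      stop("chromosome too short for ", k, " contigs of >= ", min_len, " bp")
    for (try in 1:1000) {
      cuts <- sort(round(stats::runif(k - 1, 1, L)))
      seg <- diff(c(0, cuts, L))
      if (all(seg >= min_len)) break
      if (try == 1000) stop("could not fragment chromosome ", i)
    }
    starts <- c(1, cuts + 1); ends <- c(cuts, L)
    for (j in seq_len(k)) {
      idx <- idx + 1
      contig_map[[idx]] <- data.frame(
        contig = sprintf("TIG%03d", idx), chrom = i,
        chrom_start = starts[j], chrom_end = ends[j],
        stringsAsFactors = FALSE)
    }
  }
  contig_map <- do.call(rbind, contig_map)
  markers <- list()
  for (i in seq_len(cfg$n_chromosomes)) {
    L <- chrom_lengths[i]
    n_guess <- ceiling(L / cfg$marker_spacing * 2) + 10
    pos <- cumsum(stats::rexp(n_guess, 1 / cfg$marker_spacing))
    pos <- unique(pmax(1, round(pos[pos < L])))
    cm <- contig_map[contig_map$chrom == i, , drop = FALSE]
    ci <- findInterval(pos, cm$chrom_start)
    markers[[i]] <- data.frame(
      contig = cm$contig[ci], pos = pos - cm$chrom_start[ci] + 1L,
      chrom = i, chrom_pos = pos, stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, markers)
  lens <- stats::setNames(contig_map$chrom_end - contig_map$chrom_start + 1,
                          contig_map$contig)
  seqs <- NULL
  if (cfg$with_sequence) {
    base_p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
                T = (1 - cfg$gc) / 2)
    seq_chr <- vapply(lens, function(l)
      paste(sample(names(base_p), l, replace = TRUE, prob = base_p),
            collapse = ""), character(1))
    telomere_truth <- list()
    if (cfg$telomeres) {
      for (i in seq_len(cfg$n_chromosomes)) {
        cm <- contig_map[contig_map$chrom == i, , drop = FALSE]
        first <- cm$contig[1]; last <- cm$contig[nrow(cm)]
        k5 <- sample(4:21, 1); k3 <- sample(4:21, 1)
        run5 <- strrep("TTAGTG", k5)
        seq_chr[[first]] <- paste0(run5, substr(seq_chr[[first]],
                                                nchar(run5) + 1,
                                                lens[[first]]))
        run3 <- strrep("CACTAA", k3)
        seq_chr[[last]] <- paste0(substr(seq_chr[[last]], 1,
                                         lens[[last]] - nchar(run3)), run3)
        telomere_truth[[length(telomere_truth) + 1]] <- data.frame(
          contig = c(first, last), end = c("5p", "3p"),
          repeat_count = c(k5, k3), stringsAsFactors = FALSE)
      }
    }
    seqs <- Biostrings::DNAStringSet(seq_chr)
    names(seqs) <- names(lens)
  }
  telomere_truth <- if (cfg$with_sequence && cfg$telomeres)
    do.call(rbind, telomere_truth) else NULL
  structure(list(assembly = assembly_index(lens, seqs),
                 contig_map = contig_map, markers = markers,
                 chrom_lengths = chrom_lengths,
                 telomere_truth = telomere_truth, cfg = cfg),
            class = "sim_genome")
}

# Draw one gamete: crossover breakpoints per chromosome (hotspot-weighted
# placement) and the parental haplotype at every marker.
draw_gamete <- function(cfg, genome) {
  breaks <- vector("list", cfg$n_chromosomes)
  for (i in seq_len(cfg$n_chromosomes)) {
    n_co <- (if (cfg$obligate) 1L else 0L) + stats::rpois(1, cfg$xo_lambda)
    breaks[[i]] <- if (n_co > 0)
      sample_positions(n_co, genome$chrom_lengths[i], cfg$hotspots, i)
    else numeric(0)
  }
  start_hap <- sample(1:2, cfg$n_chromosomes, replace = TRUE)
  alleles <- integer(nrow(genome$markers))
  for (i in seq_len(cfg$n_chromosomes)) {
    sel <- genome$markers$chrom == i
    n_below <- findInterval(genome$markers$chrom_pos[sel],
                            sort(breaks[[i]]))
    alleles[sel] <- 1L + (start_hap[i] - 1L + n_below) %% 2L
  }
  list(breaks = breaks, start_hap = start_hap, alleles = alleles)
}

# Sample crossover positions proportional to a piecewise-constant
# intensity: 1 everywhere, times the multiplier inside hotspot intervals.
sample_positions <- function(n, len, hotspots, chrom) {
  hs <- if (is.null(hotspots)) NULL
  else hotspots[hotspots$chrom == chrom, , drop = FALSE]
  if (is.null(hs) || nrow(hs) == 0) return(stats::runif(n, 0, len))
  bounds <- sort(unique(c(0, len, pmax(0, pmin(len, c(hs$start, hs$end))))))
  mid <- (bounds[-1] + bounds[-length(bounds)]) / 2
  mult <- rep(1, length(mid))
  for (j in seq_len(nrow(hs)))
    mult[mid >= hs$start[j] & mid <= hs$end[j]] <- hs$multiplier[j]
  seg_w <- diff(bounds) * mult
  seg <- sample.int(length(mid), n, replace = TRUE, prob = seg_w)
  stats::runif(n, bounds[seg], bounds[seg + 1])
}

# TRUE iff a gamete survives viability selection at the distortion loci
# (disfavoured allele = P2).
gamete_viable <- function(gam, cfg, genome) {
  if (is.null(cfg$distortion) || nrow(cfg$distortion) == 0) return(TRUE)
  for (j in seq_len(nrow(cfg$distortion))) {
    i <- cfg$distortion$chrom[j]
    pos <- cfg$distortion$pos[j]
    n_below <- sum(gam$breaks[[i]] < pos)
    allele <- 1L + (gam$start_hap[i] - 1L + n_below) %% 2L
    if (allele == 2L && stats::runif(1) < cfg$distortion$coef[j])
      return(FALSE)
  }
  TRUE
}

draw_viable_gamete <- function(cfg, genome, cap = 10000) {
  for (t in seq_len(cap)) {
    gam <- draw_gamete(cfg, genome)
    if (gamete_viable(gam, cfg, genome)) return(gam)
  }
  stop("viability rejection loop exceeded ", cap, " iterations")
}

#' Simulate meioses of a haploid mapping population
#'
#' Per offspring and chromosome the crossover count is
#' (1 if obligate) + Poisson(lambda), positions drawn proportionally to
#' the hotspot intensity; the gamete haplotype is read off at the marker
#' positions. Segregation distortion acts as viability resampling:
#' offspring carrying the disfavoured allele at a distortion locus are
#' rejected with the locus coefficient and redrawn. Heterokaryon
#' contaminants are unions of two independent viable gametes (HET where
#' they differ). Missing and error noise are applied last; ground truth
#' is recorded before noise.
#'
#' @param cfg a [sim_config()].
#' @param genome a [sim_genome] from [simulate_genome()].
#' @return list with `matrix` (a [geno_matrix()] of the offspring, parent
#'   `"mt50a"` not included as a column) and `truth` (crossover
#'   breakpoints per offspring, contaminant labels, hotspot/distortion
#'   settings, marker truth before noise, seed).
#' @export
simulate_meiosis <- function(cfg, genome) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_offspring
  nm <- nrow(genome$markers)
  calls <- matrix(NA_integer_, nm, n)
  colnames(calls) <- sprintf("off%03d", seq_len(n))
  n_het <- round(cfg$heterokaryon_fraction * n)
  het_samples <- if (n_het > 0) sample.int(n, n_het) else integer(0)
  breaks_truth <- vector("list", n)
  for (s in seq_len(n)) {
    if (s %in% het_samples) {
      g1 <- draw_viable_gamete(cfg, genome)
      g2 <- draw_viable_gamete(cfg, genome)
      calls[, s] <- ifelse(g1$alleles == g2$alleles, g1$alleles, GT_HET)
      breaks_truth[[s]] <- list(gamete1 = g1$breaks, gamete2 = g2$breaks)
    } else {
      g <- draw_viable_gamete(cfg, genome)
      calls[, s] <- g$alleles
      breaks_truth[[s]] <- g$breaks
    }
  }
  truth_calls <- calls
  if (cfg$missing_rate > 0)
    calls[matrix(stats::runif(length(calls)) < cfg$missing_rate,
                 nrow(calls))] <- NA_integer_
  if (cfg$error_rate > 0) {
    flip <- !is.na(calls) & calls != GT_HET &
      matrix(stats::runif(length(calls)) < cfg$error_rate, nrow(calls))
    calls[flip] <- 3L - calls[flip]
  }
  # allele labels: P1 is the parent (mt50a) haplotype; REF/ALT assignment
  # to P1/P2 is random per marker so VCF phasing is exercised
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, nm, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  p1_is_ref <- stats::runif(nm) < 0.5
  markers <- data.frame(
    id = paste0(genome$markers$contig, ":", genome$markers$pos),
    contig = genome$markers$contig, pos = genome$markers$pos,
    ref = ref, alt = alt, phased = TRUE, triallelic = FALSE,
    p1_is_ref = p1_is_ref, stringsAsFactors = FALSE)
  m <- geno_matrix(calls, markers, parent = "mt50a")
  truth <- list(
    crossovers = breaks_truth,
    contaminants = colnames(calls)[sort(het_samples)],
    hotspots = cfg$hotspots, distortion = cfg$distortion,
    chrom_lengths = genome$chrom_lengths,
    contig_map = genome$contig_map,
    calls_before_noise = truth_calls,
    seed = cfg$seed)
  list(matrix = m, truth = truth)
}

#' Simulate a gene annotation
#'
#' `uniform` mode places genes by stick breaking (gaps jointly
#' Dirichlet(1, ..., 1) over the free length); `clustered` mode groups
#' genes into dense blocks with short within-block gaps, so the intergenic
#' distribution is bimodal: an excess of small gaps and an excess of large
#' ones relative to the uniform curve.
#'
#' @param genome a `sim_genome`.
#' @param n_genes total gene count.
#' @param clustering `"uniform"` or `"clustered"`.
#' @param gene_length_mean mean gene length in bp (default 1500).
#' @param cluster_gap mean within-cluster gap in bp (default 100).
#' @param cluster_size mean genes per cluster (default 8).
#' @return a [gene_set()].
#' @export
simulate_annotation <- function(genome, n_genes,
                                clustering = c("uniform", "clustered"),
                                gene_length_mean = 1500, cluster_gap = 100,
                                cluster_size = 8) {
  clustering <- match.arg(clustering)
  set.seed(genome$cfg$seed + 2L)
  if (n_genes == 0) return(gene_set(data.frame(contig = character(),
                                               start = integer(),
                                               end = integer())))
  lens <- genome$assembly$contig_lengths
  alloc <- round(n_genes * lens / sum(lens))
  rows <- list()
  for (ct in names(lens)) {
    n <- alloc[[ct]]
    if (n < 1) next
    L <- lens[[ct]]
    gl <- pmax(200, round(stats::rgamma(n, shape = 2,
                                        scale = gene_length_mean / 2)))
    while (sum(gl) > 0.8 * L) gl <- gl[-length(gl)]
    n <- length(gl)
    if (n < 1) next
    free <- L - sum(gl)
    if (clustering == "uniform") {
      cuts <- sort(stats::runif(n)) * free
      gaps <- diff(c(0, cuts, free))
    } else {
      k <- max(1, round(n / cluster_size))
      cl_of <- sort(sample.int(k, n, replace = TRUE))
      small <- round(stats::rexp(n + 1, 1 / cluster_gap))
      new_cluster <- c(TRUE, diff(cl_of) != 0, TRUE)
      n_big <- sum(new_cluster)
      big_free <- max(0, free - sum(small[!new_cluster]))
      big <- diff(c(0, sort(stats::runif(n_big - 1)), 1)) * big_free
      gaps <- numeric(n + 1)
      gaps[new_cluster] <- big
      gaps[!new_cluster] <- small[!new_cluster]
      gaps <- gaps * (free / sum(gaps))
    }
    starts <- round(cumsum(gaps[seq_len(n)]) +
                      cumsum(c(0, gl[-n])) + 1)
    ends <- starts + gl - 1
    ok <- ends <= L & starts >= 1
    rows[[ct]] <- data.frame(contig = ct, start = starts[ok],
                             end = ends[ok],
                             strand = sample(c("+", "-"), sum(ok),
                                             replace = TRUE),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no genes could be placed")
  gene_set(do.call(rbind, rows))
}

#' Write a simulated dataset to standard formats
#'
#' Emits a VCF (haploid GTs, with the parent homokaryon `mt50a` as first
#' sample), the assembly (FASTA when sequences exist, otherwise a
#' `contig<TAB>length` index), a GFF3 of genes (when given) and the truth
#' as JSON. Reloading the VCF via [load_genotype_matrix()] reproduces the
#' genotype matrix exactly.
#'
#' @param genome a `sim_genome`.
#' @param m the [geno_matrix()] from [simulate_meiosis()].
#' @param truth the truth list from [simulate_meiosis()] (or NULL).
#' @param genes a [gene_set()] (or NULL).
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
emit_dataset <- function(genome, m, truth = NULL, genes = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  vcf <- file.path(outdir, "dataset.vcf")
  write_sim_vcf(m, genome, vcf)
  files["vcf"] <- vcf
  if (!is.null(genome$assembly$sequences)) {
    fa <- file.path(outdir, "assembly.fa")
    Biostrings::writeXStringSet(genome$assembly$sequences, fa)
    files["fasta"] <- fa
  } else {
    fai <- file.path(outdir, "assembly_lengths.tsv")
    utils::write.table(
      data.frame(contig = names(genome$assembly$contig_lengths),
                 length = genome$assembly$contig_lengths),
      fai, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    files["lengths"] <- fai
  }
  if (!is.null(genes)) {
    gff <- file.path(outdir, "genes.gff3")
    g <- genes$genes
    lines <- c("##gff-version 3",
               sprintf("%s\tkaryolink-sim\tgene\t%d\t%d\t.\t%s\t.\tID=gene%04d",
                       g$contig, g$start, g$end, g$strand, seq_len(nrow(g))))
    writeLines(lines, gff)
    files["gff3"] <- gff
  }
  if (!is.null(truth)) {
    tj <- file.path(outdir, "truth.json")
    truth$calls_before_noise <- NULL
    truth$contig_map <- NULL
    jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files["truth"] <- tj
  }
  files
}

# Minimal VCF 4.2 writer for a simulated genotype matrix. The parent
# homokaryon is written as the first sample, carrying the P1 allele
# everywhere.
write_sim_vcf <- function(m, genome, path) {
  mk <- m$markers
  p1_is_ref <- if (!is.null(mk$p1_is_ref)) mk$p1_is_ref else
    rep(TRUE, nrow(mk))
  code_to_gt <- function(code, ref_is_p1) {
    ifelse(is.na(code), ".",
           ifelse(code == GT_HET, "0/1",
                  ifelse((code == GT_P1) == ref_is_p1, "0", "1")))
  }
  gts <- vapply(seq_len(ncol(m$calls)), function(s)
    code_to_gt(m$calls[, s], p1_is_ref), character(nrow(mk)))
  gts <- matrix(gts, nrow = nrow(mk))
  parent_gt <- ifelse(p1_is_ref, "0", "1")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=karyolink-sim,seed=%d", genome$cfg$seed),
    sprintf("##contig=<ID=%s,length=%d>",
            names(genome$assembly$contig_lengths),
            as.integer(genome$assembly$contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$parent, colnames(m$calls)), collapse = "\t"))
  body <- paste(mk$contig, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".",
                "GT", parent_gt,
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
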