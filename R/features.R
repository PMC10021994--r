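#' Scan contig ends for telomeric repeat runs
#'
#' Finds maximal tandem runs of the telomere motif (on either strand, i.e.
#' the motif or its reverse complement) whose whole span lies within
#' `window` bp of a contig end, and reports the longest qualifying run per
#' end. Contigs shorter than the window are searched in full.
#'
#' @param assembly an [assembly_index()] with sequences.
#' @param motif telomere repeat unit (default `"CACTAA"`).
#' @param min_repeats minimum tandem copies to report (default 4).
#' @param window terminal search window in bp (default 1000).
#' @return data.frame: `contig`, `end` (`"5p"`/`"3p"`), `motif`,
#'   `repeat_count`, `start`, `span_end` (1-based inclusive).
#' @export
scan_telomeres <- function(assembly, motif = "CACTAA", min_repeats = 4,
                           window = 1000) {
  if (is.null(assembly$sequences)) stop("assembly has no sequences")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  hits <- list()
  for (ct in names(assembly$sequences)) {
    seq_chr <- as.character(assembly$sequences[[ct]])
    len <- nchar(seq_chr)
    for (mm in unique(c(motif, rc))) {
      runs <- gregexpr(paste0("(?:", mm, ")+"), seq_chr)[[1]]
      if (runs[1] == -1) next
      starts <- as.integer(runs)
      lens <- attr(runs, "match.length")
      reps <- lens %/% nchar(mm)
      ends_at <- starts + lens - 1L
      for (i in seq_along(starts)) {
        if (reps[i] < min_repeats) next
        side <- if (ends_at[i] <= window) "5p"
        else if (starts[i] >= len - window + 1L) "3p"
        else NA_character_
        if (is.na(side)) next
        hits[[length(hits) + 1]] <- data.frame(
          contig = ct, end = side, motif = mm, repeat_count = reps[i],
          start = starts[i], span_end = ends_at[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(), end = character(),
                      motif = character(), repeat_count = integer(),
                      start = integer(), span_end = integer()))
  out <- do.call(rbind, hits)
  # longest run per (contig, end)
  out <- out[order(out$contig, out$end, -out$repeat_count), , drop = FALSE]
  out <- out[!duplicated(out[c("contig", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window GC content and gene density
#'
#' Windows of width `window` start at 1, 1 + `step`, ...; window
#' generation stops once a window reaches the contig end, and that final
#' (possibly truncated) window is dropped when shorter than half the
#' window width. GC is computed over A/C/G/T only (Ns excluded from the
#' denominator); gene density is the fraction of the window covered by the
#' union of gene intervals.
#'
#' @param assembly an [assembly_index()] with sequences.
#' @param genes a [gene_set()] (contigs absent from it get density 0).
#' @param window window width in bp (default 30000).
#' @param step slide in bp (default 10000).
#' @return data.frame: `contig`, `start`, `end`, `gc`, `gene_density`.
#' @export
window_gc_gene_density <- function(assembly, genes, window = 30000,
                                   step = 10000) {
  if (is.null(assembly$sequences)) stop("assembly has no sequences")
  out <- list()
  for (ct in names(assembly$sequences)) {
    len <- assembly$contig_lengths[[ct]]
    starts <- integer(0); s <- 1L
    repeat {
      starts <- c(starts, s)
      if (s + window - 1L >= len) break
      s <- s + step
    }
    ends <- pmin(starts + window - 1L, len)
    widths <- ends - starts + 1L
    keep <- widths >= window / 2 | seq_along(starts) < length(starts)
    starts <- starts[keep]; ends <- ends[keep]
    v <- Biostrings::Views(assembly$sequences[[ct]], start = starts,
                           end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
    gd <- gene_coverage_fraction(genes, ct, starts, ends)
    out[[ct]] <- data.frame(contig = ct, start = starts, end = ends,
                            gc = gc, gene_density = gd,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Fraction of each window [starts, ends] covered by the merged gene
# intervals of one contig.
gene_coverage_fraction <- function(genes, contig, starts, ends) {
  g <- genes$genes[genes$genes$contig == contig, , drop = FALSE]
  if (nrow(g) == 0) return(rep(0, length(starts)))
  merged <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
  win <- IRanges::IRanges(starts, ends)
  ov <- IRanges::findOverlaps(win, merged)
  inter <- IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                               merged[S4Vectors::subjectHits(ov)])
  covered <- tapply(IRanges::width(inter),
                    factor(S4Vectors::queryHits(ov),
                           levels = seq_along(win)), sum)
  covered[is.na(covered)] <- 0
  as.numeric(covered) / IRanges::width(win)
}

#' Centromere candidates: long gene-free runs with depressed GC
#'
#' Emits every maximal gene-free run of at least `min_gene_free` bp whose
#' mean GC (width-weighted over the overlapping windows of `track`) is
#' below the genome-wide mean GC minus `gc_margin`. Terminal gene-free
#' flanks count as runs. Several candidates per contig are allowed.
#'
#' @param track a window track from [window_gc_gene_density()].
#' @param genes a [gene_set()].
#' @param min_gene_free minimum run length in bp (default 20000).
#' @param gc_margin GC depression below the genome mean, as a fraction
#'   (default 0.02, i.e. 2 percentage points).
#' @param contig_lengths optional named lengths; defaults to the last
#'   window end per contig.
#' @return data.frame: `contig`, `start`, `end`, `length`, `mean_gc`,
#'   `genome_gc`.
#' @export
call_centromere_candidates <- function(track, genes, min_gene_free = 20000,
                                       gc_margin = 0.02,
                                       contig_lengths = NULL) {
  w <- track$end - track$start + 1
  genome_gc <- sum(track$gc * w, na.rm = TRUE) / sum(w[!is.na(track$gc)])
  out <- list()
  for (ct in unique(track$contig)) {
    len <- if (!is.null(contig_lengths)) contig_lengths[[ct]]
    else max(track$end[track$contig == ct])
    g <- genes$genes[genes$genes$contig == ct, , drop = FALSE]
    free <- if (nrow(g) == 0) IRanges::IRanges(1, len)
    else IRanges::setdiff(IRanges::IRanges(1, len),
                          IRanges::reduce(IRanges::IRanges(g$start, g$end)))
    free <- free[IRanges::width(free) >= min_gene_free]
    if (!length(free)) next
    tr <- track[track$contig == ct, , drop = FALSE]
    for (i in seq_along(free)) {
      fs <- IRanges::start(free)[i]; fe <- IRanges::end(free)[i]
      ov <- tr$end >= fs & tr$start <= fe & !is.na(tr$gc)
      if (!any(ov)) next
      wts <- pmin(tr$end[ov], fe) - pmax(tr$start[ov], fs) + 1
      run_gc <- sum(tr$gc[ov] * wts) / sum(wts)
      if (run_gc <= genome_gc - gc_margin) {
        out[[length(out) + 1]] <- data.frame(
          contig = ct, start = fs, end = fe, length = fe - fs + 1,
          mean_gc = run_gc, genome_gc = genome_gc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), length = integer(),
                      mean_gc = numeric(), genome_gc = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Observed intergenic spaces
#'
#' Per contig, the gaps between consecutive gene intervals sorted by
#' start, with `gap = next_start - max(previous ends) - 1` (1-based
#' inclusive intervals). Book-ended genes yield a gap of 0; overlapping
#' genes yield no gap. Terminal flanks before the first and after the last
#' gene are excluded.
#'
#' @param genes a [gene_set()].
#' @return numeric vector of gaps (bp), with per-contig names.
#' @export
intergenic_spaces <- function(genes) {
  gaps <- numeric(0)
  for (ct in unique(genes$genes$contig)) {
    g <- genes$genes[genes$genes$contig == ct, , drop = FALSE]
    if (nrow(g) < 2) next
    prev_end <- cummax(g$end)[-nrow(g)]
    gp <- g$start[-1] - prev_end - 1
    gp <- gp[gp >= 0]
    if (length(gp)) gaps <- c(gaps, stats::setNames(gp, rep(ct, length(gp))))
  }
  gaps
}

#' Simulate intergenic spacing under uniform gene placement
#'
#' Keeps the observed gene lengths per contig and redistributes the free
#' (non-genic) length over the n + 1 gaps by stick breaking: n independent
#' uniform cut points on the free length, i.e. gaps are jointly
#' Dirichlet(1, ..., 1) scaled by the free length, so each interior gap
#' has expectation `free / (n + 1)`. Interior gaps of every replicate are
#' returned.
#'
#' @param gene_lengths list (per contig) of numeric gene lengths, or a
#'   single numeric vector for a one-contig genome.
#' @param contig_lengths numeric contig lengths, parallel to
#'   `gene_lengths`.
#' @param n_reps number of replicates (default 1000).
#' @param seed optional integer seed.
#' @return list: `replicates` (list of numeric gap vectors), `all`
#'   (pooled), `mean`, `median`.
#' @export
simulate_uniform_gene_spacing <- function(gene_lengths, contig_lengths,
                                          n_reps = 1000, seed = NULL) {
  if (!is.list(gene_lengths)) gene_lengths <- list(gene_lengths)
  stopifnot(length(gene_lengths) == length(contig_lengths))
  free <- mapply(function(gl, cl) cl - sum(gl), gene_lengths,
                 contig_lengths)
  if (any(free < 0)) stop("total gene length exceeds contig length")
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(r) {
    unlist(lapply(seq_along(gene_lengths), function(i) {
      n <- length(gene_lengths[[i]])
      if (n < 2) return(numeric(0))
      cuts <- sort(stats::runif(n)) * free[i]
      gaps <- diff(c(0, cuts, free[i]))
      gaps[2:n]  # interior gaps only
    }))
  })
  all_gaps <- unlist(reps)
  list(replicates = reps, all = all_gaps, mean = mean(all_gaps),
       median = stats::median(all_gaps))
}
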