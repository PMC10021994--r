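#' The r-bar genome-shuffling statistic
#'
#' The expected fraction of uniformly chosen locus pairs whose alleles are
#' shuffled in a random gamete, decomposed into an inter-chromosomal term
#' driven by independent assortment,
#' `(1 - sum(p_i^2)) / 2` with `p_i` the chromosome length fractions, and
#' an intra-chromosomal term driven by crossovers:
#' `sum_i p_i^2 * mean_gametes(2 q_i (1 - q_i))`, where `q_i` is the
#' fraction of chromosome i's length that a gamete inherits from one
#' parental haplotype (two independent uniform loci on the chromosome
#' differ in parental origin with probability `2 q (1 - q)`).
#'
#' @param chrom_lengths numeric vector of physical chromosome lengths.
#' @param crossovers list over gametes; each element a list over
#'   chromosomes of crossover breakpoint positions (bp, within the
#'   chromosome). An empty numeric vector means no crossover.
#' @return list with `inter`, `intra`, `rbar`.
#' @export
compute_rbar <- function(chrom_lengths, crossovers) {
  p <- chrom_lengths / sum(chrom_lengths)
  inter <- (1 - sum(p^2)) / 2
  if (length(crossovers) == 0) stop("empty gamete set: intra term undefined")
  n_chr <- length(chrom_lengths)
  shuf <- vapply(crossovers, function(gam) {
    stopifnot(length(gam) == n_chr)
    vapply(seq_len(n_chr), function(i) {
      q <- haplotype_fraction(gam[[i]], chrom_lengths[i])
      2 * q * (1 - q)
    }, numeric(1))
  }, numeric(n_chr))
  shuf <- matrix(shuf, nrow = n_chr)
  intra <- sum(p^2 * rowMeans(shuf))
  list(inter = inter, intra = intra, rbar = inter + intra)
}

# Fraction of a chromosome inherited from the haplotype present at the
# chromosome start, given crossover breakpoints.
haplotype_fraction <- function(breaks, len) {
  if (length(breaks) == 0) return(1)
  b <- sort(breaks)
  stopifnot(all(b >= 0), all(b <= len))
  seg <- diff(c(0, b, len))
  sum(seg[seq(1, length(seg), by = 2)]) / len
}
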