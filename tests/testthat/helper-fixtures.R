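# Small fixtures built in code; nothing is read from disk.

# Shorthand codes
P1 <- 1L; P2 <- 2L; HET <- 3L; MISS <- NA_integer_

# A tiny geno_matrix from a call matrix with default marker metadata.
make_gm <- function(calls, contig = "c1", pos = NULL, phased = TRUE,
                    triallelic = FALSE, parent = "mt50a") {
  nm <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(nm) * 1000L
  if (length(contig) == 1) contig <- rep(contig, nm)
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("s%02d", seq_len(ncol(calls)))
  markers <- data.frame(
    id = paste0(contig, ":", pos), contig = contig, pos = pos,
    ref = "A", alt = "C",
    phased = rep_len(phased, nm), triallelic = rep_len(triallelic, nm),
    stringsAsFactors = FALSE)
  geno_matrix(calls, markers, parent = parent)
}

# Genome with exactly one contig and markers at fixed positions, for
# landscape tests where the interval layout must be controlled.
fixed_genome <- function(positions, chrom_length, cfg) {
  contig_map <- data.frame(contig = "TIG001", chrom = 1,
                           chrom_start = 1, chrom_end = chrom_length,
                           stringsAsFactors = FALSE)
  markers <- data.frame(contig = "TIG001", pos = as.integer(positions),
                        chrom = 1, chrom_pos = as.integer(positions),
                        stringsAsFactors = FALSE)
  structure(list(
    assembly = assembly_index(c(TIG001 = chrom_length)),
    contig_map = contig_map, markers = markers,
    chrom_lengths = chrom_length, telomere_truth = NULL, cfg = cfg),
    class = "sim_genome")
}

# The hand-built 20-marker x 12-sample strict-cascade fixture.
# Contig c1: m01..m10 (pos 1000..10000), contig c2: m11..m20.
# Eleven genuine offspring s01..s11 plus the contaminant s12.
#   pattern A (contig c1): P1 s01-s06, P2 s07-s11
#   pattern B (contig c2): P1 s01-s05 + s11, P2 s06-s10
# Planted defects:
#   m03 triallelic; m05 parent-missing (unphased); m07 two missing calls
#   (s01, s02); m09 fully skewed (all P1, k = 0); m12 double-crossover
#   island (s01 is P2 between P1 neighbours m11/m13); s12 heterozygous at
#   m02, m14, m18 (3/20 = 15% > 10%).
# Hand-counted survivors with the fixture config (min_called = 8, AF rule
# disabled, binomial alpha 0.01, island threshold 1, cluster rule off):
#   markers c1: m01,m02,m04,m06,m08,m10; c2: m11,m13..m20 (15 markers),
#   samples s01..s11.
cascade_fixture <- function() {
  A <- c(rep(P1, 6), rep(P2, 5))
  B <- c(rep(P1, 5), P2, rep(P2, 4), P1)
  calls <- matrix(NA_integer_, 20, 12)
  for (i in 1:10) calls[i, 1:11] <- A
  for (i in 11:20) calls[i, 1:11] <- B
  calls[9, 1:11] <- rep(P1, 11)            # m09: k = 0 skew
  calls[7, 1:2] <- MISS                     # m07: 2/11 missing
  calls[12, 1] <- P2                        # m12: island in s01
  calls[, 12] <- P1                         # contaminant baseline
  calls[c(2, 14, 18), 12] <- HET            # contaminant HET calls
  colnames(calls) <- sprintf("s%02d", 1:12)
  contig <- rep(c("c1", "c2"), each = 10)
  pos <- rep(seq(1000L, 10000L, by = 1000L), 2)
  m <- make_gm(calls, contig = contig, pos = pos)
  m$markers$triallelic[m$markers$id == "c1:3000"] <- TRUE
  m$markers$phased[m$markers$id == "c1:5000"] <- FALSE
  m
}

cascade_cfg <- function() {
  filter_config("strict", min_called = 8, min_af = 0, max_af = 1,
                max_missing_frac = 0.1, maf_binom_alpha = 0.01,
                island_threshold = 1, min_cluster_size = 1,
                min_shared = 8)
}

cascade_survivors <- function() {
  c(paste0("c1:", c(1, 2, 4, 6, 8, 10) * 1000),
    paste0("c2:", c(1, 3:10) * 1000))
}

# All permutations of 1..n (n small), for exhaustive seriation oracles.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
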