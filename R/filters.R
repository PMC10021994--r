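#' Filter configuration
#'
#' Bundles the thresholds of the two marker filter cascades. `strict`
#' defaults reproduce the published strict cascade (min individuals called
#' 40, allele frequency in \[0.2, 0.8\], at most 10% heterozygous calls per
#' position and per sample, at most 10% missing, binomial segregation-skew
#' alpha 0.01, double-crossover island removal, and the small-cluster rule of
#' at least 5 unique markers per linkage group at LOD > 5.5). `lenient`
#' defaults reproduce the crossover-counting cascade (min individuals called
#' 10, minor allele frequency 0.05, at most one heterozygous call per
#' position, at most 30 missing calls, no segregation-skew removal).
#'
#' @param mode `"strict"` or `"lenient"`.
#' @param ... named overrides of any field.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(mode = c("strict", "lenient"), ...) {
  mode <- match.arg(mode)
  cfg <- if (mode == "strict") {
    list(mode = "strict", min_called = 40, min_af = 0.2, max_af = 0.8,
         max_het_frac_position = 0.1, max_het_frac_sample = 0.1,
         max_missing_frac = 0.1, max_missing_sample_frac = 0.1,
         maf_binom_alpha = 0.01, island_threshold = 1,
         min_cluster_size = 5, cluster_lod = 5.5, min_shared = 10)
  } else {
    list(mode = "lenient", min_called = 10, min_af = 0.05, max_af = 0.95,
         max_het_calls_position = 1, max_missing_calls = 30, min_shared = 10)
  }
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "filter_config")
}

# Per-position tallies used by several rules. HET calls are excluded from
# the allele-frequency denominator.
position_tallies <- function(m) {
  n_called <- rowSums(!is.na(m$calls))
  n_het <- rowSums(m$calls == GT_HET, na.rm = TRUE)
  n_p1 <- rowSums(m$calls == GT_P1, na.rm = TRUE)
  n_p2 <- rowSums(m$calls == GT_P2, na.rm = TRUE)
  list(n_called = n_called, n_het = n_het, n_p1 = n_p1, n_p2 = n_p2,
       af_p2 = ifelse(n_p1 + n_p2 > 0, n_p2 / (n_p1 + n_p2), NA_real_))
}

#' Basic per-position filter: call count, allele frequency, heterozygosity
#'
#' Keeps a position iff it has at least `min_called` non-missing calls, its
#' P2 allele frequency among called non-heterozygous samples lies in
#' \[`min_af`, `max_af`\], and its heterozygous fraction of non-missing calls
#' is at most `max_het_frac_position`. Rules are applied in that order and
#' removal counts per rule are recorded in the `"removed"` attribute.
#'
#' @param m a [geno_matrix()].
#' @param cfg a [filter_config()].
#' @return filtered `geno_matrix` with attribute `removed` (named counts).
#' @export
filter_positions_basic <- function(m, cfg = filter_config("strict")) {
  t <- position_tallies(m)
  fail_called <- t$n_called < cfg$min_called
  fail_af <- !fail_called &
    (is.na(t$af_p2) | t$af_p2 < cfg$min_af | t$af_p2 > cfg$max_af)
  het_frac <- ifelse(t$n_called > 0, t$n_het / t$n_called, 0)
  max_het <- if (!is.null(cfg$max_het_frac_position)) cfg$max_het_frac_position else Inf
  fail_het <- !fail_called & !fail_af & het_frac > max_het
  keep <- !(fail_called | fail_af | fail_het)
  out <- subset_geno(m, markers = keep)
  attr(out, "removed") <- c(called_count = sum(fail_called),
                            allele_frequency = sum(fail_af),
                            het_fraction = sum(fail_het))
  out
}

#' Flag and remove heterokaryon-like samples
#'
#' A sample is flagged iff its fraction of heterozygous calls among
#' non-missing calls is strictly greater than `max_het_frac_sample`
#' ("more than 10%" is read as a strict inequality, so exactly 10% is
#' retained). Samples with zero non-missing calls are flagged as unusable
#' and reported separately.
#'
#' @param m a [geno_matrix()].
#' @param max_het_frac_sample flag threshold (default 0.1).
#' @return list with `flagged` (character), `unusable` (character) and
#'   `matrix` (the `geno_matrix` without flagged/unusable samples).
#' @export
detect_heterokaryon_samples <- function(m, max_het_frac_sample = 0.1) {
  n_called <- colSums(!is.na(m$calls))
  n_het <- colSums(m$calls == GT_HET, na.rm = TRUE)
  unusable <- n_called == 0
  flagged <- !unusable & (n_het / n_called > max_het_frac_sample)
  list(flagged = colnames(m$calls)[flagged],
       unusable = colnames(m$calls)[unusable],
       matrix = subset_geno(m, samples = !(flagged | unusable)))
}

#' Set every heterozygous call to missing
#' @param m a [geno_matrix()].
#' @return `geno_matrix` with HET replaced by NA; nothing else changes.
#' @export
set_het_missing <- function(m) {
  m$calls[m$calls == GT_HET] <- NA_integer_
  m
}

#' Structural position filters: triallelic, unphased parent, missing fraction
#'
#' Removes, in order: positions flagged triallelic; positions that could not
#' be phased because the parent call is missing or heterozygous; positions
#' whose missing fraction over all remaining samples exceeds
#' `max_missing_frac` (strictly).
#'
#' @param m a [geno_matrix()].
#' @param max_missing_frac default 0.1.
#' @return filtered `geno_matrix` with attribute `removed`.
#' @export
structural_filters <- function(m, max_missing_frac = 0.1) {
  fail_tri <- m$markers$triallelic
  fail_phase <- !fail_tri & !m$markers$phased
  miss_frac <- rowMeans(is.na(m$calls))
  fail_miss <- !fail_tri & !fail_phase & miss_frac > max_missing_frac
  out <- subset_geno(m, markers = !(fail_tri | fail_phase | fail_miss))
  attr(out, "removed") <- c(triallelic = sum(fail_tri),
                            unphased_parent = sum(fail_phase),
                            missing_fraction = sum(fail_miss))
  out
}

#' Cumulative binomial probability of an observed minor-allele count
#'
#' For a 1:1 segregating haploid population the minor-allele count at an
#' undistorted position is Binomial(n, 1/2). Returns P(X <= k_minor); the
#' strict cascade removes positions with p below `maf_binom_alpha`.
#'
#' @param k_minor minor allele count, `min(#P1, #P2)` over called
#'   non-heterozygous samples.
#' @param n_called number of called (non-heterozygous) samples.
#' @return cumulative p-value(s); vectorized.
#' @export
maf_binomial_test <- function(k_minor, n_called) {
  stopifnot(all(k_minor >= 0), all(k_minor <= n_called))
  stats::pbinom(k_minor, n_called, 0.5)
}

# Remove positions whose minor-allele frequency is binomially implausible
# under 1:1 segregation.
filter_binomial_skew <- function(m, alpha = 0.01) {
  t <- position_tallies(m)
  n <- t$n_p1 + t$n_p2
  k <- pmin(t$n_p1, t$n_p2)
  p <- ifelse(n > 0, maf_binomial_test(k, n), 0)
  keep <- p >= alpha
  out <- subset_geno(m, markers = keep)
  attr(out, "removed") <- c(binomial_skew = sum(!keep))
  out
}

#' Remove positions whose calls would require double crossovers
#'
#' For each interior position j of a contig and each sample called at
#' j - 1, j and j + 1, the call at j is a single-marker island iff both
#' neighbours agree with each other and disagree with j. Positions with at
#' least `island_threshold` island samples are removed. The first and last
#' markers of a contig are never removed by this rule, and contigs with
#' fewer than 3 markers are skipped.
#'
#' @param m a [geno_matrix()] sorted by (contig, pos).
#' @param island_threshold minimum offending samples (default 1).
#' @return filtered `geno_matrix` with attribute `removed`.
#' @export
double_crossover_filter <- function(m, island_threshold = 1) {
  calls <- m$calls
  contig <- m$markers$contig
  n <- nrow(calls)
  island_counts <- integer(n)
  if (n >= 3) {
    j <- 2:(n - 1)
    same_contig <- contig[j] == contig[j - 1] & contig[j] == contig[j + 1]
    jj <- j[same_contig]
    if (length(jj)) {
      up <- calls[jj - 1, , drop = FALSE]
      mid <- calls[jj, , drop = FALSE]
      dn <- calls[jj + 1, , drop = FALSE]
      isl <- !is.na(up) & !is.na(mid) & !is.na(dn) & up == dn & up != mid
      island_counts[jj] <- rowSums(isl)
    }
  }
  keep <- island_counts < island_threshold
  out <- subset_geno(m, markers = keep)
  attr(out, "removed") <- c(double_crossover = sum(!keep))
  out
}

# Remove samples whose missing fraction exceeds the threshold (strictly).
filter_missing_samples <- function(m, max_missing_sample_frac = 0.1) {
  miss <- colMeans(is.na(m$calls))
  out <- subset_geno(m, samples = miss <= max_missing_sample_frac)
  attr(out, "removed") <- c(samples_missing = sum(miss > max_missing_sample_frac))
  out
}

#' Remove markers in small linkage clusters
#'
#' Markers are first deduplicated by identical segregation pattern
#' (including the missing pattern); connected components of the two-point
#' linkage graph at LOD > `cluster_lod` are computed over unique patterns,
#' and markers whose component contains fewer than `min_cluster_size` unique
#' patterns are removed.
#'
#' @param m a [geno_matrix()].
#' @param cluster_lod LOD threshold (default 5.5).
#' @param min_cluster_size minimum unique patterns (default 5).
#' @param min_shared minimum informative sample overlap for a pair to count.
#' @return filtered `geno_matrix` with attribute `removed`.
#' @export
small_cluster_filter <- function(m, cluster_lod = 5.5, min_cluster_size = 5,
                                 min_shared = 10) {
  key <- apply(m$calls, 1, function(z) paste(ifelse(is.na(z), "N", z),
                                             collapse = ""))
  uniq <- !duplicated(key)
  rep_idx <- which(uniq)
  tp <- two_point_all(m$calls[rep_idx, , drop = FALSE], min_shared = min_shared)
  adj <- tp$lod > cluster_lod & !is.na(tp$lod)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  comp_of_marker <- comp$membership[match(key, key[rep_idx])]
  keep <- comp$csize[comp_of_marker] >= min_cluster_size
  out <- subset_geno(m, markers = keep)
  attr(out, "removed") <- c(small_cluster = sum(!keep))
  out
}

#' Run the full strict filter cascade
#'
#' Applies, in the published order: the basic position filter; heterokaryon
#' sample removal; the basic position filter again; HET-to-missing
#' conversion; structural filters (triallelic, unphased, >10% missing);
#' binomial segregation-skew removal; the double-crossover island filter;
#' removal of samples with >10% missing positions; and the small-cluster
#' rule. The published `checkF1 qall_weights` step is not reproduced (it is
#' an undocumented package-internal statistic); its role is covered by the
#' binomial skew and island rules, and the report names the substitution.
#'
#' @param m a phased [geno_matrix()].
#' @param cfg a strict [filter_config()].
#' @return list with `matrix` (filtered) and `report` (data.frame of
#'   per-rule removal counts, plus flagged sample names as attributes).
#' @export
filter_strict <- function(m, cfg = filter_config("strict")) {
  steps <- list()
  note <- function(stage, what, n) {
    steps[[length(steps) + 1]] <<- data.frame(stage = stage, rule = what,
                                              removed = n)
  }
  s1 <- filter_positions_basic(m, cfg)
  for (r in names(attr(s1, "removed")))
    note("positions_1", r, attr(s1, "removed")[[r]])
  hk <- detect_heterokaryon_samples(s1, cfg$max_het_frac_sample)
  note("samples", "heterokaryon", length(hk$flagged))
  note("samples", "unusable", length(hk$unusable))
  s2 <- filter_positions_basic(hk$matrix, cfg)
  for (r in names(attr(s2, "removed")))
    note("positions_2", r, attr(s2, "removed")[[r]])
  s3 <- set_het_missing(s2)
  s4 <- structural_filters(s3, cfg$max_missing_frac)
  for (r in names(attr(s4, "removed")))
    note("structural", r, attr(s4, "removed")[[r]])
  s5 <- filter_binomial_skew(s4, cfg$maf_binom_alpha)
  note("skew", "binomial_skew (replaces checkF1 qall_weights)",
       attr(s5, "removed")[["binomial_skew"]])
  s6 <- double_crossover_filter(s5, cfg$island_threshold)
  note("island", "double_crossover (replaces checkF1 qall_weights)",
       attr(s6, "removed")[["double_crossover"]])
  s7 <- filter_missing_samples(s6, cfg$max_missing_sample_frac)
  note("samples2", "missing_samples", attr(s7, "removed")[["samples_missing"]])
  s8 <- small_cluster_filter(s7, cfg$cluster_lod, cfg$min_cluster_size,
                             cfg$min_shared)
  note("cluster", "small_cluster", attr(s8, "removed")[["small_cluster"]])
  report <- do.call(rbind, steps)
  attr(report, "flagged_samples") <- hk$flagged
  attr(report, "unusable_samples") <- hk$unusable
  attr(report, "n_markers_in") <- nrow(m$calls)
  attr(report, "n_markers_out") <- nrow(s8$calls)
  attr(report, "n_samples_out") <- ncol(s8$calls)
  list(matrix = s8, report = report)
}

#' Run the lenient (crossover-counting) filter cascade
#'
#' Applies, in the published order: minimum individuals called and minor
#' allele frequency; removal of positions heterozygous in the parent or
#' unphased; removal of positions with more than `max_het_calls_position`
#' heterozygous calls over all samples; HET-to-missing conversion; retention
#' of biallelic sites only; removal of positions with more than
#' `max_missing_calls` missing calls. Positions with a binomially skewed
#' minor-allele frequency are deliberately admitted (the lenient set keeps
#' distorted regions in the map).
#'
#' @param m a phased [geno_matrix()], ideally with heterokaryon samples
#'   already removed.
#' @param cfg a lenient [filter_config()].
#' @return list with `matrix` and `report` as in [filter_strict()].
#' @export
filter_lenient <- function(m, cfg = filter_config("lenient")) {
  steps <- list()
  note <- function(stage, what, n) {
    steps[[length(steps) + 1]] <<- data.frame(stage = stage, rule = what,
                                              removed = n)
  }
  t <- position_tallies(m)
  fail_called <- t$n_called < cfg$min_called
  maf <- pmin(t$af_p2, 1 - t$af_p2)
  fail_af <- !fail_called & (is.na(maf) | maf < cfg$min_af)
  s1 <- subset_geno(m, markers = !(fail_called | fail_af))
  note("positions", "called_count", sum(fail_called))
  note("positions", "minor_allele_frequency", sum(fail_af))
  fail_phase <- !s1$markers$phased
  s2 <- subset_geno(s1, markers = !fail_phase)
  note("parent", "parent_het_or_missing", sum(fail_phase))
  n_het <- rowSums(s2$calls == GT_HET, na.rm = TRUE)
  s3 <- subset_geno(s2, markers = n_het <= cfg$max_het_calls_position)
  note("het", "het_calls_position", sum(n_het > cfg$max_het_calls_position))
  s4 <- set_het_missing(s3)
  fail_tri <- s4$markers$triallelic
  s5 <- subset_geno(s4, markers = !fail_tri)
  note("biallelic", "triallelic", sum(fail_tri))
  n_miss <- rowSums(is.na(s5$calls))
  s6 <- subset_geno(s5, markers = n_miss <= cfg$max_missing_calls)
  note("missing", "missing_calls", sum(n_miss > cfg$max_missing_calls))
  report <- do.call(rbind, steps)
  attr(report, "n_markers_in") <- nrow(m$calls)
  attr(report, "n_markers_out") <- nrow(s6$calls)
  attr(report, "n_samples_out") <- ncol(s6$calls)
  list(matrix = s6, report = report)
}

#' Marker retention percentage
#' @param n_retained markers kept.
#' @param n_called raw variants called.
#' @return percentage (0-100).
#' @export
marker_retention_pct <- function(n_retained, n_called) {
  100 * n_retained / n_called
}
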