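# Strict and lenient filter cascades, rule by rule.

test_that("filter_positions_basic applies called-count, AF and het rules", {
  # 88 samples; m1 called in 39 (removed), m2 balanced (kept),
  # m3 with 10 HET of 88 called = 11.4% (removed)
  calls <- rbind(
    c(rep(P1, 20), rep(P2, 19), rep(MISS, 49)),
    c(rep(P1, 44), rep(P2, 44)),
    c(rep(HET, 10), rep(P1, 39), rep(P2, 39)))
  m <- make_gm(calls)
  out <- filter_positions_basic(m, filter_config("strict"))
  expect_equal(out$markers$id, "c1:2000")
  expect_equal(unname(attr(out, "removed")),
               c(1, 0, 1))  # called, AF, het in order
  # AF rule: 0.1 P2 frequency removed at [0.2, 0.8]
  m2 <- make_gm(rbind(c(rep(P1, 80), rep(P2, 8))))
  out2 <- filter_positions_basic(m2, filter_config("strict"))
  expect_equal(nrow(out2$calls), 0)
  expect_equal(unname(attr(out2, "removed")), c(0, 1, 0))
})

test_that("heterokaryon detection uses a strict 10% boundary", {
  # 100 markers so the het fractions are exact
  n_mark <- 100
  s_11pct <- c(rep(HET, 11), rep(P1, 89))
  s_10pct <- c(rep(HET, 10), rep(P1, 90))
  s_clean <- rep(P2, 100)
  s_empty <- rep(MISS, 100)
  calls <- cbind(s_11pct, s_10pct, s_clean, s_empty)
  colnames(calls) <- c("hk", "edge", "ok", "empty")
  m <- make_gm(calls)
  res <- detect_heterokaryon_samples(m, 0.1)
  expect_equal(res$flagged, "hk")
  expect_equal(res$unusable, "empty")
  expect_equal(colnames(res$matrix$calls), c("edge", "ok"))
})

test_that("set_het_missing only touches HET", {
  m <- make_gm(rbind(c(P1, HET, P2), c(P1, P1, P2), c(HET, HET, HET)))
  out <- set_het_missing(m)
  expect_equal(unname(out$calls[1, ]), c(P1, MISS, P2))
  expect_equal(unname(out$calls[2, ]), c(P1, P1, P2))
  expect_true(all(is.na(out$calls[3, ])))
  # identity on HET-free input, and idempotent
  expect_equal(set_het_missing(out)$calls, out$calls)
})

test_that("structural filters: triallelic, unphased, missing fraction", {
  calls <- rbind(rep(c(P1, P2), 44),
                 rep(c(P1, P2), 44),
                 c(rep(MISS, 9), rep(c(P1, P2), length.out = 79)),
                 rep(c(P1, P2), 44))
  m <- make_gm(calls, triallelic = c(TRUE, FALSE, FALSE, FALSE),
               phased = c(TRUE, FALSE, TRUE, TRUE))
  out <- structural_filters(m, 0.1)
  expect_equal(out$markers$id, "c1:4000")
  expect_equal(unname(attr(out, "removed")), c(1, 1, 1))
  # 9/88 = 10.2% > 10% was indeed the missing-rule removal
  expect_equal(attr(out, "removed")[["missing_fraction"]], 1)
})

test_that("maf_binomial_test matches the exact binomial CDF", {
  expect_equal(maf_binomial_test(0, 88), 2^-88)
  expect_gt(maf_binomial_test(44, 88), 0.5)
  # oracle: direct summation of C(88, i) / 2^88
  oracle <- sum(choose(88, 0:30)) / 2^88
  expect_equal(maf_binomial_test(30, 88), oracle, tolerance = 1e-12)
  expect_lt(maf_binomial_test(30, 88), 0.01)
})

test_that("double-crossover islands are removed, blocks are not", {
  # sample 1: P1,P2,P1 island at marker 2; sample 2: clean
  calls1 <- cbind(c(P1, P2, P1), rep(P1, 3), rep(P2, 3))
  out1 <- double_crossover_filter(make_gm(calls1))
  expect_equal(out1$markers$pos, c(1000, 3000))
  # 2-marker block is not an island
  calls2 <- cbind(c(P1, P2, P2, P1), rep(P1, 4))
  out2 <- double_crossover_filter(make_gm(calls2))
  expect_equal(nrow(out2$calls), 4)
  # missing neighbour gives no evidence
  calls3 <- cbind(c(P1, MISS, P1), c(P1, P2, MISS))
  out3 <- double_crossover_filter(make_gm(calls3))
  expect_equal(nrow(out3$calls), 3)
  # first/last markers never removed; island rule is per contig
  calls4 <- cbind(c(P2, P1, P2, P1), rep(P1, 4))
  out4 <- double_crossover_filter(make_gm(calls4,
                                          contig = c("a", "a", "b", "b")))
  expect_equal(nrow(out4$calls), 4)  # <3 markers per contig: skipped
})

test_that("small-cluster filter deduplicates segregation patterns", {
  # 30 samples; cluster 1: six distinct patterns chained by one-sample
  # differences (adjacent LOD ~ 7.1 > 5.5); cluster 2: four distinct
  # patterns; cluster 3: ten copies of one isolated pattern
  base <- c(rep(P1, 15), rep(P2, 15))
  shift1 <- lapply(0:5, function(k) c(rep(P1, 15 - k), rep(P2, 15 + k)))
  base2 <- c(rep(P2, 8), rep(P1, 15), rep(P2, 7))
  shift2 <- lapply(0:3, function(k)
    c(rep(P2, 8), rep(P1, 15 - k), rep(P2, 7 + k)))
  lone <- rep(c(rep(P1, 5), rep(P2, 5)), 3)
  calls <- do.call(rbind, c(shift1, shift2,
                            replicate(10, lone, simplify = FALSE)))
  m <- make_gm(calls)
  out <- small_cluster_filter(m, cluster_lod = 5.5, min_cluster_size = 5,
                              min_shared = 10)
  expect_equal(nrow(out$calls), 6)  # only the 6-pattern cluster survives
  out2 <- small_cluster_filter(m, cluster_lod = 5.5, min_cluster_size = 4,
                               min_shared = 10)
  expect_equal(nrow(out2$calls), 10)
})

test_that("lenient cascade follows its stated order", {
  # 88 samples throughout
  mk <- function(v) v
  calls <- rbind(
    c(rep(HET, 2), rep(P1, 43), rep(P2, 43)),        # 2 HET -> removed
    c(rep(MISS, 31), rep(P1, 29), rep(P2, 28)),      # 31 missing -> removed
    c(rep(P1, 75), rep(P2, 5), rep(MISS, 8)),        # minor AF 0.0625 kept
    c(rep(P1, 86), rep(P2, 2)),                      # minor AF 0.023 removed
    c(rep(P1, 5), rep(P2, 3), rep(MISS, 80)))        # called 8 < 10 removed
  m <- make_gm(calls)
  res <- filter_lenient(m, filter_config("lenient"))
  expect_equal(res$matrix$markers$id, "c1:3000")
  rep_df <- res$report
  expect_equal(rep_df$removed[rep_df$rule == "het_calls_position"], 1)
  expect_equal(rep_df$removed[rep_df$rule == "missing_calls"], 1)
  expect_equal(rep_df$removed[rep_df$rule == "called_count"], 1)
  expect_equal(rep_df$removed[rep_df$rule == "minor_allele_frequency"], 1)
  # a binomially skewed but balanced-enough marker is admitted:
  # minor AF 0.25 at n = 88 has cumulative p ~ 1e-6 < 0.01, yet stays
  skew <- make_gm(rbind(c(rep(P1, 66), rep(P2, 22))))
  expect_lt(maf_binomial_test(22, 88), 0.01)
  expect_equal(nrow(filter_lenient(skew)$matrix$calls), 1)
})

test_that("filter rules are idempotent and report counts sum", {
  set.seed(42)
  calls <- matrix(sample(c(P1, P2, HET, MISS), 50 * 30, replace = TRUE,
                         prob = c(0.45, 0.45, 0.05, 0.05)), 50, 30)
  m <- make_gm(calls)
  for (f in list(function(x) filter_positions_basic(x, filter_config("strict", min_called = 10)),
                 set_het_missing,
                 function(x) structural_filters(x, 0.2),
                 double_crossover_filter)) {
    once <- f(m)
    twice <- f(once)
    expect_equal(twice$calls, once$calls)
    expect_equal(twice$markers, once$markers)
  }
  res <- filter_strict(m, filter_config("strict", min_called = 10,
                                        min_shared = 5,
                                        min_cluster_size = 2,
                                        cluster_lod = 2))
  expect_equal(attr(res$report, "n_markers_in") -
                 sum(res$report$removed[!grepl("heterokaryon|unusable|missing_samples",
                                               res$report$rule)]),
               attr(res$report, "n_markers_out"))
})

test_that("binomial rule removes ~alpha of undistorted markers", {
  # high-recombination simulated population so markers are near-independent
  cfg <- sim_config(n_chromosomes = 8, chromosome_length = 5e5,
                    contigs_per_chromosome = 1, marker_spacing = 2000,
                    n_offspring = 88, obligate = FALSE, xo_lambda = 25,
                    missing_rate = 0, error_rate = 0, seed = 11)
  g <- simulate_genome(cfg)
  sim <- simulate_meiosis(cfg, g)
  n <- nrow(sim$matrix$calls)
  expect_gt(n, 1500)
  p <- maf_binomial_test(
    pmin(rowSums(sim$matrix$calls == P1), rowSums(sim$matrix$calls == P2)),
    ncol(sim$matrix$calls))
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.10)
})
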