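# Two-point statistics, clustering, seriation, strict map, r-bar.

test_that("two_point_linkage matches the backcross closed forms", {
  v <- rep(c(P1, P2), 44)
  tp0 <- two_point_linkage(v, v)
  expect_equal(tp0$rf, 0)
  expect_equal(tp0$lod, 88 * log10(2), tolerance = 1e-9)
  # rf exactly 1/2 gives LOD 0
  a <- c(rep(P1, 10), rep(P2, 10))
  b <- c(rep(P1, 5), rep(P2, 10), rep(P1, 5))
  tp5 <- two_point_linkage(a, b)
  expect_equal(tp5$rf, 0.5)
  expect_equal(tp5$lod, 0)
  # n = 20, r = 4
  a2 <- rep(P1, 20)
  b2 <- c(rep(P2, 4), rep(P1, 16))
  tp <- two_point_linkage(a2, b2)
  expect_equal(tp$rf, 0.2)
  expect_equal(tp$lod, 16 * log10(1.6) + 4 * log10(0.4), tolerance = 1e-12)
  expect_equal(tp$lod, 1.674, tolerance = 1e-3)
  # symmetry and phase-flip invariance
  tp_sym <- two_point_linkage(b2, a2)
  expect_equal(tp_sym$lod, tp$lod)
  flip <- function(v) ifelse(v == P1, P2, ifelse(v == P2, P1, v))
  expect_equal(two_point_linkage(flip(a2), flip(b2))$rf, tp$rf)
  # below min_shared: uninformative
  expect_false(two_point_linkage(rep(P1, 5), rep(P1, 5))$informative)
})

test_that("two_point_all agrees with the pairwise function", {
  set.seed(1)
  calls <- matrix(sample(c(P1, P2, MISS), 8 * 40, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), 8, 40)
  tp <- karyolink:::two_point_all(calls, min_shared = 10)
  for (i in 1:7) for (j in (i + 1):8) {
    ref <- two_point_linkage(calls[i, ], calls[j, ], min_shared = 10)
    if (ref$informative) {
      expect_equal(tp$rf[i, j], ref$rf)
      expect_equal(tp$lod[i, j], ref$lod, tolerance = 1e-12)
    } else {
      expect_true(is.na(tp$lod[i, j]))
    }
  }
})

test_that("map_distance implements Haldane and Kosambi", {
  expect_equal(map_distance(0), 0)
  expect_equal(map_distance(0.2, "haldane"), -50 * log(0.6))
  expect_equal(map_distance(0.2, "haldane"), 25.54, tolerance = 1e-3)
  expect_equal(map_distance(0.2, "kosambi"), 25 * log(1.4 / 0.6))
  expect_equal(map_distance(0.2, "kosambi"), 21.18, tolerance = 1e-3)
  expect_error(map_distance(0.6), "outside")
  expect_error(map_distance(-0.1), "outside")
  # cap: rf = 0.5 converts at the cap, finite
  expect_lt(map_distance(0.5), Inf)
})

test_that("linkage groups are single-linkage components", {
  # A,B identical (LOD 26); C close to B; D unlinked noise
  a <- rep(c(P1, P2), 44)
  b <- a
  cc <- a; cc[1:4] <- ifelse(a[1:4] == P1, P2, P1)
  set.seed(9); d <- sample(c(P1, P2), 88, replace = TRUE)
  m <- make_gm(rbind(a, b, cc, d))
  groups <- cluster_linkage_groups(m, lod_threshold = 5.5)
  expect_equal(length(groups), 2)
  expect_equal(sort(groups[[1]]), 1:3)  # transitive closure
  expect_equal(groups[[2]], 4)
  # all unlinked -> singletons
  set.seed(10)
  m2 <- make_gm(matrix(sample(c(P1, P2), 3 * 88, replace = TRUE), 3, 88))
  expect_equal(lengths(cluster_linkage_groups(m2)), rep(1L, 3))
})

test_that("order_markers recovers a gradient order up to reversal", {
  # haplotype-block population: marker i is P1 for samples with
  # breakpoint >= i, so rf grows with |i - j|
  set.seed(3)
  n_s <- 60; n_m <- 8
  bp <- sample(0:n_m, n_s, replace = TRUE)
  calls <- vapply(seq_len(n_s), function(s)
    ifelse(seq_len(n_m) <= bp[s], P2, P1), integer(n_m))
  m <- make_gm(calls)
  ord <- order_markers(m, seq_len(n_m), min_shared = 10)
  expect_true(all(ord == seq_len(n_m)) || all(ord == rev(seq_len(n_m))))
  # orientation normalization picks the smaller (contig,pos) first
  expect_equal(ord[1], 1)
  expect_equal(order_markers(m, c(2L, 5L)), c(2L, 5L))
})

test_that("build_strict_map accumulates Haldane distances", {
  # 40 samples, adjacent rf exactly 0.1 (4/40 recombinants per interval)
  base <- rep(c(P1, P2), 20)
  m2c <- base; m2c[1:4] <- ifelse(base[1:4] == P1, P2, P1)
  m3c <- m2c; m3c[5:8] <- ifelse(m2c[5:8] == P1, P2, P1)
  m <- make_gm(rbind(base, m2c, m3c))
  map <- build_strict_map(m, lod_threshold = 3)
  expect_equal(length(map$groups), 1)
  expect_equal(map$summary$genetic_length_cm,
               2 * map_distance(0.1), tolerance = 1e-9)
  expect_equal(map$summary$genetic_length_cm, 22.31, tolerance = 1e-2)
  # identical markers give a 0 cM group
  m0 <- make_gm(rbind(base, base, base))
  map0 <- build_strict_map(m0, lod_threshold = 3)
  expect_equal(map0$summary$genetic_length_cm, 0)
  # map length is invariant to feeding the markers in reversed order
  mrev <- make_gm(rbind(m3c, m2c, base))
  expect_equal(build_strict_map(mrev, lod_threshold = 3)$summary$genetic_length_cm,
               map$summary$genetic_length_cm)
})

test_that("a binary trait lands next to its generating marker", {
  set.seed(4)
  n_s <- 88
  bp <- sample(0:6, n_s, replace = TRUE)
  calls <- vapply(seq_len(n_s), function(s)
    ifelse(1:6 <= bp[s], P2, P1), integer(6))
  m <- make_gm(calls)
  map <- build_strict_map(m, lod_threshold = 3)
  # trait = marker 4's pattern scored on 30 samples
  trait <- ifelse(calls[4, 1:30] == P2, 1L, 0L)
  names(trait) <- colnames(m$calls)[1:30]
  res <- map_trait_as_marker(m, map, trait, lod_threshold = 3)
  expect_true(res$placed)
  expect_equal(res$best_marker, m$markers$id[4])
  expect_equal(res$best_lod, 30 * log10(2), tolerance = 1e-9)
  # independent trait is not placed
  set.seed(5)
  t2 <- sample(0:1, 30, replace = TRUE)
  names(t2) <- names(trait)
  expect_false(map_trait_as_marker(m, map, t2, lod_threshold = 8)$placed)
})

test_that("compute_rbar combines assortment and crossover shuffling", {
  # two equal chromosomes, no crossovers
  r0 <- compute_rbar(c(1e6, 1e6),
                     list(list(numeric(0), numeric(0)),
                          list(numeric(0), numeric(0))))
  expect_equal(r0$inter, 0.25)
  expect_equal(r0$intra, 0)
  expect_equal(r0$rbar, 0.25)
  # one chromosome, every gamete one crossover at the midpoint
  r1 <- compute_rbar(1e6, list(list(5e5), list(5e5)))
  expect_equal(r1$inter, 0)
  expect_equal(r1$intra, 0.5)
  # 10 equal chromosomes, one uniform crossover each: inter = 0.45,
  # intra ~ 0.1 * 1/3 * ... an order of magnitude below
  set.seed(6)
  gametes <- replicate(400, lapply(1:10, function(i) runif(1, 0, 1e6)),
                       simplify = FALSE)
  r10 <- compute_rbar(rep(1e6, 10), gametes)
  expect_equal(r10$inter, 0.45)
  expect_equal(r10$intra, 0.1 / 3, tolerance = 0.1)
  expect_gt(r10$inter / r10$intra, 8)
  expect_error(compute_rbar(1e6, list()), "empty")
})

test_that("summarize_map computes rates and percentages", {
  s <- data.frame(linkage_group = "LG1", n_markers = 10,
                  genetic_length_cm = 100, longest_interval_cm = 20,
                  physical_length_mb = 6, between_markers_mb = 5)
  ms <- summarize_map(s, assembly_mb = 10)
  expect_equal(ms$rate_cm_per_mb, 20)
  expect_equal(ms$pct_assembly_contigs, 60)
  expect_equal(ms$pct_assembly_between, 50)
  s0 <- s; s0$between_markers_mb <- 0
  expect_error(summarize_map(s0, 10), "zero")
})
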