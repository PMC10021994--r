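# Telomere scans, window tracks, centromere heuristic, intergenic spacing.

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

test_that("scan_telomeres finds terminal motif runs on either strand", {
  set.seed(41)
  s1 <- paste0(rand_seq(3000), strrep("CACTAA", 7))        # 3' CACTAA x7
  s2 <- paste0(strrep("TTAGTG", 5), rand_seq(3000))        # 5' revcomp x5
  s3 <- paste0(rand_seq(1500), strrep("CACTAA", 6), rand_seq(1500))
  s4 <- paste0(rand_seq(3000), strrep("CACTAA", 3))        # below min
  a <- assembly_index(
    c(c1 = nchar(s1), c2 = nchar(s2), c3 = nchar(s3), c4 = nchar(s4)),
    Biostrings::DNAStringSet(c(c1 = s1, c2 = s2, c3 = s3, c4 = s4)))
  hits <- scan_telomeres(a, min_repeats = 4, window = 1000)
  expect_equal(nrow(hits), 2)
  h1 <- hits[hits$contig == "c1", ]
  expect_equal(h1$end, "3p")
  expect_equal(h1$repeat_count, 7)
  expect_equal(h1$span_end, nchar(s1))
  h2 <- hits[hits$contig == "c2", ]
  expect_equal(h2$end, "5p")
  expect_equal(h2$motif, "TTAGTG")
  expect_equal(h2$repeat_count, 5)
})

test_that("scan_telomeres is strand-symmetric", {
  set.seed(42)
  s <- paste0(strrep("TTAGTG", 9), rand_seq(2500), strrep("CACTAA", 4))
  a <- assembly_index(c(c1 = nchar(s)),
                      Biostrings::DNAStringSet(c(c1 = s)))
  rc <- Biostrings::reverseComplement(a$sequences)
  b <- assembly_index(c(c1 = nchar(s)), rc)
  ha <- scan_telomeres(a); hb <- scan_telomeres(b)
  expect_equal(nrow(ha), 2); expect_equal(nrow(hb), 2)
  expect_setequal(ha$repeat_count, hb$repeat_count)
  expect_equal(ha$repeat_count[ha$end == "5p"],
               hb$repeat_count[hb$end == "3p"])
})

test_that("window generation stops at the contig end, drops short tails", {
  gs0 <- gene_set(data.frame(contig = character(), start = integer(),
                             end = integer()))
  a50 <- assembly_index(c(c1 = 50000),
                        Biostrings::DNAStringSet(c(c1 = rand_seq(50000))))
  t50 <- window_gc_gene_density(a50, gs0)
  expect_equal(t50$start, c(1, 10001, 20001))
  expect_equal(t50$end[3], 50000)
  a45 <- assembly_index(c(c1 = 45000),
                        Biostrings::DNAStringSet(c(c1 = rand_seq(45000))))
  t45 <- window_gc_gene_density(a45, gs0)
  expect_equal(t45$start, c(1, 10001, 20001))
  expect_equal(t45$end[3], 45000)  # truncated trailing window kept
  # with the default 10 kb step the tail is always >= 20001 bp, so the
  # W/2 drop rule can only fire for steps > W/2
  a34 <- assembly_index(c(c1 = 34000),
                        Biostrings::DNAStringSet(c(c1 = rand_seq(34000))))
  t34 <- window_gc_gene_density(a34, gs0, window = 30000, step = 20000)
  expect_equal(t34$start, 1)  # 13 kb tail window dropped
})

test_that("window GC and gene density have exact values", {
  s <- paste0(strrep("G", 15000), strrep("A", 15000))
  a <- assembly_index(c(c1 = 30000),
                      Biostrings::DNAStringSet(c(c1 = s)))
  gs <- gene_set(data.frame(contig = "c1", start = 1001L, end = 16000L))
  tr <- window_gc_gene_density(a, gs)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$gc, 0.5)
  expect_equal(tr$gene_density, 0.5)
  allgc <- assembly_index(c(c1 = 30000),
                          Biostrings::DNAStringSet(c(c1 = strrep("GC", 15000))))
  expect_equal(window_gc_gene_density(allgc, gs)$gc, 1.0)
  # window GC equals the length-weighted mean of its halves
  set.seed(43)
  left <- rand_seq(20000, gc = 0.3); right <- rand_seq(10000, gc = 0.7)
  comb <- assembly_index(c(c1 = 30000),
                         Biostrings::DNAStringSet(c(c1 = paste0(left, right))))
  gcpart <- function(x) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(x),
                                     c("A", "C", "G", "T"))
    (f[["C"]] + f[["G"]]) / sum(f)
  }
  expect_equal(window_gc_gene_density(comb, gs0 <- gene_set(data.frame(
    contig = character(), start = integer(), end = integer())))$gc,
    (20000 * gcpart(left) + 10000 * gcpart(right)) / 30000,
    tolerance = 1e-12)
})

test_that("centromere candidates need length and depressed GC", {
  # hand-built track: genome GC 0.53, one contig with a 25 kb cold region
  track <- data.frame(
    contig = "c1",
    start = seq(1, 90001, by = 10000),
    end = seq(30000, 120000, by = 10000),
    gc = c(0.55, 0.55, 0.42, 0.40, 0.41, 0.55, 0.56, 0.55, 0.54, 0.55),
    gene_density = 0.5)
  # genes everywhere except 30-55 kb (25 kb gene-free)
  genes <- gene_set(data.frame(
    contig = "c1",
    start = c(seq(1000, 29000, by = 2000), seq(56000, 119000, by = 2000)),
    end = c(seq(1000, 29000, by = 2000), seq(56000, 119000, by = 2000)) + 1500))
  cand <- call_centromere_candidates(track, genes, min_gene_free = 20000,
                                     gc_margin = 0.02,
                                     contig_lengths = c(c1 = 120000))
  expect_equal(nrow(cand), 1)
  expect_gte(cand$length, 20000)
  expect_lt(cand$mean_gc, cand$genome_gc - 0.02)
  # same run at high GC: no candidate
  track2 <- track; track2$gc <- 0.55
  expect_equal(nrow(call_centromere_candidates(track2, genes,
                                               contig_lengths = c(c1 = 120000))), 0)
  # 15 kb gene-free: too short
  genes2 <- gene_set(data.frame(
    contig = "c1",
    start = c(seq(1000, 39000, by = 2000), seq(56000, 119000, by = 2000)),
    end = c(seq(1000, 39000, by = 2000), seq(56000, 119000, by = 2000)) + 1500))
  expect_equal(nrow(call_centromere_candidates(track, genes2,
                                               min_gene_free = 20000,
                                               contig_lengths = c(c1 = 120000))), 0)
})

test_that("intergenic gaps follow the 1-based inclusive convention", {
  gs <- gene_set(data.frame(contig = "c1",
                            start = c(100, 301), end = c(200, 400)))
  expect_equal(unname(intergenic_spaces(gs)), 100)
  # overlap: no gap
  gs2 <- gene_set(data.frame(contig = "c1",
                             start = c(100, 200), end = c(300, 400)))
  expect_equal(length(intergenic_spaces(gs2)), 0)
  # book-ended: gap 0
  gs3 <- gene_set(data.frame(contig = "c1",
                             start = c(100, 201), end = c(200, 300)))
  expect_equal(unname(intergenic_spaces(gs3)), 0)
  # a single gene contributes nothing
  gs4 <- gene_set(data.frame(contig = "c1", start = 5, end = 10))
  expect_equal(length(intergenic_spaces(gs4)), 0)
})

test_that("gap extraction conserves length on clean annotations", {
  set.seed(44)
  L <- 100000
  starts <- sort(sample(seq(1, L - 2000, by = 1), 30))
  starts <- starts[c(TRUE, diff(starts) > 1200)]
  ends <- starts + 1000
  gs <- gene_set(data.frame(contig = "c1", start = starts, end = ends))
  gaps <- intergenic_spaces(gs)
  flank5 <- starts[1] - 1
  flank3 <- L - ends[length(ends)]
  expect_equal(sum(ends - starts + 1) + sum(gaps) + flank5 + flank3, L)
})

test_that("uniform spacing simulation matches the Dirichlet mean", {
  sim <- simulate_uniform_gene_spacing(rep(1000, 20), 100000,
                                       n_reps = 1000, seed = 45)
  expected <- (100000 - 20000) / 21
  rep_means <- vapply(sim$replicates, mean, numeric(1))
  se <- stats::sd(rep_means) / sqrt(length(rep_means))
  expect_lt(abs(mean(rep_means) - expected), 3 * se)
  # n = 1 gene: no interior gaps
  sim1 <- simulate_uniform_gene_spacing(1000, 10000, n_reps = 10, seed = 1)
  expect_equal(length(sim1$all), 0)
  expect_error(simulate_uniform_gene_spacing(rep(1000, 20), 10000,
                                             n_reps = 2), "exceeds")
})

test_that("clustered annotations show excess small gaps vs uniform", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_length = 4e5,
                    contigs_per_chromosome = 1, marker_spacing = 2e4,
                    seed = 46)
  g <- simulate_genome(cfg)
  uni <- simulate_annotation(g, 150, "uniform")
  clu <- simulate_annotation(g, 150, "clustered")
  gu <- intergenic_spaces(uni); gc_ <- intergenic_spaces(clu)
  thresh <- mean(gu) / 4
  expect_gt(mean(gc_ < thresh), mean(gu < thresh))
  expect_gt(max(gc_), max(gu))
})
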