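Package: karyolink
Title: Linkage Mapping and Recombination-Landscape Analysis for Haploid Fungal Populations
Version: 0.1.0
Authors@R:
    person("Karyolink", "Developers", email = "karyolink@example.org", role = c("aut", "cre"))
Description: Tools for building genetic linkage maps from haploid (homokaryotic
    basidiospore) mapping populations genotyped against a contig-level assembly.
    Implements strict and lenient SNP filter cascades (heterokaryon detection,
    binomial segregation-skew tests, double-crossover island removal), two-point
    LOD linkage and linkage-group clustering, marker seriation, a physical
    assembly-anchored "forced order" map built by chaining contigs through their
    most distal markers, crossover counting with a marker-distance-weighted
    multinomial resampling test for recombination hot- and coldspots
    (Benjamini-Hochberg corrected), the r-bar genome-shuffling statistic, and
    genome-architecture scans (telomere motif runs, sliding-window GC and gene
    density, centromere candidates, intergenic spacing versus a uniform
    gene-placement null). A meiosis simulator generates populations with known
    crossovers, hotspots, segregation distortion and heterokaryon contaminants
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
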