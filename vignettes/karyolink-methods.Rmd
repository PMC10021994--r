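---
title: "karyolink: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{karyolink: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

karyolink analyses haploid (homokaryotic basidiospore) mapping
populations: each offspring is one observable gamete of a single
heterokaryotic parent, every biallelic SNP segregates 1:1, and phase is
anchored by a sequenced parental homokaryon. This vignette records the
model, every threshold that matters, and the decisions taken where the
design was genuinely open.

## Data model and phase

Calls are stored per (marker, sample) as P1, P2, HET or missing. P1 is
*defined* as the allele carried by the sequenced parental homokaryon;
markers where that parent is missing or heterozygous cannot be phased, are
flagged, and are rejected by both filter cascades. HET calls in a haploid
sample are biologically impossible and therefore diagnostic: they arise
from contaminant heterokaryons (germinated spores that mated on the
plate), from paralogous alignment, or from caller noise. Diploid-style
homozygous genotypes (`0/0`, `1/1`) emitted by variant callers for haploid
samples are accepted as haploid calls; true `0/1` calls are kept as HET
because they drive contaminant detection. Coordinates are 1-based
inclusive internally; BED output is 0-based half-open.

## Filter cascades

Two cascades serve two purposes. The **strict** cascade produces markers
reliable enough for de-novo grouping and ordering; the **lenient** one
keeps as many phased markers as possible — including segregation-distorted
regions — for crossover counting on the physically anchored map.

Strict order and defaults (all configurable via `filter_config`):

1. per position: ≥ 40 individuals called, P2 frequency in [0.2, 0.8]
   (HET excluded from the denominator), ≤ 10% HET of called;
2. per sample: > 10% HET flags a heterokaryon, which is removed ("more
   than 10%" is read strictly, so exactly 10% stays);
3. the position rules again on the reduced sample set;
4. HET → missing;
5. triallelic positions, unphased positions, then positions with > 10%
   missing over all remaining samples (the denominator choice — all
   remaining samples, not called ones — is ours);
6. binomial segregation skew: minor-allele count k of n called has
   cumulative probability `pbinom(k, n, 1/2)`; p < 0.01 removes the
   position;
7. double-crossover islands: a call disagreeing with two agreeing
   same-contig neighbours in the same sample implies two crossovers within
   two marker intervals; one offending sample (configurable) removes the
   position. Contig-terminal markers are never removed by this rule;
8. samples with > 10% missing removed;
9. small clusters: markers deduplicated by segregation pattern, connected
   components at LOD > 5.5; components with < 5 unique patterns dropped.

One published step, a `checkF1` quality weight from a polyploid mapping
package, is an undocumented internal statistic and is *not* re-implemented;
steps 6–7 cover its role and the filter report names the substitution.

Lenient order: ≥ 10 called; minor allele frequency ≥ 0.05; parent-HET (and
unphased) positions out; positions with more than one HET call out;
HET → missing; biallelic only; > 30 missing calls out. No skew rule — that
is the point of the lenient set.

## Two-point linkage and maps

For haploid progeny the two-point likelihood is the backcross one:
`LOD = (n−r)·log10(2(1−rf)) + r·log10(2·rf)` with `rf = r/n`, `LOD =
n·log10 2` at r = 0 and 0 at rf = ½. Estimates above ½ are capped. Pairs
sharing fewer than 10 informative samples are treated as uninformative.
Linkage groups are single-linkage components at LOD > 5.5, numbered by
descending marker count.

Ordering within a strict group is seriation: minimize the sum of adjacent
recombination fractions, greedy nearest-neighbour start from the most
isolated marker, then deterministic 2-opt. This replaces the MDS ordering
of the original pipeline; for the group sizes involved 2-opt reaches the
exhaustive optimum on every ≤ 7-marker instance we enumerate in the tests.
Orientation is normalized so the first marker has the smaller
(contig, pos); duplicated patterns tie-break by input order.

Map distance is Haldane by default (`−50·ln(1−2rf)`), Kosambi optional;
the source pipeline never states its function, so it is exposed as a knob.
Adjacent fractions are capped at 0.49 before conversion so one
uninformative adjacency cannot blow up a group length.

**Forced order.** Each contig contributes a head and a tail end,
represented by its most distal marker (second-most-distal as fallback when
the distal one has too few calls — the "first two and last two markers"
device). Ends of different contigs with LOD > 5.5 are matched greedily by
decreasing LOD, each end used at most once, cycles refused; rejected
competing junctions are logged. Chains are read off the matching;
orientation follows from which end enters each junction. Missing calls are
then imputed per contig — forward fill, leading runs filled from the first
call; the imputation boundary is the contig, never the chain — and
centimorgans accumulate along physical-within-contig, chain-across-contig
order. The junction interval's genetic distance is counted in the group
length (the alternative — excluding it — is not what a cumulative map
means), but junction intervals are excluded from the landscape null
because their physical distance is undefined.

## Recombination landscape

Crossovers are counted per offspring wherever adjacent map calls differ.
The null says a crossover lands in interval i with probability
`p_i = d_i / Σd`. We draw 10,000 multinomial samples of the observed total
and compute empirical tails with the `(1+k)/(N+1)` pseudocount convention
(no zero p-values; the convention is ours, the source does not state one).
"At least the observed" includes equality. The two tails are
Benjamini–Hochberg corrected *separately* (high and low calls are separate
questions; a switch exists for joint correction) and flagged at q < 0.05.
Binning accumulates adjacent intervals greedily until 500 kb, never
crossing contig boundaries, keeping the remainder bin; binning conserves
crossover totals. The distance–count association is Spearman's rho with
average ranks and the t approximation.

The r̄ statistic decomposes gamete-level shuffling into independent
assortment, `(1 − Σp_i²)/2` over chromosome length fractions, and a
crossover term `Σ p_i² · mean(2q(1−q))` where q is the fraction of a
chromosome a gamete inherits from one haplotype — two independent uniform
loci on the same chromosome differ in origin with probability exactly
2q(1−q). For ~10 chromosomes assortment exceeds the crossover term by an
order of magnitude, which the acceptance report recomputes.

## Genome-architecture scans

* **Telomeres**: maximal tandem runs of CACTAA or its reverse complement
  TTAGTG within 1000 bp of a contig end; ≥ 4 copies reported (the minimum
  observed in the reference genome; the 1000 bp window stands in for the
  original manual inspection). The scan is strand-symmetric.
* **Windows**: 30 kb windows sliding by 10 kb, starting at 1; generation
  stops at the first window reaching the contig end, and that final
  window is dropped when shorter than half a window (with the default
  step the tail is always ≥ 20 kb, so the drop rule only matters for
  steps > W/2). GC uses ACGT only; gene density is the covered fraction
  after merging overlapping genes.
* **Centromere candidates**: maximal gene-free runs ≥ 20 kb whose
  width-weighted window GC is at least 2 points below the genome mean.
  The 2-point margin operationalizes "low GC" (the source shows deviation
  from the 53% genome mean but no threshold); several candidates per
  contig are allowed, matching the observation of more AT-rich gene
  deserts than chromosomes.
* **Intergenic spaces**: per contig, `gap = next_start − max(previous
  ends) − 1`; book-ended genes give gap 0, overlaps give no gap, terminal
  flanks are excluded. The uniform null keeps the observed per-contig
  gene counts and lengths and redistributes the free length by stick
  breaking (gaps jointly Dirichlet(1,…,1)), so each interior gap has mean
  `free/(n+1)`. The simulation forbids gene overlap and is run per contig;
  whether the original figure allowed overlap or pooled contigs is
  unstated — both choices are documented here rather than guessed.

## The simulator: a stated world

Defaults mirror the mapping design the analysis assumes: 10 chromosomes
(the karyotype evidence brackets 8–13), 7 Mb each (~70 Mb genome), 3
contigs per chromosome, exponential marker spacing with 37 kb mean (the
observed average marker distance), 88 offspring, an obligate crossover per
chromosome (required for faithful segregation) plus Poisson(0.5) extras —
about 1.5 crossovers per chromosome per gamete, i.e. ~150 cM per
chromosome, the magnitude the real maps show. Missing rate 0.05 and error
rate 0.002 are GBS-like choices: enough noise to exercise every filter
without overwhelming an 88-sample design. Hotspots multiply a
piecewise-constant crossover intensity; distortion is viability
resampling — a gamete carrying the disfavoured allele at a distortion
locus is rejected with probability c and redrawn, giving the disfavoured
allele frequency (1−c)/(2−c); heterokaryon contaminants are unions of two
independent viable gametes (HET where they differ), matching their
biological origin in sibling matings. Truth (breakpoints, contaminants,
settings) is recorded before noise. All streams derive from one integer
seed through R's default generator; `simulate_genome`, `simulate_meiosis`
and `simulate_annotation` use seed, seed+1, seed+2 so each stage is
independently reproducible.

What the simulator does **not** emulate: crossover interference (the
analyses do not model it), read-level artefacts (depth, allele balance,
reference bias), linked paralog collapse, and structural variation between
the parents. A green test therefore establishes correctness of the
statistics on data satisfying the model assumptions — not robustness to
alignment-level pathology, which the strict cascade can only partially
absorb.

Desk-scale tests shrink chromosomes ~7x and shrink marker spacing by the
same factor, so relative junction gaps — and hence chaining difficulty —
match the full-size design while suites run in seconds.

## Numerical and degenerate-input choices

* rf estimates are exact ratios; LOD at r = 0 uses the closed form.
* `map_distance` rejects rf outside [0, 0.5]; the 0.49 cap is flagged.
* Empty filter results, single-marker groups (emitted unplaced), contigs
  with < 3 markers (island rule skipped), samples with no calls on a
  contig (left missing, flagged) are all legal and tested.
* Multinomial draws are chunked (2000 per block) to bound memory;
  results are bit-reproducible for a fixed seed.
* BH uses the standard step-up with monotonicity (`p.adjust`).

## Two rate denominators

The genome-wide recombination rate is total cM over total Mb *between
markers*; dividing by the summed length of represented contigs gives a
smaller rate. Published figures mix the two (22.0/22.7 cM/Mb against a
discussion range reaching 17.9), so `summarize_map` reports both and the
package does not guess which is intended where they disagree.

## Known limitations

* Two-point, not multipoint: ordering uses pairwise fractions only; no
  HMM genotype correction.
* The strict map can split a chromosome when a distorted or marker-poor
  region interrupts linkage — the same behaviour the reference maps show
  (13 strict groups for 8–13 chromosomes); per-LG physical lengths can
  then double-count a contig shared by two groups.
* Empirical p-values are bounded below by 1/(N+1); q-value resolution is
  limited accordingly.
* The centromere heuristic is a candidate generator, not a caller; gene
  deserts of repetitive sequence satisfy it too.
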