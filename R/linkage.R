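#' Two-point linkage between two call vectors
#'
#' For a haploid 1:1 population the two-point likelihood is the backcross
#' one: with n informative samples (called in both markers, heterozygous
#' calls treated as missing) and r phase-discordant ones,
#' `rf = r / n` and `LOD = (n - r) log10(2 (1 - rf)) + r log10(2 rf)`,
#' with the conventions `LOD = n log10 2` at r = 0 and `LOD = 0` at
#' rf = 1/2. Estimates above 1/2 (possible by sampling noise) are capped at
#' 1/2.
#'
#' @param gA,gB integer call vectors over the same samples (codes as in
#'   [geno_matrix()]).
#' @param min_shared minimum informative overlap; below it the result is
#'   flagged uninformative (`lod = NA`).
#' @return list with `rf`, `lod`, `n_informative`, `informative` (logical).
#' @export
two_point_linkage <- function(gA, gB, min_shared = 10) {
  ok <- !is.na(gA) & !is.na(gB) & gA != GT_HET & gB != GT_HET
  n <- sum(ok)
  if (n < min_shared)
    return(list(rf = NA_real_, lod = NA_real_, n_informative = n,
                informative = FALSE))
  r <- sum(gA[ok] != gB[ok])
  rf <- min(r / n, 0.5)
  lod <- lod_backcross(n, r)
  list(rf = rf, lod = lod, n_informative = n, informative = TRUE)
}

lod_backcross <- function(n, r) {
  rf <- pmin(r / n, 0.5)
  lod <- ifelse(r == 0, n * log10(2),
                (n - r) * log10(2 * (1 - rf)) +
                  ifelse(r > 0, r * log10(2 * rf), 0))
  pmax(lod, 0)
}

# All-pairs two-point statistics over the rows of a call matrix.
# Returns rf, lod and n matrices; pairs with informative overlap below
# min_shared have NA lod and rf.
two_point_all <- function(calls, min_shared = 10) {
  A <- (calls == GT_P1) & !is.na(calls)
  B <- (calls == GT_P2) & !is.na(calls)
  storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
  nAA <- tcrossprod(A); nBB <- tcrossprod(B)
  nAB <- tcrossprod(A, B)
  n <- nAA + nBB + nAB + t(nAB)
  r <- nAB + t(nAB)
  rf <- ifelse(n > 0, pmin(r / n, 0.5), NA_real_)
  lod <- matrix(NA_real_, nrow(calls), nrow(calls))
  ok <- n >= min_shared
  lod[ok] <- lod_backcross(n[ok], r[ok])
  rf[!ok] <- NA_real_
  dimnames(rf) <- dimnames(lod) <- dimnames(n) <-
    list(rownames(calls), rownames(calls))
  list(rf = rf, lod = lod, n = n)
}

#' Convert a recombination fraction to map distance
#'
#' Haldane: `-50 ln(1 - 2 rf)`; Kosambi: `25 ln((1 + 2 rf)/(1 - 2 rf))`.
#' Fractions at or above `rf_cap` are capped there before conversion so a
#' single uninformative adjacency cannot blow up a map.
#'
#' @param rf recombination fraction(s) in \[0, 0.5\].
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @param rf_cap cap applied before conversion (default 0.49).
#' @return distance(s) in centimorgan.
#' @export
map_distance <- function(rf, map_function = c("haldane", "kosambi"),
                         rf_cap = 0.49) {
  map_function <- match.arg(map_function)
  if (any(rf < 0 | rf > 0.5, na.rm = TRUE))
    stop("recombination fraction outside [0, 0.5]")
  rf <- pmin(rf, rf_cap)
  if (map_function == "haldane") -50 * log(1 - 2 * rf)
  else 25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' Cluster markers into linkage groups
#'
#' Single-linkage connected components of the graph with an edge wherever
#' two-point LOD exceeds `lod_threshold`. Groups are numbered by descending
#' marker count, ties broken by first contig name.
#'
#' @param m a [geno_matrix()].
#' @param lod_threshold default 5.5.
#' @param min_shared minimum informative overlap per pair.
#' @return list of integer vectors of marker row indices, ordered.
#' @export
cluster_linkage_groups <- function(m, lod_threshold = 5.5, min_shared = 10) {
  tp <- two_point_all(m$calls, min_shared = min_shared)
  adj <- tp$lod > lod_threshold & !is.na(tp$lod)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  groups <- split(seq_len(nrow(m$calls)), comp$membership)
  first_contig <- vapply(groups, function(ix) min(m$markers$contig[ix]),
                         character(1))
  ord <- order(-lengths(groups), first_contig)
  unname(groups[ord])
}

#' Order the markers of one linkage group by seriation
#'
#' Minimizes the sum of adjacent recombination fractions with a greedy
#' nearest-neighbour start (from the marker farthest from the rest, a likely
#' end) followed by 2-opt improvement. Fully deterministic; uninformative
#' pairs contribute rf = 1/2. Orientation is normalized so that the first
#' marker has the lexicographically smaller (contig, pos).
#'
#' @param m a [geno_matrix()].
#' @param group integer vector of marker row indices (>= 2 markers).
#' @param min_shared minimum informative overlap per pair.
#' @return `group` reordered.
#' @export
order_markers <- function(m, group, min_shared = 10) {
  k <- length(group)
  if (k < 2) return(group)
  tp <- two_point_all(m$calls[group, , drop = FALSE], min_shared = min_shared)
  d <- tp$rf
  d[is.na(d)] <- 0.5
  diag(d) <- 0
  # nearest-neighbour start from the most isolated marker
  start <- which.max(rowSums(d))
  path <- integer(k); used <- logical(k)
  path[1] <- start; used[start] <- TRUE
  for (i in 2:k) {
    cand <- which(!used)
    nxt <- cand[which.min(d[path[i - 1], cand])]
    path[i] <- nxt; used[nxt] <- TRUE
  }
  path <- two_opt(path, d)
  ord <- group[path]
  key <- function(ix) paste(m$markers$contig[ix], sprintf("%012d", m$markers$pos[ix]))
  if (key(ord[1]) > key(ord[k])) ord <- rev(ord)
  ord
}

# 2-opt improvement of an open path under distance matrix d (sum of
# adjacent distances). Deterministic first-improvement sweeps; segment
# reversals at the path ends cost only the one broken edge.
two_opt <- function(path, d) {
  k <- length(path)
  if (k < 3) return(path)
  # edge cost helper with virtual zero-cost endpoints beyond the path
  edge <- function(i, j) {
    if (i < 1 || j > k) 0 else d[path[i], path[j]]
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (s in 1:(k - 1)) {
      for (t in (s + 1):k) {
        if (s == 1 && t == k) next
        delta <- edge(s - 1, t) + edge(s, t + 1) -
          edge(s - 1, s) - edge(t, t + 1)
        if (delta < -1e-12) {
          path[s:t] <- rev(path[s:t])
          improved <- TRUE
        }
      }
    }
  }
  path
}

# Build a genetic_map object from an ordered list of per-group marker
# tables (id, contig, pos, cm, junction) and an optional assembly.
new_genetic_map <- function(groups, assembly = NULL) {
  if (is.null(names(groups)) || !all(nzchar(names(groups))))
    names(groups) <- paste0("LG", seq_along(groups))
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    span <- tapply(d$pos, d$contig, function(p) max(p) - min(p))
    phys <- if (!is.null(assembly))
      sum(assembly$contig_lengths[unique(d$contig)]) else NA_real_
    gaps <- diff(d$cm)
    data.frame(linkage_group = g, n_markers = nrow(d),
               genetic_length_cm = max(d$cm),
               longest_interval_cm = if (length(gaps)) max(gaps) else 0,
               physical_length_mb = phys / 1e6,
               between_markers_mb = sum(span) / 1e6,
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups, summary = summary), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d linkage groups, %d markers, %.1f cM\n",
              length(x$groups), sum(x$summary$n_markers),
              sum(x$summary$genetic_length_cm)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Build the strict linkage map
#'
#' Clusters markers into linkage groups at `lod_threshold`, orders each
#' group by seriation, and accumulates centimorgan positions from adjacent
#' recombination fractions through the chosen map function. Singleton
#' groups are returned unplaced.
#'
#' @param m a strictly filtered [geno_matrix()].
#' @param assembly optional [assembly_index()] for physical lengths.
#' @param lod_threshold linkage threshold (default 5.5).
#' @param map_function passed to [map_distance()].
#' @param min_shared minimum informative overlap per pair.
#' @return a `genetic_map`; unplaced markers in attribute `unplaced`.
#' @export
build_strict_map <- function(m, assembly = NULL, lod_threshold = 5.5,
                             map_function = "haldane", min_shared = 10) {
  cl <- cluster_linkage_groups(m, lod_threshold, min_shared)
  placed <- cl[lengths(cl) >= 2]
  unplaced <- unlist(cl[lengths(cl) < 2])
  groups <- lapply(placed, function(ix) {
    ord <- order_markers(m, ix, min_shared)
    rfs <- vapply(seq_along(ord)[-1], function(i) {
      tp <- two_point_linkage(m$calls[ord[i - 1], ], m$calls[ord[i], ],
                              min_shared)
      if (is.na(tp$rf)) 0.5 else tp$rf
    }, numeric(1))
    cm <- c(0, cumsum(map_distance(rfs, map_function)))
    data.frame(id = m$markers$id[ord], contig = m$markers$contig[ord],
               pos = m$markers$pos[ord], cm = cm,
               junction = c(FALSE, m$markers$contig[ord][-1] !=
                              m$markers$contig[ord][-length(ord)]),
               stringsAsFactors = FALSE)
  })
  map <- new_genetic_map(groups, assembly)
  attr(map, "unplaced") <- m$markers$id[unplaced]
  map
}

#' Place a binary trait on the map as an extra marker
#'
#' The trait (scored on a subset of samples; unscored samples become
#' missing) is coded as a marker with 0 mapped to P1 and 1 to P2, then
#' placed in the linkage group and flanking interval that maximize
#' two-point LOD.
#'
#' @param m the [geno_matrix()] the map was built from.
#' @param map the `genetic_map`.
#' @param trait named vector over samples with values 0/1/NA.
#' @param min_shared minimum informative overlap (below it: unplaced).
#' @param lod_threshold minimum best LOD for placement.
#' @return list with `placed`, `linkage_group`, `best_marker`, `best_lod`,
#'   `flank_markers`, `flank_lods`.
#' @export
map_trait_as_marker <- function(m, map, trait, min_shared = 10,
                                lod_threshold = 5.5) {
  tv <- rep(NA_integer_, ncol(m$calls))
  names(tv) <- colnames(m$calls)
  shared <- intersect(names(trait), names(tv))
  tv[shared] <- ifelse(is.na(trait[shared]), NA_integer_,
                       ifelse(trait[shared] == 0, GT_P1, GT_P2))
  if (sum(!is.na(tv)) < min_shared)
    return(list(placed = FALSE, reason = "too few scored samples"))
  best <- list(lod = -Inf)
  for (g in names(map$groups)) {
    d <- map$groups[[g]]
    ix <- match(d$id, m$markers$id)
    for (i in seq_along(ix)) {
      tp <- two_point_linkage(tv, m$calls[ix[i], ], min_shared)
      if (tp$informative && !is.na(tp$lod) && tp$lod > best$lod)
        best <- list(lod = tp$lod, group = g, i = i)
    }
  }
  if (!is.finite(best$lod) || best$lod <= lod_threshold)
    return(list(placed = FALSE, reason = "no marker above LOD threshold"))
  d <- map$groups[[best$group]]
  ix <- match(d$id, m$markers$id)
  flank_i <- unique(pmax(1, pmin(nrow(d), c(best$i - 1, best$i + 1))))
  flank_i <- setdiff(flank_i, best$i)
  flank_lods <- vapply(flank_i, function(i)
    two_point_linkage(tv, m$calls[ix[i], ], min_shared)$lod, numeric(1))
  list(placed = TRUE, linkage_group = best$group,
       best_marker = d$id[best$i], best_lod = best$lod,
       flank_markers = d$id[flank_i], flank_lods = flank_lods)
}
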