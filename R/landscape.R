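#' Count crossovers per adjacent-marker interval
#'
#' For each offspring, a crossover is recorded in an interval when the
#' calls at its two flanking markers differ (both non-missing; on an
#' imputed matrix every call is present). Counts are summed over
#' offspring. Intervals spanning a junction between chained contigs are
#' included in the table and flagged (`junction = TRUE`, physical distance
#' `NA`): they contribute to crossover totals but are excluded from the
#' distance-weighted null by default.
#'
#' @param m the (imputed) [geno_matrix()] the map was built from.
#' @param map a `genetic_map` (typically forced order).
#' @return data.frame of class `crossover_table`: `linkage_group`,
#'   `marker1`, `marker2`, `contig`, `start`, `end`, `distance_bp`,
#'   `cm_dist`, `count`, `junction`. The per-offspring 0/1 crossover
#'   indicator matrix is in attribute `per_sample`.
#' @export
count_crossovers <- function(m, map) {
  rows_list <- list(); per_sample <- list()
  for (g in names(map$groups)) {
    d <- map$groups[[g]]
    if (nrow(d) < 2) next
    ix <- match(d$id, m$markers$id)
    if (anyNA(ix)) stop("map marker absent from matrix")
    a <- m$calls[ix[-nrow(d)], , drop = FALSE]
    b <- m$calls[ix[-1], , drop = FALSE]
    diffm <- (a != b) & !is.na(a) & !is.na(b)
    storage.mode(diffm) <- "integer"
    junction <- d$junction[-1]
    rows_list[[g]] <- data.frame(
      linkage_group = g,
      marker1 = d$id[-nrow(d)], marker2 = d$id[-1],
      contig = ifelse(junction, NA_character_, d$contig[-1]),
      start = ifelse(junction, NA_integer_, pmin(d$pos[-nrow(d)], d$pos[-1])),
      end = ifelse(junction, NA_integer_, pmax(d$pos[-nrow(d)], d$pos[-1])),
      distance_bp = ifelse(junction, NA_real_,
                           abs(d$pos[-1] - d$pos[-nrow(d)])),
      cm_dist = diff(d$cm),
      count = rowSums(diffm),
      junction = junction,
      stringsAsFactors = FALSE)
    per_sample[[g]] <- diffm
  }
  out <- do.call(rbind, rows_list)
  rownames(out) <- NULL
  attr(out, "per_sample") <- do.call(rbind, per_sample)
  class(out) <- c("crossover_table", class(out))
  out
}

#' Marker-distance-weighted null probabilities
#'
#' The probability that a crossover falls in interval i under the null of
#' even recombination per bp is its physical distance divided by the sum of
#' all interval distances.
#'
#' @param distances positive physical distances (bp).
#' @return probabilities summing to 1.
#' @export
interval_null_probabilities <- function(distances) {
  if (length(distances) == 0) stop("empty interval set")
  stopifnot(all(distances > 0))
  distances / sum(distances)
}

#' Multinomial resampling test for recombination hot/cold intervals
#'
#' Draws `n_draws` multinomial samples of the observed crossover total with
#' the distance-weighted null probabilities, and for each interval computes
#' the empirical probability of finding at least (`p_more`) or at most
#' (`p_less`) the observed count, with the `(1 + k)/(N + 1)` pseudocount
#' convention so no p-value is exactly zero. Each tail is
#' Benjamini-Hochberg corrected separately across intervals; an interval is
#' flagged `high` when `q_more < alpha` and `low` when `q_less < alpha`.
#'
#' @param observed integer crossover counts per interval.
#' @param probs null probabilities (sum to 1).
#' @param n_draws number of multinomial draws (default 10000).
#' @param alpha flag threshold on the q-value (default 0.05).
#' @param seed optional integer seed for reproducibility.
#' @return data.frame: `observed`, `p_null`, `expected`, `p_more`,
#'   `p_less`, `q_more`, `q_less`, `flag`.
#' @export
multinomial_interval_test <- function(observed, probs, n_draws = 10000,
                                      alpha = 0.05, seed = NULL) {
  stopifnot(length(observed) == length(probs),
            abs(sum(probs) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  total <- sum(observed)
  k <- length(observed)
  n_ge <- numeric(k); n_le <- numeric(k)
  done <- 0
  while (done < n_draws) {
    chunk <- min(2000, n_draws - done)
    draws <- stats::rmultinom(chunk, total, probs)
    n_ge <- n_ge + rowSums(draws >= observed)
    n_le <- n_le + rowSums(draws <= observed)
    done <- done + chunk
  }
  p_more <- (1 + n_ge) / (n_draws + 1)
  p_less <- (1 + n_le) / (n_draws + 1)
  q_more <- bh_adjust(p_more)
  q_less <- bh_adjust(p_less)
  flag <- ifelse(q_more < alpha, "high",
                 ifelse(q_less < alpha, "low", "none"))
  data.frame(observed = observed, p_null = probs,
             expected = total * probs, p_more = p_more, p_less = p_less,
             q_more = q_more, q_less = q_less, flag = flag,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#' @param p p-values in (0, 1].
#' @return q-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Group adjacent intervals into ~fixed-span bins
#'
#' Greedy accumulation of adjacent non-junction intervals along each
#' contig: intervals join the current bin until its cumulative physical
#' distance reaches `target_span`, at which point the bin is closed; bins
#' never cross contig boundaries and a shorter remainder bin is kept at a
#' contig's end. Bin distance and count are sums over members, so binning
#' conserves the crossover total.
#'
#' @param table a `crossover_table`.
#' @param target_span target bin span in bp (default 500 kb).
#' @return data.frame: `linkage_group`, `contig`, `start`, `end`,
#'   `distance_bp`, `count`, `n_intervals`.
#' @export
bin_intervals <- function(table, target_span = 5e5) {
  t2 <- table[!table$junction, , drop = FALSE]
  out <- list()
  for (key in unique(paste(t2$linkage_group, t2$contig))) {
    d <- t2[paste(t2$linkage_group, t2$contig) == key, , drop = FALSE]
    acc_d <- 0; acc_c <- 0; acc_n <- 0; bin_start <- d$start[1]
    for (i in seq_len(nrow(d))) {
      acc_d <- acc_d + d$distance_bp[i]
      acc_c <- acc_c + d$count[i]
      acc_n <- acc_n + 1
      if (acc_d >= target_span || i == nrow(d)) {
        out[[length(out) + 1]] <- data.frame(
          linkage_group = d$linkage_group[1], contig = d$contig[1],
          start = bin_start, end = d$end[i], distance_bp = acc_d,
          count = acc_c, n_intervals = acc_n, stringsAsFactors = FALSE)
        acc_d <- 0; acc_c <- 0; acc_n <- 0
        if (i < nrow(d)) bin_start <- d$start[i + 1]
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman correlation of marker distance and crossover count
#'
#' @param table a `crossover_table` (junction intervals excluded).
#' @return list with `rho` and `p_value` (t-approximation, average ranks
#'   for ties); `rho` is `NA` when either vector is constant.
#' @export
distance_crossover_correlation <- function(table) {
  d <- table[!table$junction, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 intervals")
  if (stats::sd(d$distance_bp) == 0 || stats::sd(d$count) == 0)
    return(list(rho = NA_real_, p_value = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(d$distance_bp, d$count, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Genetic-versus-physical position profile per linkage group
#'
#' Returns, per linkage group, the (physical position, cumulative cM)
#' series of its markers, and reports the largest genetic "jump": the
#' maximum cM increment over any physical window of at most `jump_window`
#' bp within one contig.
#'
#' @param map a `genetic_map` (typically forced order).
#' @param jump_window physical window for the jump statistic (default
#'   200 kb).
#' @return list with `profiles` (named list of data.frames `contig`,
#'   `pos`, `cm`) and `jumps` (data.frame per linkage group).
#' @export
genetic_vs_physical_profile <- function(map, jump_window = 2e5) {
  profiles <- list(); jumps <- list()
  for (g in names(map$groups)) {
    d <- map$groups[[g]]
    if (nrow(d) < 2) {
      profiles[[g]] <- data.frame(contig = character(), pos = integer(),
                                  cm = numeric())
      next
    }
    profiles[[g]] <- d[c("contig", "pos", "cm")]
    best <- data.frame(linkage_group = g, contig = NA_character_,
                       start = NA_integer_, end = NA_integer_, cm_jump = 0)
    for (ct in unique(d$contig)) {
      dd <- d[d$contig == ct, , drop = FALSE]
      dd <- dd[order(dd$pos), , drop = FALSE]
      i <- 1
      for (j in seq_len(nrow(dd))) {
        while (dd$pos[j] - dd$pos[i] > jump_window) i <- i + 1
        jump <- abs(dd$cm[j] - dd$cm[i])
        if (jump > best$cm_jump) {
          best <- data.frame(linkage_group = g, contig = ct,
                             start = dd$pos[i], end = dd$pos[j],
                             cm_jump = jump)
        }
      }
    }
    jumps[[g]] <- best
  }
  list(profiles = profiles, jumps = do.call(rbind, c(jumps,
                                                     make.row.names = FALSE)))
}
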