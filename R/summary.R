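#' Summarize a genetic map against the assembly
#'
#' Totals over linkage groups plus the genome-wide recombination rate,
#' defined as total genetic length divided by total physical length between
#' markers. Because that denominator is a choice (some studies divide by
#' the total length of the represented contigs instead), both rates are
#' reported: `rate_cm_per_mb` (between-marker denominator) and
#' `rate_cm_per_mb_contigs` (represented-contig denominator).
#'
#' @param map a `genetic_map`, or a data.frame shaped like its `$summary`
#'   slot (columns `n_markers`, `genetic_length_cm`, `physical_length_mb`,
#'   `between_markers_mb`).
#' @param assembly_mb total assembly length in Mb (number, or an
#'   [assembly_index()]).
#' @return list of class `map_summary`.
#' @export
summarize_map <- function(map, assembly_mb) {
  s <- if (inherits(map, "genetic_map")) map$summary else map
  if (inherits(assembly_mb, "assembly_index"))
    assembly_mb <- sum(assembly_mb$contig_lengths) / 1e6
  total_cm <- sum(s$genetic_length_cm)
  between_mb <- sum(s$between_markers_mb)
  physical_mb <- sum(s$physical_length_mb)
  if (between_mb <= 0) stop("zero physical length between markers")
  structure(list(
    n_markers = sum(s$n_markers),
    total_genetic_cm = total_cm,
    total_between_mb = between_mb,
    total_physical_mb = physical_mb,
    assembly_mb = assembly_mb,
    rate_cm_per_mb = total_cm / between_mb,
    rate_cm_per_mb_contigs = total_cm / physical_mb,
    pct_assembly_contigs = 100 * physical_mb / assembly_mb,
    pct_assembly_between = 100 * between_mb / assembly_mb),
    class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "map_summary: %d markers, %.1f cM\n",
    "  contigs in map: %.2f Mb (%.1f%% of assembly)\n",
    "  between markers: %.2f Mb (%.1f%% of assembly)\n",
    "  genome-wide rate: %.1f cM/Mb (between-marker), %.1f cM/Mb (contig)\n"),
    x$n_markers, x$total_genetic_cm, x$total_physical_mb,
    x$pct_assembly_contigs, x$total_between_mb, x$pct_assembly_between,
    x$rate_cm_per_mb, x$rate_cm_per_mb_contigs))
  invisible(x)
}

#' Per-linkage-group comparison of two map summaries
#'
#' Computes the percent change of genetic length and of physical length
#' between markers from map `a` to map `b` for each row of `pairing`.
#' A pairing entry on the `a` side may join several groups with `"+"`
#' (e.g. `"LG5+LG11"`), in which case their lengths are summed before the
#' comparison — the situation where two groups of one map fuse into one
#' group of the other.
#'
#' @param a,b `genetic_map` objects or summary data.frames with columns
#'   `linkage_group`, `genetic_length_cm`, `between_markers_mb`.
#' @param pairing data.frame with columns `a` and `b` naming the groups to
#'   compare.
#' @return data.frame with percent changes per pairing.
#' @export
compare_map_summaries <- function(a, b, pairing) {
  sa <- if (inherits(a, "genetic_map")) a$summary else a
  sb <- if (inherits(b, "genetic_map")) b$summary else b
  pick <- function(s, expr) {
    parts <- strsplit(expr, "+", fixed = TRUE)[[1]]
    rows <- s[s$linkage_group %in% parts, , drop = FALSE]
    if (nrow(rows) != length(parts))
      stop("unknown linkage group in pairing: ", expr)
    c(cm = sum(rows$genetic_length_cm), mb = sum(rows$between_markers_mb))
  }
  do.call(rbind, lapply(seq_len(nrow(pairing)), function(i) {
    va <- pick(sa, pairing$a[i]); vb <- pick(sb, pairing$b[i])
    data.frame(a = pairing$a[i], b = pairing$b[i],
               genetic_pct_change = 100 * (vb["cm"] - va["cm"]) / va["cm"],
               physical_pct_change = 100 * (vb["mb"] - va["mb"]) / va["mb"],
               row.names = NULL)
  }))
}
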