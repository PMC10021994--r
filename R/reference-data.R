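#' Published per-linkage-group summaries for the T. cryptogamus maps
#'
#' Reference summary statistics of the published *Termitomyces cryptogamus*
#' linkage maps: the strictly filtered map (13 linkage groups, 1417 markers)
#' and the assembly-anchored forced-order map (13 groups, 2229 markers),
#' together with the v2.0 assembly size and raw SNP count. These are
#' printed reference values, useful as inputs to [summarize_map()] and
#' [compare_map_summaries()] and as golden values in tests; nothing in the
#' package computes them.
#'
#' @return list with elements `strict` and `forced` (data.frames with
#'   columns `linkage_group`, `n_markers`, `genetic_length_cm`,
#'   `longest_interval_cm`, `physical_length_mb`, `between_markers_mb`),
#'   `assembly_mb` (70.03), `n_raw_snps` (1019581) and `n_strict_markers`
#'   (1417).
#' @export
tcryptogamus_map_summary <- function() {
  strict <- data.frame(
    linkage_group = paste0("LG", 1:13),
    n_markers = c(117, 154, 74, 99, 131, 157, 29, 93, 174, 38, 64, 210, 77),
    genetic_length_cm = c(66.9, 149.8, 41.4, 117.2, 67.6, 142.3, 39.5,
                          77.9, 126.9, 15.4, 12.0, 140.1, 104.3),
    longest_interval_cm = c(19.7, 34.6, 14.6, 35.7, 24.0, 28.4, 18.7,
                            24.9, 24.8, 7.3, 6.4, 22.5, 23.8),
    physical_length_mb = c(3.97, 8.02, 4.76, 3.97, 3.85, 5.77, 4.86,
                           1.55, 5.32, 4.22, 1.96, 7.80, 5.39),
    between_markers_mb = c(2.48, 7.08, 4.56, 3.32, 2.69, 5.75, 1.62,
                           2.95, 4.81, 1.02, 1.88, 7.49, 4.31),
    stringsAsFactors = FALSE)
  forced <- data.frame(
    linkage_group = c("LG1", "LG2", "LG3b", "LG4", "LG5_LG11", "LG6",
                      "LG7_LG8", "LG9", "LG10_TIG058", "LG12", "LG13",
                      "LG14", "LG15"),
    n_markers = c(167, 217, 195, 135, 241, 254, 152, 202, 154, 234, 119,
                  96, 63),
    genetic_length_cm = c(71.6, 156.8, 122.7, 95.5, 98.9, 128.4, 139.8,
                          108.0, 89.8, 130.7, 121.6, 62.5, 44.3),
    longest_interval_cm = c(18.2, 21.6, 43.2, 22.7, 35.2, 22.7, 21.6,
                            18.2, 18.2, 19.3, 34.1, 18.2, 18.2),
    physical_length_mb = c(3.98, 8.02, 4.16, 3.97, 5.80, 5.77, 6.41,
                           5.32, 4.65, 7.80, 5.39, 3.38, 2.01),
    between_markers_mb = c(3.35, 7.08, 4.07, 3.41, 5.24, 5.75, 5.52,
                           4.89, 4.27, 7.49, 4.68, 2.99, 1.70),
    stringsAsFactors = FALSE)
  list(strict = strict, forced = forced, assembly_mb = 70.03,
       n_raw_snps = 1019581L, n_strict_markers = 1417L)
}
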