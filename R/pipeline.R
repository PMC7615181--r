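#' Run the full MS2 fragmentation-landscape analysis
#'
#' Convenience wrapper chaining [fragment_ladder()],
#' [match_fragments()], [normalize_by_charge()], [site_profile()],
#' [coverage()], [sequence_tags()], [pair_heatmap()],
#' [group_repeats()], [complementary_pairs()] and
#' [topology_enrichment()].
#'
#' @param peaks a [peak_list()] of MS2 centroids.
#' @param spec a [protein_spec()].
#' @param z_max highest fragment charge considered (default 10).
#' @param tol_ppm match tolerance (default 10 ppm).
#' @param min_tag minimum sequence-tag length (default 3).
#' @param n_perm permutations for topology enrichment (default 1000).
#' @param seed RNG seed for the permutation null.
#' @param normalize_direction passed to [normalize_by_charge()].
#' @return list of class `fragment_analysis` with elements `matches`,
#'   `profile`, `coverage_pct`, `tags`, `heatmap`, `repeats`,
#'   `complementary`, `enrichment`, `unique_counts`.
#' @export
analyze_fragments <- function(peaks, spec, z_max = 10L, tol_ppm = 10,
                              min_tag = 3L, n_perm = 1000L, seed = 1L,
                              normalize_direction = "divide") {
  L <- nchar(spec$sequence)
  ladder <- fragment_ladder(spec, "mono")
  matches <- match_fragments(peaks, ladder, z_max = z_max, tol_ppm = tol_ppm)
  matches <- normalize_by_charge(matches, normalize_direction)
  profile <- site_profile(matches, L)
  structure(list(
    matches = matches,
    profile = profile,
    coverage_pct = coverage(matches, L),
    tags = sequence_tags(matches, spec$sequence, min_len = min_tag),
    heatmap = pair_heatmap(matches, spec$sequence),
    repeats = group_repeats(matches),
    complementary = complementary_pairs(matches, L),
    enrichment = topology_enrichment(profile, spec, n_perm = n_perm,
                                     seed = seed),
    unique_counts = unique_fragment_counts(matches)
  ), class = "fragment_analysis")
}

#' @export
print.fragment_analysis <- function(x, ...) {
  cat(sprintf(
    "fragment_analysis: %d matches, coverage %.1f%%, %d tag(s), TM fraction %.3f (p = %.3g)\n",
    nrow(x$matches), x$coverage_pct, nrow(x$tags),
    x$enrichment$tm_fraction, x$enrichment$p_value))
  invisible(x)
}

#' Bar plot of the per-site fragmentation profile
#'
#' Site abundance bars shaded by weighted average charge, with TM
#' helices overlaid as shaded boxes.
#'
#' @param profile a [site_profile()].
#' @param spec optional [protein_spec()] for the topology overlay.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the profile.
#' @export
plot_site_profile <- function(profile, spec = NULL, ...) {
  x <- profile$site
  y <- profile$abundance
  zc <- profile$weighted_avg_charge
  graphics::plot(x, y, type = "n", xlab = "cleavage site (residue)",
                 ylab = "normalized abundance (max = 100)", ...)
  if (!is.null(spec)) {
    tmseg <- spec$topology[spec$topology$kind == "TM_helix", , drop = FALSE]
    if (nrow(tmseg))
      graphics::rect(tmseg$start, 0, tmseg$end, 105,
                     col = grDevices::adjustcolor("gold", 0.25), border = NA)
  }
  zr <- range(zc, na.rm = TRUE)
  shade <- rep(0.5, length(zc))
  if (is.finite(zr[1]) && diff(zr) > 0)
    shade <- (zc - zr[1]) / diff(zr)
  cols <- grDevices::rgb(0, 0, 1 - 0.8 * ifelse(is.na(shade), 0, shade),
                         alpha = 0.9)
  graphics::segments(x, 0, x, y, col = cols, lwd = 2)
  invisible(profile)
}

#' Heat-map image of residue-pair cleavage abundance
#'
#' @param heatmap a [pair_heatmap()] matrix.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the matrix.
#' @export
plot_pair_heatmap <- function(heatmap, ...) {
  codes <- rownames(heatmap)
  graphics::image(seq_len(20), seq_len(20), unclass(heatmap),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "N-terminal residue",
                  ylab = "C-terminal residue", ...)
  graphics::axis(1, at = seq_len(20), labels = codes, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(20), labels = codes, cex.axis = 0.7, las = 2)
  graphics::box()
  invisible(heatmap)
}
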