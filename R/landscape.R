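#' Charge-normalize fragment intensities
#'
#' Image-current detectors report signal proportional to ion charge, so
#' dividing raw intensity by `z` estimates relative ion counts and
#' makes fragments comparable across charge states.  The direction is
#' configurable for detectors with other response laws.
#'
#' @param matches a [match_fragments()] result.
#' @param direction `"divide"` (default), `"multiply"` or `"none"`.
#' @return `matches` with a `normalized_intensity` column.
#' @export
normalize_by_charge <- function(matches,
                                direction = c("divide", "multiply", "none")) {
  direction <- match.arg(direction)
  matches$normalized_intensity <- switch(direction,
    divide = matches$raw_intensity / matches$z,
    multiply = matches$raw_intensity * matches$z,
    none = matches$raw_intensity)
  matches
}

#' Per-cleavage-site fragmentation profile
#'
#' Sums charge-normalized intensity per cleavage site and rescales so
#' the most abundant site reads 100 (ratio-preserving); also reports the
#' intensity-weighted average charge per site and the number of
#' distinct charge states (repeat fragments).
#'
#' @param matches a [normalize_by_charge()] result.
#' @param L sequence length.
#' @return data frame of class `site_profile` with one row per site
#'   `1..L-1`: `site`, `abundance` (max 100), `weighted_avg_charge`,
#'   `n_charge_states`, `ion_types`.  The pre-rescale sums are kept in
#'   `attr(, "raw_abundance")`.
#' @export
site_profile <- function(matches, L) {
  if (L < 2) stop("need L >= 2")
  if (nrow(matches) && is.null(matches$normalized_intensity))
    stop("call normalize_by_charge() first")
  sites <- seq_len(L - 1L)
  raw <- numeric(L - 1L)
  wz <- rep(NA_real_, L - 1L)
  nz <- integer(L - 1L)
  types <- character(L - 1L)
  if (nrow(matches)) {
    sp <- split(matches, factor(matches$site, levels = sites))
    for (i in sites) {
      m <- sp[[i]]
      if (!nrow(m)) next
      raw[i] <- sum(m$normalized_intensity)
      wz[i] <- sum(m$z * m$normalized_intensity) / raw[i]
      nz[i] <- length(unique(m$z))
      types[i] <- paste(sort(unique(m$ion_type)), collapse = ",")
    }
  }
  abundance <- if (any(raw > 0)) 100 * raw / max(raw) else raw
  out <- data.frame(site = sites, abundance = abundance,
                    weighted_avg_charge = wz, n_charge_states = nz,
                    ion_types = types)
  attr(out, "raw_abundance") <- raw
  class(out) <- c("site_profile", "data.frame")
  out
}

#' Sequence coverage
#'
#' Percentage of the `L - 1` backbone cleavage sites with at least one
#' assigned fragment.  (The residue-denominator alternative,
#' `100 * k / L`, differs by under half a percent for the proteins this
#' package targets.)
#'
#' @param matches a [match_fragments()] result.
#' @param L sequence length (>= 2).
#' @return coverage in percent.
#' @export
coverage <- function(matches, L) {
  if (L < 2) stop("need L >= 2")
  100 * length(unique(matches$site)) / (L - 1)
}

#' Extract sequence tags from runs of adjacent cleavages
#'
#' Successive cleavage at adjacent sites reads out the residues between
#' them: a maximal run of matched sites `i..i+k` yields the tag of
#' residues `i+1..i+k` (each delimited on both sides by an observed
#' cleavage).  Tags of at least `min_len` residues are returned.
#'
#' @param matches a [match_fragments()] result.
#' @param sequence protein sequence.
#' @param min_len minimum tag length in residues (default 3, enough for
#'   useful database lookup).
#' @return data frame with `start`, `end` (residue positions), `tag`,
#'   `n_sites`.
#' @export
sequence_tags <- function(matches, sequence, min_len = 3L) {
  stopifnot(min_len >= 1L)
  empty <- data.frame(start = integer(), end = integer(),
                      tag = character(), n_sites = integer())
  sites <- sort(unique(matches$site))
  if (length(sites) < 2L) return(empty)
  runs <- split(sites, cumsum(c(1L, diff(sites) != 1L)))
  out <- lapply(runs, function(r) {
    k <- length(r) - 1L
    if (k < min_len) return(NULL)
    data.frame(start = r[1] + 1L, end = r[length(r)],
               tag = substr(sequence, r[1] + 1L, r[length(r)]),
               n_sites = length(r))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Residue-pair cleavage heat map
#'
#' Accumulates per-site profile abundance into a 20x20 matrix indexed
#' by the residue pair flanking the cleaved bond (N-terminal residue in
#' rows, C-terminal in columns), so charge-remote hot channels such as
#' X|P, D|X and X|G stand out.
#'
#' @param matches a [normalize_by_charge()] result.
#' @param sequence protein sequence.
#' @return 20x20 matrix of class `pair_heatmap`; its total equals the
#'   total [site_profile()] abundance.
#' @export
pair_heatmap <- function(matches, sequence) {
  L <- nchar(sequence)
  prof <- site_profile(matches, L)
  aa <- strsplit(sequence, "")[[1]]
  codes <- rownames(mass_constants()$residues)
  h <- matrix(0, 20, 20, dimnames = list(codes, codes))
  nz <- which(prof$abundance > 0)
  for (i in nz)
    h[aa[i], aa[i + 1L]] <- h[aa[i], aa[i + 1L]] + prof$abundance[i]
  class(h) <- c("pair_heatmap", class(h))
  h
}

#' Transmembrane-topology enrichment of fragmentation
#'
#' Tests whether fragmentation abundance concentrates inside TM helices.
#' The observed statistic is the fraction of total site abundance at
#' sites whose flanking residues both lie in a TM helix.  The null
#' preserves the profile's autocorrelation by circularly shifting the
#' site-abundance vector by uniform random offsets; the p-value is the
#' permutation tail probability `(1 + #{null >= obs}) / (n_perm + 1)`.
#'
#' @param profile a [site_profile()].
#' @param spec the [protein_spec()] providing the topology.
#' @param n_perm number of circular shifts (>= 100).
#' @param seed RNG seed.
#' @return list of class `topology_enrichment`: `tm_fraction`,
#'   `p_value`, `null_mean`, `null_sd`, `per_helix` (helix_index,
#'   abundance), `degenerate` flag (all-zero profile).
#' @export
topology_enrichment <- function(profile, spec, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  x <- profile$abundance
  n <- length(x)
  tm <- topology_map(spec)
  stopifnot(length(tm$site_in_tm) == n)
  total <- sum(x)
  per_helix <- stats::aggregate(
    abundance ~ helix_index,
    data.frame(abundance = x, helix_index = tm$site_helix)[!is.na(tm$site_helix), ],
    sum)
  if (total <= 0) {
    warning("all-zero site profile; enrichment is degenerate")
    return(structure(list(tm_fraction = NA_real_, p_value = 1,
                          null_mean = NA_real_, null_sd = NA_real_,
                          per_helix = per_helix, degenerate = TRUE),
                     class = "topology_enrichment"))
  }
  obs <- sum(x[tm$site_in_tm]) / total
  null <- .with_seed(seed, {
    offs <- sample.int(n - 1L, n_perm, replace = TRUE)
    vapply(offs, function(o) {
      shifted <- x[((seq_len(n) - 1L + o) %% n) + 1L]
      sum(shifted[tm$site_in_tm]) / total
    }, numeric(1))
  })
  structure(list(tm_fraction = obs,
                 p_value = (1 + sum(null >= obs)) / (n_perm + 1),
                 null_mean = mean(null), null_sd = stats::sd(null),
                 per_helix = per_helix, degenerate = FALSE),
            class = "topology_enrichment")
}

#' @export
print.topology_enrichment <- function(x, ...) {
  cat(sprintf("topology_enrichment: TM fraction %.3f (null %.3f +/- %.3f), p = %.4g\n",
              x$tm_fraction, x$null_mean, x$null_sd, x$p_value))
  invisible(x)
}

#' Compare two fragmentation modalities
#'
#' Summarizes each match set over its unique (site, ion type, charge)
#' fragments: mean fragment neutral mass, mean fragment charge, and
#' sequence coverage.  Slow-heating IRMPD typically yields larger and
#' more highly charged fragments than HCD.
#'
#' @param matches_a,matches_b [match_fragments()] results (non-empty).
#' @param L sequence length.
#' @param labels length-2 character, row labels.
#' @return data frame with rows per modality and columns `n_fragments`,
#'   `mean_neutral_mass`, `mean_charge`, `coverage_pct`.
#' @export
compare_modalities <- function(matches_a, matches_b, L,
                               labels = c("IRMPD", "HCD")) {
  if (!nrow(matches_a) || !nrow(matches_b))
    stop("both match sets must be non-empty")
  one <- function(m) {
    u <- unique(m[c("site", "ion_type", "z", "neutral_mass")])
    data.frame(n_fragments = nrow(u),
               mean_neutral_mass = mean(u$neutral_mass),
               mean_charge = mean(u$z),
               coverage_pct = coverage(m, L))
  }
  out <- rbind(one(matches_a), one(matches_b))
  rownames(out) <- labels
  out
}
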