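#' Match observed MS2 centroids to theoretical b/y fragments
#'
#' Every admissible fragment is considered at every charge `1..z_max`.
#' Candidate (peak, fragment, charge) assignments within `tol_ppm` are
#' resolved by a greedy global best-assignment: candidates are taken in
#' order of smallest absolute ppm error, ties broken in favor of the
#' larger fragment, then b before y; each peak is consumed at most once
#' and each (fragment, charge) pair is matched at most once.
#' Disulfide-masked (inadmissible) fragments are never matched.
#'
#' @param peaks a [peak_list()] of centroids.
#' @param ladder data frame from [fragment_ladder()].
#' @param z_max highest fragment charge considered.
#' @param tol_ppm match tolerance in ppm (default 10).
#' @return data frame of class `fragment_matches` with columns `site`,
#'   `ion_type`, `length`, `z`, `neutral_mass`, `theo_mz`,
#'   `observed_mz`, `ppm_error`, `raw_intensity`.
#' @export
match_fragments <- function(peaks, ladder, z_max, tol_ppm = 10) {
  stopifnot(inherits(peaks, "peak_list"), z_max >= 1)
  frag <- ladder[ladder$admissible, , drop = FALSE]
  empty <- data.frame(site = integer(), ion_type = character(),
                      length = integer(), z = integer(),
                      neutral_mass = numeric(), theo_mz = numeric(),
                      observed_mz = numeric(), ppm_error = numeric(),
                      raw_intensity = numeric())
  class(empty) <- c("fragment_matches", "data.frame")
  pm <- peaks$peaks$mz
  pint <- peaks$peaks$intensity
  if (!nrow(frag) || !length(pm)) return(empty)

  # all (fragment, z) targets
  n_f <- nrow(frag)
  zs <- rep(seq_len(z_max), each = n_f)
  fi <- rep(seq_len(n_f), times = z_max)
  theo <- mz(frag$neutral_mass[fi], zs)
  tol_th <- theo * tol_ppm * 1e-6

  # windowed candidate generation over the sorted peak list
  lo <- findInterval(theo - tol_th, pm) + 1L
  hi <- findInterval(theo + tol_th, pm)
  n_cand <- pmax(hi - lo + 1L, 0L)
  has <- n_cand > 0L
  if (!any(has)) return(empty)
  t_idx <- rep(which(has), n_cand[has])
  p_idx <- unlist(lapply(which(has), function(t) lo[t]:hi[t]))
  ppm <- (pm[p_idx] - theo[t_idx]) / theo[t_idx] * 1e6

  cand <- data.frame(t = t_idx, p = p_idx, ppm = ppm,
                     len = frag$length[fi[t_idx]],
                     type = frag$ion_type[fi[t_idx]])
  o <- order(abs(cand$ppm), -cand$len, cand$type,
             frag$site[fi[cand$t]], zs[cand$t])
  cand <- cand[o, , drop = FALSE]

  peak_used <- rep(FALSE, length(pm))
  target_used <- rep(FALSE, length(theo))
  take <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    p <- cand$p[r]; t <- cand$t[r]
    if (peak_used[p] || target_used[t]) next
    peak_used[p] <- TRUE
    target_used[t] <- TRUE
    take[r] <- TRUE
  }
  cand <- cand[take, , drop = FALSE]
  fidx <- fi[cand$t]
  out <- data.frame(site = frag$site[fidx],
                    ion_type = frag$ion_type[fidx],
                    length = frag$length[fidx],
                    z = zs[cand$t],
                    neutral_mass = frag$neutral_mass[fidx],
                    theo_mz = theo[cand$t],
                    observed_mz = pm[cand$p],
                    ppm_error = cand$ppm,
                    raw_intensity = pint[cand$p])
  out <- out[order(out$site, out$ion_type, out$z), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_matches", "data.frame")
  out
}

#' Group repeat fragments by cleavage site
#'
#' Repeat fragments are ions from the same cleavage site detected at
#' multiple charge states; grouping them reveals preferred sites.
#'
#' @param matches a [match_fragments()] result.
#' @return data frame with one row per site: `site`, `n_matches`,
#'   `n_charge_states` (distinct charges), `charge_states`
#'   (comma-separated), `ion_types`.
#' @export
group_repeats <- function(matches) {
  if (!nrow(matches))
    return(data.frame(site = integer(), n_matches = integer(),
                      n_charge_states = integer(),
                      charge_states = character(), ion_types = character()))
  sp <- split(matches, matches$site)
  out <- do.call(rbind, lapply(sp, function(m) {
    zs <- sort(unique(m$z))
    data.frame(site = m$site[1], n_matches = nrow(m),
               n_charge_states = length(zs),
               charge_states = paste(zs, collapse = ","),
               ion_types = paste(sort(unique(m$ion_type)), collapse = ","))
  }))
  rownames(out) <- NULL
  out[order(out$site), , drop = FALSE]
}

#' Complementary b/y pairs
#'
#' Sites where both the b ion (length `i`) and the matching y ion
#' (length `L - i`) were observed; complementary pairs pin the cleavage
#' site unambiguously.
#'
#' @param matches a [match_fragments()] result.
#' @param L sequence length (for reporting the y length).
#' @return data frame with `site`, `n_b`, `n_y`, `y_length`.
#' @export
complementary_pairs <- function(matches, L) {
  if (!nrow(matches))
    return(data.frame(site = integer(), n_b = integer(), n_y = integer(),
                      y_length = integer()))
  tab <- table(matches$site, matches$ion_type)
  have_b <- "b" %in% colnames(tab)
  have_y <- "y" %in% colnames(tab)
  if (!have_b || !have_y)
    return(data.frame(site = integer(), n_b = integer(), n_y = integer(),
                      y_length = integer()))
  sites <- as.integer(rownames(tab))
  both <- tab[, "b"] > 0 & tab[, "y"] > 0
  data.frame(site = sites[both],
             n_b = as.integer(tab[both, "b"]),
             n_y = as.integer(tab[both, "y"]),
             y_length = L - sites[both])
}

#' Count unique fragments
#'
#' Two uniqueness conventions are reported side by side: by cleavage
#' site and ion type, and by site, type and charge (repeat fragments
#' counted separately).
#'
#' @param matches a [match_fragments()] result.
#' @return named list `by_site_type`, `by_site_type_charge`.
#' @export
unique_fragment_counts <- function(matches) {
  list(
    by_site_type = nrow(unique(matches[c("site", "ion_type")])),
    by_site_type_charge = nrow(unique(matches[c("site", "ion_type", "z")]))
  )
}
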