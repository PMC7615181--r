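# independent oracles and small fixture builders, kept deliberately naive

AA20 <- rownames(mass_constants()$residues)

random_sequence <- function(n) paste(sample(AA20, n, replace = TRUE),
                                     collapse = "")

match_key <- function(d) paste(d$site, d$ion_type, d$z)

# brute-force matcher: every peak x every admissible fragment x every
# charge, then greedy global assignment by (|ppm|, longer fragment,
# b before y); the reference the fast windowed matcher must equal
oracle_match_fragments <- function(peaks, ladder, z_max, tol_ppm) {
  frag <- ladder[ladder$admissible, , drop = FALSE]
  pm <- peaks$peaks$mz
  cand <- list()
  for (f in seq_len(nrow(frag))) {
    for (z in seq_len(z_max)) {
      theo <- (frag$neutral_mass[f] + z * 1.007276) / z
      for (p in seq_along(pm)) {
        ppm <- (pm[p] - theo) / theo * 1e6
        if (abs(ppm) <= tol_ppm)
          cand[[length(cand) + 1L]] <- data.frame(
            f = f, z = z, p = p, ppm = ppm,
            len = frag$length[f], type = frag$ion_type[f],
            site = frag$site[f])
      }
    }
  }
  if (!length(cand))
    return(data.frame(site = integer(), ion_type = character(),
                      z = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(abs(cand$ppm), -cand$len, cand$type, cand$site,
                     cand$z), ]
  peak_used <- rep(FALSE, length(pm))
  target_used <- character()
  out <- list()
  for (r in seq_len(nrow(cand))) {
    tk <- paste(cand$f[r], cand$z[r])
    if (peak_used[cand$p[r]] || tk %in% target_used) next
    peak_used[cand$p[r]] <- TRUE
    target_used <- c(target_used, tk)
    out[[length(out) + 1L]] <- cand[r, ]
  }
  out <- do.call(rbind, out)
  data.frame(site = out$site, ion_type = out$type, z = out$z)
}

# default 7-TM test protein (GPCR-like) and an 11-TM channel-like trimer
gpcr_spec <- function(seed = 1, n_disulfides = 2)
  make_protein(7, helix_len = 24, loop_len = 14,
               n_disulfides = n_disulfides, seed = seed)

amtb_spec <- function(seed = 3)
  make_protein(11, helix_len = 24, loop_len = 14, oligomer_count = 3,
               seed = seed, id = "channel_trimer")

# lipid-free config for detergent-removal sweeps
no_lipid_config <- function(detergent = "DDM", ...) {
  d <- detergent_presets()
  d <- d[d$detergent == detergent, ]
  sim_config(ms1 = list(
    lipid = list(mass = 720, max_count = 0L, abundance_decay = 0.45),
    detergent = list(name = d$detergent, mass = d$mass,
                     power_half = d$power_half, steepness = 8,
                     time_scale = 200, residual_mean_max = 4)), ...)
}
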