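# evaluate code under a local RNG state so generators are pure in `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic alpha-helical membrane protein
#'
#' Builds an idealized polytopic membrane protein: `n_helices`
#' transmembrane helices of `helix_len` residues joined by
#' `n_helices + 1` loops of `loop_len` residues, alternating
#' extracellular (`loop_out`) and cytoplasmic (`loop_in`) sides starting
#' extracellular (the class A GPCR arrangement).  Helices draw from a
#' hydrophobic residue pool (with glycines and prolines at realistic
#' frequencies); loops carry the basic residues.  Disulfide pair `k`
#' bridges cysteines placed in extracellular loops `k` and `k + 1`, so
#' each bond silences the helices it spans - the masked-region geometry
#' seen for receptors with extracellular disulfide networks.
#'
#' @param n_helices number of TM helices (7 for a GPCR fold, 11 for an
#'   AmtB-like channel).
#' @param helix_len residues per helix (default 24, one bilayer span).
#' @param loop_len residues per loop (default 14).
#' @param n_disulfides number of disulfide bridges; requires
#'   `n_disulfides + 1` extracellular loops.
#' @param stability_profile per-helix stability weights in \[0,1\],
#'   recycled to `n_helices`; `NULL` draws them uniformly from
#'   \[0.2, 0.95\].
#' @param oligomer_count subunits in the native complex.
#' @param seed RNG seed (construction is deterministic given the seed).
#' @param id identifier for the spec.
#' @return a [protein_spec()] of length
#'   `n_helices * helix_len + (n_helices + 1) * loop_len`.
#' @examples
#' sp <- make_protein(7, n_disulfides = 2, seed = 1)
#' sp
#' @export
make_protein <- function(n_helices, helix_len = 24L, loop_len = 14L,
                         n_disulfides = 0L, stability_profile = NULL,
                         oligomer_count = 1L, seed = 1L,
                         id = sprintf("synthetic_%dtm", n_helices)) {
  stopifnot(n_helices >= 1L, helix_len >= 1L, loop_len >= 1L,
            n_disulfides >= 0L)
  .with_seed(seed, {
    helix_pool <- c(A = 0.16, L = 0.20, I = 0.13, V = 0.13, F = 0.10,
                    G = 0.09, M = 0.05, W = 0.03, S = 0.04, T = 0.04,
                    P = 0.03)
    loop_pool <- c(R = 0.12, K = 0.10, D = 0.08, E = 0.08, N = 0.08,
                   Q = 0.07, S = 0.10, T = 0.08, G = 0.09, P = 0.05,
                   H = 0.04, A = 0.05, Y = 0.03, F = 0.02, W = 0.01)
    n_loops <- n_helices + 1L
    segs <- vector("list", n_helices + n_loops)
    seq_parts <- character(length(segs))
    pos <- 1L
    helix_i <- 0L
    loop_i <- 0L
    for (s in seq_along(segs)) {
      is_helix <- s %% 2L == 0L
      len <- if (is_helix) helix_len else loop_len
      if (is_helix) {
        helix_i <- helix_i + 1L
        kind <- "TM_helix"
        hi <- helix_i
        pool <- helix_pool
      } else {
        loop_i <- loop_i + 1L
        kind <- if (loop_i %% 2L == 1L) "loop_out" else "loop_in"
        hi <- NA_integer_
        pool <- loop_pool
      }
      seq_parts[s] <- paste(sample(names(pool), len, replace = TRUE,
                                   prob = pool), collapse = "")
      segs[[s]] <- data.frame(start = pos, end = pos + len - 1L,
                              kind = kind, helix_index = hi)
      pos <- pos + len
    }
    topology <- do.call(rbind, segs)
    aa <- strsplit(paste(seq_parts, collapse = ""), "")[[1]]

    # disulfides: pair k bridges extracellular loops k and k+1
    out_loops <- which(topology$kind == "loop_out")
    if (n_disulfides > 0L && length(out_loops) < n_disulfides + 1L)
      stop("infeasible disulfide placement: need ", n_disulfides + 1L,
           " extracellular loops, have ", length(out_loops))
    disulfides <- list()
    used <- integer()
    pick <- function(seg) {
      cand <- setdiff(topology$start[seg]:topology$end[seg], used)
      if (!length(cand)) stop("infeasible disulfide placement: loop exhausted")
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    for (k in seq_len(n_disulfides)) {
      i <- pick(out_loops[k]); used <- c(used, i)
      j <- pick(out_loops[k + 1L]); used <- c(used, j)
      aa[c(i, j)] <- "C"
      disulfides[[k]] <- c(i, j)
    }

    if (is.null(stability_profile)) {
      stability_profile <- stats::runif(n_helices, 0.2, 0.95)
    } else {
      stability_profile <- rep_len(stability_profile, n_helices)
    }
    names(stability_profile) <- as.character(seq_len(n_helices))

    protein_spec(id, paste(aa, collapse = ""),
                 oligomer_count = oligomer_count,
                 topology = topology, disulfides = disulfides,
                 helix_stability = stability_profile)
  })
}

# shared noise-peak generator
.noise_peaks <- function(mz_lo, mz_hi, max_signal, config) {
  span <- max(mz_hi - mz_lo, 0)
  n <- stats::rpois(1, config$noise_peak_rate * span / 1000)
  if (n == 0L) return(data.frame(mz = numeric(), intensity = numeric()))
  data.frame(mz = stats::runif(n, mz_lo, mz_hi),
             intensity = stats::runif(n, 0, config$noise_intensity_scale *
                                         max_signal))
}

.mz_jitter_ms1 <- function(mz_true, config) {
  if (config$resolution_fwhm <= 0) return(mz_true)
  sdv <- config$resolution_fwhm / 2.3548 * mz_true / config$reference_mz
  mz_true + stats::rnorm(length(mz_true), 0, sdv)
}

#' Simulate a native MS1 spectrum of a detergent-liberated complex
#'
#' Generates the multi-charge peak series of an intact complex carrying
#' residual detergent adducts and a phospholipid adduct ladder.  The
#' mean residual detergent count per ion follows a sigmoid in laser dose
#' (output power times irradiation time scaled to the 200 ms reference):
#' `mu = residual_mean_max / (1 + exp(steepness * (dose - power_half)))`,
#' reproducing the abrupt detergent-bound-to-liberated transition seen
#' when stepping laser power.  Per-ion detergent counts are geometric
#' with mean `mu`; lipid adduct abundance decays geometrically with
#' count.  Charge states are distributed around the Rayleigh-limit
#' heuristic `z_avg = z_coef * sqrt(M)`.
#'
#' @param spec a [protein_spec()].
#' @param power laser output power in W (>= 0).
#' @param time_ms irradiation time in ms (> 0).
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list of class `ms1_sim` with `peaks` (a [peak_list()]) and
#'   `truth` (species table with true m/z, charge and adduct counts;
#'   complex mass; expected residual detergent mean).
#' @export
simulate_ms1 <- function(spec, power, time_ms = 200, config = sim_config(),
                         seed = config$seed) {
  stopifnot(power >= 0, time_ms > 0)
  .with_seed(seed, {
    M <- intact_mass(spec, "avg")
    det <- config$ms1$detergent
    lip <- config$ms1$lipid
    z_avg <- config$ms1$z_coef * sqrt(M)
    z_lo <- max(1L, floor(z_avg - 3 * config$ms1$z_spread))
    z_hi <- ceiling(z_avg + 3 * config$ms1$z_spread)
    zs <- z_lo:z_hi
    wz <- stats::dnorm(zs, z_avg, config$ms1$z_spread)

    mu <- .residual_detergent_mean(power, time_ms, det)
    p_geom <- 1 / (1 + mu)
    kd_max <- max(0L, stats::qgeom(0.999, p_geom))
    kds <- 0L:kd_max
    wd <- stats::dgeom(kds, p_geom)
    kls <- 0L:lip$max_count
    wl <- lip$abundance_decay^kls
    wl <- wl / sum(wl)

    species <- expand.grid(z = zs, n_detergent = kds, n_lipid = kls)
    w <- stats::dnorm(species$z, z_avg, config$ms1$z_spread) *
      stats::dgeom(species$n_detergent, p_geom) *
      wl[species$n_lipid + 1L]
    species$intensity <- config$ms1$n_ions * w *
      exp(stats::rnorm(nrow(species), 0, 0.2))
    keep <- species$intensity > 1e-6 * max(species$intensity)
    species <- species[keep, , drop = FALSE]
    species$mass <- M + species$n_detergent * det$mass +
      species$n_lipid * lip$mass
    species$true_mz <- mz(species$mass, species$z)

    mz_obs <- .mz_jitter_ms1(species$true_mz, config)
    lo <- min(species$true_mz) * 0.95
    hi <- max(species$true_mz) * 1.05
    noise <- .noise_peaks(lo, hi, max(species$intensity), config)

    pk <- peak_list(c(mz_obs, noise$mz), c(species$intensity, noise$intensity),
                    metadata = list(ms_level = 1L, activation = "IR",
                                    power_W = power, time_ms = time_ms,
                                    detergent = det$name))
    rownames(species) <- NULL
    structure(list(peaks = pk,
                   truth = list(species = species, complex_mass = M,
                                residual_detergent_mean = mu,
                                z_avg = z_avg)),
              class = "ms1_sim")
  })
}

# per-site cleavage propensities for the MS2 model
.site_propensities <- function(spec, precursor_z, config) {
  aa <- strsplit(spec$sequence, "")[[1]]
  L <- length(aa)
  sites <- seq_len(L - 1L)
  pw <- config$ms2$pair_weights
  p <- pw[cbind(aa[sites], aa[sites + 1L])]

  tm <- topology_map(spec)
  stab <- rep(0, L - 1L)
  hs <- tm$site_helix
  known <- !is.na(hs) & as.character(hs) %in% names(spec$helix_stability)
  stab[known] <- spec$helix_stability[as.character(hs[known])]
  p <- p * (1 + config$ms2$helix_weight_scale * stab)

  # proton sequestration: basic side chains pin mobile protons nearby
  basic <- which(aa %in% c("R", "K"))
  if (length(basic)) {
    d <- config$ms2$basic_distance
    near <- vapply(sites, function(i)
      any(abs(basic - i) <= d | abs(basic - (i + 1L)) <= d), logical(1))
    p[near] <- p[near] * config$ms2$loop_basic_residue_penalty
  }
  p <- pmax(p, config$ms2$min_propensity_floor)

  # silence disulfide-masked sites entirely
  for (pair in spec$disulfides)
    p[sites >= pair[1] & sites < pair[2]] <- 0

  if (sum(p) <= 0) stop("all cleavage sites are disulfide-masked")
  p / sum(p)
}

#' Simulate an MS2 fragment spectrum (IRMPD or HCD)
#'
#' Samples backbone cleavages from per-site propensities built from
#' residue-pair weights (charge-remote X|P, D|X and N-terminal-to-Gly
#' channels), per-helix stability weights, and suppression near
#' proton-sequestering basic residues, with disulfide-masked sites
#' silenced.  Each sampled site emits a b or y ion - the activation
#' preset sets the probability of retaining the longer of the pair and
#' the fragment charge, partitioned roughly in proportion to fragment
#' length (`z = 1 + Binomial(z_prec - 2, charge_factor * len / L_total)`).
#' IRMPD's slow heating keeps larger, more highly charged fragments than
#' HCD.  Complementary b/y pairs co-emit with probability
#' `complementary_prob`.  Raw peak intensity is ion abundance times
#' charge (image-current detection), so downstream charge normalization
#' recovers abundance.
#'
#' @param spec a [protein_spec()].
#' @param precursor_z precursor charge (>= 2; one charge cannot
#'   partition over two fragments).
#' @param activation `"IRMPD"` or `"HCD"`.
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param jitter set `FALSE` for the exact, noise-free mode in which
#'   matching must recover every emitted fragment.
#' @return list of class `ms2_sim` with `peaks` (a [peak_list()]) and
#'   `truth`: `propensity` (length L-1, sums to 1 over admissible
#'   sites), `emitted` (site, ion_type, z, length, neutral_mass,
#'   true_mz, abundance), `mobile_protons`.
#' @export
simulate_ms2 <- function(spec, precursor_z, activation = c("IRMPD", "HCD"),
                         config = sim_config(), seed = config$seed,
                         jitter = TRUE) {
  activation <- match.arg(activation)
  precursor_z <- as.integer(precursor_z)
  if (is.na(precursor_z) || precursor_z < 2L)
    stop("precursor_z must be >= 2 (cannot partition charge)")
  .with_seed(seed, {
    L <- nchar(spec$sequence)
    L_total <- L * spec$oligomer_count
    preset <- config$ms2[[tolower(activation)]]
    prop <- .site_propensities(spec, precursor_z, config)
    ladder <- fragment_ladder(spec, "mono")
    b_mass <- ladder$neutral_mass[ladder$ion_type == "b"]
    y_mass <- ladder$neutral_mass[ladder$ion_type == "y"]

    aa <- strsplit(spec$sequence, "")[[1]]
    mobile <- max(1L, precursor_z - sum(aa %in% c("R", "K", "H")))

    n <- config$ms2$n_fragments
    site <- sample.int(L - 1L, n, replace = TRUE, prob = prop)
    longer_is_b <- site > L - site          # b length = site, y length = L - site
    take_long <- stats::runif(n) < preset$long_frag_bias
    is_b <- ifelse(take_long, longer_is_b, !longer_is_b)
    # emit complementary partner for a subset of draws
    comp <- stats::runif(n) < config$ms2$complementary_prob
    site <- c(site, site[comp])
    is_b <- c(is_b, !is_b[comp])

    len <- ifelse(is_b, site, L - site)
    zf <- 1L + stats::rbinom(length(site), max(precursor_z - 2L, 0L),
                             pmin(1, preset$charge_factor * len / L_total))
    abund <- exp(stats::rnorm(length(site), 0, config$ms2$intensity_cv))

    em <- data.frame(site = site,
                     ion_type = ifelse(is_b, "b", "y"),
                     z = zf, length = len, abundance = abund)
    em <- stats::aggregate(abundance ~ site + ion_type + z + length, em, sum)
    em$neutral_mass <- ifelse(em$ion_type == "b",
                              b_mass[em$site], y_mass[em$site])
    em$true_mz <- mz(em$neutral_mass, em$z)
    em <- em[order(em$site, em$ion_type, em$z),
             c("site", "ion_type", "z", "length", "neutral_mass",
               "true_mz", "abundance")]
    rownames(em) <- NULL

    raw_int <- em$abundance * em$z  # image current scales with charge
    if (jitter && config$ms2$jitter_ppm > 0) {
      mz_obs <- em$true_mz *
        (1 + stats::rnorm(nrow(em), 0, config$ms2$jitter_ppm) * 1e-6)
    } else {
      mz_obs <- em$true_mz
    }
    noise <- if (jitter) {
      .noise_peaks(min(em$true_mz) * 0.9, max(em$true_mz) * 1.1,
                   max(raw_int), config)
    } else data.frame(mz = numeric(), intensity = numeric())

    prec_mz <- mz(intact_mass(spec, "avg"), precursor_z)
    pk <- peak_list(c(mz_obs, noise$mz), c(raw_int, noise$intensity),
                    metadata = list(ms_level = 2L, activation = activation,
                                    precursor_mz = prec_mz,
                                    precursor_z = precursor_z))
    structure(list(peaks = pk,
                   truth = list(propensity = prop, emitted = em,
                                mobile_protons = mobile)),
              class = "ms2_sim")
  })
}
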