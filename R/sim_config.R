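#' Detergent presets for the removal model
#'
#' Half-maximal removal powers (W, at the 200 ms reference irradiation
#' time) for the three detergents used throughout: the glycol ether
#' C8E4 is easiest to strip, the dendritic oligoglycerol G1 is
#' intermediate, and the maltoside DDM needs the most activation.
#'
#' @return data frame with columns `detergent`, `mass` (Da monomer mass)
#'   and `power_half` (W).
#' @export
detergent_presets <- function() {
  data.frame(
    detergent = c("C8E4", "G1", "DDM"),
    mass = c(306.44, 422.00, 510.62),
    power_half = c(2.4, 3.0, 3.6),
    stringsAsFactors = FALSE
  )
}

#' Simulator configuration
#'
#' Bundles every tunable of the synthetic-spectrum generator.  Defaults
#' describe the regime the analysis targets: a native Orbitrap
#' instrument with broad-but-centroided peaks, a sigmoidal
#' detergent-removal law in laser dose (power x scaled time) with an
#' abrupt transition around the per-detergent half power, phospholipid
#' adduct ladders of ~720 Da, and MS2 cleavage propensities built from
#' residue-pair weights (charge-remote X|P and D|X, preference
#' N-terminal to glycine), per-helix stability weights, and suppression
#' of sites adjacent to proton-sequestering basic residues.
#'
#' @param seed default RNG seed used when a generator is called without
#'   one.
#' @param resolution_fwhm MS1 centroid jitter, FWHM in Th at
#'   `reference_mz`; the jitter s.d. scales linearly with m/z.
#' @param reference_mz reference m/z for `resolution_fwhm`.
#' @param noise_peak_rate chemical-noise peaks per 1000 Th.
#' @param noise_intensity_scale noise intensity ceiling as a fraction of
#'   the strongest signal peak.
#' @param ms1 list: `z_coef` (Rayleigh-limit heuristic, z_avg =
#'   z_coef * sqrt(M)), `z_spread` (s.d. in charges), `n_ions` (ions
#'   drawn per spectrum), `lipid` (`mass`, `max_count`,
#'   `abundance_decay`), `detergent` (`name`, `mass`, `power_half`,
#'   `steepness` per W, `time_scale` ms, `time_exponent` for the weak
#'   power-law time dependence of the dose, `residual_mean_max`).
#' @param ms2 list: `n_fragments` (sampling draws), `pair_weights`
#'   (20x20 matrix, rows = N-terminal residue, cols = C-terminal
#'   residue), `helix_weight_scale`, `loop_basic_residue_penalty`,
#'   `basic_distance` (residues), `min_propensity_floor`,
#'   `complementary_prob`, `jitter_ppm` (centroid jitter s.d.),
#'   `intensity_cv` (log-normal s.d. of per-draw abundance), and the
#'   activation presets `irmpd`/`hcd`, each with `long_frag_bias`
#'   (probability of keeping the longer of the b/y pair) and
#'   `charge_factor` (scales the length-proportional charge partition).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       resolution_fwhm = 0.1,
                       reference_mz = 6000,
                       noise_peak_rate = 20,
                       noise_intensity_scale = 0.05,
                       ms1 = list(),
                       ms2 = list()) {
  ms1_def <- list(
    z_coef = 0.0778,
    z_spread = 1.5,
    n_ions = 2000L,
    lipid = list(mass = 720, max_count = 5L, abundance_decay = 0.45),
    detergent = list(name = "DDM", mass = 510.62, power_half = 3.6,
                     steepness = 8, time_scale = 200, time_exponent = 0.135,
                     residual_mean_max = 4)
  )
  ms2_def <- list(
    n_fragments = 250L,
    pair_weights = default_pair_weights(),
    helix_weight_scale = 3,
    loop_basic_residue_penalty = 0.3,
    basic_distance = 2L,
    min_propensity_floor = 1e-4,
    complementary_prob = 0.15,
    jitter_ppm = 2,
    intensity_cv = 0.4,
    irmpd = list(long_frag_bias = 0.45, charge_factor = 0.85),
    hcd = list(long_frag_bias = 0.20, charge_factor = 0.55)
  )
  cfg <- list(
    seed = as.integer(seed),
    resolution_fwhm = resolution_fwhm,
    reference_mz = reference_mz,
    noise_peak_rate = noise_peak_rate,
    noise_intensity_scale = noise_intensity_scale,
    ms1 = utils::modifyList(ms1_def, ms1),
    ms2 = utils::modifyList(ms2_def, ms2)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  stopifnot(cfg$resolution_fwhm >= 0,
            cfg$noise_peak_rate >= 0,
            cfg$noise_intensity_scale >= 0,
            cfg$ms1$z_coef > 0, cfg$ms1$z_spread > 0,
            cfg$ms1$lipid$mass > 0, cfg$ms1$lipid$max_count >= 0,
            cfg$ms1$detergent$mass > 0,
            cfg$ms1$detergent$steepness > 0,
            cfg$ms1$detergent$time_scale > 0,
            cfg$ms1$detergent$residual_mean_max >= 0,
            cfg$ms2$n_fragments >= 1,
            all(cfg$ms2$pair_weights >= 0),
            cfg$ms2$loop_basic_residue_penalty >= 0,
            cfg$ms2$min_propensity_floor >= 0,
            cfg$ms2$complementary_prob >= 0, cfg$ms2$complementary_prob <= 1,
            cfg$ms2$jitter_ppm >= 0)
  invisible(TRUE)
}

#' Default residue-pair cleavage weights
#'
#' Baseline weight 1 for every ordered pair (N-terminal | C-terminal
#' residue), with the enhanced channels seen for low-charge-density
#' precursors: cleavage N-terminal to proline (X|P), C-terminal to
#' aspartate/glutamate (D|X, E|X), and N-terminal to glycine (X|G).
#'
#' @param base baseline weight.
#' @param xp weight for any residue followed by P.
#' @param dx weight for D followed by any residue.
#' @param ex weight for E followed by any residue.
#' @param xg weight for any residue followed by G.
#' @return 20x20 numeric matrix, dimnames the one-letter codes; rows are
#'   the N-terminal residue of the bond, columns the C-terminal one.
#' @export
default_pair_weights <- function(base = 1, xp = 4, dx = 3, ex = 2, xg = 2.5) {
  aa <- rownames(mass_constants()$residues)
  w <- matrix(base, 20, 20, dimnames = list(aa, aa))
  w[, "P"] <- xp
  w["D", ] <- pmax(w["D", ], dx)
  w["E", ] <- pmax(w["E", ], ex)
  w[, "G"] <- pmax(w[, "G"], xg)
  w
}

# Expected residual detergent adducts per ion: sigmoid in laser dose.
# Dose is power times a weak power law in irradiation time: micelle
# stripping trades time against power far less than linearly (a 20x
# shorter pulse needs only ~1.5x more power), so
# g(t) = (t / time_scale)^time_exponent with exponent ~0.135.
.residual_detergent_mean <- function(power, time_ms, det) {
  expo <- if (is.null(det$time_exponent)) 0.135 else det$time_exponent
  dose <- power * (time_ms / det$time_scale)^expo
  det$residual_mean_max / (1 + exp(det$steepness * (dose - det$power_half)))
}
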