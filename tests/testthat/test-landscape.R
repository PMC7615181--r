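fake_matches <- function(site, z, raw, ion_type = "b", L = 100) {
  data.frame(site = site, ion_type = ion_type,
             length = ifelse(ion_type == "b", site, L - site), z = z,
             neutral_mass = site * 110, theo_mz = 1, observed_mz = 1,
             ppm_error = 0, raw_intensity = raw)
}

test_that("charge normalization divides by z (configurably)", {
  m <- fake_matches(c(10, 20), c(3, 1), c(600, 100))
  n <- normalize_by_charge(m)
  expect_equal(n$normalized_intensity, c(200, 100))
  # equal ion counts from raw 300 @ z3 and raw 100 @ z1
  m2 <- normalize_by_charge(fake_matches(c(1, 2), c(3, 1), c(300, 100)))
  expect_equal(m2$normalized_intensity[1], m2$normalized_intensity[2])
  expect_equal(normalize_by_charge(m, "none")$normalized_intensity,
               m$raw_intensity)
  expect_equal(normalize_by_charge(m, "multiply")$normalized_intensity,
               m$raw_intensity * m$z)
})

test_that("site_profile rescales to max 100 preserving ratios", {
  m <- normalize_by_charge(fake_matches(c(10, 10, 30), c(2, 2, 1),
                                        c(40, 40, 20)))
  p <- site_profile(m, 100)
  expect_equal(p$abundance[10], 100)
  expect_equal(p$abundance[30], 50)
  expect_equal(sum(p$abundance > 0), 2)
  raw <- attr(p, "raw_abundance")
  expect_equal(p$abundance[10] / p$abundance[30], raw[10] / raw[30])
  # weighted average charge: equal normalized intensity at z 3 and 5 -> 4
  m2 <- normalize_by_charge(fake_matches(c(7, 7), c(3, 5), c(30, 50)))
  p2 <- site_profile(m2, 100)
  expect_equal(p2$weighted_avg_charge[7], 4)
  expect_equal(p2$n_charge_states[7], 2)
  # single match -> 100; empty -> all zero, no rescale
  expect_equal(max(site_profile(normalize_by_charge(
    fake_matches(5, 2, 8)), 100)$abundance), 100)
  expect_equal(sum(site_profile(m[0, ], 100)$abundance), 0)
})

test_that("coverage counts distinct sites over L-1", {
  m <- fake_matches(c(1, 1, 5, 9), c(1, 2, 1, 1), 1)
  expect_equal(coverage(m, 100), 100 * 3 / 99)
  expect_equal(coverage(m[0, ], 100), 0)
  all_sites <- fake_matches(1:99, 1, 1)
  expect_equal(coverage(all_sites, 100), 100)
  expect_error(coverage(m, 1), "L >= 2")
  # monotone under added matches
  expect_gte(coverage(rbind(m, fake_matches(50, 1, 1)), 100),
             coverage(m, 100))
})

test_that("sequence tags are maximal runs of adjacent cleavages", {
  seqc <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  m <- fake_matches(c(10, 11, 12, 13, 40, 60, 61), 1, 1)
  tags <- sequence_tags(m, seqc, min_len = 3)
  expect_equal(nrow(tags), 1)
  expect_equal(tags$start, 11)
  expect_equal(tags$end, 13)
  expect_equal(tags$tag, substr(seqc, 11, 13))
  expect_equal(tags$n_sites, 4)
  # isolated sites produce nothing at min_len 3
  expect_equal(nrow(sequence_tags(fake_matches(c(5, 9, 30), 1, 1), seqc, 3)), 0)
  # full ladder covers residues 2..L-1
  full <- sequence_tags(fake_matches(1:99, 1, 1), seqc, 3)
  expect_equal(c(full$start, full$end), c(2, 99))
})

test_that("pair heat map accumulates profile abundance conservatively", {
  seqc <- strrep("AG", 20)  # every site is A|G or G|A
  m <- normalize_by_charge(fake_matches(c(1, 3, 5), 1, c(10, 20, 30),
                                        L = nchar(seqc)))
  h <- pair_heatmap(m, seqc)
  expect_equal(sum(h > 0), 1)  # odd sites are all A|G
  p <- site_profile(m, nchar(seqc))
  expect_equal(sum(h), sum(p$abundance))
  expect_equal(h["A", "G"], sum(p$abundance))
})

test_that("elevated X|P weights surface as the P column of the heat map", {
  cfg <- sim_config(ms2 = list(
    pair_weights = default_pair_weights(base = 1, xp = 10, dx = 1,
                                        ex = 1, xg = 1),
    helix_weight_scale = 0, loop_basic_residue_penalty = 1))
  hits <- vapply(1:10, function(s) {
    sp <- make_protein(7, 24, 14, n_disulfides = 0, seed = s)
    s2 <- simulate_ms2(sp, 17, "IRMPD", cfg, seed = s + 400)
    m <- normalize_by_charge(match_fragments(s2$peaks, fragment_ladder(sp),
                                             10, 10))
    h <- pair_heatmap(m, sp$sequence)
    which(h == max(h), arr.ind = TRUE)[1, "col"] == which(colnames(h) == "P")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("topology enrichment behaves at its limits", {
  sp <- gpcr_spec(seed = 3, n_disulfides = 0)
  L <- nchar(sp$sequence)
  tm <- topology_map(sp)
  # all abundance inside TM helices
  m_tm <- normalize_by_charge(fake_matches(which(tm$site_in_tm)[1:20], 1, 5,
                                           L = L))
  prof <- site_profile(m_tm, L)
  enr <- topology_enrichment(prof, sp, n_perm = 200, seed = 1)
  expect_equal(enr$tm_fraction, 1)
  # uniform abundance: fraction equals the TM site share, p unremarkable
  m_u <- normalize_by_charge(fake_matches(1:(L - 1), 1, 5, L = L))
  enr_u <- topology_enrichment(site_profile(m_u, L), sp, n_perm = 200,
                               seed = 1)
  expect_equal(enr_u$tm_fraction, mean(tm$site_in_tm), tolerance = 1e-9)
  expect_gt(enr_u$p_value, 0.2)
  # degenerate all-zero profile
  expect_warning(
    enr0 <- topology_enrichment(site_profile(m_u[0, ], L), sp, 200, 1),
    "degenerate")
  expect_equal(enr0$p_value, 1)
  expect_true(enr0$degenerate)
})

test_that("strong helix weighting is detected as TM enrichment", {
  cfg <- sim_config(ms2 = list(helix_weight_scale = 20))
  ps <- vapply(1:50, function(s) {
    sp <- make_protein(7, 24, 14, n_disulfides = 0, stability_profile = 1,
                       seed = s)
    s2 <- simulate_ms2(sp, 17, "IRMPD", cfg, seed = s + 200)
    m <- normalize_by_charge(match_fragments(s2$peaks, fragment_ladder(sp),
                                             10, 10))
    topology_enrichment(site_profile(m, nchar(sp$sequence)), sp,
                        n_perm = 200, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0.9)
})

test_that("site propensities are recovered by rank at dense sampling", {
  cfg <- sim_config(ms2 = list(n_fragments = 4000L))
  rhos <- vapply(1:20, function(s) {
    sp <- make_protein(7, 24, 14, n_disulfides = 0, seed = s)
    s2 <- simulate_ms2(sp, 17, "IRMPD", cfg, seed = s + 100, jitter = FALSE)
    m <- normalize_by_charge(match_fragments(s2$peaks, fragment_ladder(sp),
                                             20, 10))
    prof <- site_profile(m, nchar(sp$sequence))
    cor(s2$truth$propensity, attr(prof, "raw_abundance"),
        method = "spearman")
  }, numeric(1))
  expect_gte(min(rhos), 0.8)
})

test_that("disulfide-masked sites carry exactly zero abundance", {
  sp <- gpcr_spec(seed = 6)
  masked <- integer()
  for (pair in sp$disulfides)
    masked <- union(masked, pair[1]:(pair[2] - 1L))
  s2 <- simulate_ms2(sp, 17, "IRMPD", sim_config(), seed = 21)
  an <- analyze_fragments(s2$peaks, sp, seed = 1, n_perm = 200)
  expect_equal(sum(an$profile$abundance[masked]), 0)
})

test_that("compare_modalities summarizes unique fragments per modality", {
  a <- fake_matches(c(10, 20), c(2, 4), c(5, 5))
  a$neutral_mass <- c(1000, 3000)
  expect_equal(compare_modalities(a, a, 100)$mean_neutral_mass,
               c(2000, 2000))
  expect_equal(compare_modalities(a, a, 100)[1, ],
               compare_modalities(a, a, 100)[2, ], ignore_attr = TRUE)
  expect_error(compare_modalities(a[0, ], a, 100), "non-empty")
  # simulated IRMPD vs HCD direction through the full pipeline
  sp <- make_protein(7, 24, 14, n_disulfides = 0, seed = 13)
  cfg <- sim_config()
  ladder <- fragment_ladder(sp)
  ir <- match_fragments(simulate_ms2(sp, 17, "IRMPD", cfg, seed = 77)$peaks,
                        ladder, 16, 10)
  hc <- match_fragments(simulate_ms2(sp, 17, "HCD", cfg, seed = 77)$peaks,
                        ladder, 16, 10)
  tab <- compare_modalities(ir, hc, nchar(sp$sequence))
  expect_gt(tab["IRMPD", "mean_neutral_mass"], tab["HCD", "mean_neutral_mass"])
  expect_gt(tab["IRMPD", "mean_charge"], tab["HCD", "mean_charge"])
})
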