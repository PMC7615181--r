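test_that("make_protein builds the requested topology deterministically", {
  sp <- make_protein(7, helix_len = 24, loop_len = 12, n_disulfides = 2,
                     seed = 11)
  expect_equal(sum(sp$topology$kind == "TM_helix"), 7)
  expect_equal(nchar(sp$sequence), 7 * 24 + 8 * 12)
  expect_length(sp$disulfides, 2)
  # both cysteines of every pair sit in extracellular loops
  tm <- topology_map(sp)
  for (pair in sp$disulfides)
    expect_true(all(tm$residue_kind[pair] == "loop_out"))
  # determinism under seed
  sp2 <- make_protein(7, helix_len = 24, loop_len = 12, n_disulfides = 2,
                      seed = 11)
  expect_identical(sp, sp2)
  expect_false(identical(
    sp$sequence,
    make_protein(7, 24, 12, n_disulfides = 2, seed = 12)$sequence))
})

test_that("make_protein arithmetic and feasibility limits hold", {
  sp <- make_protein(11, helix_len = 24, loop_len = 14, n_disulfides = 0,
                     seed = 2)
  expect_equal(nchar(sp$sequence), 11 * 24 + 12 * 14)
  expect_equal(sum(sp$topology$kind == "TM_helix"), 11)
  # 7 helices have 4 extracellular loops: at most 3 chained bridges
  expect_error(make_protein(7, 24, 14, n_disulfides = 4, seed = 1),
               "infeasible")
  # basic residues concentrate in loops
  tm <- topology_map(sp)
  aa <- strsplit(sp$sequence, "")[[1]]
  basic_rate <- function(kind) mean(aa[tm$residue_kind %in% kind] %in% c("R", "K"))
  expect_gt(basic_rate(c("loop_out", "loop_in")), basic_rate("TM_helix") + 0.05)
})

test_that("simulate_ms1 is deterministic and respects the removal-model limits", {
  sp <- amtb_spec()
  cfg <- sim_config()
  a <- simulate_ms1(sp, 4, 200, cfg, seed = 5)
  b <- simulate_ms1(sp, 4, 200, cfg, seed = 5)
  expect_identical(a, b)
  # power >> power_half: essentially bare protein
  high <- simulate_ms1(sp, 9, 200, cfg, seed = 5)
  expect_lt(high$truth$residual_detergent_mean, 0.05)
  expect_true(all(high$truth$species$n_detergent <= 1))
  # power = 0: adduct-dominated
  low <- simulate_ms1(sp, 0, 200, cfg, seed = 5)
  expect_equal(low$truth$residual_detergent_mean,
               cfg$ms1$detergent$residual_mean_max, tolerance = 1e-6)
  bare <- with(low$truth$species, sum(intensity[n_detergent == 0]) /
                 sum(intensity))
  expect_lt(bare, 0.3)
})

test_that("MS1 species m/z and lipid ladder follow the mass arithmetic", {
  sp <- amtb_spec()
  cfg <- sim_config()
  s1 <- simulate_ms1(sp, 9, 200, cfg, seed = 8)
  sp_tab <- s1$truth$species
  M <- s1$truth$complex_mass
  expect_equal(sp_tab$true_mz,
               mz(M + sp_tab$n_detergent * cfg$ms1$detergent$mass +
                    sp_tab$n_lipid * 720, sp_tab$z))
  expect_equal(sort(unique(sp_tab$n_lipid)), 0:5)
})

test_that("residual detergent is monotone non-increasing in power and time", {
  sp <- amtb_spec()
  cfg <- no_lipid_config("DDM")
  mean_adducts <- function(power, time_ms) {
    draws <- sapply(1:200, function(s) {
      tr <- simulate_ms1(sp, power, time_ms, cfg, seed = 4000 + s)$truth
      with(tr$species, sum(n_detergent * intensity) / sum(intensity))
    })
    mean(draws)
  }
  by_power <- sapply(c(2.1, 3.0, 3.6, 4.5), mean_adducts, time_ms = 200)
  expect_true(all(diff(by_power) <= 1e-9))
  by_time <- sapply(c(50, 200, 400), function(t) mean_adducts(3.3, t))
  expect_true(all(diff(by_time) <= 1e-9))
})

test_that("simulate_ms2 propensities follow the flat-model and mask contracts", {
  # all pair weights equal, stability zero, no basics near sites -> uniform
  sp <- protein_spec("flat", strrep("AG", 15))
  cfg <- sim_config(ms2 = list(
    pair_weights = default_pair_weights(1, 1, 1, 1, 1),
    helix_weight_scale = 0))
  s2 <- simulate_ms2(sp, 5, "IRMPD", cfg, seed = 1)
  p <- s2$truth$propensity
  expect_equal(p, rep(1 / length(p), length(p)), tolerance = 1e-12)
  # disulfide-masked sites emit nothing
  spd <- gpcr_spec(seed = 6)
  masked <- integer()
  for (pair in spd$disulfides)
    masked <- union(masked, pair[1]:(pair[2] - 1L))
  s2d <- simulate_ms2(spd, 17, "IRMPD", sim_config(), seed = 2)
  expect_equal(sum(s2d$truth$propensity[masked]), 0)
  expect_false(any(s2d$truth$emitted$site %in% masked))
})

test_that("simulate_ms2 is deterministic and emits exact fragment m/z", {
  sp <- gpcr_spec(seed = 4)
  cfg <- sim_config()
  a <- simulate_ms2(sp, 17, "IRMPD", cfg, seed = 3)
  expect_identical(a, simulate_ms2(sp, 17, "IRMPD", cfg, seed = 3))
  em <- a$truth$emitted
  expect_equal(em$true_mz, mz(em$neutral_mass, em$z))
  # every emitted fragment maps to an admissible theoretical fragment
  fl <- fragment_ladder(sp, "mono")
  key_l <- paste(fl$site, fl$ion_type)[fl$admissible]
  expect_true(all(paste(em$site, em$ion_type) %in% key_l))
  expect_error(simulate_ms2(sp, 1, "IRMPD", cfg), "partition")
})

test_that("IRMPD preset emits larger, more highly charged fragments than HCD", {
  cfg <- sim_config()
  wins_mass <- logical(10)
  wins_z <- logical(10)
  for (s in 1:10) {
    sp <- make_protein(7, 24, 14, n_disulfides = 0, seed = s)
    ir <- simulate_ms2(sp, 17, "IRMPD", cfg, seed = s + 50)$truth$emitted
    hc <- simulate_ms2(sp, 17, "HCD", cfg, seed = s + 50)$truth$emitted
    wins_mass[s] <- mean(ir$neutral_mass) > mean(hc$neutral_mass)
    wins_z[s] <- mean(ir$z) > mean(hc$z)
  }
  expect_true(all(wins_mass))
  expect_true(all(wins_z))
})

test_that("peak lists round-trip through TSV + JSON sidecar", {
  sp <- gpcr_spec(seed = 9)
  s2 <- simulate_ms2(sp, 17, "IRMPD", sim_config(), seed = 1)
  path <- file.path(tempdir(), "ms2.tsv")
  write_peaks(s2$peaks, path)
  back <- read_peaks(path)
  expect_equal(back$peaks, s2$peaks$peaks, tolerance = 1e-12)
  expect_equal(back$metadata$activation, "IRMPD")
  expect_equal(back$metadata$precursor_z, 17)
})

test_that("protein specs round-trip through FASTA + topology JSON", {
  sp <- gpcr_spec(seed = 10)
  fa <- file.path(tempdir(), "seq.fa")
  writeLines(c(">synthetic_7tm", sp$sequence), fa)
  topo <- file.path(tempdir(), "topo.json")
  write_topology(sp, topo)
  back <- read_topology(topo, read_fasta_sequence(fa), id = sp$id)
  expect_equal(back$sequence, sp$sequence)
  expect_equal(back$topology$kind, sp$topology$kind)
  expect_equal(back$disulfides, sp$disulfides)
  expect_equal(back$oligomer_count, sp$oligomer_count)
  expect_equal(unname(back$helix_stability), unname(sp$helix_stability),
               tolerance = 1e-12)
})
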