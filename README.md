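# topdownmem

Native top-down mass spectrometry (MS) of α-helical membrane proteins,
as an analysis pipeline plus a matched simulator.

Membrane proteins are electrosprayed inside detergent micelles that
must be stripped — e.g. by infrared multiphoton dissociation (IRMPD) —
before the liberated ions can be mass-measured and fragmented in the
same experiment. This package implements the downstream analysis of
such experiments for users who have centroided peak lists and a
protein/topology annotation:

* **Intact-mass inference (MS1).** A charge-state series of a species
  of neutral mass *M* appears at *m/z* = (*M* + *z*·m_H⁺)/*z*;
  `fit_charge_series()` grid-searches *M*, scores contiguous charge
  runs by matched intensity, and refines by the intensity-weighted mean
  of *z*(*m/z* − m_H⁺). `detect_adduct_ladder()` finds satellite series
  at fixed mass increments (phospholipids ≈700–730 Da, detergents
  ≈306–511 Da); `resolved_fraction()` scores how completely the
  detergent was removed.
* **Fragment assignment (MS2).** `fragment_ladder()` enumerates all
  b/y ions of a subunit, flags cleavages that would tear a disulfide
  bridge apart (those fragments are never observable), and applies the
  −2H per intact bridge correction. `match_fragments()` assigns peaks
  to fragments across charge states at ppm tolerance with a greedy
  global best-assignment (smallest |ppm|, then longer fragment, then b
  before y; each peak used once).
* **Fragmentation landscape.** Intensities are charge-normalized
  (ion-count estimate: *I*/*z*), summed per cleavage site and rescaled
  to max = 100 (`site_profile()`); `coverage()` reports the percentage
  of the *L*−1 backbone sites observed, `sequence_tags()` extracts runs
  of adjacent cleavages, `pair_heatmap()` accumulates abundance by
  flanking residue pair (X|P, D|X, X|G hot channels), and
  `topology_enrichment()` tests concentration of fragmentation in
  transmembrane helices with a circular-shift permutation null.
* **Simulator.** `make_protein()`, `simulate_ms1()` and
  `simulate_ms2()` generate seeded synthetic proteins and spectra with
  ground truth: charge states around the Rayleigh-limit heuristic
  z ≈ 0.0778·√M, a sigmoidal detergent-removal law in laser dose,
  lipid adduct ladders, and cleavage propensities driven by
  residue-pair weights, helix stability and mobile-proton availability.

## Worked example

```r
library(topdownmem)

spec <- make_protein(7, helix_len = 24, loop_len = 14,
                     n_disulfides = 2, seed = 42)
spec
#> protein_spec 'synthetic_7tm': 280 residues x 1 subunit(s), 7 TM helices, 2 disulfide(s)

sim <- simulate_ms2(spec, precursor_z = 17, activation = "IRMPD",
                    config = sim_config(), seed = 7)
res <- analyze_fragments(sim$peaks, spec, seed = 1)
res
#> fragment_analysis: 180 matches, coverage 29.7%, 6 tag(s), TM fraction 0.823 (p = 0.0979)

head(res$tags, 3)
#>   start end                tag n_sites
#> 1   173 179            IIILMVG       8
#> 2   182 189           TAAGGSGL       9
#> 3   209 226 AAVFALIMVAVTILVPAM      19
```

Reading the output: 180 (fragment, charge) assignments cover 29.7 % of
the 279 backbone cleavage sites — above the >20 % threshold generally
taken as sufficient for unambiguous identification. The three sequence
tags are runs of residues delimited on both sides by observed
cleavages, and all fall inside transmembrane helices; 82.3 % of the
charge-normalized abundance lies at intra-helix sites (the circular
permutation p-value of 0.098 reflects the protein's nearly periodic
helix/loop architecture, which makes shifted profiles resemble the
observed one). Sites such as 178 and 223 are "repeat fragments",
detected at five distinct charge states.

Plotting mirrors the usual figures of the field:

```r
plot_site_profile(res$profile, spec)   # per-site abundance + TM boxes
plot_pair_heatmap(res$heatmap)         # 20x20 residue-pair heat map
```

Command-line entry points live in `inst/cli/` (`deconv.R`, `assign.R`,
`landscape.R`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/deconv.R", package="topdownmem"))')" \
  --peaks spectrum.tsv --mass-min 120000 --mass-max 140000 --zmin 15 --zmax 35
```

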