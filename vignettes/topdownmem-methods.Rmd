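---
title: "Methods: models, parameters and design choices in topdownmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in topdownmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topdownmem)
```

# Scope and model

`topdownmem` analyses native top-down MS experiments on α-helical
membrane proteins: an intact complex is electrosprayed from a
detergent micelle, the micelle is stripped by tunable activation
(laser output power × irradiation time), the liberated ions are
mass-measured (MS1), and an isolated charge state is fragmented
(MS2, IRMPD or HCD) into b/y ions. The package provides both the
analysis and a seeded simulator with ground truth, so that every
statistic the analysis computes can be validated by recovery tests.

## Mass bookkeeping

All masses derive from the canonical residue-mass table
(`mass_constants()`). Intact (MS1) masses use the **average** scale —
native intact masses are reported as integer Da and isotope envelopes
are unresolved at 30–130 kDa — while fragment (MS2) masses use the
**monoisotopic** scale, appropriate for centroided fragment peaks.
Each disulfide bridge removes two hydrogens (2.01588 Da average,
2.015650 Da monoisotopic); `apply_disulfides(40980, 2, "avg")` and
`apply_disulfides(46535, 4, "avg")` reproduce the familiar
receptor-mass corrections to 40976 and 46527 Da.

Only b and y ions are generated: single-backbone-cleavage products
dominate slow-heating spectra of native proteins, and a/x/c/z ions,
internal fragments and neutral losses are out of scope. A cleavage at
site *i* that leaves exactly one cysteine of a disulfide pair on a
fragment is *inadmissible*: the fragment pair remains tethered and is
not observed. Inadmissible fragments are generated and flagged rather
than dropped, so reports can attribute absent signal to masked
regions. Admissible fragments containing *k* intact bridges carry a
−*k*·2H correction. For oligomers the ladder is per subunit; the
oligomer count only scales the MS1 precursor mass, reflecting that
covalent fragmentation of a complex yields subunit-level fragments.

## MS1 deconvolution

`fit_charge_series()` is a deliberately transparent grid search, not a
Bayesian deconvolution: candidate masses on a grid of
`mz_tol/2 × z_min` Da predict peaks at `mz(M, z)`; a candidate scores
the summed intensity of observed peaks within `mz_tol` over its best
contiguous charge run of ≥ 3 charges (shorter runs are too easily
produced by noise). Near-coincident fits (within `2·mz_tol·z_max` Da)
are harmonics of one series and are deduplicated by score. Surviving
fits are refined by the intensity-weighted mean of the per-charge mass
estimates `z·(m/z − m_H⁺)`, which removes the grid quantization: with
default jitter the refined mass is reproducibly within 2 Da of truth
(tested over 50 seeds). The default `mz_tol` of 0.5 Th reflects broad
native peaks.

`resolved_fraction()` defines "resolvedness" operationally as the
fraction of total spectral intensity within `mz_tol` of the predicted
bare-protein series: residual detergent, adduct satellites and noise
all dilute it. It is the metric the removal-threshold analyses use.

## The detergent-removal model

The simulator treats micelle stripping phenomenologically: the mean
residual detergent-adduct count per ion is a sigmoid in laser *dose*,

$$\mu(P, t) = \frac{\mu_{\max}}{1 + \exp\{s\,(P\,g(t) - P_{1/2})\}},
\qquad g(t) = (t/t_{\mathrm{ref}})^{0.135},$$

with per-ion counts geometric with mean μ. The per-detergent
half-powers (C8E4 2.4 W, G1 3.0 W, DDM 3.6 W at the 200 ms reference)
are the experimentally observed minimum liberation powers, and the
steepness (8 W⁻¹) makes the transition abrupt — a 0.3 W step flips the
spectrum from adduct-dominated to resolved. The time exponent is the
one genuinely *derived* constant: observed operating points trade
200 ms at 3.6 W against 10 ms at 5.4 W, i.e. a 20-fold shorter pulse
needs only 1.5-fold more power, giving
$\alpha = \ln(5.4/3.6)/\ln(200/10) \approx 0.135$. A linear time
factor would contradict that trade-off by an order of magnitude. No
physical photon-absorption or micelle-thermodynamics model is
attempted; the removal law is an input, not a prediction.

MS1 charge states are distributed around the Rayleigh-limit heuristic
$z_{\mathrm{avg}} = 0.0778\sqrt{M}$ (≈20+ for 127 kDa, ≈16+ for
41–47 kDa) with an s.d. of 1.5 charges. Phospholipid adducts use a
720 Da default (midpoint of the 700–730 Da signature window) with
geometrically decaying abundance (ratio 0.45) up to 5 copies.

## The MS2 cleavage-propensity model

Per-site propensity is a product of three factors, then masked and
normalized:

* **Residue-pair weights** (20×20, N-terminal | C-terminal): baseline
  1, with the charge-remote channels enhanced — X|P 4, D|X 3, E|X 2,
  X|G 2.5 — matching the empirically hot T|P, I|P, D|X, A|G/F|G/V|G
  cleavages of low-charge-density precursors.
* **Helix stability**: `1 + helix_weight_scale × stability(helix)`,
  with per-helix stability weights in [0,1] supplied by the user (or
  the generator). This encodes the observation that helices retaining
  structure during activation fragment *more*, and replaces any
  molecular-dynamics-based prediction, which is a non-goal.
* **Proton access**: sites within 2 residues of R/K are multiplied by
  0.3 — arginine/lysine sequester the few mobile protons of a native
  precursor, suppressing charge-directed cleavage nearby. The mobile
  proton count `max(1, z − #(R,K,H))` is recorded in the ground truth.

Disulfide-masked sites are zeroed exactly. Each of `n_fragments`
(default 250) multinomial draws picks a site, keeps the longer of the
b/y pair with probability `long_frag_bias`, and draws a charge
`1 + Binomial(z_prec − 2, charge_factor × len/L_total)` — charge
partitions roughly proportionally to length, capped by the precursor.
The two activation presets differ only in these two numbers (IRMPD
0.45/0.85, HCD 0.20/0.55), chosen so that the simulated IRMPD mean
fragment mass and charge sit near the observed ratios of
IRMPD-to-HCD fragment size (~8.9 vs ~5.8 kDa) and charge (~4.7 vs
~3.6) at a 16–18+ precursor — the simulator reproduces the
*direction* robustly, while absolute magnitudes depend on the protein.
Complementary b/y pairs co-emit with probability 0.15. Raw peak
intensity is ion abundance × charge, the image-current response of an
Orbitrap; dividing by *z* downstream therefore recovers abundance.

Centroid jitter is 2 ppm (s.d.) for MS2 and 0.1 Th FWHM at m/z 6000
(scaling with m/z) for MS1 — Orbitrap-like centroided accuracy.
Chemical noise is uniform at 20 peaks per 1000 Th below 5 % of the
base peak. A `jitter = FALSE` mode emits exact m/z with no noise; in
that mode the matcher provably recovers the emitted set exactly, which
is the pipeline's core identity test.

## Matching and landscape statistics

`match_fragments()` considers every admissible fragment at every
charge up to `z_max` (default 10) at 10 ppm tolerance (Orbitrap
typical; the underlying experiments report no tolerance, so it is a
declared default, not a reproduced one). Assignment is a greedy global
optimum over all in-tolerance (peak, fragment, charge) candidates
ordered by |ppm|, then longer fragment, then b before y — one peak per
assignment prevents intensity double-counting. The test suite holds
the windowed implementation equal to a brute-force all-pairs oracle.

`site_profile()` rescales summed charge-normalized intensity so the
top site reads 100 (ratio-preserving, matching the conventional
"100 %/50 %" reporting); the pre-rescale sums remain available as an
attribute and the residue-pair heat map conserves their total.
`coverage()` uses cleavage sites (*L*−1) as denominator; the residue
denominator (*L*) differs by <0.4 % for the proteins targeted and is
documented rather than implemented twice. The minimum sequence-tag
length of 3 residues is the shortest stretch useful for database
lookup.

`topology_enrichment()` uses a **circular-shift** null rather than
independent site shuffling: successive cleavages are strongly
autocorrelated (runs within helices), and shuffling would destroy that
structure and overstate significance. The cost is conservatism on
synthetic proteins whose helix/loop architecture is exactly periodic —
a shift by one helix-to-helix period realigns much of the profile with
the helices, so null values near the observed one are common. The
power test therefore uses a strong helix weighting
(`helix_weight_scale = 20`), where p ≤ 0.05 in ≥ 90 % of seeds; with
the default weighting on a perfectly periodic protein, p-values near
0.1 are expected and honest.

# What a green test does and does not establish

The simulator emulates: multi-charge MS1 series with detergent/lipid
ladders and a power-dependent removal transition; MS2 spectra whose
site propensities follow pair weights, helix stability and proton
access; repeat fragments across charge states; complementary pairs;
disulfide-silenced regions. It does **not** emulate isotope fine
structure, profile-mode peak shapes, overlapping isotope envelopes,
internal fragments, PTMs other than disulfides, real detergent
chemistry, or MD-derived stability. Green tests therefore establish
the *pipeline's* correctness and the qualitative phenomenology, not
instrument-level realism; the published per-protein numbers (26/28/19 %
coverage, 119/72 unique fragments, 8866/5843 Da and 4.7+/3.6+ modality
means) require the original raw spectra, which are not deposited, and
are covered by direction-only properties instead.

Two sampling-related choices deserve note. The rank-recovery invariant
(Spearman ≥ 0.8 between true propensities and recovered abundances) is
an asymptotic property: at a few hundred draws over ~280 sites,
multinomial sparsity leaves many low-propensity sites with zero draws
and caps the correlation near 0.72 regardless of pipeline fidelity, so
the test samples densely (4000 draws, ρ ≥ 0.88 across 20 seeds). And
the headline coverage regime evaluates the defaults exactly as stated
(7 TM, 280 residues, 2 disulfides, 17+, ≥150 fragments, default
noise): coverage lands at 27–32 % across seeds, comfortably above the
20 % identification threshold.

# Known limitations

* The grid-search deconvolution assumes contiguous charge runs; a
  species visible at only two charges is rejected by design.
* Real profile-mode data must be centroided (and isotope-deconvoluted
  for MS2) upstream; the package consumes centroids only.
* mzML I/O is not provided (no writer available in the supported
  dependency set); TSV + JSON sidecar is the interchange format.
* The charge-normalization direction (divide by *z*) is the
  image-current model; detectors with other response laws can select
  `multiply` or `none`, but the default is opinionated.
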