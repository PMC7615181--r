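#' Neutral peptide mass
#'
#' Sum of residue masses plus one water, on the monoisotopic or average
#' scale.  Intact (MS1) masses in this package use the average scale;
#' fragment (MS2) masses use the monoisotopic scale.
#'
#' @param sequence amino-acid string (canonical residues only).
#' @param scale `"mono"` or `"avg"`.
#' @return neutral mass in Da.
#' @examples
#' peptide_mass("G", "mono")   # 75.03203
#' @export
peptide_mass <- function(sequence, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  sum(.residue_masses(sequence, scale)) + .mass()$water[[scale]]
}

#' Correct a neutral mass for disulfide bond formation
#'
#' Each disulfide bridge removes two hydrogens from the sequence mass.
#'
#' @param neutral_mass sequence (fully reduced) mass in Da.
#' @param n_bonds number of disulfide bridges (>= 0).
#' @param scale `"mono"` or `"avg"`.
#' @return corrected neutral mass in Da.
#' @examples
#' apply_disulfides(40980, 2, "avg")  # ~40976
#' apply_disulfides(46535, 4, "avg")  # ~46527
#' @export
apply_disulfides <- function(neutral_mass, n_bonds, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  n_bonds <- as.integer(n_bonds)
  if (is.na(n_bonds) || n_bonds < 0L) stop("n_bonds must be >= 0")
  out <- neutral_mass - n_bonds * .mass()$disulfide_decrement[[scale]]
  if (any(out <= 0)) stop("disulfide correction drove the mass non-positive")
  out
}

#' m/z of a protonated species
#'
#' @param neutral_mass neutral mass in Da.
#' @param z positive charge (number of protons).
#' @return m/z in Th.
#' @examples
#' mz(126794, 19)  # ~6674.4, the isolation m/z of a 127 kDa trimer at 19+
#' @export
mz <- function(neutral_mass, z) {
  if (any(z < 1)) stop("charge z must be >= 1")
  (neutral_mass + z * .mass()$proton) / z
}

#' Neutral mass from an observed m/z at known charge
#'
#' Exact inverse of [mz()].
#'
#' @param mz_obs observed m/z in Th (must exceed the proton mass).
#' @param z positive charge.
#' @return neutral mass in Da.
#' @export
neutral_mass_from_mz <- function(mz_obs, z) {
  if (any(z < 1)) stop("charge z must be >= 1")
  if (any(mz_obs <= .mass()$proton)) stop("m/z must exceed the proton mass")
  z * (mz_obs - .mass()$proton)
}

#' Theoretical b/y fragment ladder under disulfide constraints
#'
#' Enumerates every single-backbone-cleavage b and y fragment of one
#' subunit.  A cleavage site `i` (the bond between residues `i` and
#' `i+1`) is *inadmissible* when it would separate the two cysteines of
#' any disulfide pair, i.e. leave exactly one partner on the fragment;
#' such fragments are generated and flagged rather than dropped, so that
#' downstream reports can attribute missing signal to masked regions.
#' Admissible fragments that fully contain `k` intact bridges carry a
#' `-k` x 2H mass correction.
#'
#' @param spec a [protein_spec()]; the ladder is subunit-level even for
#'   oligomeric precursors.
#' @param scale `"mono"` (default, centroided MS2) or `"avg"`.
#' @return data frame with one row per fragment and columns `ion_type`
#'   (`"b"`/`"y"`), `site` (1..L-1), `length`, `neutral_mass` (Da),
#'   `admissible`; 2(L-1) rows in total.
#' @examples
#' sp <- protein_spec("toy", "ACDEFCG", disulfides = list(c(2, 6)))
#' fragment_ladder(sp)
#' @export
fragment_ladder <- function(spec, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  seqc <- spec$sequence
  L <- nchar(seqc)
  if (L < 2L) stop("need at least 2 residues to fragment")
  res <- .residue_masses(seqc, scale)
  water <- .mass()$water[[scale]]
  dec <- .mass()$disulfide_decrement[[scale]]
  cums <- cumsum(res)
  total <- cums[L]
  sites <- seq_len(L - 1L)

  # b_i: residues 1..i (no water); y_j from site i: residues i+1..L (+ water)
  b_mass <- cums[sites]
  y_mass <- total - cums[sites] + water

  # a site is masked iff p <= site < q for some disulfide pair (p, q)
  masked <- rep(FALSE, L - 1L)
  # intact-bridge counts per fragment
  b_bonds <- rep(0L, L - 1L)
  y_bonds <- rep(0L, L - 1L)
  for (pair in spec$disulfides) {
    p <- pair[1]; q <- pair[2]
    masked[sites >= p & sites < q] <- TRUE
    b_bonds[sites >= q] <- b_bonds[sites >= q] + 1L
    y_bonds[sites < p] <- y_bonds[sites < p] + 1L
  }
  b_mass <- b_mass - b_bonds * dec
  y_mass <- y_mass - y_bonds * dec

  out <- data.frame(
    ion_type = rep(c("b", "y"), each = L - 1L),
    site = c(sites, sites),
    length = c(sites, L - sites),
    neutral_mass = c(b_mass, y_mass),
    admissible = c(!masked, !masked),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Intact (precursor) mass of the native complex
#'
#' Subunit sequence mass times the oligomer count, each subunit
#' corrected for its disulfide bridges.
#'
#' @param spec a [protein_spec()].
#' @param scale `"avg"` (default, native MS1) or `"mono"`.
#' @return neutral complex mass in Da.
#' @export
intact_mass <- function(spec, scale = c("avg", "mono")) {
  scale <- match.arg(scale)
  sub <- peptide_mass(spec$sequence, scale)
  if (length(spec$disulfides))
    sub <- apply_disulfides(sub, length(spec$disulfides), scale)
  sub * spec$oligomer_count
}
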