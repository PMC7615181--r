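#' Mass constants used throughout the package
#'
#' Monoisotopic and average masses (Da) of the 20 canonical amino-acid
#' residues, water, the proton, and the per-bond disulfide decrement
#' (two hydrogens lost on forming one S-S bridge).
#'
#' @return A list with elements `proton`, `water` (named vector,
#'   `mono`/`avg`), `disulfide_decrement` (named vector, `mono`/`avg`)
#'   and `residues` (data frame with columns `mono` and `avg`, row names
#'   the one-letter residue codes).
#' @examples
#' mass_constants()$proton
#' mass_constants()$residues["G", "mono"]
#' @export
mass_constants <- function() {
  residues <- data.frame(
    mono = c(
      G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
      V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
      I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
      K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
      F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931),
    avg = c(
      G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167,
      V =  99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
      I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
      K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
      F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
  )
  list(
    proton = 1.007276,
    water = c(mono = 18.010565, avg = 18.0153),
    disulfide_decrement = c(mono = 2.015650, avg = 2.01588),
    residues = residues
  )
}

# memoised internal copy (the table never changes within a session)
.mass_env <- new.env(parent = emptyenv())
.mass <- function() {
  if (is.null(.mass_env$tab)) .mass_env$tab <- mass_constants()
  .mass_env$tab
}

.check_scale <- function(scale) {
  match.arg(scale, c("mono", "avg"))
}

# residue mass lookup with position-aware error reporting
.residue_masses <- function(sequence, scale) {
  scale <- .check_scale(scale)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a non-empty character scalar")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- .mass()$residues[aa, scale]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("unknown residue symbol '%s' at position %d", aa[bad], bad))
  }
  m
}
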