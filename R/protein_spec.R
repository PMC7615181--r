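#' Construct a protein specification
#'
#' A `protein_spec` bundles everything the pipeline needs to know about a
#' membrane protein: the subunit sequence, the oligomeric state, the
#' transmembrane topology, disulfide pairs, and per-helix stability
#' weights.  It is both the ground truth handed to the simulator and the
#' annotation consumed by the analysis.
#'
#' @param id character identifier.
#' @param sequence subunit amino-acid sequence (20 canonical residues).
#' @param oligomer_count number of identical subunits in the native
#'   complex (>= 1); affects only the intact (MS1) precursor mass.
#' @param topology data frame with columns `start`, `end` (1-based,
#'   inclusive), `kind` (one of `"TM_helix"`, `"loop_out"`, `"loop_in"`,
#'   `"terminus"`) and optionally `helix_index`.  Segments must be
#'   sorted, non-overlapping and jointly cover the sequence.
#' @param disulfides list of length-2 integer vectors: residue indices of
#'   bonded cysteine pairs.  Pairs must be disjoint and point at
#'   cysteines.
#' @param helix_stability named numeric vector in \[0,1\], names are
#'   helix indices; per-helix structural-stability weights used by the
#'   MS2 simulator.
#' @return An object of class `protein_spec`.
#' @examples
#' topo <- data.frame(start = c(1, 4), end = c(3, 7),
#'                    kind = c("loop_out", "TM_helix"), helix_index = c(NA, 1))
#' protein_spec("toy", "ACDEFCG", topology = topo, disulfides = list(c(2, 6)))
#' @export
protein_spec <- function(id, sequence, oligomer_count = 1L,
                         topology = NULL, disulfides = list(),
                         helix_stability = numeric()) {
  stopifnot(is.character(id), length(id) == 1L)
  .residue_masses(sequence, "mono")  # validates residues
  L <- nchar(sequence)
  oligomer_count <- as.integer(oligomer_count)
  if (is.na(oligomer_count) || oligomer_count < 1L)
    stop("oligomer_count must be a positive integer")

  if (is.null(topology)) {
    topology <- data.frame(start = 1L, end = L, kind = "terminus",
                           helix_index = NA_integer_)
  }
  topology <- as.data.frame(topology)
  if (is.null(topology$helix_index)) topology$helix_index <- NA_integer_
  .validate_topology(topology, L)

  disulfides <- lapply(disulfides, function(p) sort(as.integer(p)))
  .validate_disulfides(disulfides, sequence)

  helix_stability <- .validate_stability(helix_stability, topology)

  structure(list(id = id, sequence = sequence,
                 oligomer_count = oligomer_count,
                 topology = topology, disulfides = disulfides,
                 helix_stability = helix_stability),
            class = "protein_spec")
}

.validate_topology <- function(topology, L) {
  need <- c("start", "end", "kind")
  if (!all(need %in% names(topology)))
    stop("topology needs columns start, end, kind")
  kinds <- c("TM_helix", "loop_out", "loop_in", "terminus")
  if (!all(topology$kind %in% kinds))
    stop("topology kind must be one of ", paste(kinds, collapse = ", "))
  o <- order(topology$start)
  if (!identical(o, seq_len(nrow(topology))))
    stop("topology segments must be sorted by start")
  covered <- unlist(Map(seq.int, topology$start, topology$end))
  if (!identical(sort(covered), seq_len(L)))
    stop("topology segments must be non-overlapping and cover 1..L")
  tm <- topology$kind == "TM_helix"
  if (any(tm) && anyNA(topology$helix_index[tm]))
    stop("TM_helix segments need a helix_index")
  invisible(TRUE)
}

.validate_disulfides <- function(disulfides, sequence) {
  if (!length(disulfides)) return(invisible(TRUE))
  aa <- strsplit(sequence, "")[[1]]
  idx <- unlist(disulfides)
  if (any(idx < 1L | idx > length(aa)))
    stop("disulfide index out of range")
  if (anyDuplicated(idx))
    stop("disulfide pairs must be disjoint (no residue in two bonds)")
  if (any(aa[idx] != "C"))
    stop("every disulfide index must point at a cysteine")
  if (any(vapply(disulfides, function(p) length(p) != 2L || p[1] == p[2],
                 logical(1))))
    stop("each disulfide must pair two distinct residues")
  invisible(TRUE)
}

.validate_stability <- function(helix_stability, topology) {
  helices <- topology$helix_index[topology$kind == "TM_helix"]
  helices <- sort(unique(helices[!is.na(helices)]))
  if (!length(helix_stability)) {
    helix_stability <- stats::setNames(rep(0.5, length(helices)),
                                       as.character(helices))
  }
  if (any(helix_stability < 0 | helix_stability > 1))
    stop("helix stability weights must lie in [0, 1]")
  if (is.null(names(helix_stability)))
    names(helix_stability) <- as.character(helices[seq_along(helix_stability)])
  helix_stability
}

#' @export
print.protein_spec <- function(x, ...) {
  n_tm <- sum(x$topology$kind == "TM_helix")
  cat(sprintf(
    "protein_spec '%s': %d residues x %d subunit(s), %d TM helices, %d disulfide(s)\n",
    x$id, nchar(x$sequence), x$oligomer_count, n_tm, length(x$disulfides)))
  invisible(x)
}

#' Map each residue, and each cleavage site, to its topology segment
#'
#' A cleavage site `i` is the bond between residues `i` and `i+1`; it is
#' assigned to a TM helix only when both flanking residues lie in that
#' helix, so helix boundaries count as loop cleavages.
#'
#' @param spec a [protein_spec()].
#' @return list with `residue_kind` (length L), `residue_helix`
#'   (helix index or NA, length L), `site_in_tm` (logical, length L-1)
#'   and `site_helix` (helix index or NA, length L-1).
#' @export
topology_map <- function(spec) {
  L <- nchar(spec$sequence)
  kind <- character(L)
  helix <- rep(NA_integer_, L)
  for (r in seq_len(nrow(spec$topology))) {
    span <- spec$topology$start[r]:spec$topology$end[r]
    kind[span] <- spec$topology$kind[r]
    if (spec$topology$kind[r] == "TM_helix")
      helix[span] <- spec$topology$helix_index[r]
  }
  site_helix <- ifelse(!is.na(helix[-L]) & !is.na(helix[-1]) &
                         helix[-L] == helix[-1], helix[-L], NA_integer_)
  list(residue_kind = kind, residue_helix = helix,
       site_in_tm = !is.na(site_helix), site_helix = site_helix)
}

#' Read a protein sequence from a FASTA file
#'
#' Uses Biostrings when available, otherwise a minimal fallback reader.
#'
#' @param path FASTA file; the first record is used.
#' @return character scalar sequence (uppercase).
#' @export
read_fasta_sequence <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    if (!length(set)) stop("no FASTA records in ", path)
    return(toupper(as.character(set[[1]])))
  }
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no FASTA records in ", path)
  end <- if (length(starts) > 1L) starts[2] - 1L else length(lines)
  toupper(paste(lines[(starts[1] + 1L):end], collapse = ""))
}

#' Read / write a topology annotation JSON
#'
#' The JSON layout is
#' `{"segments":[{"start":..,"end":..,"kind":..,"helix_index":..},...],
#'   "disulfides":[[i,j],...], "oligomer_count":n,
#'   "helix_stability":{"1":w1,...}}`.
#'
#' @param path JSON file path.
#' @param sequence subunit sequence the annotation refers to.
#' @param id identifier for the resulting spec.
#' @return [read_topology()] returns a [protein_spec()];
#'   [write_topology()] returns `path` invisibly.
#' @export
read_topology <- function(path, sequence, id = "protein") {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  topo <- as.data.frame(j$segments)
  dis <- list()
  if (!is.null(j$disulfides) && length(j$disulfides)) {
    dis <- if (is.matrix(j$disulfides)) {
      lapply(seq_len(nrow(j$disulfides)), function(i) j$disulfides[i, ])
    } else as.list(j$disulfides)
  }
  stab <- numeric()
  if (!is.null(j$helix_stability))
    stab <- unlist(j$helix_stability)
  protein_spec(id, sequence,
               oligomer_count = if (is.null(j$oligomer_count)) 1L else j$oligomer_count,
               topology = topo, disulfides = dis, helix_stability = stab)
}

#' @param spec a [protein_spec()] to serialize.
#' @rdname read_topology
#' @export
write_topology <- function(spec, path) {
  j <- list(
    segments = spec$topology,
    disulfides = if (length(spec$disulfides))
      do.call(rbind, spec$disulfides) else list(),
    oligomer_count = spec$oligomer_count,
    helix_stability = as.list(spec$helix_stability)
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
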