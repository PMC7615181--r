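#' Construct a centroided peak list
#'
#' @param mz m/z values in Th.
#' @param intensity positive intensities (arbitrary units).
#' @param metadata named list of acquisition metadata (`ms_level`,
#'   `activation`, `power_W`, `time_ms`, `precursor_mz`, `precursor_z`,
#'   ...).
#' @return An object of class `peak_list`: list with a `peaks` data
#'   frame (strictly ascending `mz`, positive `intensity`) and
#'   `metadata`.
#' @export
peak_list <- function(mz, intensity, metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  keep <- is.finite(mz) & is.finite(intensity) & intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  # coincident centroids merge into one peak
  if (length(mz) > 1L && any(diff(mz) == 0)) {
    grp <- cumsum(c(TRUE, diff(mz) != 0))
    intensity <- as.numeric(tapply(intensity, grp, sum))
    mz <- mz[!duplicated(grp)]
  }
  structure(list(peaks = data.frame(mz = mz, intensity = intensity),
                 metadata = metadata),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  n <- nrow(x$peaks)
  cat(sprintf("peak_list: %d peaks", n))
  if (n) cat(sprintf(", m/z %.2f-%.2f", min(x$peaks$mz), max(x$peaks$mz)))
  if (!is.null(x$metadata$ms_level))
    cat(sprintf(" (MS%d)", x$metadata$ms_level))
  cat("\n")
  invisible(x)
}

#' Read / write peak lists as TSV with a JSON metadata sidecar
#'
#' The on-disk format is a two-column tab-separated table (`mz`,
#' `intensity`) plus `<path>.json` holding the acquisition metadata.
#'
#' @param x a [peak_list()].
#' @param path TSV file path.
#' @return `write_peaks` returns `path` invisibly; `read_peaks` returns
#'   a [peak_list()].
#' @export
write_peaks <- function(x, path) {
  stopifnot(inherits(x, "peak_list"))
  utils::write.table(x$peaks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (length(x$metadata))
    jsonlite::write_json(x$metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::fromJSON(side, simplifyVector = TRUE)
  peak_list(tab[[1]], tab[[2]], metadata = meta)
}
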