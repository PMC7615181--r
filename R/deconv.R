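# nearest-peak lookup: for each target m/z, index of closest peak (or NA)
.nearest_peak <- function(target, peak_mz) {
  if (!length(peak_mz)) return(rep(NA_integer_, length(target)))
  idx <- findInterval(target, peak_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(peak_mz))
  d_lo <- abs(target - peak_mz[lo])
  d_hi <- abs(target - peak_mz[hi])
  ifelse(d_lo <= d_hi, lo, hi)
}

#' Construct a charge-series fit from a known mass
#'
#' Builds the `charge_series_fit` container directly, e.g. to score a
#' spectrum against a theoretical mass without running the grid search.
#'
#' @param neutral_mass neutral mass in Da.
#' @param z_range inclusive charge span, length-2 integer.
#' @return object of class `charge_series_fit` (no matched peaks).
#' @export
charge_series_fit <- function(neutral_mass, z_range) {
  z_range <- as.integer(range(z_range))
  structure(list(neutral_mass = neutral_mass, z_range = z_range,
                 matched = data.frame(z = integer(), predicted = numeric(),
                                      observed = numeric(),
                                      intensity = numeric()),
                 score = NA_real_, intensity_fraction = NA_real_),
            class = "charge_series_fit")
}

#' @export
print.charge_series_fit <- function(x, ...) {
  cat(sprintf("charge_series_fit: M = %.1f Da, z %d..%d, score %.3g, matched intensity fraction %.3f\n",
              x$neutral_mass, x$z_range[1], x$z_range[2],
              x$score, x$intensity_fraction))
  invisible(x)
}

# peaks matched (within tol) to the predicted series of mass M over zs;
# returns the best contiguous charge run of length >= min_run
.series_match <- function(M, zs, peak_mz, peak_int, mz_tol, min_run) {
  pred <- mz(M, zs)
  idx <- .nearest_peak(pred, peak_mz)
  hit <- !is.na(idx) & abs(pred - peak_mz[idx]) <= mz_tol
  if (sum(hit) < min_run) return(NULL)
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= min_run)
  if (!length(ok)) return(NULL)
  scores <- vapply(ok, function(r)
    sum(peak_int[idx[starts[r]:ends[r]]]), numeric(1))
  r <- ok[which.max(scores)]
  sel <- starts[r]:ends[r]
  list(z = zs[sel], predicted = pred[sel], observed = peak_mz[idx[sel]],
       intensity = peak_int[idx[sel]], score = scores[which.max(scores)])
}

#' Fit multi-charge series to an MS1 spectrum
#'
#' Grid search over candidate neutral masses: each candidate predicts a
#' peak at `mz(M, z)` for every charge in `z_range`, and is scored by
#' the summed intensity of observed peaks falling within `mz_tol` over
#' its best contiguous run of at least `min_run` charges.  Overlapping
#' candidates (within `2 * mz_tol * z_max` in mass) are deduplicated,
#' keeping the higher score; surviving fits are refined by the
#' intensity-weighted mean of the per-peak mass estimates
#' `z * (mz_obs - m_proton)`.
#'
#' @param peaks a [peak_list()].
#' @param mass_range length-2 numeric, candidate neutral-mass window
#'   (Da).
#' @param z_range length-2 integer, charges to consider.
#' @param mz_tol match tolerance in Th (default 0.5, broad native
#'   peaks).
#' @param min_run minimum contiguous charge-run length (default 3).
#' @param max_fits return at most this many fits.
#' @return list of `charge_series_fit`, sorted by decreasing score
#'   (possibly empty).
#' @export
fit_charge_series <- function(peaks, mass_range, z_range, mz_tol = 0.5,
                              min_run = 3L, max_fits = 10L) {
  stopifnot(inherits(peaks, "peak_list"), length(mass_range) == 2L,
            mass_range[2] >= mass_range[1])
  pm <- peaks$peaks$mz
  pint <- peaks$peaks$intensity
  if (length(pm) < min_run) return(list())
  zs <- seq.int(z_range[1], z_range[2])
  step <- mz_tol / 2 * min(zs)
  cand <- seq(mass_range[1], mass_range[2], by = step)

  # coarse vectorized score: summed intensity of within-tolerance charges
  pred <- outer(cand, zs, mz)
  idx <- matrix(.nearest_peak(as.vector(pred), pm), nrow = length(cand))
  hit <- abs(pred - matrix(pm[idx], nrow = length(cand))) <= mz_tol
  nhit <- rowSums(hit)
  keep <- which(nhit >= min_run)
  if (!length(keep)) return(list())

  fits <- list()
  for (ci in keep) {
    sm <- .series_match(cand[ci], zs, pm, pint, mz_tol, min_run)
    if (is.null(sm)) next
    fits[[length(fits) + 1L]] <- list(mass = cand[ci], sm = sm)
  }
  if (!length(fits)) return(list())
  fits <- fits[order(vapply(fits, function(f) f$sm$score, numeric(1)),
                     decreasing = TRUE)]

  # dedup: nearby candidate masses describe the same series
  dedup_window <- 2 * mz_tol * max(zs)
  kept <- list()
  for (f in fits) {
    if (length(kept) &&
        any(abs(vapply(kept, `[[`, numeric(1), "mass") - f$mass) <=
              dedup_window)) next
    kept[[length(kept) + 1L]] <- f
    if (length(kept) >= max_fits) break
  }

  total_int <- sum(pint)
  lapply(kept, function(f) {
    sm <- f$sm
    # refine: intensity-weighted mean of per-charge mass estimates
    M <- stats::weighted.mean(sm$z * (sm$observed - .mass()$proton),
                              sm$intensity)
    sm2 <- .series_match(M, zs, pm, pint, mz_tol, min_run)
    if (is.null(sm2)) sm2 <- sm
    structure(list(neutral_mass = M,
                   z_range = range(sm2$z),
                   matched = data.frame(z = sm2$z, predicted = sm2$predicted,
                                        observed = sm2$observed,
                                        intensity = sm2$intensity),
                   score = sm2$score,
                   intensity_fraction = sm2$score / total_int),
              class = "charge_series_fit")
  })
}

#' Detect adduct ladders around a fitted charge series
#'
#' For each base fit, searches for satellite charge series offset by
#' `k * s` for spacings `s` in `spacing_window` and `k = 1..max_steps`,
#' using the base fit's charge states.  Steps are accepted while a
#' satellite series with at least two matched charges is found; the
#' reported spacing is the intensity-weighted mean of consecutive step
#' mass differences.
#'
#' @param peaks a [peak_list()].
#' @param fits list of [charge_series_fit()] (or a single fit).
#' @param spacing_window length-2 numeric, Da (default the 700-730 Da
#'   phospholipid window).
#' @param max_steps maximum adduct count searched.
#' @param mz_tol match tolerance in Th.
#' @return list of `adduct_ladder` objects: `base_mass`, `spacing`,
#'   `max_count`, `steps` (k, mass, score, share).
#' @export
detect_adduct_ladder <- function(peaks, fits, spacing_window = c(700, 730),
                                 max_steps = 5L, mz_tol = 0.5) {
  if (inherits(fits, "charge_series_fit")) fits <- list(fits)
  pm <- peaks$peaks$mz
  pint <- peaks$peaks$intensity
  out <- list()
  for (fit in fits) {
    zs <- seq.int(fit$z_range[1], fit$z_range[2])
    step_grid <- mz_tol / 2 * min(zs)
    base <- fit$neutral_mass
    steps <- data.frame(k = integer(), mass = numeric(), score = numeric())
    prev_mass <- base
    for (k in seq_len(max_steps)) {
      cand <- seq(base + k * spacing_window[1], base + k * spacing_window[2],
                  by = step_grid)
      best <- NULL
      for (M in cand) {
        sm <- .series_match(M, zs, pm, pint, mz_tol, min_run = 2L)
        if (is.null(sm)) next
        if (is.null(best) || sm$score > best$sm$score)
          best <- list(mass = M, sm = sm)
      }
      if (is.null(best)) break
      # refine satellite mass
      M <- stats::weighted.mean(best$sm$z * (best$sm$observed - .mass()$proton),
                                best$sm$intensity)
      steps <- rbind(steps, data.frame(k = k, mass = M,
                                       score = best$sm$score))
      prev_mass <- M
    }
    if (!nrow(steps)) next
    diffs <- diff(c(base, steps$mass)) / 1  # consecutive step differences
    spacing <- stats::weighted.mean(diffs, steps$score)
    base_score <- if (is.na(fit$score)) sum(steps$score) else fit$score
    steps$share <- steps$score / base_score
    out[[length(out) + 1L]] <- structure(
      list(base_mass = base, spacing = spacing, max_count = max(steps$k),
           steps = steps),
      class = "adduct_ladder")
  }
  out
}

#' @export
print.adduct_ladder <- function(x, ...) {
  cat(sprintf("adduct_ladder: base %.1f Da, spacing %.2f Da, %d step(s)\n",
              x$base_mass, x$spacing, x$max_count))
  invisible(x)
}

#' Fraction of spectrum intensity in the bare-protein series
#'
#' The "resolvedness" metric: the share of total intensity lying within
#' `mz_tol` of the predicted bare-protein peaks of a fitted (or known)
#' charge series.  Adduct satellites and noise fall outside the
#' predicted series and drag the fraction down; a fully liberated,
#' noise-free spectrum scores 1.
#'
#' @param peaks a [peak_list()].
#' @param fit a [charge_series_fit()].
#' @param mz_tol tolerance in Th.
#' @return fraction in \[0, 1\].
#' @export
resolved_fraction <- function(peaks, fit, mz_tol = 0.5) {
  stopifnot(inherits(fit, "charge_series_fit"))
  pm <- peaks$peaks$mz
  pint <- peaks$peaks$intensity
  total <- sum(pint)
  if (total <= 0) return(0)
  zs <- seq.int(fit$z_range[1], fit$z_range[2])
  pred <- mz(fit$neutral_mass, zs)
  near <- rep(FALSE, length(pm))
  for (p in pred) near <- near | abs(pm - p) <= mz_tol
  sum(pint[near]) / total
}
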