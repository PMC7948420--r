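#' Construct an extracted-ion-chromatogram trace
#'
#' @param rt Retention times in minutes, strictly increasing, length >= 2.
#' @param intensity Non-negative-ish intensities (noise may dip below zero),
#'   same length as `rt`.
#' @param target_mz m/z of the extraction window center (metadata).
#' @param tol_ppm Extraction window half-width in ppm (metadata).
#' @return Object of class `chromatogram_trace`.
#' @export
chromatogram_trace <- function(rt, intensity, target_mz = NA_real_,
                               tol_ppm = 10) {
  rt <- as.numeric(rt); intensity <- as.numeric(intensity)
  if (length(rt) < 2L || length(rt) != length(intensity)) {
    stop("rt and intensity must have equal length >= 2")
  }
  if (any(diff(rt) <= 0)) stop("rt must be strictly increasing")
  structure(list(rt = rt, intensity = intensity, target_mz = target_mz,
                 tol_ppm = tol_ppm),
            class = "chromatogram_trace")
}

#' Read a trace TSV (rt, intensity)
#'
#' @param path Path to a two-column TSV with header `rt`, `intensity`.
#' @param target_mz,tol_ppm Metadata attached to the trace.
#' @return A [chromatogram_trace()].
#' @export
read_trace <- function(path, target_mz = NA_real_, tol_ppm = 10) {
  tab <- utils::read.delim(path)
  chromatogram_trace(tab$rt, tab$intensity, target_mz, tol_ppm)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

running_mean <- function(y, k = 5L) {
  # centered running mean; shrinks the window at the edges
  n <- length(y)
  if (n < 3L || k < 3L) return(y)
  h <- k %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Integrate the area under an XIC peak
#'
#' Functional stand-in for a vendor chromatographic integrator: the baseline
#' is the median of the lowest decile of in-window intensities; peak bounds
#' are found on a lightly smoothed copy of the signal by walking outward from
#' the apex while the smoothed signal stays above the window median plus 2%
#' of the apex rise (the median is the robust bound floor; the decile
#' baseline would sit below the noise band and let bounds run away); the
#' area is the trapezoidal integral of baseline-subtracted intensity
#' (clipped at zero) between the bounds. An explicit `rt_window` overrides
#' bound detection and integrates the whole window.
#'
#' @param trace A [chromatogram_trace()].
#' @param rt_window Optional `c(start, end)` in minutes.
#' @param bound_frac Fraction of the apex rise used as the peak-bound
#'   threshold (default 0.02; a Gaussian peak truncated there loses ~0.5% of
#'   its area).
#' @return List of class `peak_integration`: `rt_start`, `rt_apex`, `rt_end`,
#'   `area` (intensity x minutes), `baseline`, `empty` (TRUE when no signal
#'   rises above baseline).
#' @export
integrate_peak <- function(trace, rt_window = NULL, bound_frac = 0.02) {
  stopifnot(inherits(trace, "chromatogram_trace"))
  rt <- trace$rt; y <- trace$intensity
  if (!is.null(rt_window)) {
    keep <- rt >= rt_window[1] & rt <= rt_window[2]
    if (sum(keep) < 2L) stop("rt_window contains fewer than 2 samples")
    rt <- rt[keep]; y <- y[keep]
  }
  low <- sort(y)[seq_len(max(1L, floor(length(y) / 10)))]
  baseline <- stats::median(low)
  ys <- running_mean(y)
  apex <- which.max(ys)
  rise <- ys[apex] - baseline
  # no-peak guard: on a signal-free trace the apex is just the upper tail of
  # the noise band; require it to clear 5x the robust spread
  noise_spread <- stats::mad(ys)
  if (noise_spread > 0 && (ys[apex] - stats::median(ys)) < 5 * noise_spread) {
    rise <- 0
  }
  if (!is.finite(rise) || rise <= 0) {
    return(structure(list(rt_start = rt[1], rt_apex = rt[which.max(y)],
                          rt_end = rt[length(rt)], area = 0,
                          baseline = baseline, empty = TRUE),
                     class = "peak_integration"))
  }
  if (is.null(rt_window)) {
    center <- stats::median(ys)
    floor_level <- center + bound_frac * (ys[apex] - center)
    i <- apex
    while (i > 1L && ys[i - 1L] > floor_level) i <- i - 1L
    j <- apex
    n <- length(ys)
    while (j < n && ys[j + 1L] > floor_level) j <- j + 1L
  } else {
    i <- 1L; j <- length(y)
  }
  seg <- i:j
  area <- trapz(rt[seg], pmax(y[seg] - baseline, 0))
  structure(list(rt_start = rt[i], rt_apex = rt[apex], rt_end = rt[j],
                 area = max(area, 0), baseline = baseline, empty = FALSE),
            class = "peak_integration")
}

#' Relative phosphosite occupancy from peak areas
#'
#' Ratio of the modified-peptide signal to total (modified + unmodified)
#' signal. Ionization-efficiency differences between the two forms are not
#' corrected; the result is a relative occupancy.
#'
#' @param area_mod,area_unmod Non-negative peak areas.
#' @return Fraction in `[0, 1]`, or `NA` (with attribute `undefined = TRUE`)
#'   when both areas are zero.
#' @export
occupancy <- function(area_mod, area_unmod) {
  if (area_mod < 0 || area_unmod < 0) stop("areas must be non-negative")
  total <- area_mod + area_unmod
  if (total == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  area_mod / total
}

#' Detect peaks in a trace
#'
#' Local maxima whose baseline-subtracted height exceeds `min_frac` of the
#' largest rise; used to enumerate candidate peaks for retention-time
#' disambiguation.
#'
#' @param trace A [chromatogram_trace()].
#' @param min_frac Minimum apex rise as a fraction of the largest rise.
#' @param min_sep Minimum separation (minutes) between reported apexes; of
#'   two nearer candidates only the stronger is kept.
#' @return data.frame with `rt_apex`, `intensity`.
#' @export
find_peaks <- function(trace, min_frac = 0.2, min_sep = 0.2) {
  y <- running_mean(trace$intensity); rt <- trace$rt; n <- length(y)
  low <- sort(y)[seq_len(max(1L, floor(n / 10)))]
  baseline <- stats::median(low)
  rise_max <- max(y) - baseline
  if (rise_max <= 0) {
    return(data.frame(rt_apex = numeric(), intensity = numeric()))
  }
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  idx <- which(is_max & (y - baseline) >= min_frac * rise_max)
  idx <- idx[order(y[idx], decreasing = TRUE)]
  kept <- integer()
  for (i in idx) {
    if (all(abs(rt[i] - rt[kept]) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(rt_apex = rt[kept], intensity = y[kept])
}

#' Assign detected peaks to expected retention times
#'
#' Isobaric peptidoforms share an m/z and are distinguished only by their
#' chromatographic retention times. Each detected peak is assigned to the
#' nearest expected retention time; a peak is flagged ambiguous when it is
#' (numerically) equidistant from two expectations or farther than `tol_min`
#' from every expectation.
#'
#' @param traces A [chromatogram_trace()] or list of traces whose detected
#'   peaks are pooled.
#' @param expected_rts Distinct expected retention times (minutes), named by
#'   peptidoform id if available.
#' @param tol_min Assignment tolerance in minutes (default 0.5).
#' @return data.frame with one row per detected peak: `rt_apex`,
#'   `assigned` (index into `expected_rts`, NA when ambiguous),
#'   `expected_rt`, `distance`, `ambiguous`.
#' @export
disambiguate_isobaric <- function(traces, expected_rts, tol_min = 0.5) {
  if (inherits(traces, "chromatogram_trace")) traces <- list(traces)
  if (anyDuplicated(expected_rts)) stop("expected_rts must be distinct")
  peaks <- do.call(rbind, lapply(traces, find_peaks))
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(data.frame(rt_apex = numeric(), assigned = integer(),
                      expected_rt = numeric(), distance = numeric(),
                      ambiguous = logical()))
  }
  if (nrow(peaks) > length(expected_rts)) {
    warning("more detected peaks (", nrow(peaks), ") than expected retention times (",
            length(expected_rts), "); surplus peaks will be flagged")
  }
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    d <- abs(peaks$rt_apex[i] - expected_rts)
    o <- order(d)
    tie <- length(d) > 1L && abs(d[o[1]] - d[o[2]]) < 1e-9
    ambiguous <- tie || d[o[1]] > tol_min
    data.frame(rt_apex = peaks$rt_apex[i],
               assigned = if (ambiguous) NA_integer_ else o[1],
               expected_rt = if (ambiguous) NA_real_ else expected_rts[o[1]],
               distance = d[o[1]], ambiguous = ambiguous)
  })
  do.call(rbind, out)
}

#' Methylation-state distribution from the four peak areas
#'
#' Normalizes the me0..me3 peak areas by the total peptide signal. All-zero
#' input (e.g. a deletion strain with the methyltransferase knocked out) is
#' not an error: the result carries `all_absent = TRUE` and NA fractions.
#'
#' @param areas Numeric length-4 vector of areas, order me0, me1, me2, me3.
#' @return List of class `methyl_distribution`: `areas`, `fractions` (named,
#'   summing to 1), `all_absent`.
#' @export
methylation_distribution <- function(areas) {
  areas <- as.numeric(areas)
  if (length(areas) != 4L || any(areas < 0)) {
    stop("areas must be 4 non-negative numbers (me0..me3)")
  }
  states <- c("me0", "me1", "me2", "me3")
  total <- sum(areas)
  if (total == 0) {
    return(structure(list(areas = stats::setNames(areas, states),
                          fractions = stats::setNames(rep(NA_real_, 4), states),
                          all_absent = TRUE),
                     class = "methyl_distribution"))
  }
  structure(list(areas = stats::setNames(areas, states),
                 fractions = stats::setNames(areas / total, states),
                 all_absent = FALSE),
            class = "methyl_distribution")
}

#' @export
print.methyl_distribution <- function(x, ...) {
  if (x$all_absent) {
    cat("<methyl_distribution> all states absent (zero total signal)\n")
  } else {
    cat("<methyl_distribution>",
        paste(sprintf("%s=%.1f%%", names(x$fractions), 100 * x$fractions),
              collapse = "  "), "\n")
  }
  invisible(x)
}
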