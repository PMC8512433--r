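#' Peak-detection parameters
#'
#' Defaults mirror common untargeted GC-MS practice: peaks between 5 and 20
#' seconds wide at half height, signal-to-noise at least 6, a prefilter
#' demanding 3 consecutive scans above 100 counts, m/z tolerance 0.01 (below
#' unit-mass spacing, so every integer channel is its own slice).
#'
#' @param peakwidth Length-2 numeric, min and max full width at half height in
#'   seconds.
#' @param snthresh Minimum signal-to-noise ratio.
#' @param mzdiff Minimum m/z separation (kept for interface parity; unit-mass
#'   channels always satisfy it).
#' @param prefilter Length-2 `c(k, I)`: at least `k` consecutive scans with at
#'   least `I` counts inside the peak window.
#' @param noise Intensity floor subtracted nowhere but used to ignore channels
#'   that never exceed it.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(peakwidth = c(5, 20), snthresh = 6, mzdiff = 0.01,
                             prefilter = c(3, 100), noise = 0) {
  stopifnot(length(peakwidth) == 2, peakwidth[1] > 0, peakwidth[1] < peakwidth[2],
            snthresh >= 0, prefilter[1] >= 1)
  structure(list(peakwidth = peakwidth, snthresh = snthresh, mzdiff = mzdiff,
                 prefilter_k = as.integer(prefilter[1]), prefilter_I = prefilter[2],
                 noise = noise), class = "detection_params")
}

#' Extract ion chromatograms from a run
#'
#' Every nominal-m/z channel of the run over all scan times; absent m/z are
#' zero, so channel sums reproduce the total ion current scan by scan.
#'
#' @param run A `gc_run`.
#' @return List with `times` (minutes), `mz` (integer channels) and `mat`
#'   (channels x scans intensity matrix).
#' @export
extract_eics <- function(run) {
  stopifnot(inherits(run, "gc_run"), length(run$times) > 0)
  list(times = run$times, mz = run$mz, mat = run$mat)
}

## Gaussian smoothing along scans for every channel at once.
## sigma_scans in units of scans; kernel truncated at 4 sigma, edge-padded.
smooth_channels <- function(mat, sigma_scans) {
  half <- max(1L, ceiling(4 * sigma_scans))
  k <- stats::dnorm(seq(-half, half), sd = sigma_scans)
  k <- k / sum(k)
  n <- ncol(mat)
  padded <- cbind(mat[, rep(1L, half), drop = FALSE], mat,
                  mat[, rep(n, half), drop = FALSE])
  sm <- stats::filter(t(padded), k, sides = 2)
  t(sm[(half + 1):(half + n), , drop = FALSE])
}

## Longest run of consecutive TRUEs in a logical vector.
longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

## Interpolated full width at half height of the raw EIC around an apex,
## measured above the local linear baseline; NA when the half level is never
## crossed inside the window.
fwhm_seconds <- function(times, y, lo, hi, apex) {
  base_lo <- y[lo]; base_hi <- y[hi]
  bl <- function(i) base_lo + (base_hi - base_lo) * (times[i] - times[lo]) /
    max(times[hi] - times[lo], .Machine$double.eps)
  h <- y[apex] - bl(apex)
  if (h <= 0) return(NA_real_)
  half <- bl(apex) + h / 2
  li <- apex
  while (li > lo && y[li - 1] - bl(li - 1) > h / 2) li <- li - 1
  ri <- apex
  while (ri < hi && y[ri + 1] - bl(ri + 1) > h / 2) ri <- ri + 1
  t_left <- if (li > lo) {
    y1 <- y[li - 1] - bl(li - 1); y2 <- y[li] - bl(li)
    times[li - 1] + (times[li] - times[li - 1]) * (h / 2 - y1) / max(y2 - y1, .Machine$double.eps)
  } else times[lo]
  t_right <- if (ri < hi) {
    y1 <- y[ri] - bl(ri); y2 <- y[ri + 1] - bl(ri + 1)
    times[ri] + (times[ri + 1] - times[ri]) * (y1 - h / 2) / max(y1 - y2, .Machine$double.eps)
  } else times[hi]
  min_to_sec(t_right - t_left)
}

#' Detect chromatographic peaks in one run
#'
#' Works per integer-m/z extracted ion chromatogram: channels are smoothed
#' with a Gaussian kernel (sigma = `peakwidth[1]`/2.355 seconds), local maxima
#' of the smoothed trace become candidates, and a candidate is kept when (i) a
#' run of at least `prefilter_k` consecutive raw scans at or above
#' `prefilter_I` exists in its window, (ii) its full width at half height,
#' measured on the raw EIC above a linear baseline, lies within `peakwidth`
#' seconds, and (iii) its signal-to-noise (apex height above baseline, over
#' 1.4826 x MAD of the channel outside candidate windows, floored at 1) is at
#' least `snthresh`. The area is the trapezoidal integral above the straight
#' baseline between the window ends, clipped at zero, in counts x seconds.
#'
#' @param run A `gc_run`.
#' @param params A [detection_params()].
#' @return Data frame of peaks: `sample_id`, `run_id`, `mz`, `rt`, `rt_lo`,
#'   `rt_hi` (minutes), `area` (counts.s), `height`, `sn`. Zero rows when the
#'   run is shorter than one minimum peak width.
#' @export
detect_peaks <- function(run, params = detection_params()) {
  eic <- extract_eics(run)
  times <- eic$times
  empty <- data.frame(sample_id = character(0), run_id = character(0),
                      mz = integer(0), rt = numeric(0), rt_lo = numeric(0),
                      rt_hi = numeric(0), area = numeric(0), height = numeric(0),
                      sn = numeric(0))
  dt_min <- stats::median(diff(times))
  if (length(times) < 4 ||
      min_to_sec(times[length(times)] - times[1]) < params$peakwidth[1])
    return(empty)
  sigma_scans <- sec_to_min(params$peakwidth[1] / 2.355) / dt_min
  max_half_scans <- ceiling(sec_to_min(params$peakwidth[2]) / dt_min) + 2L

  ## cheap pre-screen: channels with any prefilter-passing run
  above <- eic$mat >= params$prefilter_I
  cand_channels <- which(apply(above, 1, longest_true_run) >= params$prefilter_k)
  out <- vector("list", length(cand_channels))
  n <- length(times)

  for (ci in seq_along(cand_channels)) {
    ch <- cand_channels[ci]
    y <- as.numeric(eic$mat[ch, ])
    if (max(y) <= params$noise) next
    sm <- as.numeric(smooth_channels(matrix(y, nrow = 1), sigma_scans))
    is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n], FALSE)
    ## only maxima near prefilter-passing stretches are worth evaluating
    reg <- which(above[ch, ])
    apexes <- which(is_max)
    apexes <- apexes[vapply(apexes, function(a)
      any(abs(reg - a) <= max_half_scans), logical(1))]
    if (!length(apexes)) next

    peaks <- list(); windows <- logical(n)
    for (a in apexes) {
      lo <- a; while (lo > 1 && sm[lo - 1] < sm[lo]) lo <- lo - 1
      hi <- a; while (hi < n && sm[hi + 1] < sm[hi]) hi <- hi + 1
      lo <- max(lo, a - max_half_scans); hi <- min(hi, a + max_half_scans)
      if (hi - lo < 2) next
      seg <- above[ch, lo:hi]
      if (longest_true_run(seg) < params$prefilter_k) next
      w <- fwhm_seconds(times, y, lo, hi, a)
      if (is.na(w) || w < params$peakwidth[1] || w > params$peakwidth[2]) next
      peaks[[length(peaks) + 1]] <- c(a = a, lo = lo, hi = hi)
      windows[lo:hi] <- TRUE
    }
    if (!length(peaks)) next
    noise_est <- max(1, 1.4826 * stats::mad(y[!windows], constant = 1))
    rows <- lapply(peaks, function(p) {
      a <- p["a"]; lo <- p["lo"]; hi <- p["hi"]
      bl <- y[lo] + (y[hi] - y[lo]) * (times[lo:hi] - times[lo]) / (times[hi] - times[lo])
      height <- y[a] - bl[a - lo + 1]
      sn <- height / noise_est
      if (sn < params$snthresh) return(NULL)
      resid <- pmax(y[lo:hi] - bl, 0)
      area <- sum(diff(min_to_sec(times[lo:hi])) * (resid[-1] + resid[-length(resid)]) / 2)
      if (area <= 0) return(NULL)
      data.frame(mz = eic$mz[ch], rt = times[a], rt_lo = times[lo],
                 rt_hi = times[hi], area = area, height = y[a], sn = sn)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) out[[ci]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  pk <- do.call(rbind, out)
  pk <- pk[order(pk$mz, pk$rt), , drop = FALSE]
  data.frame(sample_id = run$meta$sample_id %||% NA_character_,
             run_id = run$meta$run_id %||% NA_character_,
             pk, row.names = NULL)
}
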