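#' Peak-grouping (alignment) parameters
#'
#' @param mzwid m/z slice width; below unit-mass spacing, so each integer
#'   channel is its own slice on nominal-mass data.
#' @param bw Gaussian kernel-density bandwidth over retention time, seconds.
#' @param minfrac Minimum fraction (inclusive) of one metadata class's runs in
#'   which a group must be detected.
#' @param max_per_slice Maximum number of groups per m/z slice.
#' @param minsamp Minimum number of runs overall that also keeps a group.
#' @return Object of class `grouping_params`.
#' @export
grouping_params <- function(mzwid = 0.015, bw = 5, minfrac = 0.5,
                            max_per_slice = 100, minsamp = 1) {
  stopifnot(mzwid > 0, bw > 0, minfrac > 0, minfrac <= 1, max_per_slice >= 1,
            minsamp >= 1)
  structure(list(mzwid = mzwid, bw = bw, minfrac = minfrac,
                 max_per_slice = max_per_slice, minsamp = as.integer(minsamp)),
            class = "grouping_params")
}

## Kernel-density grouping of one channel's peak rts.
## Returns an integer group index per peak (NA = unassigned).
density_groups <- function(rts, bw_min, max_groups) {
  if (length(rts) == 1) return(1L)
  span <- range(rts)
  d <- stats::density(rts, bw = bw_min, from = span[1] - 3 * bw_min,
                      to = span[2] + 3 * bw_min,
                      n = max(512L, 2L * ceiling(diff(span) / bw_min * 8)))
  y <- d$y; n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  maxima <- which(is_max)
  if (!length(maxima)) return(rep(1L, length(rts)))
  if (length(maxima) > max_groups)
    maxima <- sort(maxima[order(y[maxima], decreasing = TRUE)][seq_len(max_groups)])
  ## boundaries: minima between adjacent retained maxima
  bounds <- c(-Inf, vapply(seq_len(length(maxima) - 1), function(i) {
    seg <- maxima[i]:maxima[i + 1]
    d$x[seg[which.min(y[seg])]]
  }, numeric(1)), Inf)
  findInterval(rts, bounds, rightmost.closed = FALSE)
}

#' Group corrected peaks into cross-sample features
#'
#' Within each nominal-m/z channel, peaks are grouped under maxima of a
#' Gaussian kernel density (bandwidth `bw` seconds) over retention time, at
#' most `max_per_slice` groups per channel. A group becomes a feature when it
#' is detected in at least `minfrac` (inclusive) of the runs of some metadata
#' class, or in at least `minsamp` runs overall. When one run contributes two
#' peaks to a group, the larger area wins.
#'
#' @param peaks Peak data frame (from [detect_peaks()] over all runs, ideally
#'   after [correct_rt()]).
#' @param params A [grouping_params()].
#' @param metadata Run metadata with `run_id` and the class columns
#'   (`rootstock`, `irrigation`).
#' @param class_cols Metadata columns that define sample classes.
#' @return A `feature_table`: list with `features` (feature_id "M{mz}T{rt}",
#'   mz, rtmed, median window, npeaks), `intensity` (feature x run area
#'   matrix, NA where undetected), `detected` (logical matrix),
#'   `class_fraction`, and `metadata`.
#' @export
group_peaks <- function(peaks, params = grouping_params(), metadata,
                        class_cols = intersect(c("rootstock", "irrigation"), names(metadata))) {
  stopifnot(nrow(peaks) > 0, "run_id" %in% names(metadata))
  run_ids <- metadata$run_id
  bw_min <- sec_to_min(params$bw)
  feats <- list()
  for (ch in sort(unique(peaks$mz))) {
    pk <- peaks[peaks$mz == ch, , drop = FALSE]
    grp <- density_groups(pk$rt, bw_min, params$max_per_slice)
    for (g in sort(unique(grp[!is.na(grp)]))) {
      sub <- pk[which(grp == g), , drop = FALSE]
      ## one peak per run: larger area wins
      sub <- sub[order(sub$run_id, -sub$area), , drop = FALSE]
      sub <- sub[!duplicated(sub$run_id), , drop = FALSE]
      keep <- nrow(sub) >= params$minsamp
      if (!keep) {
        for (cc in class_cols) {
          lv <- metadata[[cc]][match(sub$run_id, run_ids)]
          tab <- table(factor(lv, levels = unique(metadata[[cc]])))
          cls_n <- table(factor(metadata[[cc]], levels = unique(metadata[[cc]])))
          if (any(tab / cls_n >= params$minfrac)) { keep <- TRUE; break }
        }
      }
      if (!keep) next
      feats[[length(feats) + 1]] <- sub
    }
  }
  if (!length(feats)) stopf("no feature groups retained")
  info <- do.call(rbind, lapply(feats, function(sub) {
    data.frame(mz = sub$mz[1], rtmed = stats::median(sub$rt),
               rt_lo_med = stats::median(sub$rt_lo),
               rt_hi_med = stats::median(sub$rt_hi), npeaks = nrow(sub))
  }))
  info$feature_id <- sprintf("M%dT%.2f", info$mz, info$rtmed)
  if (anyDuplicated(info$feature_id)) {
    dup <- ave(seq_len(nrow(info)), info$feature_id, FUN = seq_along)
    info$feature_id <- ifelse(dup > 1, sprintf("%s_%d", info$feature_id, dup), info$feature_id)
  }
  o <- order(info$rtmed, info$mz)
  info <- info[o, c("feature_id", "mz", "rtmed", "rt_lo_med", "rt_hi_med", "npeaks")]
  feats <- feats[o]
  intensity <- matrix(NA_real_, nrow = nrow(info), ncol = length(run_ids),
                      dimnames = list(info$feature_id, run_ids))
  for (i in seq_along(feats))
    intensity[i, match(feats[[i]]$run_id, run_ids)] <- feats[[i]]$area
  detected <- !is.na(intensity)
  ft <- structure(list(features = info, intensity = intensity,
                       detected = detected, metadata = metadata,
                       class_cols = class_cols),
                  class = "feature_table")
  ft$class_fraction <- class_fractions(ft)
  ft
}

## Fraction of each class's runs (or biological samples) with a detected peak.
class_fractions <- function(ft) {
  md <- ft$metadata
  cols <- ft$class_cols
  out <- list()
  for (cc in cols) {
    lv <- unique(md[[cc]])
    frac <- matrix(NA_real_, nrow(ft$detected), length(lv),
                   dimnames = list(rownames(ft$detected), paste(cc, lv, sep = ":")))
    for (l in lv)
      frac[, paste(cc, l, sep = ":")] <-
        rowMeans(ft$detected[, which(md[[cc]] == l), drop = FALSE])
    out[[cc]] <- frac
  }
  do.call(cbind, out)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d features x %d runs (%.1f%% detected)>\n",
              nrow(x$intensity), ncol(x$intensity), 100 * mean(x$detected)))
  invisible(x)
}

#' Retention-time correction by peak-group warping
#'
#' Well-behaved peak groups (present in at least `anchor_frac` of runs, one
#' peak per run) act as anchors; each run's deviations from the anchor median
#' retention times are smoothed by local regression (loess) and the fitted
#' deviation curve, clamped to strict monotonicity, becomes the run's warp.
#' With fewer than 5 anchors a per-run alkane ladder (if supplied) provides
#' anchors; with none at all the warp is the identity and a warning is
#' emitted.
#'
#' @param peaks Peak data frame over at least 2 runs.
#' @param anchor_frac Minimum fraction of runs an anchor group must cover.
#' @param span loess span for the deviation fit.
#' @param ladder_rt Optional data frame (`run_id`, `carbon`, `rt`) of per-run
#'   alkane retention times, the fallback anchor set.
#' @return List with `peaks` (corrected), `warps` (named list of strictly
#'   monotone functions, raw -> corrected minutes) and `diagnostics` (per run:
#'   anchors used, median absolute deviation before/after).
#' @export
correct_rt <- function(peaks, anchor_frac = 0.9, span = 0.5, ladder_rt = NULL) {
  run_ids <- unique(peaks$run_id)
  if (length(run_ids) < 2) stopf("retention-time correction needs >= 2 runs")
  ## candidate anchor groups on raw peaks
  anchors <- list()
  for (ch in unique(peaks$mz)) {
    pk <- peaks[peaks$mz == ch, , drop = FALSE]
    grp <- density_groups(pk$rt, sec_to_min(5), 100)
    for (g in unique(grp)) {
      sub <- pk[grp == g, , drop = FALSE]
      if (anyDuplicated(sub$run_id)) next
      if (nrow(sub) < anchor_frac * length(run_ids)) next
      anchors[[length(anchors) + 1]] <-
        data.frame(run_id = sub$run_id, rt = sub$rt, ref = stats::median(sub$rt))
    }
  }
  use_ladder <- length(anchors) < 5
  if (use_ladder && !is.null(ladder_rt)) {
    anchors <- lapply(split(ladder_rt, ladder_rt$carbon), function(d)
      data.frame(run_id = d$run_id, rt = d$rt, ref = stats::median(d$rt)))
  } else if (use_ladder) {
    warnf("fewer than 5 anchor groups and no ladder: applying identity warp")
    warps <- stats::setNames(rep(list(identity), length(run_ids)), run_ids)
    return(list(peaks = peaks, warps = warps,
                diagnostics = data.frame(run_id = run_ids, n_anchors = 0L,
                                         mad_before = NA_real_, mad_after = NA_real_)))
  }
  anc <- do.call(rbind, anchors)
  rng <- range(peaks$rt)
  grid <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = 600)
  warps <- list(); diag <- list()
  for (rid in run_ids) {
    a <- anc[anc$run_id == rid, , drop = FALSE]
    dev <- a$rt - a$ref
    if (nrow(a) >= 5 && stats::sd(dev) > 1e-9) {
      fit <- suppressWarnings(stats::loess(dev ~ rt, data = data.frame(rt = a$rt, dev = dev),
                                           span = max(span, 10 / nrow(a)), degree = 1,
                                           family = "symmetric"))
      pred <- stats::predict(fit, newdata = data.frame(rt = grid))
      ## constant extrapolation beyond the anchor range
      pred[grid < min(a$rt)] <- stats::predict(fit, newdata = data.frame(rt = min(a$rt)))
      pred[grid > max(a$rt)] <- stats::predict(fit, newdata = data.frame(rt = max(a$rt)))
      pred[!is.finite(pred)] <- 0
    } else if (nrow(a) >= 1) {
      pred <- rep(stats::median(dev), length(grid))
    } else {
      pred <- rep(0, length(grid))
    }
    w <- cummax(grid - pred)
    if (any(diff(w) <= 0)) w <- w + seq_along(w) * 1e-9   # break flat stretches
    core <- stats::approxfun(grid, w, rule = 2)
    g_lo <- grid[1]; g_hi <- grid[length(grid)]
    f <- local({
      core <- core; g_lo <- g_lo; g_hi <- g_hi
      function(t) {
        out <- core(t)
        out[t < g_lo] <- core(g_lo) + (t[t < g_lo] - g_lo)  # unit-slope tails
        out[t > g_hi] <- core(g_hi) + (t[t > g_hi] - g_hi)
        out
      }
    })
    warps[[rid]] <- f
    diag[[rid]] <- data.frame(run_id = rid, n_anchors = nrow(a),
                              mad_before = stats::median(abs(dev)),
                              mad_after = stats::median(abs(f(a$rt) - a$ref)))
  }
  corrected <- peaks
  for (rid in run_ids) {
    idx <- corrected$run_id == rid
    corrected$rt[idx] <- warps[[rid]](corrected$rt[idx])
    corrected$rt_lo[idx] <- warps[[rid]](corrected$rt_lo[idx])
    corrected$rt_hi[idx] <- warps[[rid]](corrected$rt_hi[idx])
  }
  list(peaks = corrected, warps = warps,
       diagnostics = do.call(rbind, c(diag, list(make.row.names = FALSE))))
}

#' Fill undetected feature intensities from raw chromatograms
#'
#' For every (feature, run) cell without a detected peak, integrates the run's
#' raw extracted ion chromatogram (on the warped time axis when warps are
#' given) over the feature's median retention window; a non-positive integral
#' is replaced by a noise-floor area so downstream log transforms stay
#' defined. Detected intensities are never modified.
#'
#' @param ft A `feature_table`.
#' @param runs List of `gc_run` keyed by run_id.
#' @param warps Optional warp functions from [correct_rt()].
#' @return The `feature_table` with a complete intensity matrix; `detected`
#'   still marks which cells were truly detected.
#' @export
fill_missing <- function(ft, runs, warps = NULL) {
  run_ids <- colnames(ft$intensity)
  for (rid in run_ids) {
    miss <- which(is.na(ft$intensity[, rid]))
    if (!length(miss)) next
    run <- runs[[rid]]
    if (is.null(run)) stopf("no raw run available for '%s'", rid)
    tt <- if (!is.null(warps) && !is.null(warps[[rid]])) warps[[rid]](run$times) else run$times
    for (i in miss) {
      f <- ft$features[i, ]
      ch <- match(f$mz, run$mz)
      win <- which(tt >= f$rt_lo_med & tt <= f$rt_hi_med)
      val <- 0
      if (!is.na(ch) && length(win) >= 2) {
        y <- as.numeric(run$mat[ch, win])
        val <- sum(diff(min_to_sec(tt[win])) * (y[-1] + y[-length(y)]) / 2)
      }
      if (val <= 0)
        val <- min_to_sec(f$rt_hi_med - f$rt_lo_med)  # 1-count noise-floor area
      ft$intensity[i, rid] <- val
    }
  }
  ft
}

#' Average technical (injection) replicates
#'
#' Collapses run columns to biological samples by arithmetic mean of the
#' injection intensities; class fractions are recomputed on biological
#' samples (a feature counts as detected in a sample when any injection
#' detected it).
#'
#' @param ft A `feature_table` (complete, i.e. after [fill_missing()]).
#' @return A `feature_table` whose columns are biological `sample_id`s.
#' @export
average_technical_replicates <- function(ft) {
  md <- ft$metadata
  bio <- unique(md$sample_id)
  counts <- table(md$sample_id)
  if (length(unique(counts)) > 1)
    warnf("unbalanced replicate counts (%s); averaging over available injections",
          paste(range(counts), collapse = "-"))
  nf <- nrow(ft$intensity)
  intensity <- matrix(NA_real_, nf, length(bio),
                      dimnames = list(rownames(ft$intensity), bio))
  detected <- matrix(FALSE, nf, length(bio),
                     dimnames = list(rownames(ft$intensity), bio))
  for (s in bio) {
    cols <- md$run_id[md$sample_id == s]
    intensity[, s] <- rowMeans(ft$intensity[, cols, drop = FALSE], na.rm = TRUE)
    detected[, s] <- apply(ft$detected[, cols, drop = FALSE], 1, any)
  }
  md_bio <- md[!duplicated(md$sample_id),
               setdiff(names(md), c("run_id", "injection")), drop = FALSE]
  out <- structure(list(features = ft$features, intensity = intensity,
                        detected = detected, metadata = md_bio,
                        class_cols = ft$class_cols),
                   class = "feature_table")
  out$metadata$run_id <- out$metadata$sample_id  # column key after averaging
  out$class_fraction <- class_fractions(out)
  out
}
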