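#' Group significant features into pseudo-spectra
#'
#' Single-linkage clustering of features on retention time: a new cluster
#' starts wherever the gap between consecutive feature rts exceeds
#' `gap` seconds. Each cluster's composite spectrum is its members'
#' (m/z, mean intensity) pairs rescaled to base peak 999.
#'
#' @param features Data frame with `feature_id`, `mz`, `rtmed` and
#'   `mean_intensity` (cross-sample mean area).
#' @param gap Retention-time gap threshold, seconds.
#' @return List of `pseudo_spectrum` objects: `rt` (intensity-weighted member
#'   mean), `member_features`, `spectrum` matrix.
#' @export
build_pseudospectra <- function(features, gap = 3) {
  if (!nrow(features)) return(list())
  stopifnot(all(c("feature_id", "mz", "rtmed", "mean_intensity") %in% names(features)))
  o <- order(features$rtmed)
  f <- features[o, , drop = FALSE]
  newc <- c(TRUE, diff(f$rtmed) > sec_to_min(gap))
  cl <- cumsum(newc)
  lapply(split(f, cl), function(d) {
    spec <- tapply(d$mean_intensity, d$mz, max)
    spec <- cbind(mz = as.integer(names(spec)), intensity = as.numeric(spec))
    spec[, "intensity"] <- spec[, "intensity"] / max(spec[, "intensity"]) * 999
    structure(list(rt = sum(d$rtmed * d$mean_intensity) / sum(d$mean_intensity),
                   member_features = d$feature_id,
                   spectrum = spec[order(spec[, "mz"]), , drop = FALSE]),
              class = "pseudo_spectrum")
  })
}

#' Weighted-cosine spectral match factor
#'
#' NIST-identity-style score on the 0-999 scale: peak weights are
#' `intensity^0.5 * mz^weight_mz` (default exponent 1); the score is
#' `round(999 * (sum over shared m/z of Wq Wr)^2 / (sum Wq^2 * sum Wr^2))`.
#' Symmetric, invariant to uniform intensity scaling, and 999 exactly when
#' the spectra are proportional on the union of their m/z.
#'
#' @param query,reference Spectrum matrices `(mz, intensity)` (nominal m/z) or
#'   objects with a `spectrum`/`peaks` element.
#' @param weight_int,weight_mz Weighting exponents for intensity and m/z.
#' @return Integer score 0-999.
#' @export
match_factor <- function(query, reference, weight_int = 0.5, weight_mz = 1) {
  as_spec <- function(x) {
    if (inherits(x, "pseudo_spectrum")) x <- x$spectrum
    if (inherits(x, "library_spectrum")) x <- x$peaks
    if (inherits(x, "compound_spec")) x <- x$spectrum
    m <- as.matrix(as.data.frame(x)[, 1:2])
    m[m[, 2] > 0, , drop = FALSE]
  }
  q <- as_spec(query); r <- as_spec(reference)
  if (!nrow(q) || !nrow(r)) stopf("match_factor: empty spectrum")
  wq <- q[, 2]^weight_int * q[, 1]^weight_mz
  wr <- r[, 2]^weight_int * r[, 1]^weight_mz
  shared <- intersect(q[, 1], r[, 1])
  if (!length(shared)) return(0L)
  num <- sum(wq[match(shared, q[, 1])] * wr[match(shared, r[, 1])])^2
  as.integer(round(999 * num / (sum(wq^2) * sum(wr^2))))
}

#' Retention index from an alkane ladder
#'
#' Temperature-programmed (van den Dool-Kratz) linear form by default:
#' `RI = 100 n + 100 (rt - rt_n) / (rt_{n+1} - rt_n)` for the bracketing
#' alkanes. The isothermal logarithmic Kovats form is available with
#' `form = "kovats"`. Retention times outside the ladder are refused, not
#' extrapolated.
#'
#' @param rt Retention time(s), minutes.
#' @param ladder An [alkane_ladder()].
#' @param form `"linear"` (van den Dool-Kratz) or `"kovats"` (isothermal,
#'   logarithmic in rt).
#' @return Retention index (vectorised over `rt`).
#' @export
compute_retention_index <- function(rt, ladder, form = c("linear", "kovats")) {
  form <- match.arg(form)
  if (any(rt < min(ladder$rt) | rt > max(ladder$rt)))
    stopf("RI extrapolation refused: rt outside ladder range [%.2f, %.2f] min",
          min(ladder$rt), max(ladder$rt))
  idx <- findInterval(rt, ladder$rt, rightmost.closed = TRUE)
  n0 <- ladder$carbon[idx]; n1 <- ladder$carbon[idx + 1]
  t0 <- ladder$rt[idx]; t1 <- ladder$rt[idx + 1]
  if (form == "linear") {
    100 * n0 + 100 * (n1 - n0) * (rt - t0) / (t1 - t0)
  } else {
    100 * n0 + 100 * (n1 - n0) * (log(rt) - log(t0)) / (log(t1) - log(t0))
  }
}

#' Two-step identification of pseudo-spectra
#'
#' Step one: weighted-cosine match against every library entry; the
#' best-scoring entry wins (ties broken by smaller RI gap). Step two: the RI
#' gate. Status is `tentative` when match factor >= `min_match` and the
#' library RI is absent or within `ri_tolerance`; `rejected` when the match
#' is good but the RI gap too large; `orphan` when no entry reaches
#' `min_match`.
#'
#' @param pseudospectra List from [build_pseudospectra()].
#' @param library_specs List of `library_spectrum` (see [read_library()]).
#' @param ladder An [alkane_ladder()] (NULL skips RI calculation).
#' @param min_match Match-factor threshold (0-999).
#' @param ri_tolerance Maximum |calculated - literature| RI.
#' @return Data frame of hits: `rt`, `n_features`, `compound`, `match_factor`,
#'   `ri_calc`, `ri_lit`, `delta_ri`, `status`, plus `member_features` as a
#'   list column.
#' @export
two_step_confirm <- function(pseudospectra, library_specs, ladder = NULL,
                             min_match = 700, ri_tolerance = 15) {
  if (!length(pseudospectra)) return(data.frame())
  rows <- lapply(pseudospectra, function(ps) {
    ri_calc <- if (!is.null(ladder)) compute_retention_index(ps$rt, ladder) else NA_real_
    mf <- vapply(library_specs, function(l) match_factor(ps, l), integer(1))
    ri_lit <- vapply(library_specs, function(l) l$ri_lit %||% NA_real_, numeric(1))
    dri <- abs(ri_calc - ri_lit)
    best <- order(-mf, ifelse(is.na(dri), Inf, dri))[1]
    status <- if (mf[best] < min_match) "orphan"
    else if (is.na(ri_lit[best]) || is.na(ri_calc) || dri[best] <= ri_tolerance) "tentative"
    else "rejected"
    data.frame(rt = ps$rt, n_features = length(ps$member_features),
               compound = library_specs[[best]]$name,
               match_factor = mf[best], ri_calc = ri_calc,
               ri_lit = ri_lit[best],
               delta_ri = ri_calc - ri_lit[best], status = status,
               member_features = I(list(ps$member_features)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Confirm a tentative hit against an authentic-standard run
#'
#' The standard injection is processed through peak detection and
#' pseudo-spectrum construction; the hit is `confirmed` when the standard's
#' apex retention time is within `rt_tol` seconds of the hit's and the two
#' spectra match at `min_match` or better, otherwise `rejected`.
#'
#' @param hit One row of the [two_step_confirm()] table (with `rt` and the
#'   pseudo-spectrum available via `spectrum`), or a `pseudo_spectrum` plus
#'   `rt`.
#' @param pseudo The hit's `pseudo_spectrum`.
#' @param standard_run A `gc_run` of the authentic standard.
#' @param params Detection parameters for processing the standard.
#' @param rt_tol Retention-time tolerance, seconds.
#' @param min_match Match-factor threshold.
#' @return `"confirmed"` or `"rejected"`.
#' @export
confirm_with_standard <- function(hit, pseudo, standard_run,
                                  params = detection_params(), rt_tol = 3,
                                  min_match = 700) {
  pk <- detect_peaks(standard_run, params)
  if (!nrow(pk)) stopf("no peak detected in the standard run")
  pk$mean_intensity <- pk$area
  pk$rtmed <- pk$rt
  pk$feature_id <- sprintf("M%dT%.2f", pk$mz, pk$rt)
  ps_all <- build_pseudospectra(pk[, c("feature_id", "mz", "rtmed", "mean_intensity")])
  ## the standard's own compound: the pseudo-spectrum nearest the hit rt
  rts <- vapply(ps_all, `[[`, numeric(1), "rt")
  std_ps <- ps_all[[which.min(abs(rts - hit$rt))]]
  if (abs(min_to_sec(std_ps$rt - hit$rt)) > rt_tol) return("rejected")
  if (match_factor(pseudo, std_ps) < min_match) return("rejected")
  "confirmed"
}
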