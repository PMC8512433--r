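#' Analyte / internal-standard response ratio
#'
#' @param analyte_area,is_area Peak areas (counts.s), both > 0 for the ratio
#'   to be meaningful; a zero internal-standard area is an error.
#' @return Dimensionless response ratio.
#' @export
response_ratio <- function(analyte_area, is_area) {
  if (any(is_area == 0)) stopf("internal-standard area is zero")
  if (any(analyte_area < 0 | is_area < 0)) stopf("areas must be non-negative")
  analyte_area / is_area
}

#' Fit a 1/x-weighted calibration curve
#'
#' Weighted least squares `minimise sum (1/x_i) (y_i - a - b x_i)^2`, the
#' standard weighting when calibration noise grows with concentration. R2 is
#' computed on the weighted fit (`1 - sum w e^2 / sum w (y - ybar_w)^2`); a
#' curve with R2 below `min_r2` is flagged unusable, not an error.
#'
#' @param levels Data frame with `conc` (x, ug/L, > 0) and `ratio` (y).
#' @param compound,is_name Labels carried on the curve.
#' @param weighting `"1/x"` or `"none"`.
#' @param min_r2 Usability threshold on the weighted R2.
#' @return Object of class `calibration_curve`: `slope`, `intercept`, `r2`,
#'   `range`, `usable`.
#' @export
fit_calibration <- function(levels, compound = NA_character_,
                            is_name = "2-Octanol", weighting = c("1/x", "none"),
                            min_r2 = 0.99) {
  weighting <- match.arg(weighting)
  x <- levels$conc; y <- levels$ratio
  if (length(unique(x)) < 2) stopf("calibration needs >= 2 distinct concentrations")
  if (any(x <= 0)) stopf("calibration concentrations must be > 0")
  if (length(x) < 5) warnf("only %d calibration levels (5 recommended)", length(x))
  w <- if (weighting == "1/x") 1 / x else rep(1, length(x))
  fit <- stats::lm(y ~ x, weights = w)
  co <- stats::coef(fit)
  ybar_w <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - ybar_w)^2)
  ss_res <- sum(w * stats::residuals(fit)^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 0 else 1 - ss_res / ss_tot
  structure(list(compound = compound, is_name = is_name,
                 slope = unname(co[2]), intercept = unname(co[1]),
                 weighting = weighting, r2 = r2, range = range(x),
                 usable = r2 >= min_r2, n_levels = length(x)),
            class = "calibration_curve")
}

#' Predict concentration from a calibration curve
#'
#' `conc = (ratio - intercept) / slope`, clipped at zero; ratios outside the
#' calibrated range are flagged.
#'
#' @param curve A [fit_calibration()] curve (must be usable).
#' @param ratio Response ratio(s).
#' @return Data frame `conc` (ug/L), `flag` (`""`, `"below_range"`,
#'   `"above_range"`, `"clipped"`).
#' @export
predict_concentration <- function(curve, ratio) {
  if (!isTRUE(curve$usable))
    stopf("calibration curve for '%s' is not usable (r2 = %.4f)", curve$compound, curve$r2)
  if (curve$slope == 0) stopf("calibration slope is zero")
  conc <- (ratio - curve$intercept) / curve$slope
  flag <- rep("", length(conc))
  eps <- 1e-8 * max(abs(curve$range))   # numerical guard at the range ends
  flag[conc < curve$range[1] - eps] <- "below_range"
  flag[conc > curve$range[2] + eps] <- "above_range"
  clipped <- conc < 0
  conc[clipped] <- 0
  flag[clipped] <- "clipped"
  data.frame(conc = conc, flag = flag)
}

#' Semi-quantitation in internal-standard equivalents
#'
#' Assumes a response factor of 1 relative to the internal standard:
#' `conc = ratio x is_conc`.
#'
#' @param ratio Response ratio(s).
#' @param is_conc Internal-standard concentration, ug/L (default 50, the
#'   2-octanol spike).
#' @return Concentration(s), ug/L.
#' @export
semi_quantify <- function(ratio, is_conc = 50) {
  stopifnot(is_conc > 0, all(ratio >= 0))
  ratio * is_conc
}

#' Odor activity value
#'
#' `OAV = concentration / odor threshold`; a missing threshold yields `NA`
#' (never 0).
#'
#' @param conc Concentration, ug/L.
#' @param odor_threshold Odor threshold, ug/L (> 0), or `NA`.
#' @return OAV (dimensionless).
#' @export
compute_oav <- function(conc, odor_threshold) {
  if (any(!is.na(odor_threshold) & odor_threshold <= 0))
    stopf("odor thresholds must be > 0")
  ifelse(is.na(odor_threshold), NA_real_, conc / odor_threshold)
}

## Compact letter display by insert-and-absorb on the non-significance
## relation: start from one all-inclusive letter; each significant pair
## splits every letter containing both; absorbed (subset) letters are
## dropped. Guarantees: two cells share a letter iff their pairwise p >= alpha.
cld_insert_absorb <- function(pmat, alpha = 0.05, order_by = NULL) {
  k <- nrow(pmat)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    newcols <- list()
    for (cc in cols) {
      if (cc[i] && cc[j]) {
        a <- cc; a[i] <- FALSE
        b <- cc; b[j] <- FALSE
        newcols <- c(newcols, list(a, b))
      } else newcols <- c(newcols, list(cc))
    }
    ## absorb: drop columns that are subsets of another
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a == b || !keep[a]) next
      if (all(newcols[[a]] <= newcols[[b]]) && any(newcols[[b]] & !newcols[[a]]))
        keep[a] <- FALSE
      else if (a < b && identical(newcols[[a]], newcols[[b]])) keep[a] <- FALSE
    }
    cols <- newcols[keep]
  }
  ## letter order: by descending group mean of the first cell each letter covers
  if (!is.null(order_by)) {
    first_rank <- vapply(cols, function(cc) min(rank(-order_by)[cc]), numeric(1))
    cols <- cols[order(first_rank)]
  }
  letters_vec <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
  names(letters_vec) <- rownames(pmat)
  letters_vec
}

#' Compound-level two-way ANOVA with post-hoc letter groups
#'
#' Fixed-effects two-way ANOVA (`conc ~ rootstock + irrigation +
#' rootstock:irrigation`, type-I sums of squares in that order) per compound,
#' followed by all-pairwise comparison of the 12 interaction cells —
#' studentized-range (Tukey HSD) by default, Duncan's multiple range test as
#' an option — summarised as a compact letter display (highest cell mean gets
#' "a"). With empty design cells the interaction is dropped and letters are
#' computed per main effect instead.
#'
#' @param conc_table Data frame `sample_id`, `conc` for one compound.
#' @param metadata Sample metadata (`sample_id`, `rootstock`, `irrigation`).
#' @param alpha Significance level for the letters.
#' @param posthoc `"tukey"` or `"duncan"`.
#' @return Object of class `compound_anova`: `p_values` (rootstock,
#'   irrigation, interaction), `cell_means` (rootstock x irrigation, ug/L),
#'   `letters` (per interaction cell), `pairwise_p`.
#' @export
compound_anova <- function(conc_table, metadata, alpha = 0.05,
                           posthoc = c("tukey", "duncan")) {
  posthoc <- match.arg(posthoc)
  d <- merge(conc_table, metadata, by = "sample_id")
  d$rootstock <- factor(d$rootstock)
  d$irrigation <- factor(d$irrigation)
  cell_n <- table(d$rootstock, d$irrigation)
  if (any(cell_n == 0)) {
    warnf("empty design cells: interaction dropped, letters on main-effect means")
    fit <- stats::aov(conc ~ rootstock + irrigation, data = d)
    sm <- summary(fit)[[1]]
    pv <- c(rootstock = sm["rootstock", "Pr(>F)"],
            irrigation = sm["irrigation", "Pr(>F)"], interaction = NA_real_)
    letters_main <- lapply(c("rootstock", "irrigation"), function(f) {
      tk <- stats::TukeyHSD(fit, which = f)[[f]]
      lv <- levels(d[[f]])
      pm <- pairwise_matrix(tk, lv)
      mns <- tapply(d$conc, d[[f]], mean)
      cld_insert_absorb(pm, alpha, order_by = mns)
    })
    names(letters_main) <- c("rootstock", "irrigation")
    return(structure(list(p_values = pv, cell_means = tapply(d$conc, list(d$rootstock, d$irrigation), mean),
                          letters = letters_main, pairwise_p = NULL,
                          posthoc = posthoc), class = "compound_anova"))
  }
  fit <- stats::aov(conc ~ rootstock + irrigation + rootstock:irrigation, data = d)
  sm <- summary(fit)[[1]]
  rn <- trimws(rownames(sm))
  pv <- c(rootstock = sm[rn == "rootstock", "Pr(>F)"],
          irrigation = sm[rn == "irrigation", "Pr(>F)"],
          interaction = sm[rn == "rootstock:irrigation", "Pr(>F)"])
  ## a constant response carries no evidence against any null
  if (stats::var(d$conc) < .Machine$double.eps) pv[] <- 1
  d$cell <- interaction(d$rootstock, d$irrigation, sep = ":")
  cfit <- stats::aov(conc ~ cell, data = d)
  lv <- levels(d$cell)
  if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(cfit, "cell")$cell
    pm <- pairwise_matrix(tk, lv)
  } else {
    pm <- duncan_pairwise(d$conc, d$cell)
  }
  mns <- tapply(d$conc, d$cell, mean)
  letters_vec <- cld_insert_absorb(pm, alpha, order_by = mns)
  structure(list(p_values = pv,
                 cell_means = tapply(d$conc, list(d$rootstock, d$irrigation), mean),
                 letters = letters_vec, pairwise_p = pm, posthoc = posthoc),
            class = "compound_anova")
}

## Symmetric pairwise p matrix from a TukeyHSD table.
pairwise_matrix <- function(tk, lv) {
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    a <- pairs[[r]][1]; b <- pairs[[r]][2]
    pm[a, b] <- pm[b, a] <- tk[r, "p adj"]
  }
  diag(pm) <- 1
  pm
}

## Duncan's multiple range test: pairwise p from the studentized range with
## the span-dependent protection level alpha_p = 1 - (1 - alpha)^(p - 1),
## expressed here as an equivalent p-value on the alpha = 0.05 scale.
duncan_pairwise <- function(y, g) {
  g <- factor(g)
  lv <- levels(g)
  mns <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  df_err <- length(y) - nlevels(g)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_err
  rk <- rank(mns)
  pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i == j) { pm[i, j] <- 1; next }
    span <- abs(rk[i] - rk[j]) + 1
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    qstat <- abs(mns[i] - mns[j]) / se
    p_range <- stats::ptukey(qstat, span, df_err, lower.tail = FALSE)
    ## invert the protection level so alpha comparisons stay at 0.05 scale
    pm[i, j] <- 1 - (1 - p_range)^(1 / max(span - 1, 1))
  }
  pm
}

#' Assemble a Table-1-style quantitation summary
#'
#' One row per compound: the 12 rootstock x irrigation cell means with their
#' compact letters and the interaction p-value.
#'
#' @param anovas Named list of [compound_anova()] results.
#' @return Data frame, one column per cell (`<rootstock>:<irrigation>`), plus
#'   `interaction_p`.
#' @export
quantitation_table <- function(anovas) {
  rows <- lapply(names(anovas), function(cmp) {
    a <- anovas[[cmp]]
    if (is.list(a$letters) && !is.null(a$letters$rootstock))
      return(NULL)  # interaction dropped; no cell table
    cm <- a$cell_means
    cells <- as.vector(t(cm))
    nms <- as.vector(outer(rownames(cm), colnames(cm), paste, sep = ":"))
    nms <- as.vector(t(matrix(nms, nrow(cm))))
    lets <- a$letters[nms]
    vals <- sprintf("%.1f %s", cells, lets)
    out <- as.data.frame(as.list(stats::setNames(vals, nms)), check.names = FALSE)
    out$interaction_p <- unname(a$p_values["interaction"])
    out$compound <- cmp
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  out[, c("compound", setdiff(names(out), "compound"))]
}
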