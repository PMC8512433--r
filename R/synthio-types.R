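#' Factor levels used throughout the workflow
#'
#' The study design crosses four root systems (own-rooted plus three
#' commercial rootstocks) with three irrigation regimes (full irrigation,
#' regulated deficit irrigation, and none).
#' @name design-levels
#' @keywords internal
NULL

ROOTSTOCK_LEVELS  <- c("Own", "1103P", "3309C", "SO4")
IRRIGATION_LEVELS <- c("Full", "RDI", "None")

#' Construct a compound specification for the study generator
#'
#' A `compound_spec` describes one volatile compound as the generator plants it
#' in a synthetic study: its unit-mass EI spectrum, its true retention index on
#' the column, its baseline concentration, per-treatment-level effect
#' multipliers, and biological variability.
#'
#' @param name Compound name.
#' @param spectrum Two-column matrix or data.frame `(mz, intensity)`; nominal
#'   integer m/z, relative intensities on the 0-999 scale with the base peak at
#'   999 (rescaled if not).
#' @param true_ri True retention index (dimensionless, alkane scale: Cn = 100n).
#' @param base_conc Baseline concentration in ug/L (> 0).
#' @param effect_multiplier Named numeric vector mapping factor levels (e.g.
#'   `c(Own = 1.3)`) to multiplicative concentration effects; all > 0.
#' @param cv Biological coefficient of variation (log-normal, mean preserved).
#' @param response Instrument response factor: apex counts contributed to a
#'   fragment channel per (ug/L x relative intensity unit).
#' @param odor_threshold Odor threshold in ug/L, or `NA` if unknown.
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(name, spectrum, true_ri, base_conc,
                          effect_multiplier = numeric(0), cv = 0,
                          response = 1, odor_threshold = NA_real_) {
  spectrum <- as.matrix(as.data.frame(spectrum)[, 1:2])
  colnames(spectrum) <- c("mz", "intensity")
  if (nrow(spectrum) == 0) stopf("compound '%s': spectrum is empty", name)
  if (any(spectrum[, "intensity"] < 0)) stopf("compound '%s': negative intensity", name)
  spectrum[, "intensity"] <- spectrum[, "intensity"] / max(spectrum[, "intensity"]) * 999
  spectrum <- spectrum[order(spectrum[, "mz"]), , drop = FALSE]
  if (base_conc <= 0) stopf("compound '%s': base_conc must be > 0", name)
  if (length(effect_multiplier) && any(effect_multiplier <= 0))
    stopf("compound '%s': effect multipliers must be > 0", name)
  if (cv < 0) stopf("compound '%s': cv must be >= 0", name)
  structure(list(name = name, spectrum = spectrum, true_ri = true_ri,
                 base_conc = base_conc, effect_multiplier = effect_multiplier,
                 cv = cv, response = response, odor_threshold = odor_threshold),
            class = "compound_spec")
}

#' Build a full-factorial study design with technical replicates
#'
#' @param rootstocks,irrigations Factor levels (defaults: the four root systems
#'   and three irrigation regimes of the workflow).
#' @param year Vintage year.
#' @param vines Number of replicate vines per treatment cell.
#' @param injections Number of technical (injection) replicates per sample.
#' @return Data frame with one row per injection: `sample_id`, `run_id`,
#'   `rootstock`, `irrigation`, `year`, `vine`, `injection`.
#' @export
study_design <- function(rootstocks = ROOTSTOCK_LEVELS,
                         irrigations = IRRIGATION_LEVELS,
                         year = 2018, vines = 2, injections = 2) {
  d <- expand.grid(injection = seq_len(injections), vine = seq_len(vines),
                   irrigation = irrigations, rootstock = rootstocks,
                   year = year, stringsAsFactors = FALSE)
  d <- d[, c("rootstock", "irrigation", "year", "vine", "injection")]
  d$sample_id <- sprintf("Y%d_%s_%s_v%d", d$year, d$rootstock, d$irrigation, d$vine)
  d$run_id <- sprintf("%s_inj%d", d$sample_id, d$injection)
  if (anyDuplicated(d[, c("sample_id", "injection")]))
    stopf("(sample_id, injection) must be unique")
  d[, c("sample_id", "run_id", "rootstock", "irrigation", "year", "vine", "injection")]
}

#' Construct an n-alkane retention ladder
#'
#' @param carbon Integer carbon numbers (subset of 7..30).
#' @param rt Retention times in minutes, strictly increasing with carbon.
#' @return Data frame of class `alkane_ladder` with columns `carbon`, `rt`.
#' @export
alkane_ladder <- function(carbon, rt) {
  o <- order(carbon)
  carbon <- as.integer(carbon[o]); rt <- as.numeric(rt[o])
  if (length(carbon) < 2) stopf("ladder needs at least 2 alkanes")
  if (anyDuplicated(carbon)) stopf("duplicate carbon numbers in ladder")
  if (any(diff(rt) <= 0)) stopf("ladder retention times must increase strictly with carbon number")
  structure(data.frame(carbon = carbon, rt = rt), class = c("alkane_ladder", "data.frame"))
}

#' Default C7-C30 alkane ladder
#'
#' A mildly curved temperature-programmed elution profile spanning
#' 2.4-36.8 min, used by the default synthetic study.
#' @return An [alkane_ladder()].
#' @export
default_ladder <- function() {
  n <- 7:30
  rt <- 2.4 + 1.62 * (n - 7) - 0.0045 * (n - 7)^2
  alkane_ladder(n, rt)
}

## Piecewise-linear inverse of the van den Dool mapping: RI -> retention time.
ri_to_rt <- function(ri, ladder) {
  lo <- 100 * min(ladder$carbon); hi <- 100 * max(ladder$carbon)
  if (any(ri < lo | ri > hi)) stopf("RI out of ladder range [%d, %d]", lo, hi)
  stats::approx(x = 100 * ladder$carbon, y = ladder$rt, xout = ri)$y
}

#' Assemble a synthetic-study recipe
#'
#' A recipe fully determines a synthetic study: design, compound panel,
#' internal standards, alkane ladder, acquisition grid and noise model.
#' Given the same seed, [simulate_study()] output is reproducible.
#'
#' @param design Data frame from [study_design()].
#' @param compounds List of [compound_spec()] objects.
#' @param internal_standards List of [compound_spec()] objects spiked at fixed
#'   concentration (their `base_conc`); by convention 2-octanol at 50,
#'   4-methyl-2-pentanol at 100 and 3-octanone at 50 ug/L.
#' @param ladder An [alkane_ladder()].
#' @param rt_drift_sd Per-run retention-time drift sd, minutes.
#' @param response_drift_cv Per-run global instrument-response CV (log-normal);
#'   affects all compounds and internal standards alike, so internal-standard
#'   normalisation cancels it.
#' @param noise_floor Constant baseline level, counts. Counting (Poisson)
#'   noise is applied on top of signal + floor; `noise_floor = 0` switches all
#'   noise off and yields the deterministic noise-free signal.
#' @param scans_per_min Acquisition rate, scans/minute.
#' @param rt_range Length-2 numeric, acquisition window in minutes.
#' @param peak_sigma_s Gaussian elution-profile sigma in seconds.
#' @param seed Integer seed.
#' @return Object of class `study_recipe`.
#' @export
study_recipe <- function(design, compounds, internal_standards = list(),
                         ladder = default_ladder(),
                         rt_drift_sd = 0.02, response_drift_cv = 0.05,
                         noise_floor = 5, scans_per_min = 240,
                         rt_range = c(1.5, 38), peak_sigma_s = 2.5,
                         seed = 1L) {
  stopifnot(is.data.frame(design), length(rt_range) == 2, rt_range[1] < rt_range[2])
  all_specs <- c(compounds, internal_standards)
  ris <- vapply(all_specs, `[[`, numeric(1), "true_ri")
  lo <- 100 * min(ladder$carbon); hi <- 100 * max(ladder$carbon)
  if (any(ris < lo | ris > hi)) stopf("RI out of ladder range")
  rts <- ri_to_rt(ris, ladder)
  pad <- 4 * sec_to_min(peak_sigma_s)
  if (any(rts - pad < rt_range[1] | rts + pad > rt_range[2]))
    stopf("rt_range does not cover all compound elution profiles")
  structure(list(design = design, compounds = compounds,
                 internal_standards = internal_standards, ladder = ladder,
                 rt_drift_sd = rt_drift_sd, response_drift_cv = response_drift_cv,
                 noise_floor = noise_floor, scans_per_min = scans_per_min,
                 rt_range = rt_range, peak_sigma_s = peak_sigma_s,
                 seed = as.integer(seed)),
            class = "study_recipe")
}

## A raw GC-MS injection in rastered form: one row per nominal m/z channel,
## one column per scan.  Equivalent to the per-scan centroid form (write_runs
## expands, read_runs re-rasters) but much cheaper to process.
new_run <- function(meta, times, mz, mat) {
  stopifnot(nrow(mat) == length(mz), ncol(mat) == length(times))
  if (any(diff(times) <= 0)) stopf("scan times must be strictly increasing")
  structure(list(meta = meta, times = times, mz = as.integer(mz), mat = mat),
            class = "gc_run")
}

#' @export
print.gc_run <- function(x, ...) {
  cat(sprintf("<gc_run %s: %d scans, m/z %d-%d, rt %.2f-%.2f min>\n",
              x$meta$run_id %||% "?", length(x$times), min(x$mz), max(x$mz),
              min(x$times), max(x$times)))
  invisible(x)
}
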