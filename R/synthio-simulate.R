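#' Simulate a synthetic GC-MS study
#'
#' Generates one scan-mode run per design row plus a ground-truth table of
#' per-biological-sample concentrations. Each compound elutes as a Gaussian
#' profile centred at the retention time its true RI maps to on the ladder
#' (piecewise-linear inverse of the van den Dool convention), shifted by a
#' per-run drift. Per-sample concentration is
#' `base_conc x prod(effect multipliers for the sample's levels) x LogNormal(cv)`
#' (mean-preserving). A fragment channel's apex contribution is
#' `conc x response x relative intensity x run response drift`. Counting noise
#' is Poisson with mean = signal + `noise_floor`; `noise_floor = 0` disables
#' noise entirely.
#'
#' @param recipe A [study_recipe()].
#' @return List with `runs` (list of `gc_run`), `truth` (data.frame compound x
#'   biological sample, true concentrations in ug/L), `run_info` (per-run
#'   drift and response factor) and the `recipe`.
#' @export
simulate_study <- function(recipe) {
  stopifnot(inherits(recipe, "study_recipe"))
  set.seed(recipe$seed)
  design <- recipe$design
  compounds <- recipe$compounds
  is_specs <- recipe$internal_standards
  all_specs <- c(compounds, is_specs)
  bio <- unique(design$sample_id)
  bio_meta <- design[!duplicated(design$sample_id), , drop = FALSE]

  ## --- ground truth: biological concentrations ------------------------------
  conc <- matrix(NA_real_, nrow = length(all_specs), ncol = length(bio),
                 dimnames = list(vapply(all_specs, `[[`, character(1), "name"), bio))
  for (ci in seq_along(all_specs)) {
    sp <- all_specs[[ci]]
    for (bi in seq_along(bio)) {
      m <- bio_meta[bi, ]
      mult <- 1
      em <- sp$effect_multiplier
      if (length(em)) {
        hit <- names(em) %in% c(m$rootstock, m$irrigation)
        if (any(hit)) mult <- prod(em[hit])
      }
      noise <- if (sp$cv > 0) {
        sdlog <- sqrt(log(1 + sp$cv^2))
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else 1
      conc[ci, bi] <- sp$base_conc * mult * noise
    }
  }

  ## --- per-run nuisance parameters ------------------------------------------
  n_run <- nrow(design)
  drift <- if (recipe$rt_drift_sd > 0) stats::rnorm(n_run, 0, recipe$rt_drift_sd) else numeric(n_run)
  resp_drift <- if (recipe$response_drift_cv > 0) {
    sdlog <- sqrt(log(1 + recipe$response_drift_cv^2))
    stats::rlnorm(n_run, -sdlog^2 / 2, sdlog)
  } else rep(1, n_run)

  ## --- raster grid -----------------------------------------------------------
  times <- seq(recipe$rt_range[1], recipe$rt_range[2], by = 1 / recipe$scans_per_min)
  mz_grid <- 29:300
  sigma <- sec_to_min(recipe$peak_sigma_s)
  apex_rt <- ri_to_rt(vapply(all_specs, `[[`, numeric(1), "true_ri"), recipe$ladder)

  runs <- vector("list", n_run)
  for (r in seq_len(n_run)) {
    meta <- design[r, , drop = FALSE]
    lam <- matrix(0, nrow = length(mz_grid), ncol = length(times))
    for (ci in seq_along(all_specs)) {
      sp <- all_specs[[ci]]
      rt0 <- apex_rt[ci] + drift[r]
      win <- which(abs(times - rt0) <= 5 * sigma)
      if (!length(win)) next
      g <- exp(-((times[win] - rt0)^2) / (2 * sigma^2))
      amp <- conc[ci, meta$sample_id] * sp$response * resp_drift[r]
      rows <- match(sp$spectrum[, "mz"], mz_grid)
      ok <- !is.na(rows)
      if (!any(ok)) next
      lam[rows[ok], win] <- lam[rows[ok], win] +
        amp * sp$spectrum[ok, "intensity", drop = TRUE] %o% g
    }
    mat <- if (recipe$noise_floor > 0) {
      matrix(stats::rpois(length(lam), lam + recipe$noise_floor),
             nrow = nrow(lam))
    } else lam
    runs[[r]] <- new_run(meta, times, mz_grid, mat)
  }
  names(runs) <- design$run_id

  truth <- as.data.frame(conc[seq_along(compounds), , drop = FALSE])
  list(runs = runs, truth = truth,
       run_info = data.frame(run_id = design$run_id, rt_drift = drift,
                             response_factor = resp_drift),
       recipe = recipe)
}

#' Simulate a single authentic-standard run
#'
#' One injection containing only the given compound (at `conc`) and the
#' internal standards, with no biological noise; used for identity
#' confirmation against pseudo-spectra.
#'
#' @param spec A [compound_spec()].
#' @param recipe The study [study_recipe()] whose acquisition settings to use.
#' @param conc Standard concentration, ug/L.
#' @param seed Seed for counting noise.
#' @return A `gc_run`.
#' @export
simulate_standard_run <- function(spec, recipe, conc = spec$base_conc, seed = 1L) {
  std <- compound_spec(spec$name, spec$spectrum, spec$true_ri, conc,
                       cv = 0, response = spec$response,
                       odor_threshold = spec$odor_threshold)
  des <- data.frame(sample_id = paste0("STD_", spec$name), rootstock = "Own",
                    irrigation = "Full", year = 0L, vine = 1L, injection = 1L)
  des$run_id <- paste0(des$sample_id, "_inj1")
  rec <- study_recipe(design = des, compounds = list(std),
                      internal_standards = recipe$internal_standards,
                      ladder = recipe$ladder, rt_drift_sd = 0,
                      response_drift_cv = 0, noise_floor = recipe$noise_floor,
                      scans_per_min = recipe$scans_per_min,
                      rt_range = recipe$rt_range,
                      peak_sigma_s = recipe$peak_sigma_s, seed = seed)
  simulate_study(rec)$runs[[1]]
}

#' Simulate a calibration response series for a compound
#'
#' Produces the (concentration, response-ratio) table an authentic-standard
#' dilution series would give on the quantifier (base-peak) ion: ratios of
#' Gaussian peak areas cancel the common profile width, so the true ratio is
#' linear in concentration; optional proportional noise on top.
#'
#' @param spec A [compound_spec()] for the analyte.
#' @param is_spec Internal-standard [compound_spec()] (its `base_conc` is the
#'   spiked concentration).
#' @param levels Concentrations (ug/L) of the dilution series; default five
#'   levels spanning 0.2x-5x the analyte's base concentration.
#' @param noise_cv Proportional measurement noise CV on the ratios.
#' @param seed Seed for the noise draws (private stream).
#' @return Data frame `conc`, `ratio`.
#' @export
simulate_calibration <- function(spec, is_spec,
                                 levels = spec$base_conc * c(0.2, 0.5, 1, 2, 5),
                                 noise_cv = 0, seed = 1L) {
  bp <- function(s) s$response * max(s$spectrum[, "intensity"])
  true_slope <- bp(spec) / (is_spec$base_conc * bp(is_spec))
  ratio <- true_slope * levels
  if (noise_cv > 0)
    ratio <- with_local_seed(seed, ratio * (1 + stats::rnorm(length(ratio), 0, noise_cv)))
  data.frame(conc = levels, ratio = ratio)
}
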