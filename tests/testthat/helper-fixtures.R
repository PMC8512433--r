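## Shared in-code fixtures: tiny runs, recipes and design tables.

## A run with Gaussian peaks planted directly on given channels.
## peaks: data.frame(mz, rt, height, sigma_s)
make_run <- function(peaks, rt_range = c(0, 6), scans_per_min = 240,
                     mz_range = c(29, 160), floor = 0, run_id = "r1",
                     sample_id = "s1") {
  times <- seq(rt_range[1], rt_range[2], by = 1 / scans_per_min)
  mz <- seq(mz_range[1], mz_range[2])
  mat <- matrix(floor, nrow = length(mz), ncol = length(times))
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    ch <- match(p$mz, mz)
    mat[ch, ] <- mat[ch, ] + p$height * exp(-(times - p$rt)^2 / (2 * (p$sigma_s / 60)^2))
  }
  meta <- data.frame(sample_id = sample_id, run_id = run_id,
                     rootstock = "Own", irrigation = "Full",
                     year = 2018L, vine = 1L, injection = 1L)
  vinomix:::new_run(meta, times, mz, mat)
}

## Small balanced design + metadata for statistics tests.
small_design <- function(vines = 3) {
  study_design(vines = vines, injections = 1)
}

## A compact study recipe for end-to-end tests: few compounds, short runs.
small_recipe <- function(seed = 1L, n_compounds = 8, cv = 0.1,
                         noise_floor = 2, planted = integer(0), shift = 1.6,
                         injections = 2, vines = 2) {
  panel <- synthetic_compound_panel(n = n_compounds, n_planted = 0, cv = cv)
  for (i in planted)
    panel[[i]] <- compound_spec(panel[[i]]$name, panel[[i]]$spectrum,
                                panel[[i]]$true_ri, panel[[i]]$base_conc,
                                effect_multiplier = c(Own = shift), cv = cv,
                                odor_threshold = panel[[i]]$odor_threshold)
  lad <- alkane_ladder(7:16, seq(1.2, 10.8, length.out = 10))
  keep <- vapply(panel, function(s) s$true_ri <= 1580, logical(1))
  panel <- panel[keep]
  is_specs <- Filter(function(s) s$true_ri <= 1580, internal_standard_specs())
  study_recipe(design = study_design(vines = vines, injections = injections),
               compounds = panel, internal_standards = is_specs,
               ladder = lad, rt_range = c(0.5, 11.5), noise_floor = noise_floor,
               seed = seed)
}

## Random nominal-mass spectrum for match-factor property tests.
random_spectrum <- function(n = NULL) {
  n <- n %||% sample(3:12, 1)
  mz <- sort(sample(29:300, n))
  int <- stats::runif(n, 1, 999)
  cbind(mz = mz, intensity = int / max(int) * 999)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
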