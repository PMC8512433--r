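#' Assemble a pipeline configuration
#'
#' All stage parameters of the full funnel in one validated object;
#' serialisable to/from YAML. Unknown keys are rejected.
#'
#' @param recipe A [study_recipe()] for synthetic input, or `NULL` when
#'   reading runs from disk.
#' @param runs_dir,metadata_csv mzML directory and metadata table (used when
#'   `recipe` is `NULL`).
#' @param library_path Optional MSP library path (synthetic mode builds its
#'   own library, with decoys, from the recipe).
#' @param n_decoys Decoy entries added to the synthetic library.
#' @param detection A [detection_params()].
#' @param grouping A [grouping_params()].
#' @param alpha FDR threshold on q-values.
#' @param pcs Principal components for the variance partition.
#' @param plsda_components,permutations PLS-DA settings.
#' @param min_match,ri_tol,pseudospec_gap Identification settings (match
#'   factor 0-999, RI units, seconds).
#' @param is_name,is_conc,min_r2 Quantitation settings (internal standard
#'   name, its concentration in ug/L, minimum calibration R2).
#' @param posthoc Post-hoc test for compound ANOVA letters.
#' @param fill Integrate raw chromatograms for undetected cells before
#'   statistics.
#' @param seed Pipeline seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(recipe = default_study_recipe(),
                            runs_dir = NULL, metadata_csv = NULL,
                            library_path = NULL, n_decoys = 10,
                            detection = detection_params(),
                            grouping = grouping_params(),
                            alpha = 0.05, pcs = 20,
                            plsda_components = 2, permutations = 1000,
                            min_match = 700, ri_tol = 15, pseudospec_gap = 3,
                            is_name = "2-Octanol", is_conc = 50, min_r2 = 0.99,
                            posthoc = "tukey", fill = TRUE, seed = 1L) {
  structure(list(recipe = recipe, runs_dir = runs_dir,
                 metadata_csv = metadata_csv, library_path = library_path,
                 n_decoys = n_decoys, detection = detection,
                 grouping = grouping, alpha = alpha, pcs = pcs,
                 plsda_components = plsda_components,
                 permutations = permutations, min_match = min_match,
                 ri_tol = ri_tol, pseudospec_gap = pseudospec_gap,
                 is_name = is_name, is_conc = is_conc, min_r2 = min_r2,
                 posthoc = posthoc, fill = fill, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar settings only (the recipe stays the default study unless runs are
#' read from disk); unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), c("recipe", "detection", "grouping"))
  allowed <- c(allowed, "peakwidth", "snthresh", "prefilter", "mzwid", "bw",
               "minfrac", "max_per_slice", "minsamp")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  det <- detection_params(
    peakwidth = unlist(y$peakwidth) %||% c(5, 20),
    snthresh = y$snthresh %||% 6,
    prefilter = unlist(y$prefilter) %||% c(3, 100))
  grp <- grouping_params(mzwid = y$mzwid %||% 0.015, bw = y$bw %||% 5,
                         minfrac = y$minfrac %||% 0.5,
                         max_per_slice = y$max_per_slice %||% 100,
                         minsamp = y$minsamp %||% 1)
  args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("recipe", "detection", "grouping")))]
  do.call(pipeline_config, c(list(detection = det, grouping = grp),
                             lapply(args, function(v) if (is.list(v)) unlist(v) else v)))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[vinomix] ", fmt), ...))
}

write_stage_csv <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full untargeted-to-targeted funnel
#'
#' Executes: simulate (or read) -> detect -> retention-time correction ->
#' group -> fill -> average technical replicates -> internal-standard
#' normalisation, log, autoscale -> per-factor ANOVA with BH FDR -> PCA +
#' PLS-DA (with permutation validation) + per-PC variance partition ->
#' pseudo-spectra -> two-step identification -> calibration-based
#' quantitation of identified panel compounds (semi-quantitation when no
#' curve is available) -> odor activity values -> per-compound two-way ANOVA
#' with letter groups. Every intermediate table is written as CSV and a JSON
#' manifest records parameters, seed and the funnel counts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for CSVs and the manifest (`NULL` for
#'   in-memory only).
#' @param verbose Log one line per stage.
#' @return List with every stage's result and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = interactive()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  ## --- input ----------------------------------------------------------------
  if (!is.null(config$recipe)) {
    log_stage(verbose, "simulate: %d runs, %d compounds",
              nrow(config$recipe$design), length(config$recipe$compounds))
    sim <- simulate_study(config$recipe)
    runs <- sim$runs
    metadata <- config$recipe$design
    ladder <- config$recipe$ladder
    truth <- sim$truth
  } else {
    metadata <- utils::read.csv(config$metadata_csv, check.names = FALSE)
    if (!"run_id" %in% names(metadata))
      metadata$run_id <- sprintf("%s_inj%d", metadata$sample_id, metadata$injection)
    paths <- file.path(config$runs_dir, paste0(metadata$run_id, ".mzML"))
    runs <- read_runs(paths, metadata)
    ladder <- NULL
    truth <- NULL
    sim <- NULL
  }

  ## --- detection ------------------------------------------------------------
  log_stage(verbose, "detect: %d runs", length(runs))
  peaks <- do.call(rbind, lapply(runs, detect_peaks, params = config$detection))
  rownames(peaks) <- NULL
  if (is.null(peaks) || !nrow(peaks)) stopf("stage detect: no peaks found in any run")
  write_stage_csv(peaks, out_dir, "peaks")

  ## --- alignment ------------------------------------------------------------
  log_stage(verbose, "align: %d peaks", nrow(peaks))
  rtc <- correct_rt(peaks)
  write_stage_csv(rtc$diagnostics, out_dir, "warp_diagnostics")
  ft <- group_peaks(rtc$peaks, config$grouping, metadata)
  if (config$fill) ft <- fill_missing(ft, runs, rtc$warps)
  else ft$intensity[is.na(ft$intensity)] <- 0
  ft_avg <- average_technical_replicates(ft)
  n_detected <- nrow(ft_avg$features)
  feat_out <- cbind(ft_avg$features, as.data.frame(ft_avg$intensity))
  write_stage_csv(feat_out, out_dir, "feature_table")

  ## --- preprocessing --------------------------------------------------------
  fm_raw <- as_feature_matrix(ft_avg)
  is_feats <- find_is_features(ft_avg, config$recipe, config$is_name)
  log_stage(verbose, "preprocess: IS feature %s", is_feats$quant)
  fm <- preprocess(fm_raw, is_feats$quant, drop_features = is_feats$drop)
  n_features <- ncol(fm$values)   # the universe entering statistics

  ## --- univariate stats -----------------------------------------------------
  res_root <- anova_per_feature(fm, "rootstock")
  res_irr <- anova_per_feature(fm, "irrigation")
  write_stage_csv(rbind(res_root, res_irr), out_dir, "anova_features")
  ## alpha = 1 disables filtering (q values are capped at exactly 1)
  sig_root <- if (config$alpha >= 1) res_root$feature_id
  else res_root$feature_id[res_root$q < config$alpha]
  sig_irr <- if (config$alpha >= 1) res_irr$feature_id
  else res_irr$feature_id[res_irr$q < config$alpha]
  sig <- union(sig_root, sig_irr)
  log_stage(verbose, "stats: %d/%d significant (rootstock %d, irrigation %d)",
            length(sig), n_features, length(sig_root), length(sig_irr))
  if (length(sig) < 3) {
    warnf("fewer than 3 significant features; multivariate stage uses all features")
    sig_model <- colnames(fm$values)
  } else sig_model <- sig
  fm_sig <- feature_matrix(fm$values[, sig_model, drop = FALSE], fm$samples,
                           state = "autoscaled")

  ## --- multivariate stats ---------------------------------------------------
  k <- min(config$pcs, nrow(fm_sig$values) - 1, ncol(fm_sig$values))
  pca <- pca_fit(fm_sig, k)
  vp <- variance_partition(pca)
  write_stage_csv(vp, out_dir, "variance_partition")
  plsda <- list()
  for (fac in c("rootstock", "irrigation")) {
    m <- plsda_fit(fm_sig, fac, config$plsda_components)
    pt <- permutation_test(fm_sig, fac, B = config$permutations,
                           ncomp = config$plsda_components)
    plsda[[fac]] <- list(model = m, perm_p = pt$perm_p)
  }
  write_stage_csv(data.frame(
    factor = names(plsda),
    R2Y = vapply(plsda, function(z) z$model$R2Y, numeric(1)),
    Q2 = vapply(plsda, function(z) z$model$Q2, numeric(1)),
    perm_p = vapply(plsda, function(z) z$perm_p, numeric(1)),
    n_vip_gt1 = vapply(plsda, function(z) sum(z$model$vip > 1), numeric(1))),
    out_dir, "plsda_summary")

  ## --- identification -------------------------------------------------------
  sig_feat <- ft_avg$features[ft_avg$features$feature_id %in% sig, , drop = FALSE]
  sig_feat$mean_intensity <- rowMeans(ft_avg$intensity[sig_feat$feature_id, , drop = FALSE])
  ps <- build_pseudospectra(sig_feat, gap = config$pseudospec_gap)
  lib <- if (!is.null(config$library_path)) read_library(config$library_path)
  else synthetic_spectral_library(c(config$recipe$compounds,
                                    config$recipe$internal_standards),
                                  n_decoys = config$n_decoys)
  hits <- two_step_confirm(ps, lib, ladder, config$min_match, config$ri_tol)
  n_tentative <- if (nrow(hits)) sum(hits$status == "tentative") else 0L
  log_stage(verbose, "identify: %d pseudo-spectra, %d tentative", length(ps), n_tentative)
  if (nrow(hits))
    write_stage_csv(cbind(hits[setdiff(names(hits), "member_features")],
                          member_features = vapply(hits$member_features, paste,
                                                   character(1), collapse = ";")),
                    out_dir, "identification_hits")

  ## --- quantitation ---------------------------------------------------------
  quant <- NULL; anovas <- list(); n_confirmed <- 0L; n_quantified <- 0L
  if (!is.null(config$recipe) && n_tentative > 0) {
    quant <- quantify_hits(hits, ft_avg, config)
    n_confirmed <- length(unique(quant$conc$compound[quant$conc$mode == "quantified"]))
    n_quantified <- length(unique(quant$conc$compound))
    write_stage_csv(quant$conc, out_dir, "quantitation")
    anovas <- quant$anovas
    if (length(anovas)) write_stage_csv(quantitation_table(anovas), out_dir, "compound_anova")
  }

  manifest <- list(
    package = "vinomix",
    version = as.character(utils::packageVersion("vinomix")),
    seed = config$seed,
    params = list(alpha = config$alpha, min_match = config$min_match,
                  ri_tol = config$ri_tol, permutations = config$permutations,
                  snthresh = config$detection$snthresh,
                  peakwidth = config$detection$peakwidth,
                  bw = config$grouping$bw, minfrac = config$grouping$minfrac),
    funnel = list(n_features_detected = n_detected,
                  n_features = n_features, n_significant = length(sig),
                  n_tentative = n_tentative, n_confirmed = n_confirmed,
                  n_quantified = n_quantified))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(runs = runs, truth = truth, peaks = peaks, warps = rtc$warps,
       feature_table = ft_avg, matrix = fm,
       anova = list(rootstock = res_root, irrigation = res_irr),
       significant = list(rootstock = sig_root, irrigation = sig_irr, union = sig),
       pca = pca, variance_partition = vp, plsda = plsda,
       pseudospectra = ps, hits = hits, quant = quant, manifest = manifest)
}

## Locate the internal standards' quantifier features (base-peak channel at
## the IS retention time) in an averaged feature table.
find_is_features <- function(ft, recipe, is_name) {
  if (is.null(recipe)) stopf("internal-standard location requires a recipe or explicit feature id")
  specs <- recipe$internal_standards
  nms <- vapply(specs, `[[`, character(1), "name")
  ids <- lapply(specs, function(sp) {
    rt <- ri_to_rt(sp$true_ri, recipe$ladder)
    bp <- sp$spectrum[which.max(sp$spectrum[, "intensity"]), "mz"]
    cand <- ft$features[ft$features$mz == bp &
                          abs(ft$features$rtmed - rt) < 0.1, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    cand$feature_id[which.max(cand$npeaks)]
  })
  main <- which(tolower(nms) == tolower(is_name))
  if (!length(main) || is.na(ids[[main]]))
    stopf("internal standard '%s' feature not found", is_name)
  ## drop every feature inside any IS elution window from the model matrix
  drop <- character(0)
  for (sp in specs) {
    rt <- ri_to_rt(sp$true_ri, recipe$ladder)
    win <- abs(ft$features$rtmed - rt) < 0.05 &
      ft$features$mz %in% sp$spectrum[, "mz"]
    drop <- c(drop, ft$features$feature_id[win])
  }
  list(quant = ids[[main]], drop = setdiff(drop, ids[[main]]))
}

## Quantify tentative hits: calibration curves simulated from the matching
## compound specs (panel compounds double as authentic standards), semi-
## quantitation in 2-octanol equivalents for the rest.
quantify_hits <- function(hits, ft, config) {
  recipe <- config$recipe
  specs <- recipe$compounds
  spec_names <- vapply(specs, `[[`, character(1), "name")
  is_spec <- recipe$internal_standards[[
    which(tolower(vapply(recipe$internal_standards, `[[`, character(1), "name")) ==
            tolower(config$is_name))]]
  is_feat <- find_is_features(ft, recipe, config$is_name)$quant
  is_area <- ft$intensity[is_feat, ]
  tent <- hits[hits$status == "tentative", , drop = FALSE]
  conc_rows <- list(); anovas <- list(); curves <- list()
  for (r in seq_len(nrow(tent))) {
    cmp <- tent$compound[r]
    si <- match(cmp, spec_names)
    if (is.na(si)) next   # identified as decoy/IS name: no quantitation
    sp <- specs[[si]]
    ## quantifier feature: the member feature on the compound's base peak,
    ## falling back to the strongest member
    members <- tent$member_features[[r]]
    mf <- ft$features[ft$features$feature_id %in% members, , drop = FALSE]
    bp <- sp$spectrum[which.max(sp$spectrum[, "intensity"]), "mz"]
    qf <- if (bp %in% mf$mz) mf$feature_id[mf$mz == bp][1]
    else members[which.max(rowMeans(ft$intensity[members, , drop = FALSE]))]
    ratio <- response_ratio(ft$intensity[qf, ], is_area)
    cal <- fit_calibration(simulate_calibration(sp, is_spec, noise_cv = 0.02,
                                                seed = config$seed + si),
                           compound = cmp, is_name = config$is_name,
                           min_r2 = config$min_r2)
    curves[[cmp]] <- cal
    if (cal$usable) {
      pred <- predict_concentration(cal, ratio)
      conc <- pred$conc; flag <- pred$flag; mode <- "quantified"
    } else {
      conc <- semi_quantify(ratio, is_spec$base_conc)
      flag <- ""; mode <- "semi"
    }
    oav <- compute_oav(conc, sp$odor_threshold)
    conc_rows[[cmp]] <- data.frame(compound = cmp, sample_id = names(ratio),
                                   conc = unname(conc), mode = mode,
                                   flag = flag, oav = unname(oav),
                                   row.names = NULL)
    anovas[[cmp]] <- compound_anova(
      data.frame(sample_id = names(ratio), conc = unname(conc)),
      ft$metadata, posthoc = config$posthoc)
  }
  if (!length(conc_rows)) return(NULL)
  list(conc = do.call(rbind, c(conc_rows, list(make.row.names = FALSE))),
       anovas = anovas, curves = curves)
}
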