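#' Write runs to mzML files
#'
#' One centroided MS1 mzML file per run (32-bit encoding, uncompressed),
#' retention times stored in seconds per the standard. Zero-intensity channels
#' are dropped from each scan (centroid representation).
#'
#' @param runs List of `gc_run` objects.
#' @param dir Output directory (created if needed).
#' @return Manifest data frame (`run_id`, `path` plus the run metadata); empty
#'   (zero-row) for an empty run list.
#' @export
write_runs <- function(runs, dir) {
  if (!length(runs))
    return(data.frame(run_id = character(0), path = character(0)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(runs, function(run) {
    meta <- as.data.frame(run$meta)
    path <- file.path(dir, paste0(meta$run_id, ".mzML"))
    n <- length(run$times)
    pks <- lapply(seq_len(n), function(i) {
      keep <- run$mat[, i] > 0
      cbind(mz = as.numeric(run$mz[keep]), intensity = as.numeric(run$mat[keep, i]))
    })
    hdr <- mzml_header(pks, min_to_sec(run$times), range(run$mz))
    mzR::writeMSData(object = pks, file = path, header = hdr, outformat = "mzml")
    cbind(meta[, "run_id", drop = FALSE], path = path,
          meta[, setdiff(names(meta), "run_id"), drop = FALSE])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## MS1-centroid mzML header table in the layout mzR::writeMSData expects.
mzml_header <- function(pks, rt_sec, mz_range) {
  n <- length(pks)
  tic <- vapply(pks, function(p) sum(p[, 2]), numeric(1))
  bpi <- vapply(pks, function(p) if (nrow(p)) which.max(p[, 2]) else NA_integer_, integer(1))
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 0L, peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = tic, retentionTime = rt_sec,
    basePeakMZ = vapply(seq_len(n), function(i) if (is.na(bpi[i])) 0 else pks[[i]][bpi[i], 1], numeric(1)),
    basePeakIntensity = vapply(seq_len(n), function(i) if (is.na(bpi[i])) 0 else pks[[i]][bpi[i], 2], numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 70,
    lowMZ = mz_range[1], highMZ = mz_range[2],
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = mz_range[1], scanWindowUpperLimit = mz_range[2])
}

#' Read mzML files into runs
#'
#' Reads centroided MS1 mzML and rasters each file onto its integer
#' nominal-m/z grid (m/z values are rounded; intensities at one nominal mass
#' are summed). Scan times must be strictly increasing.
#'
#' @param paths mzML file paths.
#' @param meta Optional data frame of run metadata, one row per path (must
#'   contain `run_id`); row order matches `paths`.
#' @return List of `gc_run` objects (named by `run_id` when metadata given).
#' @export
read_runs <- function(paths, meta = NULL) {
  runs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    parsed <- tryCatch({
      f <- mzR::openMSfile(p)
      h <- mzR::header(f)
      pk <- mzR::peaks(f)
      mzR::close(f)
      list(h = h, pk = if (is.matrix(pk)) list(pk) else pk)
    }, error = function(e) stopf("failed to parse mzML file '%s': %s", p, conditionMessage(e)))
    rt <- sec_to_min(parsed$h$retentionTime)
    bad <- which(diff(rt) <= 0)
    if (length(bad))
      stopf("non-monotone scan times in '%s' at scan %d", p, bad[1] + 1L)
    pk <- parsed$pk
    mz_all <- unlist(lapply(pk, function(m) round(m[, 1])))
    grid <- if (length(mz_all)) seq(min(mz_all), max(mz_all)) else integer(0)
    mat <- matrix(0, nrow = length(grid), ncol = length(rt))
    for (s in seq_along(pk)) {
      m <- pk[[s]]
      if (!nrow(m)) next
      idx <- round(m[, 1]) - grid[1] + 1L
      mat[, s] <- mat[, s] + as.numeric(tapply(m[, 2], factor(idx, levels = seq_along(grid)), sum, default = 0))
    }
    mrow <- if (!is.null(meta)) meta[i, , drop = FALSE] else
      data.frame(run_id = sub("\\.mzML$", "", basename(p)))
    runs[[i]] <- new_run(mrow, rt, grid, mat)
  }
  names(runs) <- vapply(runs, function(r) as.character(r$meta$run_id), character(1))
  runs
}
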