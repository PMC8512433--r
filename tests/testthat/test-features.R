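test_that("extracted ion chromatograms conserve the total ion current", {
  run <- make_run(data.frame(mz = c(43, 71, 55), rt = c(1.2, 1.2, 3.8),
                             height = c(100, 50, 800), sigma_s = 2.5),
                  floor = 2)
  eic <- extract_eics(run)
  expect_equal(dim(eic$mat), c(length(eic$mz), length(eic$times)))
  expect_equal(colSums(eic$mat), colSums(run$mat))   # per-scan TIC both ways
  ## single scan membership
  i <- which.min(abs(eic$times - 1.2))
  expect_gt(eic$mat[match(43, eic$mz), i], eic$mat[match(44, eic$mz), i])
})

test_that("a clean Gaussian peak is found at its apex with the right width gate", {
  run <- make_run(data.frame(mz = 71, rt = 3, height = 1000, sigma_s = 2.5),
                  floor = 1)
  pk <- detect_peaks(run)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$rt - 3), 1 / 240 + 1e-9)          # within one scan
  expect_gt(pk$sn, 6)
  ## half-height width 2 s (< 5 s minimum) must be rejected
  narrow <- make_run(data.frame(mz = 71, rt = 3, height = 1000,
                                sigma_s = 2 / 2.355), floor = 1)
  expect_equal(nrow(detect_peaks(narrow)), 0)
  ## too-wide peaks are rejected as well
  wide <- make_run(data.frame(mz = 71, rt = 3, height = 1000,
                              sigma_s = 25 / 2.355), floor = 1)
  expect_equal(nrow(detect_peaks(wide)), 0)
})

test_that("pure Poisson noise yields no peaks at S/N 6 in nearly all seeds", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    times <- seq(0, 6, by = 1 / 240)
    mat <- matrix(rpois(3 * length(times), 5), nrow = 3)
    run <- vinomix:::new_run(data.frame(sample_id = "s", run_id = "r"),
                             times, 55:57, mat)
    nrow(detect_peaks(run))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("a run shorter than one peak width yields an empty peak list", {
  run <- make_run(data.frame(mz = 71, rt = 0.02, height = 1000, sigma_s = 1),
                  rt_range = c(0, 0.05))
  expect_equal(nrow(detect_peaks(run)), 0)
})

test_that("peak areas track planted peak heights linearly", {
  heights <- c(500, 1000, 2000, 4000)
  areas <- vapply(heights, function(h) {
    run <- make_run(data.frame(mz = 71, rt = 3, height = h, sigma_s = 2.5), floor = 1)
    detect_peaks(run)$area[1]
  }, numeric(1))
  expect_gt(cor(areas, heights), 0.9999)
  ## absolute scale: area of a Gaussian = height * sigma * sqrt(2*pi) seconds
  expect_equal(areas[2], 1000 * 2.5 * sqrt(2 * pi), tolerance = 0.05)
})

make_shifted_peakset <- function(shifts, n_anchor = 12) {
  ## identical anchor peaks in every run, shifted per run
  rts <- seq(1, 10, length.out = n_anchor)
  do.call(rbind, lapply(seq_along(shifts), function(i) {
    data.frame(sample_id = sprintf("s%d", i), run_id = sprintf("r%d", i),
               mz = rep(60 + seq_len(n_anchor), 1),
               rt = rts + shifts[[i]](rts),
               rt_lo = rts + shifts[[i]](rts) - 0.05,
               rt_hi = rts + shifts[[i]](rts) + 0.05,
               area = 1000, height = 500, sn = 50)
  }))
}

test_that("retention-time correction is near-identity on aligned data", {
  pk <- make_shifted_peakset(list(function(t) 0, function(t) 0, function(t) 0))
  rtc <- correct_rt(pk)
  expect_lt(max(abs(rtc$peaks$rt - pk$rt)), 1 / 240)
})

test_that("a constant shift is recovered within 10%", {
  pk <- make_shifted_peakset(list(function(t) 0, function(t) 0, function(t) 0.1))
  rtc <- correct_rt(pk)
  s3 <- rtc$peaks$run_id == "r3"
  correction <- pk$rt[s3] - rtc$peaks$rt[s3]
  ## the consensus median splits the shift; the shifted run must move back
  ## towards it by most of its deviation from the reference
  dev_before <- median(abs(pk$rt[s3] - ave(pk$rt, pk$mz, FUN = median)[s3]))
  dev_after <- median(abs(rtc$peaks$rt[s3] - ave(rtc$peaks$rt, rtc$peaks$mz, FUN = median)[s3]))
  expect_lt(dev_after, 0.1 * dev_before + 1e-6)
  expect_gt(median(correction), 0)
})

test_that("linear drift shrinks anchor spread and warps stay monotone", {
  pk <- make_shifted_peakset(list(function(t) 0, function(t) 0.005 * t,
                                  function(t) -0.005 * t, function(t) 0))
  rtc <- correct_rt(pk)
  sd_before <- mean(tapply(pk$rt, pk$mz, sd))
  sd_after <- mean(tapply(rtc$peaks$rt, rtc$peaks$mz, sd))
  expect_lt(sd_after, sd_before)
  expect_true(all(rtc$diagnostics$mad_after <= rtc$diagnostics$mad_before + 1e-9))
  grid <- seq(0.5, 11, by = 0.01)
  for (w in rtc$warps) expect_true(all(diff(w(grid)) > 0))
})

test_that("too few anchors falls back to identity with a warning", {
  pk <- make_shifted_peakset(list(function(t) 0, function(t) 0.05), n_anchor = 2)
  pk <- pk[pk$run_id == "r1" | pk$mz == 61, ]   # only one shared group
  expect_warning(rtc <- correct_rt(pk), "identity warp")
  expect_equal(rtc$peaks$rt, pk$rt)
})

grouping_metadata <- function(pk) {
  md <- unique(pk[, c("sample_id", "run_id")])
  md$rootstock <- rep(c("Own", "1103P"), length.out = nrow(md))
  md$irrigation <- "Full"
  md
}

test_that("co-eluting peaks across samples collapse into one feature", {
  pk <- do.call(rbind, lapply(1:4, function(i)
    data.frame(sample_id = sprintf("s%d", i), run_id = sprintf("r%d", i),
               mz = 71, rt = 3 + i * 0.003, rt_lo = 2.9, rt_hi = 3.1,
               area = 1000 + i, height = 500, sn = 50)))
  ft <- group_peaks(pk, metadata = grouping_metadata(pk))
  expect_equal(nrow(ft$features), 1)
  expect_equal(sum(!is.na(ft$intensity)), 4)
  expect_match(ft$features$feature_id, "^M71T3\\.0")
})

test_that("the minfrac boundary is inclusive", {
  ## peak in 1 of 4 runs; that run's class has 2 members: fraction 1/2 >= 0.5
  pk <- data.frame(sample_id = "s1", run_id = "r1", mz = 71, rt = 3,
                   rt_lo = 2.9, rt_hi = 3.1, area = 1000, height = 500, sn = 50)
  md <- data.frame(sample_id = sprintf("s%d", 1:4), run_id = sprintf("r%d", 1:4),
                   rootstock = c("Own", "Own", "1103P", "1103P"),
                   irrigation = "Full")
  ft <- group_peaks(pk, grouping_params(minsamp = 2), md)  # minsamp cannot keep it
  expect_equal(nrow(ft$features), 1)                        # 1/2 = minfrac keeps it
  expect_error(group_peaks(pk, grouping_params(minfrac = 0.6, minsamp = 2), md),
               "no feature groups")
})

test_that("two compounds 30 s apart on one channel become two features", {
  pk <- do.call(rbind, lapply(1:4, function(i) {
    rbind(data.frame(sample_id = sprintf("s%d", i), run_id = sprintf("r%d", i),
                     mz = 71, rt = 3 + i * 0.002, rt_lo = 2.9, rt_hi = 3.1,
                     area = 1000, height = 500, sn = 50),
          data.frame(sample_id = sprintf("s%d", i), run_id = sprintf("r%d", i),
                     mz = 71, rt = 3.5 + i * 0.002, rt_lo = 3.4, rt_hi = 3.6,
                     area = 2000, height = 900, sn = 80))
  }))
  ft <- group_peaks(pk, metadata = grouping_metadata(pk))
  expect_equal(nrow(ft$features), 2)
})

test_that("duplicate peaks from one run keep the larger area", {
  pk <- rbind(
    data.frame(sample_id = "s1", run_id = "r1", mz = 71, rt = 3.00,
               rt_lo = 2.9, rt_hi = 3.1, area = 500, height = 300, sn = 20),
    data.frame(sample_id = "s1", run_id = "r1", mz = 71, rt = 3.01,
               rt_lo = 2.9, rt_hi = 3.1, area = 900, height = 500, sn = 30),
    data.frame(sample_id = "s2", run_id = "r2", mz = 71, rt = 3.00,
               rt_lo = 2.9, rt_hi = 3.1, area = 700, height = 350, sn = 25))
  md <- data.frame(sample_id = c("s1", "s2"), run_id = c("r1", "r2"),
                   rootstock = c("Own", "1103P"), irrigation = "Full")
  ft <- group_peaks(pk, metadata = md)
  expect_equal(unname(ft$intensity[1, "r1"]), 900)
})

test_that("filling recovers missed real signal and floors empty windows", {
  run1 <- make_run(data.frame(mz = 71, rt = 3, height = 1000, sigma_s = 2.5),
                   run_id = "r1", sample_id = "s1")
  run2 <- make_run(data.frame(mz = 71, rt = 3, height = 600, sigma_s = 2.5),
                   run_id = "r2", sample_id = "s2")
  run3 <- make_run(data.frame(mz = 99, rt = 5, height = 600, sigma_s = 2.5),
                   run_id = "r3", sample_id = "s3")  # no signal at 71
  pk <- rbind(detect_peaks(run1), detect_peaks(run3))  # r2's peak "missed"
  md <- data.frame(sample_id = c("s1", "s2", "s3"), run_id = c("r1", "r2", "r3"),
                   rootstock = c("Own", "Own", "1103P"), irrigation = "Full")
  ft <- group_peaks(pk, grouping_params(minfrac = 0.3), md)
  detected_before <- ft$intensity
  ft2 <- fill_missing(ft, list(r1 = run1, r2 = run2, r3 = run3))
  expect_false(anyNA(ft2$intensity))
  ## detected intensities never modified
  expect_equal(ft2$intensity[!is.na(detected_before)],
               detected_before[!is.na(detected_before)])
  f71 <- which(ft2$features$mz == 71)
  truth_area <- 600 * 2.5 * sqrt(2 * pi)
  expect_lt(abs(ft2$intensity[f71, "r2"] - truth_area) / truth_area, 0.3)
  ## no signal at all: positive floor
  f99 <- which(ft2$features$mz == 99)
  expect_gt(ft2$intensity[f99, "r1"], 0)
  expect_lt(ft2$intensity[f99, "r1"], ft2$intensity[f99, "r3"] / 10)
})

test_that("technical replicates average to the arithmetic mean", {
  md <- data.frame(sample_id = rep(c("a", "b"), each = 2),
                   run_id = c("a1", "a2", "b1", "b2"),
                   rootstock = rep(c("Own", "1103P"), each = 2),
                   irrigation = "Full", injection = rep(1:2, 2))
  ft <- structure(list(
    features = data.frame(feature_id = "M71T3.00", mz = 71, rtmed = 3,
                          rt_lo_med = 2.9, rt_hi_med = 3.1, npeaks = 4),
    intensity = matrix(c(100, 120, 80, 90), 1, dimnames = list("M71T3.00", md$run_id)),
    detected = matrix(c(TRUE, TRUE, TRUE, FALSE), 1,
                      dimnames = list("M71T3.00", md$run_id)),
    metadata = md, class_cols = c("rootstock", "irrigation")),
    class = "feature_table")
  avg <- average_technical_replicates(ft)
  expect_equal(unname(avg$intensity[1, ]), c(110, 85))
  expect_equal(colnames(avg$intensity), c("a", "b"))
  ## detection at sample level: any injection
  expect_equal(unname(avg$detected[1, ]), c(TRUE, TRUE))
  ## single-injection tables pass through unchanged
  ft1 <- ft
  ft1$metadata <- md[c(1, 3), ]
  ft1$intensity <- ft$intensity[, c(1, 3), drop = FALSE]
  ft1$detected <- ft$detected[, c(1, 3), drop = FALSE]
  avg1 <- average_technical_replicates(ft1)
  expect_equal(unname(avg1$intensity[1, ]), c(100, 80))
})

test_that("feature count is monotone non-increasing in the S/N threshold", {
  rec <- small_recipe(seed = 11, n_compounds = 6, injections = 1, vines = 1)
  runs <- simulate_study(rec)$runs
  counts <- vapply(c(3, 6, 20, 100), function(sn) {
    pk <- do.call(rbind, lapply(runs, detect_peaks,
                                params = detection_params(snthresh = sn)))
    nrow(pk)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
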