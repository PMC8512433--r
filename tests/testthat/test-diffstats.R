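stats_metadata <- function(n = 24) {
  data.frame(sample_id = sprintf("s%02d", 1:n),
             rootstock = rep(c("Own", "1103P", "3309C", "SO4"), each = n / 4),
             irrigation = rep(rep(c("Full", "RDI", "None"), each = n / 12), 4))
}

test_that("internal-standard normalisation cancels global response drift", {
  md <- data.frame(sample_id = sprintf("s%02d", 1:4),
                   rootstock = c("Own", "Own", "SO4", "SO4"))
  v <- matrix(exp(rnorm(4 * 6)), 4, 6,
              dimnames = list(NULL, c(paste0("F", 1:5), "IS")))
  v2 <- v
  v2[2, ] <- v2[2, ] * 2    # sample 2 measured at doubled response
  fm <- feature_matrix(v, md)
  fm2 <- feature_matrix(v2, md)
  expect_equal(preprocess(fm, "IS")$values, preprocess(fm2, "IS")$values)
})

test_that("autoscaled features have mean 0 and variance 1, and re-preprocessing errors", {
  md <- stats_metadata(12)
  v <- matrix(exp(rnorm(12 * 8)), 12, 8,
              dimnames = list(NULL, c(paste0("F", 1:7), "IS")))
  fm <- preprocess(feature_matrix(v, md), "IS")
  expect_equal(unname(colMeans(fm$values)), rep(0, 7), tolerance = 1e-8)
  expect_equal(unname(apply(fm$values, 2, var)), rep(1, 7), tolerance = 1e-8)
  expect_equal(fm$state, "autoscaled")
  expect_error(preprocess(fm, "F1"), "already autoscaled")
  ## missing IS names the sample
  v_bad <- v; v_bad[3, "IS"] <- 0
  expect_error(preprocess(feature_matrix(v_bad, md), "IS"), "s03")
})

test_that("per-feature ANOVA matches aov and handles degenerate features", {
  md <- stats_metadata(24)
  set.seed(1)
  v <- matrix(rnorm(24 * 10), 24, 10, dimnames = list(NULL, paste0("F", 1:10)))
  v[, 3] <- v[, 3] + 5 * (md$rootstock == "Own")
  fm <- feature_matrix(scale(v), md, state = "autoscaled")
  res <- anova_per_feature(fm, "rootstock")
  for (j in c(1, 3, 7)) {
    ref <- summary(stats::aov(fm$values[, j] ~ factor(md$rootstock)))[[1]]
    expect_equal(res$F[j], ref[1, "F value"], tolerance = 1e-10)
    expect_equal(res$p[j], ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
  expect_lt(res$p[3], 0.001)
  ## identical groups: F = 0, p = 1
  md2 <- data.frame(sample_id = sprintf("t%d", 1:4),
                    rootstock = c("Own", "Own", "SO4", "SO4"))
  fm2 <- feature_matrix(matrix(c(1, 2, 1, 2), 4, 1,
                               dimnames = list(NULL, "F1")), md2)
  res2 <- anova_per_feature(fm2, "rootstock")
  expect_equal(res2$F, 0)
  expect_equal(res2$p, 1)
  ## textbook separation: means 0 vs 10, sd ~ 1
  md3 <- data.frame(sample_id = sprintf("u%d", 1:6),
                    rootstock = rep(c("Own", "SO4"), each = 3))
  y <- c(-1, 0, 1, 9, 10, 11)
  res3 <- anova_per_feature(feature_matrix(matrix(y, 6, 1, dimnames = list(NULL, "F1")), md3),
                            "rootstock")
  expect_lt(res3$p, 0.001)
})

test_that("significant-feature count grows with planted effect size", {
  md <- stats_metadata(24)
  counts <- vapply(c(0, 1, 2.5), function(d) {
    set.seed(7)
    v <- matrix(rnorm(24 * 40), 24, 40, dimnames = list(NULL, paste0("F", 1:40)))
    v[, 1:8] <- v[, 1:8] + d * (md$rootstock == "Own")
    res <- anova_per_feature(feature_matrix(scale(v), md, state = "autoscaled"),
                             "rootstock")
    sum(res$q < 0.05)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})

test_that("BH adjustment reproduces hand-computed and p.adjust values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  set.seed(3)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  ## order preservation
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("PCA matches an eigen-decomposition oracle", {
  set.seed(21)
  md <- data.frame(sample_id = sprintf("s%d", 1:10))
  X <- scale(matrix(rnorm(10 * 50), 10, 50, dimnames = list(NULL, paste0("F", 1:50))))
  fm <- feature_matrix(X, md, state = "autoscaled")
  mod <- pca_fit(fm, 5)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  var_oracle <- ev$values / sum(ev$values)
  expect_equal(mod$var_fraction, var_oracle[1:5], tolerance = 1e-8)
  for (j in 1:3)
    expect_equal(unname(abs(mod$scores[, j])),
                 unname(abs(X %*% ev$vectors[, j])[, 1]), tolerance = 1e-8)
  ## scores Gram matrix diagonal
  g <- crossprod(mod$scores)
  expect_equal(g - diag(diag(g)), matrix(0, 5, 5), ignore_attr = TRUE, tolerance = 1e-8)
  ## one varying feature -> PC1 explains everything
  X1 <- matrix(0, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  X1[, 2] <- scale(rnorm(10))
  expect_equal(pca_fit(feature_matrix(X1, md, state = "autoscaled"), 1)$var_fraction, 1)
  expect_error(pca_fit(fm, 10), "rank bound")
})

test_that("PLS-DA separates well-separated classes and not noise", {
  set.seed(5)
  md <- data.frame(sample_id = sprintf("s%d", 1:20),
                   grp = rep(c("A", "B"), each = 10))
  X <- matrix(rnorm(20 * 30), 20, 30, dimnames = list(NULL, paste0("F", 1:30)))
  X[md$grp == "B", 1:10] <- X[md$grp == "B", 1:10] + 6
  fm <- feature_matrix(scale(X), md, state = "autoscaled")
  m <- plsda_fit(fm, md$grp)
  expect_gt(m$Q2, 0.8)
  expect_lte(m$Q2, m$R2Y + 1e-9)
  ## null labels: Q2 <= 0 in most seeds
  mdn <- data.frame(sample_id = sprintf("n%d", 1:24),
                    grp = rep(c("A", "B"), each = 12))
  nulls <- vapply(1:40, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(24 * 60), 24, 60, dimnames = list(NULL, paste0("F", 1:60)))
    fmn <- feature_matrix(scale(Xn), mdn, state = "autoscaled")
    plsda_fit(fmn, sample(mdn$grp))$Q2
  }, numeric(1))
  expect_gte(mean(nulls <= 0), 0.8)
})

test_that("VIP satisfies its mean-square identity on arbitrary fits", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(c(12, 18, 24), 1); p <- sample(c(8, 40, 100), 1)
    md <- data.frame(sample_id = sprintf("s%d", 1:n),
                     grp = sample(rep(c("A", "B", "C"), length.out = n)))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("F", 1:p)))
    m <- plsda_fit(feature_matrix(scale(X), md, state = "autoscaled"), md$grp)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-6)
    expect_equal(sum(m$vip^2), p, tolerance = 1e-6 * p)
  }
})

test_that("PLS-DA cross-checks against an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(31)
  md <- data.frame(sample_id = sprintf("s%d", 1:24),
                   grp = rep(c("A", "B", "C"), each = 8))
  X <- matrix(rnorm(24 * 15), 24, 15, dimnames = list(md$sample_id, paste0("F", 1:15)))
  X[md$grp == "B", 1:5] <- X[md$grp == "B", 1:5] + 1.5
  Xs <- scale(X)
  m <- plsda_fit(feature_matrix(Xs, md, state = "autoscaled"), md$grp)
  ref <- mixOmics::plsda(Xs, factor(md$grp), ncomp = 2, scale = FALSE)
  ## component scores agree up to sign
  for (j in 1:2)
    expect_gt(abs(cor(m$scores[, j], ref$variates$X[, j])), 0.999)
  vip_ref <- mixOmics::vip(ref)[, 2]
  expect_gt(cor(m$vip, vip_ref), 0.99)
})

test_that("permutation p-values honour their bounds and nullity", {
  set.seed(13)
  md <- data.frame(sample_id = sprintf("s%d", 1:16),
                   grp = rep(c("A", "B"), each = 8))
  X <- matrix(rnorm(16 * 10), 16, 10, dimnames = list(NULL, paste0("F", 1:10)))
  X[md$grp == "B", ] <- X[md$grp == "B", ] + 5
  fm <- feature_matrix(scale(X), md, state = "autoscaled")
  pt <- permutation_test(fm, md$grp, B = 49)
  expect_equal(pt$perm_p, 1 / 50)                # nothing beats real labels
  expect_gte(pt$perm_p, 1 / (49 + 1))
  expect_lte(pt$perm_p, 1)
  expect_error(permutation_test(fm, md$grp, B = 10), "uninformative")
})

test_that("variance partition recovers the generating term", {
  md <- stats_metadata(24)
  ## scores equal to a numeric coding of rootstock -> all variance to rootstock
  sc <- matrix(as.numeric(factor(md$rootstock)), 24, 1,
               dimnames = list(md$sample_id, "PC1"))
  pca <- structure(list(scores = sc, samples = md), class = "pca_model")
  vp <- suppressWarnings(variance_partition(pca))  # perfect fit: F unreliable
  expect_equal(vp$frac_variance[vp$term == "rootstock"], 1, tolerance = 1e-12)
  expect_equal(vp$frac_variance[vp$term != "rootstock"], c(0, 0), tolerance = 1e-12)
  ## balanced decomposition sums to 1 with the residual
  set.seed(2)
  sc2 <- matrix(rnorm(24), 24, 1, dimnames = list(md$sample_id, "PC1"))
  pca2 <- structure(list(scores = sc2, samples = md), class = "pca_model")
  vp2 <- variance_partition(pca2)
  resid_frac <- 1 - sum(vp2$frac_variance)
  expect_gte(resid_frac, 0)
  a <- stats::anova(stats::lm(sc2[, 1] ~ factor(md$rootstock) * factor(md$irrigation)))
  expect_equal(resid_frac, a["Residuals", "Sum Sq"] / sum(a$`Sum Sq`), tolerance = 1e-9)
  ## planted irrigation effect lands on the matching PC
  sc3 <- cbind(PC1 = rnorm(24, sd = 0.1),
               PC2 = 2 * as.numeric(factor(md$irrigation)) + rnorm(24, sd = 0.1))
  rownames(sc3) <- md$sample_id
  pca3 <- structure(list(scores = sc3, samples = md), class = "pca_model")
  vp3 <- variance_partition(pca3)
  irr2 <- vp3[vp3$pc == 2 & vp3$term == "irrigation", ]
  expect_lt(irr2$p, 0.01)
  expect_gt(irr2$frac_variance, 0.5)
})

test_that("overlap counts cover shared and exclusive regions", {
  oc <- overlap_counts(list(y2017 = c("a", "b", "c"), y2018 = c("b", "c", "d")))
  expect_equal(oc$count[oc$region == "common_all"], 2)
  expect_equal(oc$count[oc$region == "y2017"], 1)
  expect_equal(oc$count[oc$region == "y2018"], 1)
  oc2 <- overlap_counts(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(oc2$count[oc2$region == "common_all"], 2)
  oc3 <- overlap_counts(list(a = "x", b = "y"))
  expect_equal(oc3$count[oc3$region == "common_all"], 0)
})

test_that("top-k tables rank by p with deterministic tie-breaks", {
  md <- stats_metadata(24)
  set.seed(4)
  v <- matrix(rnorm(24 * 6), 24, 6, dimnames = list(NULL, paste0("F", 1:6)))
  v[, 5] <- v[, 5] + 4 * (md$rootstock == "Own")
  fm <- feature_matrix(scale(v), md, state = "autoscaled")
  res <- anova_per_feature(fm, "rootstock")
  t1 <- top_k_table(fm, res, k = 1)
  expect_equal(rownames(t1), "F5")
  expect_equal(dim(t1), c(1, 4))
  tall <- top_k_table(fm, res, k = 100)
  expect_equal(nrow(tall), 6)
  expect_equal(ncol(tall), length(unique(md$rootstock)))
})
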