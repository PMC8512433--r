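#' Construct a sample-by-feature matrix for statistics
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param samples Sample metadata data frame (one row per matrix row; must
#'   contain `sample_id` and the treatment factors).
#' @param state Processing state of the values.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, samples,
                           state = c("raw", "is_normalized", "log", "autoscaled")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(samples), !anyNA(values))
  rownames(values) <- samples$sample_id
  structure(list(values = values, samples = samples, state = state),
            class = "feature_matrix")
}

#' Convert an averaged feature table to a feature matrix
#' @param ft A `feature_table` after [average_technical_replicates()].
#' @return A raw-state [feature_matrix()].
#' @export
as_feature_matrix <- function(ft) {
  feature_matrix(t(ft$intensity), ft$metadata, state = "raw")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features, state=%s>\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Normalise, log-transform and autoscale a feature matrix
#'
#' Three steps in the standard order: (1) each sample's intensities are
#' divided by that sample's internal-standard response, cancelling per-run
#' instrument-response drift; (2) `log(x + 1)`; (3) per-feature autoscaling
#' (unit variance after centring). Internal-standard features and features
#' with zero variance are dropped before scaling.
#'
#' @param fm A raw-state [feature_matrix()].
#' @param is_feature Feature id (column name) of the internal-standard
#'   quantifier feature.
#' @param drop_features Further feature ids to drop after normalisation
#'   (e.g. the other internal standards' features).
#' @return An autoscaled [feature_matrix()].
#' @export
preprocess <- function(fm, is_feature, drop_features = character(0)) {
  if (fm$state == "autoscaled") stopf("matrix is already autoscaled")
  if (!is_feature %in% colnames(fm$values))
    stopf("internal-standard feature '%s' not in matrix", is_feature)
  is_resp <- fm$values[, is_feature]
  bad <- which(!is.finite(is_resp) | is_resp <= 0)
  if (length(bad))
    stopf("internal standard missing in sample '%s'", rownames(fm$values)[bad[1]])
  v <- sweep(fm$values, 1, is_resp, "/")
  v <- v[, setdiff(colnames(v), c(is_feature, drop_features)), drop = FALSE]
  v <- log(v + 1)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("dropping %d zero-variance feature(s) before autoscaling", sum(sds == 0)))
    v <- v[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  v <- scale(v, center = TRUE, scale = TRUE)
  attr(v, "scaled:center") <- NULL; attr(v, "scaled:scale") <- NULL
  feature_matrix(v, fm$samples, state = "autoscaled")
}

#' Per-feature one-way ANOVA for a design factor
#'
#' Fixed-effects one-way ANOVA of every feature against one factor, vectorised
#' over features; p-values from the F distribution, q-values by
#' Benjamini-Hochberg within this factor's family.
#'
#' @param fm A [feature_matrix()].
#' @param factor_name Metadata column (`"rootstock"` or `"irrigation"`).
#' @return Data frame: `feature_id`, `factor`, `F`, `p`, `q`, ordered as the
#'   matrix columns.
#' @export
anova_per_feature <- function(fm, factor_name) {
  g <- factor(fm$samples[[factor_name]])
  if (nlevels(g) < 2 || min(table(g)) < 2)
    stopf("factor '%s' needs >= 2 levels with >= 2 samples each", factor_name)
  X <- fm$values
  n <- nrow(X); k <- nlevels(g)
  gm <- rowsum(X, g) / as.vector(table(g))          # level x feature means
  grand <- colMeans(X)
  ssb <- colSums(as.vector(table(g)) * (gm - rep(grand, each = k))^2)
  sst <- colSums((X - rep(grand, each = n))^2)
  ssw <- pmax(sst - ssb, 0)
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fv, k - 1, n - k, lower.tail = FALSE)
  degen <- ssw < .Machine$double.eps & ssb < .Machine$double.eps
  Fv[degen] <- 0; p[degen] <- 1
  p[ssw < .Machine$double.eps & !degen] <- 0
  data.frame(feature_id = colnames(X), factor = factor_name, F = Fv, p = p,
             q = bh_fdr(p), row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' `q_i = min over ranks j >= rank(i) of p_(j) * n / j`, capped at 1;
#' order-preserving in p.
#'
#' @param p P-values in `[0, 1]`.
#' @return Q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Overlap accounting between significant-feature sets
#'
#' Venn-style counts for two or three sets of feature ids.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Data frame `region`, `count` covering each exclusive region and
#'   the common intersection.
#' @export
overlap_counts <- function(sets) {
  stopifnot(length(sets) %in% 2:3)
  sets <- lapply(sets, unique)
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  all_ids <- unique(unlist(sets))
  member <- sapply(sets, function(s) all_ids %in% s)
  if (!is.matrix(member)) member <- matrix(member, nrow = length(all_ids))
  key <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  counts <- table(key)
  out <- data.frame(region = names(counts), count = as.integer(counts),
                    row.names = NULL)
  common <- sum(rowSums(member) == length(sets))
  rbind(out, data.frame(region = "common_all", count = common))
}

#' Per-treatment-level means of the most significant features
#'
#' Features ranked by ascending p (ties by feature id); the heat-map-style
#' table of per-level mean autoscaled values for the top `k`.
#'
#' @param fm An autoscaled [feature_matrix()].
#' @param results [anova_per_feature()] output for one factor.
#' @param k Number of features (all if `k` exceeds the feature count).
#' @return Matrix, one row per selected feature, one column per factor level.
#' @export
top_k_table <- function(fm, results, k = 25) {
  factor_name <- results$factor[1]
  o <- order(results$p, results$feature_id)
  top <- results$feature_id[o][seq_len(min(k, nrow(results)))]
  g <- factor(fm$samples[[factor_name]])
  m <- rowsum(fm$values[, top, drop = FALSE], g) / as.vector(table(g))
  t(m)
}
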