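#' Principal component analysis by singular value decomposition
#'
#' @param fm An autoscaled [feature_matrix()] (typically restricted to
#'   significant features).
#' @param k Number of components; at most `min(n_samples - 1, n_features)`.
#' @return Object of class `pca_model`: `scores` (samples x k), `loadings`
#'   (features x k), `var_fraction` (share of total variance per component,
#'   denominated over all components). Sign convention: the largest-magnitude
#'   loading of each component is positive.
#' @export
pca_fit <- function(fm, k = 2) {
  X <- fm$values
  kmax <- min(nrow(X) - 1, ncol(X))
  if (k > kmax) stopf("k = %d exceeds the rank bound %d", k, kmax)
  X <- sweep(X, 2, colMeans(X))   # no-op on autoscaled input
  sv <- svd(X)
  var_fraction <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  for (j in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) { loadings[, j] <- -loadings[, j]; scores[, j] <- -scores[, j] }
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_along(sv$d)))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(sv$d)))
  structure(list(scores = scores[, seq_len(k), drop = FALSE],
                 loadings = loadings[, seq_len(k), drop = FALSE],
                 var_fraction = var_fraction[seq_len(k)],
                 samples = fm$samples),
            class = "pca_model")
}

## NIPALS PLS2 core. X, Y centred. Returns weights W (normalised), scores T,
## X-loadings P, Y-loadings Q, and per-component explained Y sum of squares.
pls_nipals <- function(X, Y, ncomp, tol = 1e-10, maxit = 200) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); TT <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  Xa <- X; Ya <- Y
  used <- 0L
  for (a in seq_len(ncomp)) {
    if (sum(Ya^2) < 1e-12 * max(sum(Y^2), 1)) break  # Y exhausted
    u <- Ya[, which.max(colSums(Ya^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(Xa, u)
      wn <- sqrt(sum(w^2))
      if (!is.finite(wn) || wn < 1e-14) break
      w <- w / wn
      tt <- Xa %*% w
      q <- crossprod(Ya, tt) / sum(tt^2)
      u <- Ya %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    if (!is.finite(sum(w)) || sum(w^2) < 0.5) break
    pp <- crossprod(Xa, tt) / sum(tt^2)
    ssy[a] <- sum((tt %*% t(q))^2)
    Xa <- Xa - tt %*% t(pp)
    Ya <- Ya - tt %*% t(q)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; TT[, a] <- tt
    used <- a
  }
  if (used == 0L) stopf("PLS fit failed: response carries no usable variance")
  idx <- seq_len(used)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Q = Q[, idx, drop = FALSE], T = TT[, idx, drop = FALSE],
       ssy = ssy[idx], Yres = Ya, ncomp = used)
}

## Regression-coefficient form for prediction: B = W (P'W)^-1 Q'.
pls_coef <- function(fit) {
  fit$W %*% solve(crossprod(fit$P, fit$W), t(fit$Q))
}

one_hot <- function(g) {
  g <- factor(g)
  Y <- stats::model.matrix(~ g - 1)
  colnames(Y) <- levels(g)
  Y
}

#' Fit a PLS-DA model with LOOCV Q2 and VIP scores
#'
#' NIPALS PLS2 on the autoscaled matrix against the one-hot class membership
#' matrix. `R2Y` is the cumulative fraction of class-matrix variance
#' explained; `Q2 = 1 - PRESS/TSS` with PRESS from leave-one-out refits
#' (one biological sample out per fold). VIP for feature j is
#' `sqrt(p * sum_a ssy_a (w_ja / ||w_a||)^2 / sum_a ssy_a)`, so mean VIP^2 is
#' exactly 1.
#'
#' @param fm An autoscaled [feature_matrix()].
#' @param labels Class labels (length = samples) or a metadata column name.
#' @param ncomp Number of PLS components.
#' @return Object of class `plsda_model`: `R2Y`, `Q2`, `vip`, `scores`,
#'   `ncomp`, plus the fitted core.
#' @export
plsda_fit <- function(fm, labels, ncomp = 2) {
  if (length(labels) == 1 && is.character(labels)) labels <- fm$samples[[labels]]
  g <- factor(labels)
  if (nlevels(g) < 2) stopf("PLS-DA needs >= 2 classes")
  if (min(table(g)) < 2)
    warnf("class '%s' has a single sample; its LOOCV fold trains without that class",
          names(which.min(table(g))))
  X <- fm$values
  Y0 <- one_hot(g)
  Ym <- colMeans(Y0)
  Y <- sweep(Y0, 2, Ym)
  fit <- pls_nipals(X, Y, ncomp)
  tss <- sum(Y^2)
  r2y <- 1 - sum(fit$Yres^2) / tss
  ## VIP
  p <- ncol(X)
  w2 <- fit$W^2                      # columns already unit norm
  vip <- sqrt(p * as.numeric(w2 %*% fit$ssy) / sum(fit$ssy))
  names(vip) <- colnames(X)
  ## LOOCV PRESS
  press <- 0
  n <- nrow(X)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y0[-i, , drop = FALSE]
    mx <- colMeans(Xi); my <- colMeans(Yi)
    f <- pls_nipals(sweep(Xi, 2, mx), sweep(Yi, 2, my), ncomp)
    B <- pls_coef(f)
    pred <- (X[i, ] - mx) %*% B + my
    press <- press + sum((Y0[i, ] - pred)^2)
  }
  q2 <- 1 - press / tss
  structure(list(R2Y = r2y, Q2 = q2, vip = vip, ncomp = ncomp,
                 scores = fit$T, fit = fit, labels = g),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model: %d components, R2Y = %.3f, Q2 = %.3f>\n",
              x$ncomp, x$R2Y, x$Q2))
  invisible(x)
}

#' Permutation test of a PLS-DA model
#'
#' Class labels are permuted `B` times and the model statistic (LOOCV Q2)
#' recomputed each time; `perm_p = (1 + #(perm >= observed)) / (B + 1)`.
#'
#' @param fm An autoscaled [feature_matrix()].
#' @param labels Class labels or metadata column name.
#' @param B Number of permutations (>= 20).
#' @param ncomp PLS components.
#' @return List: `perm_p`, `observed` Q2, `perm_stats`.
#' @export
permutation_test <- function(fm, labels, B = 1000, ncomp = 2) {
  if (B < 20) stopf("B = %d permutations is uninformative; use >= 20", B)
  if (length(labels) == 1 && is.character(labels)) labels <- fm$samples[[labels]]
  obs <- plsda_fit(fm, labels, ncomp)$Q2
  stats_perm <- vapply(seq_len(B), function(b) {
    plsda_fit(fm, sample(labels), ncomp)$Q2
  }, numeric(1))
  list(perm_p = (1 + sum(stats_perm >= obs)) / (B + 1), observed = obs,
       perm_stats = stats_perm)
}

#' Partition per-component variance into design terms
#'
#' For each principal component, fits the fixed-effects linear model
#' `score ~ rootstock + irrigation + rootstock:irrigation` with type-I sums
#' of squares in that order (equal to type-III on a balanced design) and
#' reports each term's variance fraction `SS_term / SS_total` with its F-test
#' p-value.
#'
#' @param pca A [pca_fit()] result (fit with up to 20 components).
#' @param factors Character vector of the two factor names.
#' @return Data frame: `pc`, `term`, `frac_variance`, `p`.
#' @export
variance_partition <- function(pca, factors = c("rootstock", "irrigation")) {
  md <- pca$samples
  f1 <- factor(md[[factors[1]]]); f2 <- factor(md[[factors[2]]])
  has_empty <- any(table(f1, f2) == 0)
  with_int <- !has_empty && all(table(f1, f2) >= 1) && nrow(md) > nlevels(f1) * nlevels(f2)
  if (has_empty) warnf("empty design cells: interaction term dropped")
  out <- list()
  for (j in seq_len(ncol(pca$scores))) {
    y <- pca$scores[, j]
    fml <- if (with_int) y ~ f1 + f2 + f1:f2 else y ~ f1 + f2
    a <- stats::anova(stats::lm(fml))
    ss <- a$`Sum Sq`; terms <- rownames(a)
    tot <- sum(ss)
    keep <- terms != "Residuals"
    lab <- c(f1 = factors[1], f2 = factors[2])[terms[keep]]
    lab[terms[keep] == "f1:f2"] <- "interaction"
    out[[j]] <- data.frame(pc = j, term = unname(lab),
                           frac_variance = ss[keep] / tot,
                           p = a$`Pr(>F)`[keep], row.names = NULL)
  }
  do.call(rbind, out)
}
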