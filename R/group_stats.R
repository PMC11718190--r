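#' Nonparametric group comparison (Kruskal-Wallis / rank-sum)
#'
#' Rank-based H statistic with tie correction and a chi-squared p-value
#' (df = groups - 1). With exactly two groups the p-value is taken from the
#' Mann-Whitney rank-sum test (normal approximation, no continuity
#' correction, which coincides with the Kruskal-Wallis chi-squared p); the H
#' statistic is reported either way.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, total n >= 3).
#' @return list with `H`, `p`, `df`, `method`.
#' @export
kw_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2,
            length(values) >= 3)
  if (length(unique(values)) == 1) {
    warning("all values identical; zero variance, p = 1")
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L,
                method = "degenerate"))
  }
  kw <- kruskal.test(values, groups)
  H <- unname(kw$statistic)
  if (nlevels(groups) == 2) {
    sp <- split(values, groups)
    mw <- suppressWarnings(wilcox.test(sp[[1]], sp[[2]], exact = FALSE,
                                       correct = FALSE))
    return(list(H = H, p = unname(mw$p.value), df = 1L,
                method = "mann-whitney"))
  }
  list(H = H, p = unname(kw$p.value), df = unname(kw$parameter),
       method = "kruskal-wallis")
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' The adaptive two-stage step-up procedure: stage 1 runs Benjamini-Hochberg
#' at `q' = q / (1 + q)` and uses its rejection count `r1` to estimate the
#' number of true nulls `m0 = m - r1`; stage 2 reruns BH at level
#' `q' * m / m0`. If stage 1 rejects nothing, nothing is discovered; if it
#' rejects everything, everything is. More powerful than plain BH (its
#' discoveries always contain BH's at the same `q`). Deterministic.
#'
#' @param p p-values in `[0, 1]`.
#' @param q target FDR level.
#' @return list with `reject` (logical, same order as `p`), `r1`, `m0`, and
#'   the stage-2 `level`.
#' @export
bky_fdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  m <- length(p)
  if (m == 0)
    return(list(reject = logical(0), r1 = 0L, m0 = 0L, level = NA_real_))
  qp <- q / (1 + q)
  bh_reject <- function(p, level) {
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= level * seq_len(m) / m)
    rej <- logical(m)
    if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  r1 <- sum(bh_reject(p, qp))
  if (r1 == 0L)
    return(list(reject = logical(m), r1 = 0L, m0 = m, level = qp))
  if (r1 == m)
    return(list(reject = rep(TRUE, m), r1 = as.integer(m), m0 = 0L,
                level = qp))
  m0 <- m - r1
  level2 <- qp * m / m0
  list(reject = bh_reject(p, level2), r1 = as.integer(r1),
       m0 = as.integer(m0), level = level2)
}

#' Per-fibre morphology feature matrix
#'
#' Builds the fibre-by-feature matrix used by the multivariate analyses:
#' mean and median of volume, MCI and sphericity per fibre, plus
#' mitochondrial volume density (total mitochondrial volume / ROI volume)
#' when ROI volumes are supplied.
#'
#' @param records per-mitochondrion records with `fibre_id`, `volume`, `mci`,
#'   `sphericity`.
#' @param roi_volume optional named vector of ROI volumes (um^3) per fibre.
#' @return data.frame with `fibre_id` and feature columns.
#' @export
fibre_feature_matrix <- function(records, roi_volume = NULL) {
  rows <- lapply(split(records, records$fibre_id), function(r) {
    out <- data.frame(fibre_id = r$fibre_id[1],
                      volume_mean = mean(r$volume),
                      volume_median = median(r$volume),
                      mci_mean = mean(r$mci), mci_median = median(r$mci),
                      sphericity_mean = mean(r$sphericity),
                      sphericity_median = median(r$sphericity),
                      stringsAsFactors = FALSE)
    if (!is.null(roi_volume))
      out$volume_density <- sum(r$volume) / roi_volume[[r$fibre_id[1]]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# centre + unit-variance scale; constant columns dropped with a warning
autoscale <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(X, center = TRUE, scale = sds)
}

#' PLS-DA via NIPALS with VIP scores
#'
#' Partial least squares discriminant analysis: features are autoscaled
#' (centred, unit variance), the class response is one-hot encoded and
#' centred, and components are extracted by the NIPALS algorithm with
#' X-deflation. Reports per-component explained X-variance (shares of total
#' X sum of squares; they sum to 1 at full rank), scores, normalized weights,
#' loadings, and VIP scores
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` whose squares average
#' to 1 over features. Deterministic given the fixed deflation order.
#'
#' @param X numeric matrix or data.frame of fibre features (rows = fibres).
#' @param y class labels, length `nrow(X)`, >= 2 classes.
#' @param n_components number of latent components (<= rank of scaled X).
#' @return a `plsda_model` with `scores`, `weights`, `loadings`,
#'   `y_loadings`, `explained_x_variance`, `ssy`, `vip`, `features`,
#'   `classes`.
#' @export
plsda_fit <- function(X, y, n_components = 3) {
  if (is.data.frame(X)) X <- as.matrix(X)
  y <- factor(y)
  stopifnot(nrow(X) == length(y), nlevels(y) >= 2, n_components >= 1)
  Xs <- autoscale(X)
  Y <- stats::model.matrix(~ y - 1)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  rk <- qr(Xs)$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds rank of X (", rk, ")")

  n <- nrow(Xs); p <- ncol(Xs)
  ssx_total <- sum(Xs^2)
  ssy_total <- sum(Y^2)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  xvar <- ssy <- numeric(n_components)
  Xd <- Xs; Yd <- Y
  for (a in seq_len(n_components)) {
    u <- Yd[, 1]
    w <- rep(0, p)
    for (it in 1:500) {
      w_new <- crossprod(Xd, u) / sum(u^2)
      w_new <- w_new / sqrt(sum(w_new^2))
      t <- Xd %*% w_new
      q <- crossprod(Yd, t) / sum(t^2)
      u <- Yd %*% q / sum(q^2)
      if (sqrt(sum((w_new - w)^2)) < 1e-12) { w <- w_new; break }
      w <- w_new
    }
    t <- Xd %*% w
    pv <- crossprod(Xd, t) / sum(t^2)
    q <- crossprod(Yd, t) / sum(t^2)
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; Q[, a] <- q
    xvar[a] <- sum(t^2) * sum(pv^2) / ssx_total
    ssy[a] <- sum(t^2) * sum(q^2) / ssy_total
    Xd <- Xd - tcrossprod(t, pv)
    Yd <- Yd - tcrossprod(t, q)
  }
  rownames(W) <- rownames(P) <- colnames(Xs)
  model <- structure(list(scores = Tm, weights = W, loadings = P,
                          y_loadings = Q, explained_x_variance = xvar,
                          ssy = ssy, n_components = n_components,
                          features = colnames(Xs), classes = levels(y),
                          y = y),
                     class = "plsda_model")
  model$vip <- vip_scores(model)
  model
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a [SSY_a (w_ja / ||w_a||)^2] / sum_a SSY_a)` with
#' `p` features and `SSY_a` the response variance explained by component `a`.
#' By construction `mean(VIP^2) = 1`, so VIP > 1 conventionally marks a
#' feature as contributing more than average to class separation.
#'
#' @param model a fitted `plsda_model`.
#' @return named numeric vector of VIP scores per feature.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W <- model$weights                      # columns already unit norm
  ssy <- model$ssy
  p <- nrow(W)
  vip2 <- p * (W^2 %*% ssy) / sum(ssy)
  out <- sqrt(as.numeric(vip2))
  names(out) <- model$features
  out
}

#' Ward/Euclidean hierarchical clustering of the fibre feature matrix
#'
#' Agglomerative clustering with Ward linkage (`ward.D2`) on Euclidean
#' distances over autoscaled features, applied to rows (fibres) and columns
#' (parameters); also returns the group-mean matrix (heatmap of class
#' averages). Deterministic: `hclust` breaks merge ties by index.
#'
#' @param X numeric matrix/data.frame, rows = fibres, columns = features.
#' @param groups optional class label per row for the group-mean matrix.
#' @return list with `row_dendrogram`, `col_dendrogram` (hclust objects),
#'   `ordered` (autoscaled matrix in dendrogram order), `scaled`, and
#'   `group_means` (autoscaled feature means per group, or NULL).
#' @export
ward_heatmap <- function(X, groups = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  Xs <- autoscale(X)
  hr <- hclust(dist(Xs), method = "ward.D2")
  hc <- hclust(dist(t(Xs)), method = "ward.D2")
  gm <- NULL
  if (!is.null(groups)) {
    gm <- apply(Xs, 2, function(col) tapply(col, groups, mean))
  }
  list(row_dendrogram = hr, col_dendrogram = hc,
       ordered = Xs[hr$order, hc$order, drop = FALSE], scaled = Xs,
       group_means = gm)
}
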