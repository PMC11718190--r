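test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  # groups {1,2,3} vs {4,5,6}: ranks 1..6, H = 12/(6*7)*(3*2^2+3*5^2) - 3*7
  res <- kw_test(1:6, rep(c("a", "b"), each = 3))
  expect_equal(res$H, 12 / 42 * (3 * 4 + 3 * 25) - 21, tolerance = 1e-12)
  expect_equal(res$H, 3.857143, tolerance = 1e-6)
  # two identical groups: H = 0
  expect_equal(kw_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$H, 0)
  # all values identical: degenerate, p = 1 with a warning
  expect_warning(res0 <- kw_test(rep(5, 9), rep(c("a", "b", "c"), 3)),
                 "identical")
  expect_equal(res0$p, 1)
})

test_that("two-group dispatch reproduces the rank-sum p-value", {
  set.seed(10)
  for (i in 1:10) {
    v <- rnorm(24)
    g <- rep(c("a", "b"), each = 12)
    res <- kw_test(v, g)
    kwp <- kruskal.test(v, factor(g))$p.value
    expect_equal(res$p, kwp, tolerance = 1e-10)  # same approximation
    expect_identical(res$method, "mann-whitney")
  }
})

test_that("null simulation holds the type-I error near its nominal level", {
  set.seed(1234)
  rej <- mean(replicate(1000, {
    kw_test(rnorm(60), rep(c("a", "b", "c"), each = 20))$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

# straight transcription of the two-stage step-up definition, kept naive on
# purpose as the independent oracle
naive_bky <- function(p, q = 0.05) {
  m <- length(p)
  qp <- q / (1 + q)
  bh <- function(p, level) {
    o <- order(p)
    k <- which(p[o] <= level * seq_len(m) / m)
    rej <- rep(FALSE, m)
    if (length(k)) rej[o[1:max(k)]] <- TRUE
    rej
  }
  r1 <- sum(bh(p, qp))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, qp * m / (m - r1))
}

test_that("BKY two-stage flags match the naive reference and dominate BH", {
  expect_true(all(bky_fdr(rep(0.001, 10))$reject))
  expect_false(any(bky_fdr(rep(0.9, 10))$reject))
  expect_length(bky_fdr(numeric(0))$reject, 0)
  set.seed(55)
  for (i in 1:300) {
    p <- c(runif(sample(10:50, 1)), rbeta(sample(0:20, 1), 0.2, 8))
    p <- pmin(p, 1)
    mine <- bky_fdr(p)$reject
    expect_identical(mine, naive_bky(p))
    # guaranteed dominance: BH at the two-stage working level q' = q/(1+q)
    # (dominance over BH at q itself fails in general when stage 1 rejects
    # almost nothing, since the stage-2 level q'*m/m0 can stay below q)
    bh <- p.adjust(p, "BH") <= 0.05 / 1.05
    expect_true(all(bh <= mine))
  }
})

test_that("PLS-DA finds a planted informative feature and honours identities", {
  set.seed(21)
  n <- 60
  y <- rep(c("g1", "g2"), each = n / 2)
  X <- cbind(sig = rnorm(n, ifelse(y == "g1", 0, 2)),
             matrix(rnorm(n * 5), n, 5))
  colnames(X) <- c("sig", paste0("noise", 1:5))
  m <- plsda_fit(X, y, n_components = 3)
  expect_equal(names(which.max(abs(m$weights[, 1]))), "sig")
  expect_gt(m$vip[["sig"]], 1)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)
  # scores of distinct components are orthogonal
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # full-rank fit explains all of X
  mf <- plsda_fit(X, y, n_components = qr(scale(X))$rank)
  expect_equal(sum(mf$explained_x_variance), 1, tolerance = 1e-6)
  # duplicating rows and labels leaves the model unchanged
  m2 <- plsda_fit(rbind(X, X), c(y, y), n_components = 3)
  expect_equal(m2$weights, m$weights, tolerance = 1e-8)
  expect_equal(m2$vip, m$vip, tolerance = 1e-8)
  # constant features are dropped with a warning, rank guard errors
  Xc <- cbind(X, flat = 1)
  expect_warning(plsda_fit(Xc, y, n_components = 2), "constant")
  expect_error(plsda_fit(X, y, n_components = 10), "rank")
})

test_that("PLS-DA matches the mixOmics implementation on the same data", {
  set.seed(33)
  n <- 40
  y <- rep(c("a", "b"), each = 20)
  X <- cbind(matrix(rnorm(n * 3), n, 3), sig = rnorm(n, ifelse(y == "a", 0, 1.5)))
  colnames(X) <- c(paste0("f", 1:3), "sig")
  mine <- plsda_fit(X, y, n_components = 2)
  mo <- mixOmics::plsda(X, factor(y), ncomp = 2)
  expect_equal(unname(mine$explained_x_variance),
               unname(unlist(mo$prop_expl_var$X)), tolerance = 1e-8)
  expect_equal(unname(mine$vip), unname(mixOmics::vip(mo)[, 2]),
               tolerance = 1e-6)
})

test_that("symmetric equal-weight one-component model gives unit VIPs", {
  set.seed(44)
  n <- 200
  t <- rnorm(n)
  X <- sapply(1:4, function(j) t + rnorm(n, 0, 1e-6))
  colnames(X) <- paste0("f", 1:4)
  y <- ifelse(t > 0, "a", "b")
  m <- plsda_fit(X, y, n_components = 1)
  expect_equal(unname(m$vip), rep(1, 4), tolerance = 1e-3)
})

test_that("Ward/Euclidean clustering recovers planted partitions deterministically", {
  set.seed(66)
  X <- rbind(matrix(rnorm(60, 0), 10, 6), matrix(rnorm(60, 6), 10, 6))
  colnames(X) <- paste0("f", 1:6)
  res <- ward_heatmap(X, groups = rep(c("a", "b"), each = 10))
  expect_identical(unname(cutree(res$row_dendrogram, 2)),
                   rep(c(1L, 2L), each = 10))
  expect_equal(dim(res$group_means), c(2L, 6L))
  # duplicated rows merge at height zero
  X2 <- rbind(X, X[1, , drop = FALSE])
  res2 <- ward_heatmap(X2)
  expect_equal(min(res2$row_dendrogram$height), 0)
  # row permutation changes labels only, not the tree geometry
  perm <- sample(nrow(X))
  res3 <- ward_heatmap(X[perm, ])
  expect_equal(sort(res3$row_dendrogram$height),
               sort(res$row_dendrogram$height), tolerance = 1e-12)
  a <- unname(cutree(res$row_dendrogram, 2))
  b <- unname(cutree(res3$row_dendrogram, 2)[order(perm)])
  expect_true(all(outer(a, a, "==") == outer(b, b, "==")))  # same partition
})

test_that("fibre feature matrix carries the documented morphology summaries", {
  rec <- data.frame(fibre_id = rep(c("f1", "f2"), each = 3),
                    volume = c(1, 2, 3, 4, 5, 6),
                    mci = c(1, 1, 4, 2, 2, 2),
                    sphericity = c(0.9, 0.8, 0.7, 0.95, 0.9, 0.85))
  fm <- fibre_feature_matrix(rec, roi_volume = c(f1 = 100, f2 = 100))
  expect_equal(fm$volume_mean, c(2, 5))
  expect_equal(fm$mci_median, c(1, 2))
  expect_equal(fm$volume_density, c(0.06, 0.15))
})
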