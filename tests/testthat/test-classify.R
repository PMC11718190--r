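# canonical intensity mixture used across these tests
draw_mixture <- function(n, seed, w = c(0.5, 0.3, 0.2), mu = c(40, 120, 200),
                         sd = c(15, 20, 15)) {
  set.seed(seed)
  k <- sample(1:3, n, TRUE, prob = w)
  pmin(pmax(rnorm(n, mu[k], sd[k]), 0), 255)
}

test_that("EM recovers the generating mixture", {
  x <- draw_mixture(10000, seed = 1)
  fit <- fit_gmm3(x, seed = 1)
  expect_lt(max(abs(fit$components$mean - c(40, 120, 200))), 5)
  expect_equal(sum(fit$components$weight), 1)
  expect_true(all(diff(fit$components$mean) > 0))
  t <- fit$thresholds
  m <- fit$components$mean
  expect_true(m[1] < t[1] && t[1] < m[2] && m[2] < t[2] && t[2] < m[3])
})

test_that("EM agrees with an independent mixture implementation", {
  suppressMessages(library(mclust))
  x <- draw_mixture(4000, seed = 5)
  fit <- fit_gmm3(x, seed = 1)
  mc <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(fit$components$mean) - sort(mc$parameters$mean))), 1)
  expect_lt(abs(fit$log_likelihood - mc$loglik), 1)
})

test_that("a three-point mass is recovered exactly with sds at the floor", {
  x <- rep(c(40, 120, 200), each = 50)
  fit <- fit_gmm3(x, seed = 1)
  expect_equal(fit$components$mean, c(40, 120, 200), tolerance = 1e-6)
  expect_equal(fit$components$sd, rep(1e-3 * 160, 3), tolerance = 1e-6)
})

test_that("the fit is invariant to input order and demands enough data", {
  x <- draw_mixture(2000, seed = 3)
  f1 <- fit_gmm3(x, seed = 2)
  f2 <- fit_gmm3(rev(x), seed = 2)
  expect_equal(f1$components, f2$components, tolerance = 1e-6)
  expect_error(fit_gmm3(x[1:29], seed = 1), "at least 30")
})

test_that("intersection thresholds solve the weighted density equation", {
  mk_fit <- function(w, mu, sd) {
    structure(list(components = data.frame(
      component = c("normal", "intermediate", "deficient"),
      weight = w, mean = mu, sd = sd)), class = "mixture_fit")
  }
  # symmetric two components: exact midpoint
  f <- mk_fit(c(0.4, 0.4, 0.2), c(40, 120, 200), c(15, 15, 10))
  expect_equal(unname(intersection_thresholds(f)[1]), 80)
  # unequal weights, equal sds: closed form midpoint + s^2 log(w1/w2)/(mu2-mu1)
  f <- mk_fit(c(0.7, 0.3, 0.0001), c(40, 120, 200), c(15, 15, 10))
  expect_equal(unname(intersection_thresholds(f)[1]),
               80 + 225 * log(0.7 / 0.3) / 80, tolerance = 1e-9)
  # unequal sds: matches a 0.001-step grid scan of the density difference
  f <- mk_fit(c(0.5, 0.3, 0.2), c(40, 120, 200), c(12, 25, 15))
  t <- intersection_thresholds(f)
  for (pair in list(c(1, 2, t[1]), c(2, 3, t[2]))) {
    grid <- seq(f$components$mean[pair[1]], f$components$mean[pair[2]],
                by = 0.001)
    dens <- function(k) f$components$weight[k] *
      dnorm(grid, f$components$mean[k], f$components$sd[k])
    t_grid <- grid[which.min(abs(dens(pair[1]) - dens(pair[2])))]
    expect_lt(abs(pair[3] - t_grid), 0.01)
  }
})

test_that("hard class assignment uses half-open intervals", {
  cls <- assign_classes(c(30, 80, 159, 200), c(80, 160))
  expect_equal(as.character(cls),
               c("normal", "intermediate", "intermediate", "deficient"))
  expect_true(all(assign_classes(c(1, 20, 79.9), c(80, 160)) == "normal"))
  # exhaustive and exclusive
  x <- runif(500, 0, 255)
  cls <- assign_classes(x, c(80, 160))
  expect_false(any(is.na(cls)))
})

test_that("fibre majority rule matches a brute-force implementation on a simplex grid", {
  brute <- function(p) {
    cls <- c("normal", "intermediate", "deficient")
    if (p[1] > 0.5) return("normal")
    if (p[2] > 0.5) return("intermediate")
    if (p[3] > 0.5) return("deficient")
    mx <- max(p)
    win <- cls[p == mx]
    if (length(win) > 1) "unresolved" else win
  }
  # integer grid keeps ties exact (no floating-point near-ties)
  for (i in 0:20) for (j in 0:(20 - i)) {
    p <- c(i, j, 20 - i - j) / 20
    got <- classify_fibre(p)
    expect_identical(got$class, brute(p))
    expect_identical(got$unresolved_majority, max(p) <= 0.5)
  }
  expect_identical(classify_fibre(c(0.6, 0.3, 0.1))$class, "normal")
  expect_identical(classify_fibre(c(0.5, 0.5, 0))$class, "unresolved")
  r <- classify_fibre(c(0.45, 0.35, 0.20))
  expect_identical(r$class, "normal")
  expect_true(r$unresolved_majority)
})

test_that("spherical-deficient percentage follows its definition", {
  rec <- data.frame(cox_class = rep("deficient", 4),
                    sphericity = c(0.8, 0.9, 0.5, 0.76))
  expect_equal(percent_spherical_deficient(rec), 75)
  none <- data.frame(cox_class = "normal", sphericity = 1)
  expect_warning(out <- percent_spherical_deficient(none), "undefined")
  expect_true(is.na(out))
})

test_that("well-separated mixtures are classified with at least 95% agreement", {
  set.seed(12)
  n <- 2000
  k <- sample(1:3, n, TRUE, prob = c(0.4, 0.3, 0.3))
  x <- pmin(pmax(rnorm(n, c(40, 120, 200)[k], c(12, 15, 12)[k]), 0), 255)
  fit <- fit_gmm3(x, seed = 1)
  cls <- assign_classes(x, fit$thresholds)
  truth <- c("normal", "intermediate", "deficient")[k]
  expect_gte(mean(as.character(cls) == truth), 0.95)
})

test_that("measured deficient proportion rises with the planted fraction", {
  p_def <- seq(0.1, 0.9, length.out = 5)
  measured <- vapply(seq_along(p_def), function(i) {
    set.seed(100 + i)
    w <- c((1 - p_def[i]) * 0.6, (1 - p_def[i]) * 0.4, p_def[i])
    x <- draw_mixture(3000, seed = 200 + i, w = w,
                      mu = c(40, 120, 200), sd = c(12, 15, 12))
    fit <- fit_gmm3(x, seed = 1)
    mean(assign_classes(x, fit$thresholds) == "deficient")
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("per-dataset fits recover shifted mixtures that a pooled fit cannot", {
  xa <- draw_mixture(3000, seed = 31, mu = c(30, 100, 170), sd = c(10, 12, 10))
  xb <- draw_mixture(3000, seed = 32, mu = c(70, 150, 225), sd = c(10, 12, 10))
  fa <- fit_gmm3(xa, seed = 1)
  fb <- fit_gmm3(xb, seed = 1)
  expect_lt(max(abs(fa$components$mean - c(30, 100, 170))), 5)
  expect_lt(max(abs(fb$components$mean - c(70, 150, 225))), 5)
  pooled <- fit_gmm3(c(xa, xb), seed = 1)
  dev_a <- max(abs(pooled$components$mean - c(30, 100, 170)))
  dev_b <- max(abs(pooled$components$mean - c(70, 150, 225)))
  expect_true(dev_a > 5 && dev_b > 5)   # pooling loses both patients
})

test_that("fibre summaries aggregate composition, class and dispersion", {
  rec <- data.frame(
    fibre_id = rep(c("f1", "f2"), c(4, 3)),
    mean_intensity = c(40, 50, 60, 200, 120, 130, 121),
    mci = c(1, 3, 2, 2, 1, 1, 1),
    sphericity = c(0.9, 0.8, 0.7, 0.95, 0.8, 0.8, 0.8),
    cox_class = c("normal", "normal", "normal", "deficient",
                  "intermediate", "intermediate", "intermediate"))
  fs <- fibre_summary(rec)
  expect_equal(fs$fibre_class, c("normal", "intermediate"))
  expect_equal(fs$p_normal, c(0.75, 0))
  f1 <- rec[rec$fibre_id == "f1", ]
  expect_equal(fs$sem_intensity[1], sd(f1$mean_intensity) / 2)
  expect_equal(fs$percent_spherical_deficient[1], 100)  # one deficient, 0.95
  # MCI {1, 3}: mean 2, SEM 1
  two <- data.frame(fibre_id = "f", mean_intensity = c(10, 20), mci = c(1, 3),
                    sphericity = c(1, 1), cox_class = "normal")
  fs2 <- fibre_summary(two)
  expect_equal(fs2$mean_mci, 2)
  expect_equal(fs2$sem_mci, 1)
})
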