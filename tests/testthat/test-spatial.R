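test_that("mitotype table reports means and SEMs per fibre", {
  rec <- data.frame(fibre_id = rep(c("f1", "f2"), c(2, 3)),
                    mean_intensity = c(100, 120, 30, 30, 30),
                    mci = c(1, 3, 2, 2, 2))
  mt <- mitotype_table(rec)
  expect_equal(mt$mean_mci, c(2, 2))
  expect_equal(mt$sem_mci, c(1, 0))       # {1,3}: sd sqrt(2), n 2 -> SEM 1
  expect_equal(mt$sem_intensity[2], 0)    # identical mitochondria
  one <- mitotype_table(data.frame(fibre_id = "f", mean_intensity = 5, mci = 1))
  expect_true(is.na(one$sem_mci))
})

test_that("3D class maps export deterministic colour keys", {
  rec <- data.frame(x = 1:3, y = 1:3, z = 1:3,
                    cox_class = c("normal", "intermediate", "deficient"),
                    mci = c(0.8, 1.2, 3))
  m <- class_map_3d(rec)
  expect_equal(nrow(m), 3)
  expect_equal(length(unique(m$colour)), 3)
  m2 <- class_map_3d(rec, colour_by = "mci")
  expect_equal(nrow(m2), 3)
  empty <- class_map_3d(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("perfectly segregated blobs give concordance exactly 1", {
  set.seed(5)
  blob1 <- matrix(rnorm(60, 0, 0.3), 20, 3)
  blob2 <- matrix(rnorm(60, 10, 0.3), 20, 3)
  res <- spatial_concordance(rbind(blob1, blob2),
                             rep(c("a", "b"), each = 20), k = 3,
                             n_permutations = 200, seed = 1)
  expect_equal(res$c_obs, 1)
  expect_gt(res$z, 3)
})

test_that("uniformly shuffled labels produce null-consistent z scores", {
  set.seed(77)
  centroids <- matrix(runif(60 * 3, 0, 5), 60, 3)
  zs <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    classes <- sample(rep(c("a", "b", "c"), each = 20))
    spatial_concordance(centroids, classes, k = 6, n_permutations = 300,
                        seed = i)$z
  }, numeric(1))
  expect_gte(mean(abs(zs) < 3), 0.95)
})

test_that("the z statistic is approximately standard under exchangeability", {
  set.seed(99)
  centroids <- matrix(runif(200 * 3, 0, 10), 200, 3)
  zs <- vapply(1:80, function(i) {
    set.seed(2000 + i)
    classes <- sample(rep(c("a", "b"), each = 100))
    spatial_concordance(centroids, classes, k = 6, n_permutations = 200,
                        seed = i)$z
  }, numeric(1))
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("concordance is invariant under rigid motion and deterministic under ties", {
  set.seed(3)
  centroids <- matrix(runif(90, 0, 4), 30, 3)
  classes <- sample(rep(c("a", "b"), 15))
  base <- spatial_concordance(centroids, classes, k = 4,
                              n_permutations = 100, seed = 9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- centroids %*% R + matrix(rep(c(5, -2, 1), each = 30), 30, 3)
  rot <- spatial_concordance(moved, classes, k = 4,
                             n_permutations = 100, seed = 9)
  expect_equal(rot$c_obs, base$c_obs)
  # duplicate centroids: tie break by id, reproducible
  dup <- rbind(centroids, centroids[1:5, ])
  cls <- c(classes, classes[1:5])
  r1 <- spatial_concordance(dup, cls, k = 4, n_permutations = 100, seed = 2)
  r2 <- spatial_concordance(dup, cls, k = 4, n_permutations = 100, seed = 2)
  expect_identical(r1, r2)
})

test_that("degenerate fibres report missing statistics rather than failing", {
  centroids <- matrix(runif(30), 10, 3)
  res <- spatial_concordance(centroids, rep("a", 10), k = 3,
                             n_permutations = 100, seed = 1)
  expect_true(is.na(res$z))
  expect_error(spatial_concordance(centroids[1:3, ], rep(c("a", "b"), 2)[1:3],
                                   k = 6, n_permutations = 100, seed = 1),
               "at least k \\+ 1")
})

test_that("segmental phantom fibres score higher concordance than shuffled ones", {
  ph <- generate_phantom(small_phantom_spec(seed = 53, n_fibres = 2,
                                            shapes = c(60, 60)))
  rec <- phantom_records(ph)
  wins <- 0L; total <- 0L
  for (fid in unique(rec$fibre_id)) {
    r <- rec[rec$fibre_id == fid, ]
    tr <- ph$truth$mitochondria
    ctr <- tr[match(paste(r$fibre_id, r$label_id),
                    paste(tr$fibre_id, tr$label_id)), c("x", "y", "z")]
    z_seg <- spatial_concordance(as.matrix(ctr), r$true_class, k = 6,
                                 n_permutations = 300, seed = 4)$z
    for (s in 1:10) {
      set.seed(s)
      z_shuf <- spatial_concordance(as.matrix(ctr), sample(r$true_class),
                                    k = 6, n_permutations = 300, seed = 4)$z
      wins <- wins + (z_seg > z_shuf); total <- total + 1L
    }
  }
  expect_gte(wins / total, 0.95)
})

test_that("per-fibre concordance derives reproducible fibre seeds", {
  ph <- generate_phantom(small_phantom_spec(seed = 59, n_fibres = 2,
                                            shapes = c(40, 40)))
  rec <- phantom_records(ph, morphometry = TRUE)
  rec$cox_class <- rec$true_class
  c1 <- concordance_by_fibre(rec, k = 5, n_permutations = 150, seed = 8)
  c2 <- concordance_by_fibre(rec, k = 5, n_permutations = 150, seed = 8)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 2)
  expect_true(all(is.finite(c1$z)))
})
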