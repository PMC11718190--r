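test_that("extract_objects returns one object per instance label with QC flags", {
  ph <- generate_phantom(small_phantom_spec(seed = 41, n_fibres = 1,
                                            shapes = c(12, 12)))
  labs <- ph$fibres[[1]]$labels
  objs <- extract_objects(labs)
  expect_length(objs, 12)
  expect_identical(unname(vapply(objs, `[[`, 1L, "label_id")), 1:12)

  # border contact: plant a voxel at z = 1
  lv <- labs$voxels
  lv[1, 5, 5] <- 12L
  objs2 <- extract_objects(label_stack(lv, labs$voxel_size))
  expect_true(objs2[[12]]$touches_border)
  # the edit put label 12 in two disconnected blobs: still ONE object, flagged
  expect_length(objs2, 12)
  expect_true(objs2[[12]]$disconnected)
  expect_false(objs2[[1]]$disconnected)

  # empty stack: explicit empty result, not an error
  expect_identical(extract_objects(label_stack(array(0, c(4, 4, 4)))), list())

  # sub-minimum objects are flagged, never dropped
  tiny <- array(0, c(6, 6, 6)); tiny[3, 3, 3] <- 1
  o <- extract_objects(label_stack(tiny), min_voxels = 10)
  expect_length(o, 1)
  expect_true(o[[1]]$too_small)
})

test_that("volume is voxel count times voxel volume and scales as expected", {
  o <- list(voxel_count = 1000L)
  expect_equal(measure_volume(o, rep(0.07, 3)), 0.343)
  expect_equal(measure_volume(o, rep(0.14, 3)), 0.343 * 8)
  sph <- sphere_object(25)
  expect_rel_error(measure_volume(sph, rep(0.07, 3)),
                   4 / 3 * pi * (25 * 0.07)^3, 0.02)
})

test_that("mesh surface area matches closed forms and converges with radius", {
  vs <- rep(0.07, 3)
  errs <- vapply(c(10, 20, 40), function(r) {
    o <- sphere_object(r)
    abs(measure_surface_area(o, vs) / (4 * pi * (r * 0.07)^2) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_true(all(diff(errs) < 0))     # error shrinks with resolution

  o25 <- sphere_object(25)
  expect_rel_error(measure_surface_area(o25, vs), 4 * pi * (25 * 0.07)^2, 0.05)

  ell <- shape_ellipsoid(10 * 0.07, 40 * 0.07, c(5, 5, 5))
  o <- shape_object(ell)
  expect_rel_error(measure_surface_area(o, vs), ell$surface_area, 0.05)

  # face-count alternative exists and overestimates smooth bodies
  expect_gt(measure_surface_area(o25, vs, method = "faces"),
            4 * pi * (25 * 0.07)^2)
})

test_that("single-voxel objects use the voxel cuboid closed form", {
  o <- list(voxel_count = 1L, idx = cbind(z = 3L, y = 3L, x = 3L))
  expect_equal(measure_surface_area(o, rep(0.07, 3)), 6 * 0.07^2)
  expect_equal(measure_surface_area(o, rep(0.07, 3), method = "faces"),
               6 * 0.07^2)
})

test_that("MCI and sphericity reproduce symbolic values and identities", {
  # exact sphere: MCI = 9 / (4 pi), psi = 1
  expect_equal(compute_mci(4 * pi / 3, 4 * pi), 9 / (4 * pi))
  expect_equal(compute_sphericity(4 * pi / 3, 4 * pi), 1)
  # exact cube side a: MCI = 216 / (16 pi^2), psi = (pi / 6)^(1/3)
  a <- 2.7
  expect_equal(compute_mci(a^3, 6 * a^2), 216 / (16 * pi^2))
  expect_equal(compute_sphericity(a^3, 6 * a^2), (pi / 6)^(1 / 3))
  # scale invariance: (lambda^3 V, lambda^2 SA) leaves MCI unchanged
  for (lambda in c(0.1, 3, 42))
    expect_equal(compute_mci(lambda^3 * 5, lambda^2 * 17),
                 compute_mci(5, 17))
  # identity MCI * psi^3 = 9 / (4 pi) (the sphere MCI, since psi(sphere) = 1)
  # on arbitrary valid pairs
  set.seed(8)
  V <- runif(50, 0.01, 10); SA <- runif(50, 0.1, 50)
  expect_equal(unname(compute_mci(V, SA) * compute_sphericity(V, SA)^3),
               rep(9 / (4 * pi), 50), tolerance = 1e-9)
  expect_error(compute_mci(-1, 3))
  expect_error(compute_sphericity(1, 0))
})

test_that("MCI rank-order tracks elongation, in exact and mesh estimates", {
  vs <- rep(0.07, 3)
  exact_mci <- exact_psi <- mesh_mci <- mesh_psi <- numeric(0)
  for (ar in c(1, 2, 4, 8)) {
    a <- 12 / ar^(1 / 3) * 0.07
    ell <- shape_ellipsoid(a, a * ar, c(5, 5, 5))
    o <- shape_object(ell)
    V <- measure_volume(o, vs); SA <- measure_surface_area(o, vs)
    exact_mci <- c(exact_mci, compute_mci(ell$volume, ell$surface_area))
    exact_psi <- c(exact_psi, compute_sphericity(ell$volume, ell$surface_area))
    mesh_mci <- c(mesh_mci, compute_mci(V, SA))
    mesh_psi <- c(mesh_psi, compute_sphericity(V, SA))
  }
  expect_true(all(diff(exact_mci) > 0) && all(diff(mesh_mci) > 0))
  expect_true(all(diff(exact_psi) < 0) && all(diff(mesh_psi) < 0))
  # mesh sphericity honours the tolerance ceiling above 1
  expect_lte(max(mesh_psi), 1.05)
})

test_that("centroids follow the voxel-centre convention", {
  vs <- rep(0.07, 3)
  one <- list(idx = cbind(z = 1L, y = 1L, x = 1L), voxel_count = 1L)
  expect_equal(compute_centroid(one, vs), c(x = 0, y = 0, z = 0))
  two <- list(idx = cbind(z = c(1L, 1L), y = c(1L, 1L), x = c(1L, 11L)))
  expect_equal(compute_centroid(two, vs)[["x"]], 5 * 0.07)
  sph <- shape_object(shape_sphere(0.5, c(2.1, 2.8, 1.4)))
  ctr <- compute_centroid(sph, vs)
  expect_lt(max(abs(ctr - c(2.1, 2.8, 1.4))), 0.07 / 2)
})

test_that("measure_morphometry emits a complete per-label table", {
  ph <- generate_phantom(small_phantom_spec(seed = 43, n_fibres = 1,
                                            shapes = c(15, 15)))
  tab <- measure_morphometry(ph$fibres[[1]]$labels)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$volume > 0) && all(tab$surface_area > 0))
  expect_true(all(tab$mci >= 0.7 * 9 / (4 * pi)))
  expect_true(all(tab$sphericity > 0 & tab$sphericity <= 1.05))
  # agreement with planted analytic volume within voxelization error
  tr <- ph$truth$mitochondria
  expect_lt(max(abs(tab$volume / tr$volume[match(tab$label_id, tr$label_id)]
                    - 1)), 0.12)
  empty <- measure_morphometry(label_stack(array(0, c(4, 4, 4))))
  expect_equal(nrow(empty), 0)
})
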