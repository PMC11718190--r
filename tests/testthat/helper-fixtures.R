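# shared fixture builders: everything is generated in code at test time

# voxel object (as produced by extract_objects) for a rasterized shape
shape_object <- function(shape, voxel_size = rep(0.07, 3),
                         grid = c(160, 160, 160)) {
  ras <- rasterize_shape(shape, voxel_size, grid)
  list(label_id = 1L, idx = ras$idx, voxel_count = nrow(ras$idx),
       touches_border = FALSE, too_small = FALSE, disconnected = FALSE)
}

# sphere of radius r voxels. Centred on a voxel centre by default (the
# canonical construction for convergence series: its systematic lattice
# deficit shrinks monotonically with radius, whereas off-lattice centres
# fluctuate around zero); pass an explicit centre for generic positions.
sphere_object <- function(r_vox, voxel_size = rep(0.07, 3),
                          centre = rep(71 * voxel_size[1], 3)) {
  shape_object(shape_sphere(r_vox * voxel_size[1], centre),
               voxel_size, grid = rep(143, 3))
}

# small phantom cohort for fast integration tests
small_phantom_spec <- function(seed, n_fibres = 3, shapes = c(40, 50),
                               pattern = "segmental", ...) {
  phantom_spec(grid_shape = c(48, 64, 64), n_fibres = n_fibres,
               shapes_per_fibre = shapes, spatial_pattern = pattern,
               seed = seed, ...)
}

# per-mitochondrion table (cox + morphometry) from a generated phantom,
# joined with planted truth
phantom_records <- function(ph, morphometry = FALSE) {
  ints <- lapply(ph$fibres, `[[`, "intensity")
  normed <- normalize_dataset(ints)
  rows <- lapply(seq_along(ph$fibres), function(i) {
    cx <- measure_cox(normed[[i]], ph$fibres[[i]]$labels)
    if (morphometry) {
      mo <- measure_morphometry(ph$fibres[[i]]$labels)
      cx <- merge(mo, cx, by = "label_id")
    } else {
      cx$fibre_id <- ph$fibres[[i]]$fibre_id
    }
    cx
  })
  rec <- do.call(rbind, rows)
  tr <- ph$truth$mitochondria
  i <- match(paste(rec$fibre_id, rec$label_id), paste(tr$fibre_id, tr$label_id))
  rec$true_class <- tr$true_class[i]
  rec$true_dark_fraction <- tr$dark_fraction[i]
  rec$shape_kind <- tr$shape_kind[i]
  rec
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
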