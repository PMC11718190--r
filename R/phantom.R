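#' Specify a synthetic COX-SBFSEM phantom cohort
#'
#' Describes a cohort of fibre ROIs populated with non-overlapping voxelized
#' mitochondria of known geometry, a three-component per-mitochondrion
#' intensity model on the 0-255 scale, per-fibre class compositions, and a
#' planted spatial class pattern. The defaults emulate the imaging study
#' design at desk scale: isotropic 0.07 um voxels (70 nm sections), three
#' fibre classes in equal proportion, and roughly 150 mitochondria per fibre
#' ROI; see the package vignette for the rationale behind each default.
#'
#' The intensity model plants the enzyme-histochemistry contrast: each
#' mitochondrion draws a target mean intensity from its class component
#' (means ordered normal < intermediate < deficient, since dark = electron
#' dense = high COX activity), which is realised as a per-voxel Bernoulli
#' mixture of dark "precipitate" voxels (below the threshold 50) and light
#' matrix voxels, so the dark-voxel fraction scales with COX class.
#'
#' @param grid_shape voxels per fibre ROI, `(z, y, x)`.
#' @param voxel_size micrometres per voxel, `(z, y, x)`.
#' @param n_fibres number of fibre ROIs.
#' @param fibre_class_mix proportions of normal/intermediate/deficient
#'   fibres (sums to 1).
#' @param shapes_per_fibre inclusive range of mitochondria per fibre.
#' @param fibre_composition 3 x 3 matrix: per fibre class (rows), the
#'   mitochondrial class proportions (columns normal/intermediate/deficient);
#'   each row sums to 1.
#' @param intensity_model list with `mu` (ascending component means),
#'   `sigma` (component sds of per-mitochondrion targets), `dark`, `light`
#'   (precipitate / matrix voxel distributions, mean and sd), `background`
#'   (non-mitochondrial voxels; no measured distribution is available, so the
#'   default is a light, richly textured N(195, 55) emulating sarcoplasm and
#'   myofibril structure — see the vignette).
#' @param spatial_pattern `"segmental"` (classes occupy bands along the x
#'   axis, with the intermediate class as the transition zone between normal
#'   and deficient regions) or `"random"` (classes i.i.d. over positions).
#' @param morphology_coupling couple class to shape menu (deficient favour
#'   spheres, normal favour capsule chains)? Mirrors the observation that
#'   COX-deficient mitochondria tend to be morphologically simpler.
#' @param shape_params ranges (micrometres / radians) for the shape menu.
#' @param class_shape_weights 3 x 3 matrix of shape-kind weights (columns
#'   sphere/ellipsoid/chain) per class; used when `morphology_coupling` is
#'   TRUE, else uniform.
#' @param seed integer seed; identical spec + seed reproduce identical
#'   stacks byte for byte.
#' @param max_retries placement retries per shape before failing.
#' @return a validated `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(80, 96, 96),
                         voxel_size = c(0.07, 0.07, 0.07),
                         n_fibres = 12,
                         fibre_class_mix = c(normal = 1 / 3,
                                             intermediate = 1 / 3,
                                             deficient = 1 / 3),
                         shapes_per_fibre = c(130, 170),
                         fibre_composition = rbind(
                           normal = c(0.75, 0.15, 0.10),
                           intermediate = c(0.15, 0.70, 0.15),
                           deficient = c(0.10, 0.15, 0.75)),
                         intensity_model = list(
                           mu = c(normal = 40, intermediate = 120,
                                  deficient = 200),
                           sigma = c(12, 15, 12),
                           dark = c(mean = 30, sd = 8),
                           light = c(mean = 230, sd = 8),
                           background = c(mean = 195, sd = 55)),
                         spatial_pattern = c("segmental", "random"),
                         morphology_coupling = TRUE,
                         shape_params = list(
                           sphere_r = c(0.16, 0.32),
                           ellipsoid_a = c(0.13, 0.20),
                           ellipsoid_aspect = c(2, 4),
                           chain_r = c(0.11, 0.16),
                           chain_seg_len = c(0.40, 0.70),
                           chain_n_seg = c(2, 4),
                           chain_max_bend = 30 * pi / 180),
                         class_shape_weights = rbind(
                           normal = c(0.15, 0.30, 0.55),
                           intermediate = c(0.35, 0.35, 0.30),
                           deficient = c(0.70, 0.25, 0.05)),
                         seed = 1,
                         max_retries = 1000) {
  spatial_pattern <- match.arg(spatial_pattern)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(voxel_size) == 3, all(voxel_size > 0),
            n_fibres >= 1, length(shapes_per_fibre) == 2,
            shapes_per_fibre[1] >= 1,
            shapes_per_fibre[2] >= shapes_per_fibre[1])
  if (abs(sum(fibre_class_mix) - 1) > 1e-8)
    stop("fibre_class_mix must sum to 1")
  if (any(fibre_class_mix < 0) || any(fibre_class_mix > 1))
    stop("fibre_class_mix proportions must lie in [0, 1]")
  if (any(abs(rowSums(fibre_composition) - 1) > 1e-8))
    stop("each fibre_composition row must sum to 1")
  mu <- intensity_model$mu
  if (length(mu) != 3 || any(diff(mu) <= 0))
    stop("intensity component means must be ascending ",
         "(normal < intermediate < deficient on the 0-255 scale)")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size), n_fibres = n_fibres,
                 fibre_class_mix = fibre_class_mix,
                 shapes_per_fibre = as.integer(shapes_per_fibre),
                 fibre_composition = fibre_composition,
                 intensity_model = intensity_model,
                 spatial_pattern = spatial_pattern,
                 morphology_coupling = morphology_coupling,
                 shape_params = shape_params,
                 class_shape_weights = class_shape_weights,
                 seed = seed, max_retries = max_retries),
            class = "phantom_spec")
}

# integer allocation of n items to proportions p (largest remainder)
alloc_counts <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# random shape of a given kind; geometry relative to the origin,
# positioned later
sample_shape <- function(kind, sp) {
  if (kind == "sphere") {
    r <- runif(1, sp$sphere_r[1], sp$sphere_r[2])
    return(shape_sphere(r, c(0, 0, 0)))
  }
  if (kind == "ellipsoid") {
    a <- runif(1, sp$ellipsoid_a[1], sp$ellipsoid_a[2])
    ar <- runif(1, sp$ellipsoid_aspect[1], sp$ellipsoid_aspect[2])
    u <- rnorm(3)
    return(shape_ellipsoid(a, a * ar, c(0, 0, 0), axis = u))
  }
  r <- runif(1, sp$chain_r[1], sp$chain_r[2])
  nseg <- sample(sp$chain_n_seg[1]:sp$chain_n_seg[2], 1)
  lens <- pmax(runif(nseg, sp$chain_seg_len[1], sp$chain_seg_len[2]), 2 * r)
  bends <- runif(max(nseg - 1, 1), 0, sp$chain_max_bend)
  az <- runif(max(nseg - 1, 1), 0, 2 * pi)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  v <- chain_vertices(c(0, 0, 0), u, lens, bends, az)
  v <- sweep(v, 2, (apply(v, 2, min) + apply(v, 2, max)) / 2)  # centre bbox
  shape_capsule_chain(r, v)
}

# translate a shape so its reference point sits at `pos` (physical x,y,z)
translate_shape <- function(shape, pos) {
  if (shape$kind == "capsule_chain") {
    shape$vertices <- sweep(shape$vertices, 2, pos, "+")
    shape$centre <- colMeans(shape$vertices)
  } else {
    shape$centre <- shape$centre + pos
  }
  shape
}

# half-extent (physical units, x/y/z) of a shape's bounding box
shape_half_extent <- function(shape) {
  bb <- shape_bbox(shape)
  (bb[2, ] - bb[1, ]) / 2
}

#' Generate a phantom cohort with planted ground truth
#'
#' Places non-overlapping shapes by rejection sampling (uniform positions,
#' up to `max_retries` attempts per shape), paints class-conditional
#' intensities over a light background, and returns per-fibre co-registered
#' intensity/label stacks plus truth tables scoring every downstream stage.
#'
#' Under the segmental pattern each class occupies a band along x (normal,
#' then intermediate as the transition zone, then deficient), with band
#' widths proportional to the fibre's class composition.
#'
#' @param spec a [phantom_spec()].
#' @return list with `fibres` (per fibre: `intensity` stack, `labels` stack,
#'   `fibre_id`, `fibre_class`), `truth` (`mitochondria` and `fibres`
#'   data.frames), and the echoed `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  classes <- c("normal", "intermediate", "deficient")
  kinds <- c("sphere", "ellipsoid", "capsule_chain")
  nf <- spec$n_fibres
  fibre_classes <- rep(classes, alloc_counts(nf, spec$fibre_class_mix))
  fibre_classes <- sample(fibre_classes)
  fibre_ids <- sprintf("fibre%02d", seq_len(nf))
  vs <- spec$voxel_size
  ext_phys <- rev((spec$grid_shape - 1) * vs)     # physical extent (x, y, z)
  im <- spec$intensity_model

  shape_weights <- if (spec$morphology_coupling) spec$class_shape_weights else
    matrix(1 / 3, 3, 3, dimnames = list(classes, kinds))

  truth_rows <- list()
  fibres <- vector("list", nf)
  for (fi in seq_len(nf)) {
    fid <- fibre_ids[fi]
    fclass <- fibre_classes[fi]
    comp <- spec$fibre_composition[fclass, ]
    n_shapes <- if (spec$shapes_per_fibre[1] == spec$shapes_per_fibre[2])
      spec$shapes_per_fibre[1] else
      sample(spec$shapes_per_fibre[1]:spec$shapes_per_fibre[2], 1)
    mito_classes <- rep(classes, alloc_counts(n_shapes, comp))
    if (spec$spatial_pattern == "random")
      mito_classes <- sample(mito_classes)
    # x bands per class (segmental): cumulative composition along x
    bands <- cbind(c(0, cumsum(comp)[1:2]), cumsum(comp)) * ext_phys[1]
    rownames(bands) <- classes

    lab <- array(0L, spec$grid_shape)
    placed <- 0L
    for (si in seq_len(n_shapes)) {
      cls <- mito_classes[si]
      kind <- sample(kinds, 1, prob = shape_weights[cls, ])
      ok <- FALSE
      for (try in seq_len(spec$max_retries)) {
        # fresh geometry each attempt: at high packing fractions this lets
        # smaller draws fill the remaining gaps instead of stalling
        proto <- sample_shape(kind, spec$shape_params)
        he <- shape_half_extent(proto)
        lo <- he + vs[3:1]          # one-voxel margin off the border
        hi <- ext_phys - he - vs[3:1]
        if (any(hi <= lo))
          stop("phantom placement failed in ", fid, ": shape of kind '",
               kind, "' is larger than the grid")
        pos <- runif(3, lo, hi)
        if (spec$spatial_pattern == "segmental") {
          # class band drives the x position; clamped so the shape still fits
          bx <- runif(1, bands[cls, 1], bands[cls, 2])
          pos[1] <- min(max(bx, lo[1]), hi[1])
        }
        shape <- translate_shape(proto, pos)
        ras <- tryCatch(rasterize_shape(shape, vs, spec$grid_shape),
                        error = function(e) NULL)
        if (is.null(ras) || nrow(ras$idx) == 0) next
        if (any(lab[ras$idx] != 0L)) next
        placed <- placed + 1L
        lab[ras$idx] <- placed
        ctr <- if (shape$kind == "sphere" || shape$kind == "ellipsoid")
          shape$centre else colMeans(shape$vertices)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          fibre_id = fid, label_id = placed, true_class = cls,
          shape_kind = shape$kind, volume = shape$volume,
          surface_area = shape$surface_area,
          x = ctr[1], y = ctr[2], z = ctr[3],
          voxel_count = nrow(ras$idx), stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("phantom placement failed in ", fid, " after ",
             spec$max_retries, " retries (shape ", si, " of ", n_shapes,
             "); enlarge the grid or reduce shapes_per_fibre")
    }

    # intensities: light background, then class-conditional mitochondria
    nvox <- prod(spec$grid_shape)
    iv <- array(rnorm(nvox, im$background["mean"], im$background["sd"]),
                spec$grid_shape)
    this_truth <- do.call(rbind, truth_rows[
      vapply(truth_rows, function(r) r$fibre_id == fid, TRUE)])
    dark_frac <- numeric(placed)
    for (li in seq_len(placed)) {
      cls_i <- this_truth$true_class[this_truth$label_id == li]
      ki <- match(cls_i, classes)
      # truncated-normal target: rejection keeps the dark fraction strictly
      # inside (0, 1) so no class piles up at a point mass
      t_lo <- im$dark["mean"] + 2
      t_hi <- im$light["mean"] - 2
      repeat {
        target <- rnorm(1, im$mu[ki], im$sigma[ki])
        if (target > t_lo && target < t_hi) break
      }
      f <- (im$light["mean"] - target) /
        (im$light["mean"] - im$dark["mean"])
      dark_frac[li] <- f
      vox <- which(lab == li)
      nb <- length(vox)
      is_dark <- runif(nb) < f
      vals <- ifelse(is_dark,
                     rnorm(nb, im$dark["mean"], im$dark["sd"]),
                     rnorm(nb, im$light["mean"], im$light["sd"]))
      iv[vox] <- vals
    }
    iv <- round_half_up(pmin(pmax(iv, 0), 255))
    idx <- which(vapply(truth_rows, function(r) r$fibre_id == fid, TRUE))
    for (j in seq_along(idx))
      truth_rows[[idx[j]]]$dark_fraction <- dark_frac[
        truth_rows[[idx[j]]]$label_id]

    fibres[[fi]] <- list(
      intensity = intensity_stack(iv, vs, fibre_id = fid),
      labels = label_stack(lab, vs, fibre_id = fid),
      fibre_id = fid, fibre_class = fclass)
  }

  mito_truth <- do.call(rbind, truth_rows)
  rownames(mito_truth) <- NULL
  comp_true <- t(vapply(split(mito_truth, mito_truth$fibre_id), function(r)
    as.numeric(table(factor(r$true_class, levels = classes))) / nrow(r),
    numeric(3)))
  fibre_truth <- data.frame(fibre_id = fibre_ids,
                            true_class = fibre_classes,
                            n_mito = as.integer(table(factor(
                              mito_truth$fibre_id,
                              levels = fibre_ids))),
                            p_normal = comp_true[fibre_ids, 1],
                            p_intermediate = comp_true[fibre_ids, 2],
                            p_deficient = comp_true[fibre_ids, 3],
                            stringsAsFactors = FALSE)
  rownames(fibre_truth) <- NULL
  list(fibres = fibres, truth = list(mitochondria = mito_truth,
                                     fibres = fibre_truth),
       spec = spec)
}

#' Write a generated phantom to disk
#'
#' Emits one 8-bit multi-page intensity TIFF and one label TIFF per fibre,
#' the truth tables as CSV, and the generator specification echoed as JSON.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (f in phantom$fibres) {
    ip <- file.path(dir, paste0(f$fibre_id, "_intensity.tif"))
    lp <- file.path(dir, paste0(f$fibre_id, "_labels.tif"))
    write_stack(f$intensity, ip)
    write_stack(f$labels, lp)
    paths <- c(paths, ip, lp)
  }
  mt <- file.path(dir, "truth_mitochondria.csv")
  ft <- file.path(dir, "truth_fibres.csv")
  write.csv(phantom$truth$mitochondria, mt, row.names = FALSE)
  write.csv(phantom$truth$fibres, ft, row.names = FALSE)
  sp <- file.path(dir, "phantom_spec.json")
  jsonlite::write_json(phantom$spec[setdiff(names(phantom$spec),
                                            "fibre_composition")],
                       sp, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(paths, mt, ft, sp))
}
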