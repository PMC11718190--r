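#' Intensity and label stack containers
#'
#' An intensity stack holds 8-bit-scale grayscale voxels (0 is black /
#' electron dense = high COX activity, 255 = white = none); a label stack
#' holds one non-negative integer instance id per voxel (0 = background).
#' Both are 3D arrays ordered `(z, y, x)` with physical voxel dimensions in
#' micrometres. Normalized intensities are tracked with a provenance flag and
#' may leave the 0-255 range; clamping happens only at TIFF export.
#'
#' @param voxels 3D numeric array `(z, y, x)`.
#' @param voxel_size micrometres per voxel, `(z, y, x)`.
#' @param fibre_id,patient_id identifiers carried through all tables.
#' @param normalized has dataset normalization been applied?
#' @return an `intensity_stack` / `label_stack` object.
#' @name stacks
NULL

#' @rdname stacks
#' @export
intensity_stack <- function(voxels, voxel_size = c(0.07, 0.07, 0.07),
                            fibre_id = "fibre1", patient_id = "P1",
                            normalized = FALSE) {
  stopifnot(length(dim(voxels)) == 3, all(voxel_size > 0),
            length(voxel_size) == 3)
  if (!normalized && (min(voxels) < 0 || max(voxels) > 255))
    stop("raw intensity values must lie in [0, 255]")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 fibre_id = fibre_id, patient_id = patient_id,
                 normalized = normalized),
            class = "intensity_stack")
}

#' @rdname stacks
#' @export
label_stack <- function(voxels, voxel_size = c(0.07, 0.07, 0.07),
                        fibre_id = "fibre1") {
  stopifnot(length(dim(voxels)) == 3, all(voxel_size > 0))
  if (any(voxels < 0) || any(voxels != round(voxels)))
    stop("labels must be non-negative integers")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 fibre_id = fibre_id),
            class = "label_stack")
}

#' Write stacks as multi-page TIFF
#'
#' Intensity stacks are clamped to the 0-255 range, rounded half-up, and written as
#' 8-bit pages (one page per z slice). Label stacks are written 16-bit when
#' the largest label fits, else as 32-bit float scaled by 2^-24 (lossless for
#' integer labels up to 2^24); the scaling is recovered transparently by
#' [load_stack_pair()].
#'
#' @param stack an `intensity_stack` or `label_stack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  v <- stack$voxels
  nz <- dim(v)[1]
  if (inherits(stack, "intensity_stack")) {
    v <- round_half_up(pmin(pmax(v, 0), 255))
    pages <- lapply(seq_len(nz), function(z) v[z, , ] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else if (inherits(stack, "label_stack")) {
    mx <- max(v)
    if (mx <= 65535) {
      pages <- lapply(seq_len(nz), function(z) v[z, , ] / 65535)
      tiff::writeTIFF(pages, path, bits.per.sample = 16)
    } else {
      if (mx > 2^24) stop("labels above 2^24 cannot be stored losslessly")
      pages <- lapply(seq_len(nz), function(z) v[z, , ] / 2^24)
      tiff::writeTIFF(pages, path, bits.per.sample = 32)
    }
  } else stop("not a stack object")
  invisible(path)
}

read_tiff_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8
  scale <- switch(as.character(bits), "8" = 255, "16" = 65535, "32" = 2^24,
                  stop("unsupported TIFF bit depth: ", bits))
  a <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]] * scale
  round_half_up(a)
}

#' Load a co-registered intensity/label stack pair
#'
#' @param intensity_path,label_path multi-page TIFF files.
#' @param voxel_size micrometres per voxel `(z, y, x)`.
#' @param fibre_id,patient_id identifiers attached to the loaded stacks.
#' @return list with elements `intensity` and `labels`.
#' @export
load_stack_pair <- function(intensity_path, label_path,
                            voxel_size = c(0.07, 0.07, 0.07),
                            fibre_id = "fibre1", patient_id = "P1") {
  iv <- read_tiff_array(intensity_path)
  lv <- read_tiff_array(label_path)
  if (!identical(dim(iv), dim(lv)))
    stop("shape mismatch: intensity ", paste(dim(iv), collapse = "x"),
         " vs labels ", paste(dim(lv), collapse = "x"))
  if (any(lv != round(lv)) || any(lv < 0))
    stop("label stack contains non-integer or negative values")
  list(intensity = intensity_stack(iv, voxel_size, fibre_id, patient_id),
       labels = label_stack(lv, voxel_size, fibre_id))
}

#' Dataset-wide intensity normalization
#'
#' Standard EM stack normalization in three steps: compute the dataset-wide
#' target mean `M` and standard deviation `S`, then remap each image affinely
#' so its mean/sd match the targets: `out = (img - m_i) / s_i * S + M`. An
#' "image" is one 2D slice by default (`scope = "slice"`), or a whole stack
#' (`scope = "stack"`). The dataset targets are the unweighted means of the
#' per-image means and sds, which makes the operation exactly idempotent (the
#' remap's fixed point). The map is strictly increasing per image, so
#' within-image intensity ranking is preserved. Values are kept real-valued
#' (no clamping) until export.
#'
#' @param stacks list of `intensity_stack` objects (a whole dataset; stacks
#'   from several patients are normalized together unless split by the
#'   caller).
#' @param scope normalization granularity, `"slice"` or `"stack"`.
#' @return list of normalized `intensity_stack` objects (flagged
#'   `normalized = TRUE`).
#' @export
normalize_dataset <- function(stacks, scope = c("slice", "stack")) {
  scope <- match.arg(scope)
  if (inherits(stacks, "intensity_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1,
            all(vapply(stacks, inherits, TRUE, "intensity_stack")))
  image_stats <- function(s) {
    v <- s$voxels
    if (scope == "stack")
      return(cbind(mean(v), sd(as.numeric(v))))
    t(vapply(seq_len(dim(v)[1]), function(z)
      c(mean(v[z, , ]), sd(as.numeric(v[z, , ]))), numeric(2)))
  }
  st <- do.call(rbind, lapply(stacks, image_stats))
  M <- mean(st[, 1])
  S <- mean(st[, 2])
  lapply(stacks, function(s) {
    v <- s$voxels
    if (scope == "stack") {
      si <- sd(as.numeric(v))
      if (si == 0) stop("zero-variance stack: ", s$fibre_id)
      v <- (v - mean(v)) / si * S + M
    } else {
      for (z in seq_len(dim(v)[1])) {
        sl <- v[z, , ]
        si <- sd(as.numeric(sl))
        if (si == 0)
          stop("zero-variance slice ", z, " in stack ", s$fibre_id)
        v[z, , ] <- (sl - mean(sl)) / si * S + M
      }
    }
    intensity_stack(v, s$voxel_size, s$fibre_id, s$patient_id,
                    normalized = TRUE)
  })
}
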