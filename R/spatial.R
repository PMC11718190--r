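#' Per-fibre mitotype table
#'
#' A fibre's "mitotype" is its position in the plane of mean COX intensity
#' (x) versus mean MCI (y), with standard errors — one summary point per
#' fibre. Note the intensity axis is inverted biology-wise: lower intensity
#' means higher COX activity.
#'
#' @param records classified per-mitochondrion records with `fibre_id`,
#'   `mean_intensity`, `mci` (and optionally `fibre_class` carried through).
#' @return data.frame with one row per fibre: `fibre_id`, `n_mito`,
#'   `mean_intensity`, `sem_intensity`, `mean_mci`, `sem_mci` (SEMs `NA` for
#'   single-mitochondrion fibres).
#' @export
mitotype_table <- function(records) {
  sem <- function(v) if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  rows <- lapply(split(records, records$fibre_id), function(r) {
    data.frame(fibre_id = r$fibre_id[1], n_mito = nrow(r),
               mean_intensity = mean(r$mean_intensity),
               sem_intensity = sem(r$mean_intensity),
               mean_mci = mean(r$mci), sem_mci = sem(r$mci),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 3D class/MCI map export
#'
#' Deterministic plot-ready export of mitochondrion centroids coloured by COX
#' class (fixed colour key: normal = orange, intermediate = light blue,
#' deficient = dark blue) or by MCI; no statistics are computed.
#'
#' @param records records with `x`, `y`, `z` centroids plus `cox_class`
#'   and/or `mci`.
#' @param colour_by `"class"` or `"mci"`.
#' @return data.frame `x, y, z, value, colour` (for MCI colouring, `colour`
#'   is a ramp index in 1..256).
#' @export
class_map_3d <- function(records, colour_by = c("class", "mci")) {
  colour_by <- match.arg(colour_by)
  if (nrow(records) == 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      value = character(), colour = character(),
                      stringsAsFactors = FALSE))
  if (colour_by == "class") {
    key <- c(normal = "#E69F00", intermediate = "#56B4E9",
             deficient = "#0A2472")
    data.frame(x = records$x, y = records$y, z = records$z,
               value = as.character(records$cox_class),
               colour = unname(key[as.character(records$cox_class)]),
               stringsAsFactors = FALSE)
  } else {
    ramp <- grDevices::colorRampPalette(c("#FFF5B1", "#D7301F"))(256)
    rel <- (records$mci - min(records$mci)) /
      max(max(records$mci) - min(records$mci), .Machine$double.eps)
    data.frame(x = records$x, y = records$y, z = records$z,
               value = as.character(round(records$mci, 4)),
               colour = ramp[pmin(256, 1 + floor(rel * 255))],
               stringsAsFactors = FALSE)
  }
}

# k-nearest-neighbour index matrix (n x k). Euclidean distance on physical
# centroids; ties broken deterministically by point order (label id order).
knn_index <- function(centroids, k) {
  n <- nrow(centroids)
  dm <- as.matrix(dist(centroids))
  res <- vapply(seq_len(n), function(i) {
    o <- order(dm[i, ], seq_len(n))    # self first (distance 0), ties by id
    o[o != i][seq_len(k)]
  }, integer(k))
  if (k == 1) matrix(res, ncol = 1) else t(res)
}

# C_obs: mean over points of the fraction of k nearest neighbours sharing the
# point's class; neighbour structure precomputed so the permutation null can
# reuse it.
knn_concordance <- function(nbrs, classes) {
  mean(rowMeans(matrix(classes[nbrs] == rep(classes, ncol(nbrs)),
                       nrow(nbrs), ncol(nbrs))))
}

#' k-nearest-neighbour spatial class concordance within a fibre
#'
#' Quantifies the spatial segregation of COX classes that the 3D maps show
#' qualitatively. This statistic is an extension of the visual neighbourhood
#' analysis, not a reproduction of it: `C_obs` is the mean fraction of each
#' mitochondrion's `k` nearest neighbours (Euclidean distance on physical
#' centroids) sharing its class; the null distribution is built by permuting
#' class labels over the fixed centroids, preserving composition exactly, and
#' `z = (C_obs - mean(null)) / sd(null)`.
#'
#' @param centroids numeric matrix `n x 3` of `(x, y, z)` positions in
#'   micrometres.
#' @param classes class labels, length `n`; at least 2 distinct classes must
#'   be present (else the statistic is undefined and `NA` is returned).
#' @param k neighbour count; needs `n >= k + 1`.
#' @param n_permutations permutation count for the null (>= 100).
#' @param seed integer seed for the permutations.
#' @return list with `c_obs`, `null_mean`, `null_sd`, `z`, `k`,
#'   `n_permutations`, `seed`.
#' @export
spatial_concordance <- function(centroids, classes, k = 6,
                                n_permutations = 1000, seed = 1) {
  centroids <- as.matrix(centroids)
  classes <- as.character(classes)
  n <- nrow(centroids)
  stopifnot(n == length(classes), n_permutations >= 100)
  if (n < k + 1)
    stop("need at least k + 1 = ", k + 1, " mitochondria (got ", n, ")")
  if (length(unique(classes)) < 2)
    return(list(c_obs = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
                z = NA_real_, k = k, n_permutations = n_permutations,
                seed = seed))
  nbrs <- knn_index(centroids, k)
  c_obs <- knn_concordance(nbrs, classes)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i)
    knn_concordance(nbrs, sample(classes)), numeric(1))
  nm <- mean(null)
  ns <- sd(null)
  list(c_obs = c_obs, null_mean = nm, null_sd = ns,
       z = (c_obs - nm) / ns, k = k, n_permutations = n_permutations,
       seed = seed)
}

#' Spatial concordance for every fibre of a classified table
#'
#' Each fibre gets its own reproducible seed derived from the run seed and
#' the fibre id (recorded in the output).
#'
#' @param records classified records with `fibre_id`, `x`, `y`, `z`,
#'   `cox_class`.
#' @param k,n_permutations see [spatial_concordance()].
#' @param seed run seed fanned out per fibre via [derive_seed()].
#' @return data.frame with one row per fibre (`NA` statistics for fibres
#'   with fewer than `k + 1` mitochondria or a single class).
#' @export
concordance_by_fibre <- function(records, k = 6, n_permutations = 1000,
                                 seed = 1) {
  rows <- lapply(split(records, records$fibre_id), function(r) {
    fseed <- derive_seed(seed, paste0("concordance-", r$fibre_id[1]))
    res <- if (nrow(r) < k + 1)
      list(c_obs = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
           z = NA_real_, k = k, n_permutations = n_permutations, seed = fseed)
    else
      spatial_concordance(as.matrix(r[, c("x", "y", "z")]), r$cox_class,
                          k = k, n_permutations = n_permutations, seed = fseed)
    data.frame(fibre_id = r$fibre_id[1], n_mito = nrow(r),
               c_obs = res$c_obs, null_mean = res$null_mean,
               null_sd = res$null_sd, z = res$z, k = k,
               n_permutations = n_permutations, seed = fseed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
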