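#' Fit a three-component Gaussian mixture to mean COX intensities
#'
#' Maximum-likelihood univariate mixture of three Gaussians fitted by
#' expectation-maximization, best of `n_restarts` initializations (one
#' quantile-based start plus randomized starts drawn from the data range).
#' Components are relabelled by ascending mean, which on the COX intensity
#' scale means component 1 = COX-normal (darkest), 2 = COX-intermediate,
#' 3 = COX-deficient. Intersection thresholds between adjacent weighted
#' component densities are attached (see [intersection_thresholds()]).
#'
#' Component standard deviations are floored at `1e-3` of the data range;
#' a restart whose fit collapses (vanishing weight or non-finite likelihood)
#' is discarded. The mixture is intended to be fitted per patient/dataset,
#' not per fibre.
#'
#' @param x numeric vector of per-mitochondrion mean intensities in
#'   `[0, 255]`; at least 30 values.
#' @param seed integer seed controlling the randomized restarts.
#' @param n_restarts number of initializations.
#' @param max_iter EM iteration cap per restart.
#' @param tol stop when the log-likelihood gain drops below this.
#' @return a `mixture_fit` with `components` (weight/mean/sd, ascending
#'   mean), `thresholds` `(t1, t2)`, `log_likelihood`, `n_points`, `seed`,
#'   `n_restarts`.
#' @export
fit_gmm3 <- function(x, seed = 1, n_restarts = 20, max_iter = 500,
                     tol = 1e-8) {
  x <- as.numeric(x)
  if (length(x) < 30)
    stop("need at least 30 data points to fit 3 components (got ",
         length(x), ")")
  # normalized stacks are clamped only at export, so per-mitochondrion means
  # may overshoot the nominal 8-bit range a little; reject only gross misuse
  if (min(x) < -25.5 || max(x) > 280.5)
    stop("intensities must lie on the 0-255 scale")
  rng <- diff(range(x))
  if (rng == 0) stop("all intensities identical; mixture undefined")
  sd_floor <- 1e-3 * rng

  em_run <- function(mu, sigma, w) {
    res <- cpp_gmm_em(x, mu, sigma, w, as.integer(max_iter), tol, sd_floor)
    if (res[11] < 0) return(NULL)    # degenerate run
    list(w = res[1:3], mu = res[4:6], sigma = res[7:9], ll = res[10])
  }

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    if (rs == 1) {
      mu <- as.numeric(quantile(x, c(1, 3, 5) / 6))
      sigma <- rep(max(sd(x) / 3, sd_floor), 3)
      w <- rep(1 / 3, 3)
    } else {
      set.seed(derive_seed(seed, paste0("gmm-restart-", rs)))
      mu <- sort(runif(3, min(x), max(x)))
      sigma <- rep(max(sd(x) / 2, sd_floor), 3)
      w <- rep(1 / 3, 3)
    }
    fit <- em_run(mu, sigma, w)
    if (is.null(fit)) next
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  if (is.null(best))
    stop("all EM restarts degenerated; the data may not support 3 components")

  o <- order(best$mu)
  comps <- data.frame(component = c("normal", "intermediate", "deficient"),
                      weight = best$w[o], mean = best$mu[o],
                      sd = best$sigma[o], stringsAsFactors = FALSE)
  fit <- structure(list(components = comps, thresholds = c(NA_real_, NA_real_),
                        log_likelihood = best$ll, n_points = length(x),
                        seed = seed, n_restarts = n_restarts),
                   class = "mixture_fit")
  fit$thresholds <- intersection_thresholds(fit)
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("3-component Gaussian mixture on COX intensity (n =", x$n_points, ")\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("thresholds: t1 = %.3f, t2 = %.3f; logLik = %.2f\n",
              x$thresholds[1], x$thresholds[2], x$log_likelihood))
  invisible(x)
}

# weighted component density w_k * N(x | mu_k, sd_k)
wdens <- function(fit, k, x)
  fit$components$weight[k] * dnorm(x, fit$components$mean[k],
                                   fit$components$sd[k])

# intersection of weighted densities of components a, b (mu_a < mu_b),
# solved from the log-density quadratic; NA when no root lies between means
pair_intersection <- function(w1, m1, s1, w2, m2, s2) {
  if (abs(s1 - s2) < 1e-12) {
    # equal variances: the quadratic degenerates to a line
    t <- (m1 + m2) / 2 + s1^2 * log(w1 / w2) / (m2 - m1)
    if (t > m1 && t < m2) return(t)
    return(NA_real_)
  }
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(w1 * s2 / (w2 * s1))
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NA_real_)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  roots <- roots[roots > m1 & roots < m2]
  if (length(roots) == 0) return(NA_real_)
  roots[1]
}

#' Class thresholds from adjacent component intersections
#'
#' `t1` solves `w1 phi(x | mu1, sd1) = w2 phi(x | mu2, sd2)` strictly between
#' the normal and intermediate means; `t2` likewise between intermediate and
#' deficient. Solved in closed form from the log-density quadratic; if no
#' root lies between the means (pathological overlap) a 0.001-step grid
#' search minimizing the absolute density difference is used, with a warning.
#'
#' @param fit a `mixture_fit`.
#' @return numeric `(t1, t2)` with `mu1 < t1 < mu2 < t2 < mu3`.
#' @export
intersection_thresholds <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  cp <- fit$components
  solve_pair <- function(a, b) {
    t <- pair_intersection(cp$weight[a], cp$mean[a], cp$sd[a],
                           cp$weight[b], cp$mean[b], cp$sd[b])
    if (is.na(t)) {
      warning("no density intersection strictly between component means ",
              a, " and ", b, "; falling back to grid search")
      grid <- seq(cp$mean[a], cp$mean[b], by = 0.001)
      t <- grid[which.min(abs(wdens(fit, a, grid) - wdens(fit, b, grid)))]
    }
    t
  }
  c(t1 = solve_pair(1, 2), t2 = solve_pair(2, 3))
}

#' Posterior component membership probabilities
#'
#' Emitted for QC alongside the hard threshold classification: intersection
#' thresholds keep every mitochondrion classified, and the posterior
#' quantifies the uncertainty near the class boundaries.
#'
#' @param fit a `mixture_fit`.
#' @param x intensities.
#' @return matrix `length(x) x 3`, columns normal/intermediate/deficient.
#' @export
gmm_posterior <- function(fit, x) {
  cp <- fit$components
  d <- vapply(1:3, function(k) wdens(fit, k, x), numeric(length(x)))
  out <- d / rowSums(d)
  colnames(out) <- cp$component
  out
}

#' Hard COX class assignment from intensity thresholds
#'
#' `intensity < t1` is COX-normal, `t1 <= intensity < t2` COX-intermediate,
#' `intensity >= t2` COX-deficient (half-open intervals; every mitochondrion
#' receives exactly one class).
#'
#' @param x mean intensities.
#' @param thresholds numeric `(t1, t2)` with `t1 < t2`, e.g. from a
#'   `mixture_fit`.
#' @return factor with levels `normal`, `intermediate`, `deficient`.
#' @export
assign_classes <- function(x, thresholds) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  cls <- ifelse(x < thresholds[1], "normal",
                ifelse(x < thresholds[2], "intermediate", "deficient"))
  factor(cls, levels = c("normal", "intermediate", "deficient"))
}

#' Fibre class from its mitochondrial class composition
#'
#' A fibre takes the class held by a strict majority (> 50%) of its
#' mitochondria. When no class exceeds 50% the plurality winner is returned
#' but flagged `unresolved_majority`; an exact tie for the plurality yields
#' class `"unresolved"`.
#'
#' @param proportions numeric length 3 `(normal, intermediate, deficient)`,
#'   non-negative, summing to 1.
#' @return list with `class` (character) and `unresolved_majority` (logical).
#' @export
classify_fibre <- function(proportions) {
  stopifnot(length(proportions) == 3, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-8)
  classes <- c("normal", "intermediate", "deficient")
  mx <- max(proportions)
  if (mx > 0.5)
    return(list(class = classes[which.max(proportions)],
                unresolved_majority = FALSE))
  winners <- which(abs(proportions - mx) < 1e-12)
  if (length(winners) > 1)
    return(list(class = "unresolved", unresolved_majority = TRUE))
  list(class = classes[winners], unresolved_majority = TRUE)
}

#' Percentage of COX-deficient mitochondria that are spherical
#'
#' Spherical means Wadell sphericity at or above `cutoff` (default 0.75).
#' The denominator is all COX-deficient mitochondria (they represent 100%).
#'
#' @param records data.frame with columns `cox_class` and `sphericity`.
#' @param cutoff sphericity cutoff defining "spherical".
#' @param class which COX class to profile (default `"deficient"`).
#' @return percentage in `[0, 100]`, or `NA` (with a warning) when the class
#'   is empty.
#' @export
percent_spherical_deficient <- function(records, cutoff = 0.75,
                                        class = "deficient") {
  sel <- records$cox_class == class
  if (!any(sel)) {
    warning("no mitochondria of class '", class,
            "'; spherical percentage undefined")
    return(NA_real_)
  }
  100 * mean(records$sphericity[sel] >= cutoff)
}

#' Per-fibre composition, class and summary statistics
#'
#' Aggregates classified per-mitochondrion records into one row per fibre:
#' class proportions, the majority-rule fibre class (see [classify_fibre()]),
#' mean and SEM of COX intensity and of MCI (`SEM = sd / sqrt(n)`; `NA` for
#' single-mitochondrion fibres), and the percentage of the fibre's
#' COX-deficient mitochondria that are spherical.
#'
#' @param records data.frame with columns `fibre_id`, `mean_intensity`,
#'   `mci`, `sphericity`, `cox_class`.
#' @param sphericity_cutoff passed to [percent_spherical_deficient()].
#' @return data.frame, one row per fibre.
#' @export
fibre_summary <- function(records, sphericity_cutoff = 0.75) {
  stopifnot(all(c("fibre_id", "mean_intensity", "mci", "cox_class")
                %in% names(records)))
  sem <- function(v) if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  rows <- lapply(split(records, records$fibre_id), function(r) {
    p <- as.numeric(table(factor(r$cox_class,
                                 levels = c("normal", "intermediate",
                                            "deficient")))) / nrow(r)
    fc <- classify_fibre(p)
    psd <- if ("sphericity" %in% names(r) && any(r$cox_class == "deficient"))
      percent_spherical_deficient(r, sphericity_cutoff) else NA_real_
    data.frame(fibre_id = r$fibre_id[1], n_mito = nrow(r),
               p_normal = p[1], p_intermediate = p[2], p_deficient = p[3],
               fibre_class = fc$class,
               unresolved_majority = fc$unresolved_majority,
               mean_intensity = mean(r$mean_intensity),
               sem_intensity = sem(r$mean_intensity),
               mean_mci = mean(r$mci), sem_mci = sem(r$mci),
               percent_spherical_deficient = psd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
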