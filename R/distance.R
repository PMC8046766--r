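#' Euclidean distance matrix
#'
#' Pairwise Euclidean distances between sample rows, the dissimilarity the
#' comparator (distance-based) track operates on. Computed through
#' [vegan::vegdist()]; missing values are an explicit error rather than
#' being silently imputed.
#'
#' @param data numeric matrix/data frame, samples in rows.
#' @return a `dist` object (symmetric, zero diagonal) with sample labels.
#' @export
euclidean_distances <- function(data) {
  data <- as.matrix(data)
  if (any(!complete.cases(data)))
    stop("missing values in data; remove or impute explicitly",
         call. = FALSE)
  vegan::vegdist(data, method = "euclidean")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the sum of
#' squared inter-point dissimilarities into between- and within-group
#' components and forms the pseudo-F statistic
#' `(SS_between / (a-1)) / (SS_within / (n-a))`, with a permutation p-value
#' from `B` random reassignments of the group labels (via
#' [vegan::adonis2()]). On one-dimensional Euclidean data the pseudo-F
#' equals the classical one-way ANOVA F. Note PERMANOVA assumes
#' homogeneous multivariate dispersion — check with [dispersion_test()].
#'
#' @param dist a `dist` object, e.g. from [euclidean_distances()].
#' @param groups group (site) labels.
#' @param B number of permutations (default 999).
#' @param seed optional integer seed.
#' @return An object of class `permanova_result`: `pseudo_F`, `df_between`,
#'   `df_within`, `p_value`, `n_permutations`, `table` (the adonis2 table).
#' @export
permanova <- function(dist, groups, B = 999, seed = NULL) {
  stopifnot(inherits(dist, "dist"))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tabulate(g, nlevels(g)) < 1)) stop("empty group", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(g = g)
  tab <- vegan::adonis2(dist ~ g, data = df, permutations = B)
  Fv <- tab$F[1]
  pv <- tab$`Pr(>F)`[1]
  if (!is.finite(Fv)) {          # degenerate: zero total sum of squares
    Fv <- 0
    pv <- 1
  }
  structure(list(pseudo_F = Fv, df_between = tab$Df[1],
                 df_within = tab$Df[2], p_value = pv, n_permutations = B,
                 table = as.data.frame(tab)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F(%d,%d) = %.2f, P = %.4g (B = %d)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Multivariate dispersion homogeneity test
#'
#' Tests equality of multivariate spread between groups (the assumption
#' PERMANOVA relies on): the distance matrix is embedded by principal
#' coordinates, each sample's distance to its group centroid is computed
#' combining real and imaginary axes as `sqrt(max(0, d_real^2 - d_imag^2))`
#' (negative-eigenvalue handling), and a one-way ANOVA F with df
#' `(a-1, n-a)` is applied to those distances (via [vegan::betadisper()]
#' with centroids, not spatial medians, so the result is deterministic).
#' A significant result (P < 0.05) indicates unequal dispersion, so
#' location tests on the same distances may be misleading.
#'
#' @inheritParams permanova
#' @return An object of class `dispersion_result`: `F_stat`, `df_between`,
#'   `df_within`, `p_value`, `distances` (per-sample distance to group
#'   centroid).
#' @export
dispersion_test <- function(dist, groups) {
  stopifnot(inherits(dist, "dist"))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  n <- attr(dist, "Size")
  if (max(dist) < 1e-12) {       # all points identical: zero dispersion
    return(structure(list(F_stat = 0, df_between = nlevels(g) - 1,
                          df_within = n - nlevels(g), p_value = 1,
                          distances = rep(0, n)),
                     class = "dispersion_result"))
  }
  bd <- vegan::betadisper(dist, g, type = "centroid")
  an <- anova(bd)
  structure(list(F_stat = an$`F value`[1], df_between = an$Df[1],
                 df_within = an$Df[2], p_value = an$`Pr(>F)`[1],
                 distances = bd$distances),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_test> F(%d,%d) = %.3f, P = %.4g%s\n",
              x$df_between, x$df_within, x$F_stat, x$p_value,
              if (is.finite(x$p_value) && x$p_value < 0.05)
                "  [dispersion differs: PERMANOVA/nMDS may mislead]"
              else ""))
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal nMDS of a distance matrix: a `k`-dimensional configuration
#' minimising stress-1 with monotone regression of configuration distances
#' on input dissimilarities, initialised from classical (metric) scaling
#' and refined by [MASS::isoMDS()]. Stress is returned as a fraction
#' (the conventional 0.12 means 12%).
#'
#' @param dist a `dist` object with strictly positive off-diagonal entries.
#' @param k number of dimensions (default 2).
#' @param seed optional integer seed (kept for interface symmetry; the
#'   optimisation itself is deterministic from the metric-scaling start).
#' @return An object of class `nmds_result`: `points` (n x k configuration),
#'   `stress` (fraction), `converged`.
#' @export
nmds <- function(dist, k = 2, seed = NULL) {
  stopifnot(inherits(dist, "dist"))
  n <- attr(dist, "Size")
  if (k < 1 || n <= k + 1) stop("need n > k + 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- MASS::isoMDS(dist, k = k, maxit = 200, trace = FALSE, tol = 1e-6)
  structure(list(points = fit$points, stress = fit$stress / 100,
                 converged = TRUE),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds> %d points in %d dims, stress = %.2f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}
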