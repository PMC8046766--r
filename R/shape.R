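# Outline-based otolith shape quantification: smoothing, polar radii,
# periodic orthonormal discrete wavelet transform, variance accounting,
# fish-length standardisation and per-site mean shapes.

# Orthonormal scaling filters. "sym4" = Daubechies least-asymmetric,
# order 4 (standard published taps); "haar" for degenerate/test cases.
.dwt_filters <- function(wavelet = c("sym4", "haar")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    sym4 = c(-0.07576571478927333, -0.02963552764599851,
              0.49761866763201545,  0.80373875180591614,
              0.29785779560527736, -0.09921954357684722,
             -0.01260396726203783,  0.03222310060404270),
    haar = c(1, 1) / sqrt(2))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature-mirror high-pass
  list(h = h, g = g, L = L)
}

# one analysis step, periodic boundary: x (even length) -> approx, detail
.dwt_step <- function(x, flt) {
  N <- length(x)
  k2 <- seq.int(0L, N - 2L, by = 2L)
  a <- d <- numeric(N / 2)
  for (n in seq_len(flt$L)) {
    xi <- x[((k2 + n - 1L) %% N) + 1L]
    a <- a + flt$h[n] * xi
    d <- d + flt$g[n] * xi
  }
  list(a = a, d = d)
}

# one synthesis step (transpose of the orthogonal analysis matrix)
.idwt_step <- function(a, d, flt) {
  N <- 2L * length(a)
  k2 <- seq.int(0L, N - 2L, by = 2L)
  x <- numeric(N)
  for (n in seq_len(flt$L)) {
    idx <- ((k2 + n - 1L) %% N) + 1L
    contrib <- flt$h[n] * a + flt$g[n] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

# full decomposition to length-1 approx; details listed coarsest first
.dwt_full <- function(x, wavelet = "sym4") {
  N <- length(x)
  depth <- as.integer(round(log2(N)))
  if (2^depth != N) stop("length must be a power of 2", call. = FALSE)
  flt <- .dwt_filters(wavelet)
  details <- vector("list", depth)
  a <- x
  for (lev in seq_len(depth)) {
    st <- .dwt_step(a, flt)
    a <- st$a
    details[[depth - lev + 1L]] <- st$d   # store coarsest first
  }
  list(approx = a, details = details, depth = depth, wavelet = wavelet)
}

.idwt_full <- function(decomp) {
  flt <- .dwt_filters(decomp$wavelet)
  a <- decomp$approx
  for (lev in seq_len(decomp$depth))
    a <- .idwt_step(a, decomp$details[[lev]], flt)
  a
}

#' Smooth a closed outline
#'
#' Removes high-frequency pixel noise by iterated neighbour averaging on
#' the closed polygon: each iteration replaces every point with the mean of
#' itself and its two neighbours. The default 100 iterations matches
#' standard otolith practice.
#'
#' @param outline two-column matrix/data frame of (x, y) vertices in order;
#'   a duplicated closing point is tolerated and preserved.
#' @param iterations number of smoothing passes (0 = identity).
#' @return the smoothed outline, same shape as the input.
#' @export
smooth_outline <- function(outline, iterations = 100) {
  xy <- .as_outline(outline)
  closed_dup <- attr(xy, "closed_dup")
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  n <- nrow(xy)
  if (n < 3) stop("outline needs at least 3 distinct points", call. = FALSE)
  prev <- c(n, seq_len(n - 1))
  nxt <- c(seq_len(n)[-1], 1)
  for (i in seq_len(iterations)) xy <- (xy + xy[prev, ] + xy[nxt, ]) / 3
  .restore_outline(xy, outline, closed_dup)
}

.as_outline <- function(outline) {
  xy <- as.matrix(outline[, 1:2])
  storage.mode(xy) <- "double"
  closed_dup <- nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])
  if (closed_dup) xy <- xy[-nrow(xy), , drop = FALSE]
  structure(xy, closed_dup = closed_dup)
}

.restore_outline <- function(xy, original, closed_dup) {
  attr(xy, "closed_dup") <- NULL
  if (closed_dup) xy <- rbind(xy, xy[1, ])
  colnames(xy) <- colnames(original)[1:2] %||% c("x", "y")
  xy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# area-weighted polygon centroid
.polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-300) return(colMeans(xy))
  c(sum((x + xn) * cr) / (6 * A), sum((y + yn) * cr) / (6 * A))
}

# even-odd ray-casting point-in-polygon test
.point_in_polygon <- function(pt, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < (xn - x) * (pt[2] - y) / (yn - y) + x)
  sum(crosses) %% 2 == 1
}

#' Extract centroid-centred radii from an outline
#'
#' Samples the outline's centroid-radius function at `n_angles` equally
#' spaced angles by linear interpolation along the polygon, with the
#' angular origin anchored at the point farthest from the centroid
#' (deterministic rotation registration across fish). The outline must be
#' star-shaped about its centroid.
#'
#' @param outline two-column (x, y) outline.
#' @param n_angles number of sampled angles; a power of 2 (default 512) so
#'   the radii feed directly into [wavelet_coefficients()].
#' @return numeric vector of `n_angles` radii; the anchor angle is stored
#'   in attribute `"origin_angle"`.
#' @export
extract_radii <- function(outline, n_angles = 512) {
  xy <- .as_outline(outline)
  if (nrow(xy) < 8) stop("outline has too few points", call. = FALSE)
  ctr <- .polygon_centroid(xy)
  if (!.point_in_polygon(ctr, xy))
    stop("centroid lies outside the outline (not star-shaped); ",
         "smooth the outline or supply a simpler contour", call. = FALSE)
  dx <- xy[, 1] - ctr[1]; dy <- xy[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  th0 <- th[which.max(r)]
  t <- (th - th0) %% (2 * pi)
  o <- order(t)
  t <- t[o]; r <- r[o]
  # close the angular domain for wrap-around interpolation
  tt <- c(t[length(t)] - 2 * pi, t, t[1] + 2 * pi)
  rr <- c(r[length(r)], r, r[1])
  out <- approx(tt, rr, xout = 2 * pi * (seq_len(n_angles) - 1) / n_angles,
                ties = mean)$y
  structure(out, origin_angle = th0, centroid = ctr)
}

#' Wavelet coefficients of an outline's radius function
#'
#' Full periodic orthonormal discrete wavelet transform of the sampled
#' radii, retaining the coarsest detail levels. For 512 radii the default
#' keeps the 6 coarsest detail levels — 1+2+4+8+16+32 = 63 coefficients —
#' while the level-9 scaling coefficient (pure size) is stored separately
#' and excluded from between-site testing.
#'
#' @param radii numeric vector, length a power of 2 (e.g. from
#'   [extract_radii()]).
#' @param n_detail number of detail coefficients to retain; must be
#'   `2^m - 1` (whole coarsest levels). Default 63.
#' @param wavelet `"sym4"` (default) or `"haar"`.
#' @return An object of class `shape_coeffs`: `detail` (named length-
#'   `n_detail` vector, coarsest level first), `scaling` (the size
#'   coefficient), `n`, `depth`, `n_levels`, `wavelet`.
#' @export
wavelet_coefficients <- function(radii, n_detail = 63, wavelet = "sym4") {
  dec <- .dwt_full(as.numeric(radii), wavelet)
  m <- log2(n_detail + 1)
  if (abs(m - round(m)) > 1e-9 || m < 1 || m > dec$depth)
    stop("n_detail must be 2^m - 1 with m <= log2(length(radii))",
         call. = FALSE)
  m <- as.integer(round(m))
  kept <- dec$details[seq_len(m)]
  lev_id <- rep(seq_len(m), lengths(kept))
  detail <- unlist(kept, use.names = FALSE)
  names(detail) <- sprintf("w%d.%d", lev_id,
                           unlist(lapply(lengths(kept), seq_len)))
  structure(list(detail = detail, scaling = dec$approx,
                 n = length(radii), depth = dec$depth, n_levels = m,
                 wavelet = wavelet),
            class = "shape_coeffs")
}

# radii reconstruction from retained coefficients (finer details zeroed)
.reconstruct_radii <- function(coeffs, detail = coeffs$detail,
                               scaling = coeffs$scaling) {
  depth <- coeffs$depth
  details <- lapply(seq_len(depth), function(l) numeric(2^(l - 1)))
  pos <- 1L
  for (l in seq_len(coeffs$n_levels)) {
    len <- 2^(l - 1)
    details[[l]] <- detail[pos:(pos + len - 1)]
    pos <- pos + len
  }
  .idwt_full(list(approx = scaling, details = details, depth = depth,
                  wavelet = coeffs$wavelet))
}

#' Fraction of radius variance captured by retained coefficients
#'
#' Reconstructs the radii from the retained wavelet coefficients (finer
#' details zero-filled) and returns
#' `1 - var(residual) / var(radii about their mean)`. With the full
#' coefficient set this is exactly 1 (perfect reconstruction); smooth
#' otolith-like outlines exceed 0.99 with the default 63 coefficients.
#'
#' @param radii the radii the coefficients were computed from.
#' @param coeffs the matching [wavelet_coefficients()] object.
#' @return the explained-variance fraction, or `NA` (with a warning and
#'   attribute `undefined = TRUE`) for zero-variance radii.
#' @export
variance_explained <- function(radii, coeffs) {
  stopifnot(inherits(coeffs, "shape_coeffs"))
  if (length(radii) != coeffs$n)
    stop("radii length does not match coefficients", call. = FALSE)
  v <- var(as.numeric(radii))
  if (v == 0) {
    warning("zero-variance radii: explained fraction undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  rec <- .reconstruct_radii(coeffs)
  1 - var(as.numeric(radii) - rec) / v
}

#' Standardise shape coefficients for fish length
#'
#' Removes the allometric length effect from every coefficient: with
#' `b_j` the pooled within-site regression slope of coefficient `j` on
#' total length `L`, the standardised value is
#' `c_std = c - b_j (L - mean(L))`. After standardisation the pooled
#' within-site correlation of every coefficient with length is zero.
#'
#' @param coeffs numeric matrix, fish in rows, wavelet coefficients in
#'   columns (>= 3 fish).
#' @param lengths positive total lengths (mm), one per fish.
#' @param sites optional site labels; with sites, slopes are pooled
#'   within-site so site mean-shape differences are not removed.
#' @return the standardised matrix, with attributes `slopes` (per-column
#'   `b_j`) and `standardised = TRUE`. Constant lengths skip
#'   standardisation with a warning.
#' @export
length_standardise <- function(coeffs, lengths, sites = NULL) {
  coeffs <- as.matrix(coeffs)
  n <- nrow(coeffs)
  if (n < 3) stop("need >= 3 fish", call. = FALSE)
  if (length(lengths) != n) stop("lengths/coeffs mismatch", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (is.null(sites)) sites <- rep(1L, n)
  g <- factor(sites)
  Lc <- lengths - ave(lengths, g)            # within-site centred length
  ssx <- sum(Lc^2)
  if (ssx < 1e-12) {
    warning("lengths are constant (within sites): standardisation skipped")
    attr(coeffs, "slopes") <- rep(0, ncol(coeffs))
    attr(coeffs, "standardised") <- FALSE
    return(coeffs)
  }
  Cc <- coeffs - apply(coeffs, 2, function(cc) ave(cc, g))
  slopes <- colSums(Cc * Lc) / ssx
  out <- coeffs - outer(lengths - mean(lengths), slopes)
  dimnames(out) <- dimnames(coeffs)
  attr(out, "slopes") <- slopes
  attr(out, "standardised") <- TRUE
  out
}

#' Per-site mean shapes from wavelet coefficients
#'
#' Averages the retained wavelet coefficients (and the scaling/size
#' coefficient) over the fish of each site and reconstructs the mean
#' outline by the inverse transform, mirroring mean-shape plots used to
#' visualise stock differences.
#'
#' @param coeffs_list list of [wavelet_coefficients()] objects, one per
#'   fish (identical structure).
#' @param sites site label per fish.
#' @return named list (one element per site) of data frames with columns
#'   `angle`, `radius`, `x`, `y` describing the closed mean outline.
#' @export
mean_shape <- function(coeffs_list, sites) {
  stopifnot(length(coeffs_list) == length(sites),
            all(vapply(coeffs_list, inherits, TRUE, "shape_coeffs")))
  proto <- coeffs_list[[1]]
  g <- factor(sites)
  D <- t(vapply(coeffs_list, function(cf) cf$detail,
                numeric(length(proto$detail))))
  s <- vapply(coeffs_list, function(cf) cf$scaling, 0)
  out <- lapply(levels(g), function(lv) {
    i <- which(g == lv)
    r <- .reconstruct_radii(proto, detail = colMeans(D[i, , drop = FALSE]),
                            scaling = mean(s[i]))
    ang <- 2 * pi * (seq_along(r) - 1) / length(r)
    data.frame(angle = ang, radius = r,
               x = r * cos(ang), y = r * sin(ang))
  })
  names(out) <- levels(g)
  out
}

#' Map signed coefficients to strict positivity
#'
#' Gamma-family modelling needs strictly positive responses, but raw
#' wavelet detail coefficients are signed. Two configurable mappings:
#' `"shift"` (default) applies, to each column whose minimum is not
#' positive, an affine shift to its observed support plus `eps`;
#' `"abs"` takes absolute magnitudes (floored at `eps`).
#'
#' @param coeffs numeric matrix of coefficients (fish x coefficient).
#' @param method `"shift"` or `"abs"`.
#' @param eps small positive offset guaranteeing strict positivity.
#' @return positive matrix with attributes `positivity_method` and
#'   `already_positive` (logical per column).
#' @export
shift_to_positive <- function(coeffs, method = c("shift", "abs"),
                              eps = 1e-3) {
  method <- match.arg(method)
  coeffs <- as.matrix(coeffs)
  mins <- apply(coeffs, 2, min)
  ok <- mins > 0
  out <- switch(method,
    shift = sweep(coeffs, 2, ifelse(ok, 0, mins - eps), "-"),
    abs = pmax(abs(coeffs), eps))
  dimnames(out) <- dimnames(coeffs)
  attr(out, "positivity_method") <- method
  attr(out, "already_positive") <- ok
  out
}

#' @export
print.shape_coeffs <- function(x, ...) {
  cat(sprintf(
    "<shape_coeffs> %d detail coefficients (%d coarsest levels of a %d-point %s transform), scaling = %.4g\n",
    length(x$detail), x$n_levels, x$n, x$wavelet, x$scaling))
  invisible(x)
}
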