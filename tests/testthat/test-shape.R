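# Outline smoothing, polar radii, wavelet coefficients, standardisation.

test_that("wavelet transform reconstructs perfectly from the full set", {
  set.seed(30)
  r <- exp(rnorm(512, 0, 0.2)) + 2
  full <- wavelet_coefficients(r, n_detail = 511)
  rec <- otostock:::.reconstruct_radii(full)
  expect_equal(rec, r, tolerance = 1e-10)
  expect_equal(variance_explained(r, full), 1, tolerance = 1e-10)
  # and for the Haar basis too
  fullh <- wavelet_coefficients(r, n_detail = 511, wavelet = "haar")
  expect_equal(otostock:::.reconstruct_radii(fullh), r, tolerance = 1e-10)
})

test_that("constant radii have zero detail coefficients", {
  cf <- wavelet_coefficients(rep(3, 512))
  expect_lt(max(abs(cf$detail)), 1e-9)
  expect_equal(cf$scaling * 2^(-9 / 2), 3, tolerance = 1e-10)
  v <- suppressWarnings(variance_explained(rep(3, 512), cf))
  expect_true(is.na(v))
  expect_true(attr(v, "undefined"))
})

test_that("retained coefficients explain >99% of a smooth outline", {
  # low-order harmonic perturbation of an ellipse, the synthetic stand-in
  # for an otolith outline
  th <- 2 * pi * (0:511) / 512
  r <- 2 * (1 + 0.15 * cos(2 * th) + 0.06 * cos(3 * th) +
              0.03 * sin(5 * th))
  cf <- wavelet_coefficients(r)
  expect_length(cf$detail, 63)
  expect_gt(variance_explained(r, cf), 0.99)
})

test_that("non-power-of-2 or bad retention sizes are rejected", {
  expect_error(wavelet_coefficients(rep(1, 500)), "power of 2")
  expect_error(wavelet_coefficients(rep(1, 512), n_detail = 60), "2\\^m")
})

test_that("smoothing preserves circles, kills spikes, and 0 iterations is identity", {
  circ <- make_ellipse(1, 1, n = 512)
  sm <- smooth_outline(circ, 100)
  r <- sqrt(rowSums(sm^2))
  expect_true(all(abs(r - 1) < 0.01))          # shrinkage < 1% of radius
  expect_identical(smooth_outline(circ, 0), circ)

  spiked <- circ
  spiked[100, ] <- spiked[100, ] * 2            # radial spike of height 1
  sm2 <- smooth_outline(spiked, 100)
  spike_amp <- max(abs(sqrt(rowSums(sm2^2)) - mean(sqrt(rowSums(sm2^2)))))
  expect_lt(spike_amp, 0.1)                     # > 90% reduction
  expect_error(smooth_outline(circ[1:2, ]), "3 distinct")
})

test_that("radii extraction matches closed forms and is translation invariant", {
  circ <- make_ellipse(1, 1, n = 2048)
  r <- extract_radii(circ)
  expect_true(all(abs(r - 1) < 1e-3))

  shifted <- sweep(circ, 2, c(12, -7), "+")
  expect_equal(as.numeric(extract_radii(shifted)), as.numeric(r),
               tolerance = 1e-9)

  ell <- make_ellipse(2, 1, n = 4096)
  re <- extract_radii(ell)
  th <- 2 * pi * (0:511) / 512    # origin anchored at the major axis
  expect_true(all(abs(re - 2 * 1 / sqrt((cos(th))^2 + (2 * sin(th))^2))
                  < 1e-2))
  # non-star-shaped input: centroid outside a thin crescent
  crescent <- rbind(make_ellipse(1, 1, 100)[1:50, ],
                    make_ellipse(0.98, 0.98, 100)[50:1, ])
  expect_error(extract_radii(crescent), "star-shaped")
})

test_that("shape pipeline is invariant to rotation by the sampling step", {
  th <- 2 * pi * (0:2047) / 2048
  r0 <- 3 * (1 + 0.2 * cos(2 * th) + 0.05 * cos(3 * th))
  outline <- cbind(r0 * cos(th), r0 * sin(th))
  rot <- 2 * pi * 16 / 512
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  cf1 <- wavelet_coefficients(extract_radii(outline))
  cf2 <- wavelet_coefficients(extract_radii(outline %*% t(R)))
  expect_equal(cf1$detail, cf2$detail, tolerance = 1e-6)
})

test_that("length standardisation removes the planted allometry", {
  set.seed(31)
  n <- 54
  site <- rep(c("A", "B", "C"), each = 18)
  L <- rnorm(n, rep(c(320, 280, 290), each = 18), 15)
  b <- 0.02
  coeffs <- sapply(1:6, function(j)
    0.5 * j + b * (L - mean(L)) + rnorm(n, 0, 0.3))
  std <- length_standardise(coeffs, L, site)
  expect_lt(max(abs(attr(std, "slopes") - b) / b), 0.35)
  # pooled within-site correlation with length is zero
  Lc <- L - ave(L, site)
  for (j in 1:6) {
    cs <- std[, j] - ave(std[, j], site)
    expect_lt(abs(sum(cs * Lc)), 1e-8)
  }
  # slope-free coefficients are (nearly) unchanged
  flat <- sapply(1:3, function(j) rep(j, n) + rnorm(n, 0, 0.2))
  std2 <- length_standardise(flat, L, site)
  expect_lt(max(abs(attr(std2, "slopes"))), 0.01)
  # centring invariance: shifting all lengths changes nothing
  std3 <- length_standardise(coeffs, L + 100, site)
  expect_equal(unclass(std3)[, ], unclass(std)[, ], tolerance = 1e-10)
  expect_warning(length_standardise(coeffs, rep(300, n), site), "constant")
})

test_that("planted slope recovery at study scale is within 10%", {
  set.seed(32)
  n <- 54
  site <- rep(c("A", "B", "C"), each = 18)
  L <- rnorm(n, 300, 25)
  coeffs <- matrix(1 + 0.02 * (L - 300), n, 4) +
    matrix(rnorm(n * 4, 0, 0.05), n, 4)
  std <- length_standardise(coeffs, L, site)
  expect_lt(max(abs(attr(std, "slopes") - 0.02) / 0.02), 0.10)
})

test_that("mean shapes reproduce single fish and planted lobe differences", {
  th <- 2 * pi * (0:511) / 512
  mk <- function(amp) wavelet_coefficients(2 * (1 + amp * cos(2 * th)))
  one <- mean_shape(list(mk(0.1)), sites = "A")
  rec <- otostock:::.reconstruct_radii(mk(0.1))
  expect_equal(one$A$radius, rec, tolerance = 1e-12)
  two <- mean_shape(list(mk(0.1), mk(0.1)), sites = c("A", "A"))
  expect_equal(two$A$radius, one$A$radius, tolerance = 1e-12)

  ms <- mean_shape(list(mk(0.1), mk(0.2)), sites = c("A", "B"))
  # radial difference at the lobe angle (theta = 0) close to planted 2*0.1
  dif <- ms$B$radius[1] - ms$A$radius[1]
  expect_lt(abs(dif - 0.2) / 0.2, 0.10)
})

test_that("positivity mapping yields gamma-compatible columns", {
  set.seed(33)
  x <- matrix(rnorm(60), 20, 3)
  x[, 3] <- abs(x[, 3]) + 1          # already positive
  pos <- shift_to_positive(x)
  expect_true(all(pos > 0))
  expect_identical(attr(pos, "already_positive"),
                   c(FALSE, FALSE, TRUE))
  expect_equal(pos[, 3], x[, 3])     # untouched when already positive
  pa <- shift_to_positive(x, method = "abs")
  expect_true(all(pa > 0))
})
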