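# Synthetic study generator: dimensions, reproducibility, distributional
# structure.

test_that("chemistry generator honours the study design", {
  cfg <- synthetic_config()
  sim <- generate_chemistry(cfg, seed = 50)
  expect_equal(dim(sim$data), c(54L, 12L))
  expect_true(all(sim$data >= 0))
  expect_equal(as.vector(table(sim$site)), rep(18L, 3))
  expect_identical(sim$data, generate_chemistry(cfg, seed = 50)$data)
  # default mean ordering: one site highest for 10 of 12 elements, one
  # highest for Zn and Mg, one lowest everywhere
  mm <- cfg$site_means
  top <- setNames(rownames(mm)[apply(mm, 2, which.max)], colnames(mm))
  expect_equal(sum(top == "Agra"), 10)
  expect_equal(unname(top[c("Zn", "Mg")]), c("Narora", "Narora"))
  expect_true(all(apply(mm, 2, which.min) ==
                    which(rownames(mm) == "Lucknow")))
})

test_that("generated zero fractions match the closed-form zero mass", {
  cfg <- synthetic_config(n_per_site = 600)
  sim <- generate_chemistry(cfg, seed = 51)
  for (e in c("Zn", "Cd")) {
    p0 <- mean(tweedie_zero_prob(cfg$site_means[, e], cfg$phi[[e]],
                                 cfg$power))
    obs <- mean(sim$data[, e] == 0)
    expect_lt(abs(obs - p0), 3 * sqrt(p0 * (1 - p0) / nrow(sim$data)))
  }
  # high-mean elements are effectively zero-free
  expect_equal(sum(sim$data[, "Na"] == 0), 0)
})

test_that("generated moments follow the configured mean-variance law", {
  cfg <- synthetic_config(n_per_site = 2000)
  sim <- generate_chemistry(cfg, seed = 52)
  for (e in c("Na", "Sr", "Cd")) {
    for (s in levels(sim$site)) {
      y <- sim$data[sim$site == s, e]
      mu <- cfg$site_means[s, e]
      v <- cfg$phi[[e]] * mu^cfg$power
      expect_lt(abs(mean(y) - mu), 4 * sqrt(v / length(y)))
      expect_lt(abs(var(y) - v) / v, 0.25)
    }
  }
})

test_that("shape generator is positive with a weak planted site effect", {
  cfg <- synthetic_config()
  sim <- generate_shape_coefficients(cfg, seed = 53)
  expect_equal(dim(sim$data), c(54L, 63L))
  expect_true(all(sim$data > 0))
  expect_identical(sim$data, generate_shape_coefficients(cfg, seed = 53)$data)
  hit <- sim$site == cfg$shape_effect_site
  ratio <- colMeans(sim$data[hit, 1:6]) / colMeans(sim$data[!hit, 1:6])
  expect_gt(mean(ratio), 1.1)
})

test_that("null generator removes site structure", {
  cfg <- synthetic_config(n_per_site = 500)
  nul <- generate_null(cfg, seed = 54)
  grand <- colMeans(nul$data)
  for (s in levels(nul$site)) {
    gm <- colMeans(nul$data[nul$site == s, ])
    expect_lt(max(abs(gm - grand) / pmax(grand, 0.01)), 0.25)
  }
  expect_identical(nul$data, generate_null(cfg, seed = 54)$data)
})

test_that("planted shape site effects are detectable by the sum-of-LR test", {
  cfg <- synthetic_config(n_shape_coeffs = 10, shape_effect_size = 2,
                          shape_effect_coeffs = 1:5)
  hits <- vapply(1:100, function(r) {
    sim <- generate_shape_coefficients(cfg, seed = 6000 + r)
    sum_of_lr_test(sim$data, sim$site, family_spec("gamma"), B = 39,
                   seed = r)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.80)
})

test_that("generated outlines are star-shaped and wavelet-analysable", {
  cfg <- synthetic_config(n_per_site = 3)
  out <- generate_outlines(cfg, seed = 55)
  expect_length(out$outlines, 9)
  for (o in out$outlines) {
    r <- extract_radii(smooth_outline(o, 20))
    expect_true(all(r > 0))
  }
  # a noise-free circular config gives constant radii
  cfg2 <- synthetic_config(n_per_site = 2,
                           outline_c2 = c(Agra = 0, Lucknow = 0,
                                          Narora = 0),
                           outline_c3 = 0, outline_noise_sd = 0,
                           outline_pixel_sd = 0)
  out2 <- generate_outlines(cfg2, seed = 56)
  r2 <- extract_radii(out2$outlines[[1]])
  expect_lt(diff(range(r2)) / mean(r2), 1e-3)
})

test_that("planted outline differences propagate to a detectable site effect", {
  cfg <- synthetic_config(n_per_site = 12,
                          outline_c2 = c(Agra = 0.20, Lucknow = 0.10,
                                         Narora = 0.15),
                          outline_pixel_sd = 0.002)
  hits <- vapply(1:20, function(r) {
    out <- generate_outlines(cfg, seed = 8000 + r)
    cfs <- lapply(out$outlines, function(o)
      wavelet_coefficients(extract_radii(smooth_outline(o, 50))))
    raw <- t(sapply(cfs, function(cf) cf$detail))
    pos <- shift_to_positive(length_standardise(raw, out$lengths,
                                                out$site))
    sum_of_lr_test(pos, out$site, family_spec("gamma"), B = 39,
                   seed = r)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.80)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_per_site = 1), "n_per_site")
  mm <- synthetic_config()$site_means
  mm[1, 1] <- -1
  expect_error(synthetic_config(site_means = mm), "positive")
  expect_error(synthetic_config(power = 2.3), "power")
})
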