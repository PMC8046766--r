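# Multivariate sum-of-LR testing, contribution decomposition, post-hoc.

test_that("sum-of-LR is the exact sum of per-variable statistics", {
  sim <- generate_chemistry(synthetic_config(), seed = 2)
  x <- sim$data[, 1:4]
  fit <- sum_of_lr_test(x, sim$site, B = 19, seed = 1)
  expect_identical(fit$sum_lr, sum(fit$per_variable_lr))
  expect_true(all(fit$per_variable_lr >= -1e-8))
  expect_equal(sum(fit$contributions_pct), 100, tolerance = 0.01)

  # duplicating every column doubles the statistic exactly
  fit2 <- sum_of_lr_test(cbind(x, x), sim$site, B = 19, seed = 1)
  expect_equal(fit2$sum_lr, 2 * fit$sum_lr, tolerance = 1e-9)
  expect_equal(unname(fit2$contributions_pct[1:4] +
                        fit2$contributions_pct[5:8]),
               unname(fit$contributions_pct), tolerance = 1e-8)
})

test_that("single-column test reduces to the univariate LR test", {
  sim <- generate_chemistry(synthetic_config(), seed = 3)
  y <- sim$data[, "Sr"]
  fit <- sum_of_lr_test(matrix(y, dimnames = list(NULL, "Sr")),
                        sim$site, B = 19, seed = 1)
  full <- fit_glm(y, sim$site, family_spec("tweedie"))
  null <- fit_glm(y, NULL, family_spec("tweedie"))
  expect_equal(fit$sum_lr, 2 * (full$loglik - null$loglik),
               tolerance = 1e-10)
})

test_that("contribution decomposition reproduces published-style arithmetic", {
  # univariate chemistry LR values as printed in a three-site field study
  lr <- c(Na = 296.57, Sr = 216.61, Mg = 113.60, Ni = 91.59, Cd = 90.53,
          Ba = 88.85, Mn = 74.82, Cr = 66.78, Pb = 66.60, Zn = 30.30,
          Fe = 8.23, K = 3.44)
  pct <- contribution_decomposition(lr)
  expect_equal(round(unname(pct["Na"]), 2), 25.84)
  expect_equal(round(unname(pct["Sr"]), 2), 18.87)
  expect_equal(round(unname(pct["K"]), 2), 0.30)
  expect_equal(sum(pct), 100)

  expect_equal(unname(contribution_decomposition(c(x = 5))), 100)
  expect_equal(unname(contribution_decomposition(rep(2, 4))), rep(25, 4))
  expect_error(contribution_decomposition(rep(0, 3)), "undefined")
  expect_error(contribution_decomposition(c(-1, 2)), "non-negative")
})

test_that("permutation p-values respect their attainable range", {
  sim <- generate_chemistry(synthetic_config(), seed = 4)
  fit <- sum_of_lr_test(sim$data[, 1:3], sim$site, B = 19, seed = 9)
  expect_gte(fit$p_value, 1 / 20)
  expect_lte(fit$p_value, 1)
  expect_true(all(fit$per_variable_p >= 1 / 20 & fit$per_variable_p <= 1))
  # identical seed reproduces identical inference
  fit2 <- sum_of_lr_test(sim$data[, 1:3], sim$site, B = 19, seed = 9)
  expect_identical(fit$p_value, fit2$p_value)
  expect_identical(fit$per_variable_p, fit2$per_variable_p)
})

test_that("Bonferroni adjustment follows the pairwise arithmetic", {
  expect_equal(p.adjust(0.02, "bonferroni", n = 3), 0.06)
  cfg <- synthetic_config()
  sim <- generate_chemistry(cfg, seed = 6)
  ph <- pairwise_posthoc(sim$data[, 1:3], sim$site, B = 19, seed = 1)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p_raw))
})

test_that("post-hoc tests localise a single deviating site", {
  el <- c("Na", "Sr", "Ba")
  base <- c(Na = 10, Sr = 1.2, Ba = 0.02)
  mm <- rbind(Agra = 3 * base, Lucknow = base, Narora = base)
  cfg <- synthetic_config(site_means = mm,
                          phi = c(Na = 0.1, Sr = 0.15, Ba = 0.2))
  hits <- matrix(NA, 100, 3)
  for (r in seq_len(100)) {
    sim <- generate_chemistry(cfg, seed = 1000 + r)
    ph <- pairwise_posthoc(sim$data, sim$site, B = 99, seed = r)
    key <- paste(ph$site_a, ph$site_b)
    hits[r, ] <- (ph$p_adj < 0.05)[order(key)]
  }
  # alphabetical pair order: Agra-Lucknow, Agra-Narora, Lucknow-Narora
  expect_gte(mean(hits[, 1] & hits[, 2] & !hits[, 3]), 0.90)
})

test_that("larger true mean differences never shrink the median statistic", {
  el <- c(Na = 10, Sr = 1.2)
  med <- vapply(c(1, 2, 4), function(scale) {
    mm <- rbind(Agra = el * scale, Lucknow = el, Narora = el)
    cfg <- synthetic_config(site_means = mm,
                            phi = c(Na = 0.1, Sr = 0.15))
    stats <- vapply(1:10, function(r) {
      sim <- generate_chemistry(cfg, seed = 300 + r)
      sum_of_lr_test(sim$data, sim$site, B = 1, seed = r)$sum_lr
    }, 0)
    median(stats)
  }, 0)
  expect_true(all(diff(med) >= 0))
})

test_that("family violations and bad configs raise clear errors", {
  sim <- generate_chemistry(synthetic_config(), seed = 8)
  zn <- sim$data[, "Zn", drop = FALSE]
  stopifnot(any(zn == 0))
  expect_error(sum_of_lr_test(zn, sim$site, family_spec("gamma"), B = 9),
               "Zn")
  expect_error(sum_of_lr_test(sim$data, sim$site, B = 0), "B")
  expect_error(sum_of_lr_test(sim$data, rep("A", nrow(sim$data)), B = 9),
               "2 sites")
})
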