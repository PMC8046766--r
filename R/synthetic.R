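# Synthetic-data generator emulating the three-river study design:
# 3 sites x 18 fish, 12 element:Ca ratios with Tweedie error structure and
# site-ordered means, 63 positive gamma shape coefficients with weak site
# effects, site-dependent fish lengths, and harmonic otolith outlines.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the statistical structure of the three-site field
#' design: 18 fish per site; 12 element:Ca ratios (mmol:mol) drawn from
#' Tweedie distributions (variance power 1.75) whose site mean ordering has
#' one "Agra-like" site highest for 10 of 12 elements, a "Narora-like" site
#' highest for Zn and Mg, and a "Lucknow-like" site lowest for every
#' element; low Zn and Cd means so exact zeros (below-detection analogues)
#' occur with non-trivial probability; 63 strictly positive gamma shape
#' coefficients with weak site effects; and site-specific normal length
#' distributions with the largest fish at the Agra-like site.
#'
#' @param n_per_site fish per site (default 18).
#' @param sites site names (default Agra, Lucknow, Narora).
#' @param site_means site x element matrix of Tweedie means (mmol:mol).
#' @param phi named per-element dispersion vector.
#' @param power Tweedie variance power (default 1.75).
#' @param n_shape_coeffs number of shape coefficients (default 63).
#' @param shape_k gamma shape parameter of the coefficients (default 20,
#'   i.e. dispersion 0.05).
#' @param shape_effect_size multiplicative mean shift applied to
#'   `shape_effect_coeffs` for `shape_effect_site` (default a weak 1.3 on
#'   the 6 coarsest coefficients of the Lucknow-like site).
#' @param shape_effect_coeffs,shape_effect_site see above.
#' @param shape_length_slope planted per-mm length dependence of the shape
#'   coefficients (default 0; set positive to exercise
#'   [length_standardise()]).
#' @param length_mean,length_sd named per-site length distributions (mm).
#' @param outline_c2,outline_c3 per-site and common harmonic amplitudes of
#'   the generated outlines; `outline_noise_sd` the fish-to-fish amplitude
#'   noise; `outline_pixel_sd` relative vertex jitter; `outline_points`
#'   polygon vertices per fish.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_per_site = 18,
    sites = c("Agra", "Lucknow", "Narora"),
    site_means = NULL,
    phi = c(Na = 0.1, Mg = 0.2, Sr = 0.15, Ba = 0.2, Mn = 0.2, Fe = 0.2,
            Pb = 0.2, Ni = 0.2, Zn = 1, Cd = 1, Cr = 0.2, K = 0.1),
    power = 1.75,
    n_shape_coeffs = 63,
    shape_k = 20,
    shape_effect_size = 1.3,
    shape_effect_coeffs = 1:6,
    shape_effect_site = "Lucknow",
    shape_length_slope = 0,
    length_mean = c(Agra = 320, Lucknow = 280, Narora = 290),
    length_sd = c(Agra = 20, Lucknow = 20, Narora = 20),
    outline_c2 = c(Agra = 0.16, Lucknow = 0.14, Narora = 0.15),
    outline_c3 = 0.06,
    outline_noise_sd = 0.01,
    outline_pixel_sd = 0.001,
    outline_points = 720) {
  if (is.null(site_means)) {
    site_means <- rbind(
      Agra    = c(Na = 16, Mg = 0.30, Sr = 2.4, Ba = 0.050, Mn = 0.040,
                  Fe = 0.10, Pb = 0.045, Ni = 0.080, Zn = 0.020,
                  Cd = 0.020, Cr = 0.050, K = 2.0),
      Lucknow = c(Na = 8,  Mg = 0.15, Sr = 0.8, Ba = 0.010, Mn = 0.010,
                  Fe = 0.05, Pb = 0.010, Ni = 0.015, Zn = 0.015,
                  Cd = 0.004, Cr = 0.010, K = 1.5),
      Narora  = c(Na = 10, Mg = 0.45, Sr = 1.2, Ba = 0.020, Mn = 0.018,
                  Fe = 0.07, Pb = 0.020, Ni = 0.030, Zn = 0.060,
                  Cd = 0.012, Cr = 0.020, K = 1.7))
    rownames(site_means) <- sites
  }
  cfg <- list(n_per_site = n_per_site, sites = sites,
              site_means = site_means, phi = phi, power = power,
              n_shape_coeffs = n_shape_coeffs, shape_k = shape_k,
              shape_effect_size = shape_effect_size,
              shape_effect_coeffs = shape_effect_coeffs,
              shape_effect_site = shape_effect_site,
              shape_length_slope = shape_length_slope,
              length_mean = length_mean, length_sd = length_sd,
              outline_c2 = outline_c2, outline_c3 = outline_c3,
              outline_noise_sd = outline_noise_sd,
              outline_pixel_sd = outline_pixel_sd,
              outline_points = outline_points)
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  if (cfg$n_per_site < 2) stop("n_per_site must be >= 2", call. = FALSE)
  if (!all(rownames(cfg$site_means) == cfg$sites))
    stop("site_means rows must match sites", call. = FALSE)
  if (any(cfg$site_means <= 0)) stop("site means must be positive",
                                     call. = FALSE)
  if (!all(colnames(cfg$site_means) %in% names(cfg$phi)))
    stop("phi must name every element", call. = FALSE)
  if (any(cfg$phi <= 0)) stop("phi must be positive", call. = FALSE)
  .check_power(cfg$power)
  invisible(cfg)
}

.site_factor <- function(cfg) {
  factor(rep(cfg$sites, each = cfg$n_per_site), levels = cfg$sites)
}

.draw_lengths <- function(cfg, site) {
  pmax(round(rnorm(length(site), cfg$length_mean[as.character(site)],
                   cfg$length_sd[as.character(site)])), 50)
}

#' Generate a synthetic otolith-chemistry matrix
#'
#' Draws every cell from a Tweedie distribution with the configured
#' site-by-element mean, per-element dispersion and common variance power;
#' low-mean Zn/Cd cells produce exact zeros, emulating below-detection
#' samples.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (reproducible).
#' @return list: `data` (n x 12 non-negative matrix of element:Ca ratios),
#'   `site` (factor), `lengths` (mm).
#' @export
generate_chemistry <- function(config = synthetic_config(), seed = NULL) {
  .validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  site <- .site_factor(config)
  el <- colnames(config$site_means)
  data <- sapply(el, function(e)
    tweedie_sample(length(site),
                   mu = config$site_means[as.character(site), e],
                   phi = config$phi[[e]], power = config$power))
  rownames(data) <- sprintf("fish%02d", seq_along(site))
  list(data = data, site = site, lengths = .draw_lengths(config, site))
}

#' Generate synthetic shape coefficients
#'
#' Strictly positive gamma draws (shape `shape_k`, so dispersion
#' `1/shape_k`) with means decaying across coefficient index, a weak
#' multiplicative site effect on a subset of coefficients, and an optional
#' planted linear length dependence.
#'
#' @inheritParams generate_chemistry
#' @return list: `data` (n x 63 positive matrix), `site`, `lengths`.
#' @export
generate_shape_coefficients <- function(config = synthetic_config(),
                                        seed = NULL) {
  .validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  site <- .site_factor(config)
  lengths <- .draw_lengths(config, site)
  J <- config$n_shape_coeffs
  base_mu <- 2 / (1 + 0.05 * (seq_len(J) - 1))
  mu <- matrix(base_mu, length(site), J, byrow = TRUE)
  hit <- site == config$shape_effect_site
  mu[hit, config$shape_effect_coeffs] <-
    mu[hit, config$shape_effect_coeffs] * config$shape_effect_size
  data <- matrix(rgamma(length(mu), shape = config$shape_k,
                        scale = mu / config$shape_k),
                 nrow(mu), J)
  if (config$shape_length_slope != 0)
    data <- data + config$shape_length_slope * (lengths - mean(lengths))
  colnames(data) <- sprintf("w%02d", seq_len(J))
  rownames(data) <- sprintf("fish%02d", seq_along(site))
  list(data = data, site = site, lengths = lengths)
}

#' Generate null datasets (no site effect)
#'
#' Same marginal structure as [generate_chemistry()] /
#' [generate_shape_coefficients()] but with identical means at every site
#' (the across-site average), for type-I-error and calibration studies.
#'
#' @inheritParams generate_chemistry
#' @param block `"chemistry"` or `"shape"`.
#' @return as the corresponding generator.
#' @export
generate_null <- function(config = synthetic_config(), seed = NULL,
                          block = c("chemistry", "shape")) {
  block <- match.arg(block)
  .validate_config(config)
  grand <- colMeans(config$site_means)
  config$site_means <- matrix(grand, nrow(config$site_means),
                              ncol(config$site_means), byrow = TRUE,
                              dimnames = dimnames(config$site_means))
  config$shape_effect_size <- 1
  if (block == "chemistry") generate_chemistry(config, seed)
  else generate_shape_coefficients(config, seed)
}

#' Generate synthetic otolith outlines
#'
#' Per-fish closed polygons from a star-shaped harmonic radius model
#' `r(theta) = a (1 + c2 cos(2 theta) + c3 cos(3 theta) + ...)` with a
#' site-specific second-harmonic amplitude, fish-level amplitude noise and
#' vertex-level pixel jitter; overall size `a` scales with fish length.
#'
#' @inheritParams generate_chemistry
#' @return list: `outlines` (list of two-column matrices), `site`,
#'   `lengths`.
#' @export
generate_outlines <- function(config = synthetic_config(), seed = NULL) {
  .validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  site <- .site_factor(config)
  lengths <- .draw_lengths(config, site)
  th <- 2 * pi * (seq_len(config$outline_points) - 1) / config$outline_points
  outlines <- lapply(seq_along(site), function(i) {
    a <- 0.018 * lengths[i]
    c2 <- config$outline_c2[[as.character(site[i])]] +
      rnorm(1, 0, config$outline_noise_sd)
    c3 <- config$outline_c3 + rnorm(1, 0, config$outline_noise_sd)
    r <- a * (1 + c2 * cos(2 * th) + c3 * cos(3 * th))
    xy <- cbind(x = r * cos(th), y = r * sin(th))
    xy + rnorm(length(xy), 0, config$outline_pixel_sd * a)
  })
  list(outlines = outlines, site = site, lengths = lengths)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d sites x %d fish; %d elements (Tweedie, power %g); %d shape coefficients (gamma, k = %g)\n",
    length(x$sites), x$n_per_site, ncol(x$site_means), x$power,
    x$n_shape_coeffs, x$shape_k))
  invisible(x)
}
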