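#' Dunn-Smyth (randomised quantile) residuals
#'
#' Residuals that are standard normal under a correctly specified model,
#' including for distributions with a point mass at zero. For `y > 0` the
#' residual is deterministic, `qnorm(F(y; mu_hat, phi_hat, power))`; for a
#' Tweedie exact zero it is `qnorm(u)` with `u` drawn uniformly on
#' `(0, F(0)]` — only the zero atom consumes randomness.
#'
#' @param data matrix/data frame of responses (samples x variables).
#' @param fits list of [fit_glm()] objects, one per column of `data`,
#'   fitted to those columns (typically the site-factor model under test).
#' @param seed optional integer seed for the zero-atom jitter.
#' @return An object of class `residual_set`: `residuals` and
#'   `linear_predictors` (matrices shaped like `data`), `variable_ids`,
#'   `seed`.
#' @export
dunn_smyth_residuals <- function(data, fits, seed = NULL) {
  data <- as.matrix(data)
  if (length(fits) != ncol(data))
    stop("need one fit per data column", call. = FALSE)
  if (!all(vapply(fits, inherits, TRUE, "glm_fit")))
    stop("fits must be glm_fit objects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- eta <- matrix(NA_real_, nrow(data), ncol(data),
                     dimnames = dimnames(data))
  for (j in seq_len(ncol(data))) {
    f <- fits[[j]]
    if (f$n_obs != nrow(data))
      stop("fit ", j, " does not match data rows", call. = FALSE)
    mu <- f$fitted
    p <- f$family$power
    y <- data[, j]
    Fy <- tweedie_cdf(y, mu, f$phi_hat, p)
    rj <- qnorm(pmin(pmax(Fy, 1e-300), 1 - 1e-16))
    z <- which(y == 0)
    if (length(z)) {
      u <- runif(length(z)) * Fy[z]          # uniform on (0, F(0)]
      rj[z] <- qnorm(pmax(u, 1e-300))
    }
    r[, j] <- rj
    eta[, j] <- log(mu)
  }
  structure(list(residuals = r, linear_predictors = eta,
                 variable_ids = colnames(data), seed = seed),
            class = "residual_set")
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("<residual_set> %d samples x %d variables\n",
              nrow(x$residuals), ncol(x$residuals)))
  cat(sprintf("  residual mean %.3f, sd %.3f\n",
              mean(x$residuals), sd(x$residuals)))
  invisible(x)
}

#' Mean-variance diagnostic points
#'
#' Sample mean and sample variance of every response variable within every
#' site — the data behind a mean-variance plot, which reveals the
#' increasing mean-variance relationship (Taylor's power law,
#' `Var = phi mu^power`) that motivates Tweedie/gamma error structures and
#' breaks homogeneity-of-variance assumptions of distance-based methods.
#' Plot on log-log axes; the slope approximates the variance power.
#'
#' @param data matrix/data frame of responses.
#' @param groups site labels, one per row.
#' @return data frame with columns `variable`, `group`, `mean`, `variance`,
#'   `n`. Groups with a single observation get `NA` variance and a warning.
#' @export
mean_variance_points <- function(data, groups) {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- paste0("V", seq_len(ncol(data)))
  g <- factor(groups)
  if (any(tabulate(g, nlevels(g)) < 2))
    warning("groups with a single observation have undefined variance")
  out <- expand.grid(variable = colnames(data), group = levels(g),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean <- out$variance <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    y <- data[g == out$group[i], out$variable[i]]
    out$mean[i] <- mean(y)
    out$variance[i] <- if (length(y) > 1) var(y) else NA_real_
    out$n[i] <- length(y)
  }
  out[, c("variable", "group", "mean", "variance", "n")]
}
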