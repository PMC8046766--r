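# Small independent helpers used as test oracles.

# mean silhouette width of a labelling on a distance matrix
mean_silhouette <- function(d, labels) {
  m <- as.matrix(d)
  labels <- as.character(labels)
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(m[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(m[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# quadrature-based total probability mass of a Tweedie distribution
tweedie_total_mass <- function(mu, phi, power) {
  cont <- integrate(function(x) exp(tweedie_logpdf(x, mu, phi, power)),
                    lower = 0, upper = Inf, rel.tol = 1e-9,
                    subdivisions = 500L)$value
  tweedie_zero_prob(mu, phi, power) + cont
}

# brute-force Euclidean distance matrix
brute_force_dist <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  out
}

# polygon sampled on a circle/ellipse
make_ellipse <- function(a = 1, b = 1, n = 2048, centre = c(0, 0),
                         rot = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  x <- a * cos(th); y <- b * sin(th)
  cbind(x = centre[1] + cos(rot) * x - sin(rot) * y,
        y = centre[2] + sin(rot) * x + cos(rot) * y)
}
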