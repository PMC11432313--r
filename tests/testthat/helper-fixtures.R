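# Shared fixture builders. Everything is generated in code; no files.

# effect-level simulator: k effects with true mean mu, between-effect
# variance tau2, sampling variances v (drawn or supplied)
sim_effects <- function(k, mu = 0, tau2 = 0, v = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(v)) v <- runif(k, 0.05, 0.2)
  theta <- rnorm(k, mu, sqrt(tau2))
  data.frame(rr = rnorm(k, theta, sqrt(v)), v = v, w = 1 / v)
}

# a small observation table: two studies, two traits, three temperatures
toy_observations <- function() {
  data.frame(
    study_id = rep(c("s1", "s2"), each = 6),
    variable = rep(rep(c("egg", "fecundity"), each = 3), 2),
    temperature_c = rep(c(18, 24, 30), 4),
    rel_humidity_pct = rep(c(65, 75), each = 6),
    photoperiod = "12:12",
    photoperiod_light_h = 12,
    mean = c(5.0, 3.2, 2.1, 300, 600, 900,
             5.5, 3.0, 2.0, 280, 640, 950),
    dispersion_value = 0.4,
    dispersion_kind = "SD",
    n = 30,
    stringsAsFactors = FALSE
  )
}

write_toy_csv <- function(df = toy_observations(), path = tempfile(fileext = ".csv")) {
  cols <- c("study_id", "variable", "temperature_c", "rel_humidity_pct",
            "photoperiod", "mean", "dispersion_value", "dispersion_kind", "n")
  utils::write.csv(df[, cols], path, row.names = FALSE)
  path
}

# independent restricted log-likelihood for intercept-only model,
# written from the textbook formula (grid-search oracle for REML)
oracle_reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

oracle_reml_grid <- function(y, v, upper = 10, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, oracle_reml_loglik, numeric(1), y = y, v = v)
  grid[which.max(ll)]
}

# brute-force fail-safe N: add null studies one at a time until the
# Stouffer Z drops below the critical value
oracle_fail_safe <- function(z, z_alpha = qnorm(0.95), n_max = 1e6) {
  S <- abs(sum(z))
  k <- length(z)
  n <- 0
  while (S / sqrt(k + n) >= z_alpha) {
    n <- n + 1
    if (n > n_max) stop("fail-safe oracle exceeded n_max")
  }
  n
}
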