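# small, fast synthetic setups shared across test files

small_config <- function(seed = 1, ...) {
  synth_config(n_species = 6, n_years = 15, n_realizations = 4, seed = seed, ...)
}

# short forcing for column tests
short_forcing <- function(seed = 1, n_years = 6) {
  gen_forcing(synth_config(n_years = n_years, seed = seed))
}

# closed-form two-variable OLS used as an independent oracle
ols_oracle <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(b0 = b0, b1 = b1, r2 = r2)
}

# a seasonal toy shape for building synthetic series in tests
season_weight_test <- function(doy) 0.5 * (1 + sin(2 * pi * doy / 365))

# brute-force Spearman for tie-free data
spearman_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
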