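# Shared fixtures, built in code at test time.

# 4-row toy table: outcome missing in row 1, exposure missing in rows 1 and 3
toy_table <- function() {
  study_table(
    data.frame(
      y = c(NA, 50, 60, 70),
      x = c(NA, 1, NA, 0),
      z = c(1, 0, 1, 0)),
    roles = c(y = "outcome", x = "exposure", z = "confounder"),
    scales = c(y = "continuous", x = "binary", z = "binary"))
}

# small complete table with a known linear law
linear_table <- function(n = 200, beta = 2, noise_sd = 1, seed = 42) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  y <- 10 + beta * x + 3 * z + rnorm(n, 0, noise_sd)
  study_table(
    data.frame(y = y, x = x, z = z),
    roles = c(y = "outcome", x = "exposure", z = "confounder"),
    scales = c(y = "continuous", x = "binary", z = "continuous"))
}

# small preset used by several suites
small_preset <- function(n = 1500, seed = 3, delta_true = 0)
  alspac_like_preset(n, seed = seed, delta_true = delta_true)
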