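# Shared fixtures: small phantoms/cohorts generated in code, plus tiny
# independent oracles used across tests.

smallPhantom <- function(..., gridShape = c(40, 40, 12), seed = 1L) {
  generatePhantom(phantomSpec(gridShape = gridShape, seed = seed, ...))
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force CPE oracle: sort, take the ceiling(N/10) largest, average
bruteCpe <- function(values) {
  k <- ceiling(0.1 * length(values))
  mean(rev(sort(values))[seq_len(k)])
}

# brute-force equal-tertile oracle by rank
bruteTertiles <- function(x) {
  n <- length(x)
  sizes <- c(n %/% 3 + (n %% 3 >= 1), n %/% 3, n %/% 3 + (n %% 3 == 2))
  lab <- character(n)
  lab[order(x)] <- rep(c("low", "intermediate", "high"), sizes)
  lab
}

# minimal survival-table fixture with all three tertiles populated
survFixture <- function(n = 300, rate = 0.0017, seed = 1) {
  set.seed(seed)
  t <- rexp(n, rate)
  e <- as.integer(t <= 120)
  data.frame(
    patient_id = seq_len(n),
    tertile = factor(rep(c("low", "intermediate", "high"), length.out = n),
                     levels = c("low", "intermediate", "high")),
    idfs_time_months = pmin(t, 120), idfs_event = e,
    os_time_months = pmin(t, 120), os_event = e)
}
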