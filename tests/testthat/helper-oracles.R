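# Independent brute-force oracles used across the suite.  These deliberately
# take the dumbest correct route (loops, enumeration, stats:: refits) so they
# stay independent of the package's vectorised implementations.

# Eq.-style evidence evaluated term by term with scalar arithmetic.
oracle_evidence <- function(slope_t, slope_d, presented, t) {
  act <- function(s) (1 / (1 + exp(-s * t)))^10
  num <- act(slope_t[presented]) + 6
  den <- 6
  for (j in setdiff(1:3, presented)) den <- den - act(slope_t[j])
  den <- den - 3 * act(slope_d)
  log(num / den)
}

# First integer cycle at which the evidence reaches beta: plain loop.
oracle_scan_rt <- function(slope_t, slope_d, presented, beta = 1,
                           max_cycles = 5000) {
  if (oracle_evidence(slope_t, slope_d, presented, 0) >= beta) return(0)
  for (t in seq_len(max_cycles))
    if (oracle_evidence(slope_t, slope_d, presented, t) >= beta) return(t)
  NA_real_
}

# Objective as an explicit per-trial loop.
oracle_objective <- function(par, rt, level, x, beta = 1) {
  total <- 0
  for (h in seq_along(rt)) {
    st <- plogis(par[1:3] + par[4] * x[h]) * 0.023
    sd_ <- plogis(par[5] + par[6] * x[h]) * 0.023
    total <- total + (beta - oracle_evidence(st, sd_, level[h], rt[h]))^2
  }
  total
}

# Quantile binning by explicit index arithmetic.
oracle_vincentize <- function(rt, k = 20) {
  s <- sort(rt)
  n <- length(s)
  base <- n %/% k
  r <- n %% k
  out <- numeric(k)
  pos <- 0
  for (i in seq_len(k)) {
    size <- base + as.integer(i <= r)
    out[i] <- mean(s[(pos + 1):(pos + size)])
    pos <- pos + size
  }
  out
}

oracle_moments <- function(rt) {
  n <- length(rt)
  m <- sum(rt) / n
  v <- sum((rt - m)^2) / n
  d <- sqrt(v)
  c(mean = m, dispersion = d,
    skewness = sum((rt - m)^3) / (n * d^3),
    kurtosis = sum((rt - m)^4) / (n * d^4) - 3)
}

# Small synthetic dataset shared by the heavier fitting tests.
small_dataset <- function(n_participants = 2, seed = 11,
                          noise = "gaussian") {
  simulate_experiment(n_participants = n_participants, seed = seed,
                      noise = noise)
}

random_slope_set <- function() {
  list(slope_t = runif(3, 1e-4, 0.023), slope_d = runif(1, 1e-4, 0.023))
}
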