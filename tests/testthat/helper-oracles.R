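# Independent oracles and small fixtures shared across tests.

# Bisection root of the mass-action quadratic (x - C)(y - C) = K * C on
# [0, min(x, y)]; independent of the closed form under test.
oracle_eq_bisect <- function(x, y, K, tol = 1e-12) {
  f <- function(C) (x - C) * (y - C) - K * C
  lo <- 0; hi <- min(x, y)
  if (f(hi) >= 0) return(hi)
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small, fast parameter set for unit tests (identical physics, fewer cells).
small_params <- function(...) il2_params(n_sim_cells = 20L, ...)

# Synthetic trajectory with a prescribed IL-2 curve and producer count,
# for testing summary statistics without an ODE run.
fake_trajectory <- function(time, il2_molar, producer_count = NULL) {
  structure(list(time = time, il2_molar = il2_molar,
                 producer_count = producer_count),
            class = "il2_trajectory")
}
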