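test_that("equilibrium_complex matches limits and the bisection oracle", {
  # limiting cases
  expect_equal(equilibrium_complex(10, 0, 30000), 0)
  expect_equal(equilibrium_complex(0, 10, 30000), 0)
  expect_equal(equilibrium_complex(500, 800, 0), 500)
  expect_equal(equilibrium_complex(800, 500, 0), 500)
  # mass-action quadratic root, frozen against the bisection oracle
  expect_equal(equilibrium_complex(3e4, 1e3, 3e4),
               oracle_eq_bisect(3e4, 1e3, 3e4), tolerance = 1e-9)
  for (case in list(c(3e4, 1e5, 3e4), c(1e3, 1e4, 2700), c(2e6, 1e4, 2700),
                    c(7, 5, 1), c(1e-3, 1e9, 1e4))) {
    expect_equal(equilibrium_complex(case[1], case[2], case[3]),
                 oracle_eq_bisect(case[1], case[2], case[3]),
                 tolerance = 1e-8)
  }
  # bounds and numerical stability where x*y << (x+y+K)^2
  C <- equilibrium_complex(1e-2, 1e10, 1e10)
  expect_gt(C, 0); expect_lt(C, 1e-2)
  expect_error(equilibrium_complex(-1, 5, 10), "non-negative")
})

test_that("step_indicator includes the threshold boundary", {
  expect_identical(step_indicator(0.5, 1), 0)
  expect_identical(step_indicator(1, 1), 1)
  expect_identical(step_indicator(-3, -3), 1)
  expect_identical(step_indicator(c(0, 2, 5), 2), c(0, 1, 1))
})

test_that("pstat5_fraction saturates, is inhibited by TCR, and obeys toggles", {
  p <- il2_params()
  expect_equal(pstat5_fraction(0, 0, p), 0)
  expect_equal(pstat5_fraction(1e4, 0, p), 0.5)      # half-saturation
  expect_equal(pstat5_fraction(1e4, 100, p), 0.25)   # 0.5 / (1 + 0.01*100)
  # strictly increasing and saturating in complex count
  v <- pstat5_fraction(c(1e2, 1e3, 1e4, 1e6, 1e9), 0, p)
  expect_true(all(diff(v) > 0)); expect_true(all(v >= 0 & v <= 1))
  # strictly decreasing in engaged TCR
  w <- pstat5_fraction(1e4, c(0, 10, 100, 1e4), p)
  expect_true(all(diff(w) < 0))
  # cross-talk off: second factor dropped
  p_no <- set_variant(p, "nocrosstalk")
  expect_equal(pstat5_fraction(1e4, 1e4, p_no), 0.5)
  # JAK blockade: identically zero
  p_jak <- set_variant(p, "jak")
  expect_equal(pstat5_fraction(1e4, 0, p_jak), 0)
})

test_that("engaged TCR is zero before activation and splits antigen equally", {
  p <- il2_params()
  st <- list(n_pMHC = 4e6, t_act = c(12, 3, 8, 100, 2))
  expect_equal(engaged_tcr(5, 1, st, p), 0)          # not yet activated
  st0 <- list(n_pMHC = 0, t_act = c(1, 1))
  expect_equal(engaged_tcr(10, 1, st0, p), 0)        # no antigen
  # 3 of 5 cells active at t = 10: each sees n_pMHC / 3
  eng <- engaged_tcr(10, 2, st, p)
  expect_equal(eng, equilibrium_complex(3e4, 4e6 / 3, 3e4))
  expect_equal(eng, oracle_eq_bisect(3e4, 4e6 / 3, 3e4), tolerance = 1e-8)
  # no active cell: guarded division
  st_none <- list(n_pMHC = 1e6, t_act = c(50, 60))
  expect_equal(engaged_tcr(10, 1, st_none, p), 0)
})

test_that("secretion rate is gated and spans [basal, 31 x basal]", {
  p <- il2_params()
  mkstate <- function(eng, p5, boost) list(n_engagedTCR = eng, p_stat5 = p5,
                                           n_boost = boost)
  expect_equal(il2_secretion_rate(1, mkstate(0, 0, 0), p), 0)
  expect_equal(il2_secretion_rate(1, mkstate(10, 0, 0), p), 7.5 * 3600)
  # pSTAT5 inhibition closes the gate: 10 / (1 + 3e5 * 0.01) < 1
  expect_equal(il2_secretion_rate(1, mkstate(10, 0.01, 0), p), 0)
  # full Boost: 31 x basal
  expect_equal(il2_secretion_rate(1, mkstate(100, 0, 1e5), p),
               31 * 7.5 * 3600)
  # Boost disabled variant ignores the Boost pool
  expect_equal(il2_secretion_rate(1, mkstate(100, 0, 1e5),
                                  set_variant(p, "noboost")), 7.5 * 3600)
})

test_that("model_rhs has the quiescent fixed point and bookkeeping identity", {
  p <- small_params()
  n <- p$n_sim_cells
  t_act <- rep(100, n)
  # all-zero per-cell states except basal IL-2Rbeta, no antigen:
  # everything still except IL-2Rbeta relaxation toward its basal level
  y <- c(0, 0, rep(0, n), rep(p$n_IL2Rb_0, n), rep(0, n), rep(0, n))
  d <- model_rhs(10, y, p, N_Tcell = 1e4, t_act = t_act)[[1]]
  expect_equal(d, rep(0, length(y)))
  # from Rb = 0 the relaxation pulls toward n_IL2Rb_0
  y2 <- c(0, 0, rep(0, n), rep(0, n), rep(0, n), rep(0, n))
  d2 <- model_rhs(10, y2, p, N_Tcell = 1e4, t_act = t_act)[[1]]
  expect_equal(d2[(2 + n + 1):(2 + 2 * n)],
               rep(p$k_receptor_deg * p$n_IL2Rb_0, n))
  # with binding disabled, d n_IL2 / dt is the summed secretion rate
  p0 <- small_params(k_bind = 1e-300)
  y3 <- c(4e6, 0, rep(1000, n), rep(1e4, n), rep(0, n), rep(0, n))
  out <- model_rhs(50, y3, p0, N_Tcell = 1e4, t_act = rep(10, n))
  expect_equal(out[[1]][2], sum((p0$k_IL2_basal) * out$producing))
  expect_true(all(out$producing == 1))  # high antigen, no pSTAT5
  # error contract: non-finite / negative states are named
  yb <- y3; yb[4] <- NaN
  expect_error(model_rhs(50, yb, p0, 1e4, rep(10, n)), "index 4")
  yn <- y3; yn[3] <- -10
  expect_error(model_rhs(50, yn, p0, 1e4, rep(10, n)), "negative")
})

test_that("IL-2Ralpha relaxes to the TCR plateau with the receptor half-life", {
  # single activated cell, engaged TCR above threshold, no IL-2:
  # closed form Ra(t) = 1000 (1 - exp(-k t)) checked against the integrator
  p <- il2_params(n_sim_cells = 1L, k_bind = 1e-300)
  tr <- run_cohort(p, N_Tcell = 1, N_Antigen = 1e8, t_end = 20,
                   t_act = 0)
  expect_equal(unname(tr$n_IL2Ra[, 1]),
               p$n_TCR_IL2Ra_max * (1 - exp(-p$k_receptor_deg * tr$time)),
               tolerance = 1e-4)
  # half-life check: at t = 5 h, halfway to the plateau
  expect_equal(unname(tr$n_IL2Ra[match(5, tr$time), 1]), 500,
               tolerance = 1e-3)
})

test_that("compiled and reference right-hand sides integrate identically", {
  p <- small_params(n_sim_cells = 8L)
  n <- p$n_sim_cells
  N <- 1e4; Ag <- 1e8
  t_act <- sample_activation_times(n, p$activation_window, seed = 42)
  tr_c <- run_cohort(p, N, Ag, t_end = 60, t_act = t_act)
  # same system through deSolve with the pure-R derivative function;
  # states there carry IL-2 as molecules in the scaled cohort volume
  S <- N / n
  VsNA <- (p$V / S) * p$N_A
  y0 <- c(Ag / S, 0, rep(0, n), rep(p$n_IL2Rb_0, n), rep(0, n), rep(0, n))
  out <- deSolve::lsoda(y0, seq(0, 60, 0.5),
                        function(t, y, parms)
                          model_rhs(t, pmax(y, 0), p, N, t_act),
                        parms = NULL, rtol = p$rtol, atol = p$atol)
  il2_r <- pmax(out[, 3], 0) / VsNA
  expect_equal(il2_r, unname(tr_c$il2_molar), tolerance = 5e-3)
  expect_equal(unname(out[, 2]), unname(tr_c$n_pMHC), tolerance = 5e-3)
  ra_r <- out[, 3 + seq_len(n), drop = FALSE]
  expect_equal(max(abs(ra_r - tr_c$n_IL2Ra)) / max(ra_r), 0,
               tolerance = 5e-3)
})

test_that("mass is conserved when endocytosis and secretion are off", {
  # inactive cells (t < t_act) with preformed receptor and free IL-2:
  # binding moves molecules between pool and complexes only
  p <- small_params(n_sim_cells = 5L, k_endo = 1e-300)
  n <- p$n_sim_cells
  t_act <- rep(1e6, n)
  y0 <- c(0, 1e7, rep(2e3, n), rep(1e4, n), rep(0, n), rep(0, n))
  d <- model_rhs(1, y0, p, N_Tcell = 1e3, t_act = t_act)[[1]]
  expect_equal(d[2] + sum(d[(2 + 2 * n + 1):(2 + 3 * n)]), 0)
  # and along an integrated trajectory, to solver tolerance
  out <- deSolve::lsoda(y0, seq(0, 30, 0.5),
                        function(t, y, parms)
                          model_rhs(t, pmax(y, 0), p, 1e3, t_act),
                        parms = NULL, rtol = 1e-8, atol = 1e-8)
  total <- out[, 3] + rowSums(out[, 3 + 2 * n + seq_len(n), drop = FALSE])
  expect_equal(total, rep(1e7, nrow(out)), tolerance = 1e-6)
})
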