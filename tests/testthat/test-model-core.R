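test_that("rectified gain is threshold-linear and rejects negative gains", {
  expect_equal(gain_rectified(2, m = 1, theta = 0), 2)
  expect_equal(gain_rectified(0.5, m = 3, theta = 1), 0)
  expect_equal(gain_rectified(4, m = 2, theta = 1), 6)
  # continuity and monotonicity across the threshold
  x <- seq(0.9, 1.1, by = 0.001)
  y <- gain_rectified(x, m = 2, theta = 1)
  expect_true(all(diff(y) >= 0))
  expect_lt(max(abs(diff(y))), 0.003)
  expect_error(gain_rectified(1, m = -1), "non-negative")
})

test_that("steady state matches the divisive-normalization fixed point", {
  p <- circuit_params(0.01, 0.04, m_e = 2, m_i = 1, sigma = 1)
  ss <- steady_state(1, p)
  expect_equal(ss$A_i, 1)
  expect_equal(ss$A_e, 1)
  # no inhibition: A_e = m_e * I0 / sigma
  p0 <- circuit_params(0.01, 0.04, m_e = 3, m_i = 0, sigma = 2)
  expect_equal(steady_state(1.5, p0)$A_e, 3 * 1.5 / 2)
  # subthreshold inhibition behaves identically
  pth <- circuit_params(0.01, 0.04, m_e = 3, m_i = 1, sigma = 2, theta_i = 5)
  expect_equal(steady_state(1.5, pth)$A_e, 3 * 1.5 / 2)
  expect_equal(steady_state(1.5, pth)$A_i, 0)
})

test_that("integrator converges to the steady state under constant input", {
  p <- circuit_params(0.008, 0.035, m_e = 150, m_i = 1.2, sigma = 1)
  tg <- seq(0, 20 * p$tau_i, length.out = 400)
  # start far from the fixed point
  tc <- integrate_circuit(p, 0.8, tg, init = list(A_e = 0, A_i = 0))
  ss <- steady_state(0.8, p)
  expect_equal(tail(tc$A_e, 1), ss$A_e, tolerance = 1e-6)
  expect_equal(tail(tc$A_i, 1), ss$A_i, tolerance = 1e-6)
  # a system started at the fixed point stays there
  tc2 <- integrate_circuit(p, 0.8, tg)
  expect_lt(max(abs(tc2$A_e - ss$A_e)), 1e-8 * ss$A_e)
})

test_that("integrator refuses too-coarse steps and is step-converged", {
  p <- circuit_params(0.010, 0.040, m_e = 120, m_i = 1, sigma = 1)
  tg <- seq(0, 0.5, by = 0.001)
  expect_error(integrate_circuit(p, 1, tg, step = 0.01), "min\\(tau_e, tau_i\\)/20")
  inp <- list(t = c(0, 0.1), I = c(0.05, 0.4))
  a1 <- integrate_circuit(p, inp, tg)$A_e
  a2 <- integrate_circuit(p, inp, tg, step = p$tau_e / 40)$A_e
  expect_lt(max(abs(a1 - a2)) / max(a2), 0.001)
})

test_that("reduced response reproduces the example transient", {
  r <- reduced_params(50, 100, 120, 0.010, 0.040)
  tc <- reduced_response(r, seq(0, 1, by = 0.0005))
  # overshoot above the post-change sustained level, then settle at 100
  expect_gt(max(tc$A_e), 110)
  expect_equal(tail(tc$A_e, 1), 100, tolerance = 0.005)
  expect_equal(tc$A_e[1], 50, tolerance = 1e-9)
  # no change in input: constant output
  r0 <- reduced_params(60, 60, 120, 0.010, 0.040)
  tc0 <- reduced_response(r0, seq(0, 0.5, by = 0.001))
  expect_lt(max(abs(tc0$A_e - 60)), 1e-8)
  expect_error(reduced_params(130, 100, 120, 0.01, 0.04), "strictly between")
  expect_error(reduced_params(50, 120, 120, 0.01, 0.04), "strictly between")
})

test_that("reduced response agrees with the full-circuit integration", {
  # oracle equivalence on random valid parameter sets
  set.seed(42)
  for (k in 1:12) {
    A_max <- runif(1, 60, 200)
    A_pre <- runif(1, 0.05, 0.6) * A_max
    A_post <- runif(1, 0.1, 0.9) * A_max
    tau_e <- runif(1, 0.003, 0.05)
    tau_i <- runif(1, 0.01, 0.2)
    r <- reduced_params(A_pre, A_post, A_max, tau_e, tau_i, t_change = 0.05)
    cir <- circuit_for_reduced(r)
    tg <- seq(0, 1, by = min(tau_e, tau_i) / 20)
    full <- integrate_circuit(cir$params, list(t = c(0, 0.05),
                                               I = c(cir$I_pre, cir$I_post)), tg)
    red <- reduced_response(r, tg)
    expect_lt(max(abs(full$A_e - red$A_e)) / max(red$A_e), 0.005)
  }
})

test_that("fast-excitation peak formula matches its ODE limit", {
  expect_equal(peak_fast_excitation(50, 100, 120), 350)
  expect_equal(peak_fast_excitation(100, 50, 120), 1000 / 70)
  expect_equal(peak_fast_excitation(70, 70, 120), 70)
  expect_error(peak_fast_excitation(50, 120, 120), "below A_max")
  # decrement at time-scale ratio 1e-3: trough within 1% of the closed form
  ti <- 0.040
  grid_for <- function(te) c(seq(0, 50 * te, by = te / 10),
                             seq(50 * te + 0.001, 0.3, by = 0.001))
  tc_dec <- reduced_response(reduced_params(100, 50, 120, ti / 1000, ti),
                             grid_for(ti / 1000))
  expect_equal(min(tc_dec$A_e), 1000 / 70, tolerance = 0.01)
  # increment converges to the closed form as the ratio shrinks
  peak_at <- function(ratio) {
    te <- ti * ratio
    max(reduced_response(reduced_params(50, 100, 120, te, ti),
                         grid_for(te))$A_e)
  }
  err3 <- abs(peak_at(1e-3) - 350) / 350
  err4 <- abs(peak_at(1e-4) - 350) / 350
  expect_lt(err4, err3)
  expect_lt(err4, 0.01)
})

test_that("speed tuning is log-Gaussian around the preferred speed", {
  tun <- speed_tuning(A0 = 5, A_pref = 60, v_pref = 8, sigma_v = log(2^2.5))
  expect_equal(speed_tuning_rate(8, tun), 65)
  for (k in c(1.7, 3, 0.4))
    expect_equal(speed_tuning_rate(8 * k, tun), speed_tuning_rate(8 / k, tun))
  tun0 <- speed_tuning(A0 = 0, A_pref = 60, v_pref = 8, sigma_v = log(2^2.5))
  expect_equal(speed_tuning_rate(8 * 2^2.5, tun0), 60 * exp(-0.5))
  expect_error(speed_tuning_rate(-1, tun), "positive")
})

test_that("predicted change response has consistent transient signs", {
  tun <- speed_tuning(A0 = 0, A_pref = 60, v_pref = 8, sigma_v = log(2^2.5))
  A_max <- 1.4 * tun$A_pref
  # no change
  r0 <- predict_change_response(4, 4, tun, A_max)
  expect_equal(r0$A_peak, r0$A_pre)
  expect_equal(r0$transient_change, 1)
  # sign(A_peak - A_pre) equals sign(A_post - A_pre) across a grid
  for (v_pre in c(2, 4, 6, 12, 20)) for (fac in c(0.4, 0.7, 1.5, 2.2)) {
    r <- predict_change_response(v_pre, v_pre * fac, tun, A_max)
    expect_equal(sign(r$A_peak - r$A_pre), sign(r$A_post - r$A_pre))
  }
  # ascending flank, large Weber fraction: transient exceeds sustained change
  r <- predict_change_response(2, 6, tun, A_max)
  expect_gt(r$A_peak / r$A_pre, r$A_post / r$A_pre)
  expect_gt(r$A_post, r$A_pre)
  expect_error(predict_change_response(8, 8, tun, A_max = 50),
               "A_max")
})
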