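lin_of <- function(a1, a2, tau1, tau2) {
  linearize_model(two_delay_model(a1 = a1, a2 = a2, tau1 = tau1,
                                  tau2 = tau2), "zero")
}

test_that("characteristic residual vanishes at known exact roots", {
  # lambda = i solves lambda = -e^{-lambda pi/2}
  expect_equal(char_residual(lin_of(-1, 0, pi / 2, pi / 2), 1i), 0 + 0i,
               tolerance = 1e-14)
  # at lambda = 0 the exponentials are 1: residual is -(c1 + c2)
  expect_equal(char_residual(lin_of(3, -4, 0.7, 1.9), 0), 1 + 0i)
  # exact Hopf point at omega = 10
  expect_lt(Mod(char_residual(lin_of(-7, 3, pi / 20, 3 * pi / 20), 10i)),
            1e-12)
})

test_that("rightmost root matches the Lambert-W and limiting oracles", {
  # principal Lambert W branch at -1 (frozen from an independent
  # special-function evaluation)
  r <- rightmost_root(lin_of(-1, 0, 1, 1))
  expect_equal(Re(r$lambda), -0.3181315052047642, tolerance = 1e-6)
  expect_equal(Im(r$lambda), 1.3372357014306893, tolerance = 1e-6)
  expect_lt(r$residual, 1e-9)

  # exact marginal root i at tau = pi/2
  r2 <- rightmost_root(lin_of(-1, 0, pi / 2, pi / 2))
  expect_lt(abs(Re(r2$lambda)), 1e-9)
  expect_equal(Im(r2$lambda), 1, tolerance = 1e-9)

  # vanishing delays: root tends to a1 + a2
  r3 <- rightmost_root(lin_of(-2, -3, 1e-6, 1e-6))
  expect_equal(Re(r3$lambda), -5, tolerance = 1e-3)

  # exactly zero delays: the equation is linear
  r0 <- rightmost_root(lin_of(-7, 3, 0, 0))
  expect_identical(r0$lambda, -4 + 0i)
})

test_that("reported roots come in conjugate pairs", {
  for (lin in list(lin_of(-1, 0, 1, 1), lin_of(-3, -5, 0.1, 0.3),
                   lin_of(-7, 3, pi / 20, 3 * pi / 20))) {
    r <- rightmost_root(lin)
    for (z in r$roots)
      expect_lt(Mod(char_residual(lin, Conj(z))), 1e-9)
  }
})

test_that("small-delay verdicts follow the sign conditions and the root", {
  # both feedbacks negative: stable zero point
  v <- small_delay_verdict(
    two_delay_model(a1 = -3, a2 = -5, tau1 = 0.1, tau2 = 0.3), "zero")
  expect_true(v$small_delay_stable)
  expect_identical(v$verdict, "stable")
  # at these actual delays the second-order reduction is outside its
  # small-delay regime: 1 + a1 tau1 + a2 tau2 = -0.8 < 0 even though the
  # delay model itself is stable
  expect_true(v$reduced_ode_conditions[["denom_negative"]])
  expect_true(v$reduced_ode_conditions[["feedback_sum_negative"]])
  expect_false(v$reduced_ode_conditions[["damping_term_positive"]])

  # pure positive feedback: unstable
  v2 <- small_delay_verdict(
    two_delay_model(a1 = 1, a2 = 1, tau1 = 0.01, tau2 = 0.02), "zero")
  expect_false(v2$small_delay_stable)
  expect_identical(v2$verdict, "unstable")

  # exact Hopf point classifies as marginal, not by floating-point luck
  v3 <- small_delay_verdict(
    two_delay_model(a1 = -7, a2 = 3, tau1 = pi / 20, tau2 = 3 * pi / 20),
    "zero")
  expect_identical(v3$verdict, "marginal")

  # tremor model at the non-zero point: a1 + a2 > 0 is the stability
  # condition there, confirmed by the rightmost root
  v4 <- small_delay_verdict(
    two_delay_model(a1 = 0.2, a2 = 0.1, b1 = -1, b2 = 1.15,
                    tau1 = 0.1, tau2 = 0.3), "positive")
  expect_true(v4$small_delay_stable)
  expect_identical(v4$verdict, "stable")
})

test_that("approximate real root of the tremor model carries a residual", {
  m <- two_delay_model(a1 = 0.2, a2 = 0.1, b1 = -1, b2 = 1.15,
                       tau1 = 0.1, tau2 = 0.3)
  ap <- approx_root_parkinson(m)
  expect_equal(ap$lambda, -0.6)

  # small delays: the delayed terms nearly cancel and the residual is small
  m2 <- two_delay_model(a1 = 1, a2 = 1, b1 = -1, b2 = 2,
                        tau1 = 0.01, tau2 = 0.02)
  ap2 <- approx_root_parkinson(m2)
  expect_equal(ap2$lambda, -4)
  expect_lt(ap2$residual, 0.2)

  # marginal feedback sum: approximation degenerates to 0 and there is
  # no non-zero point to linearize at
  m3 <- two_delay_model(a1 = 1, a2 = -1, b1 = -1, b2 = 2,
                        tau1 = 0.01, tau2 = 0.02)
  ap3 <- approx_root_parkinson(m3)
  expect_equal(ap3$lambda, 0)
  expect_true(is.na(ap3$residual))

  expect_error(approx_root_parkinson(
    two_delay_model(a1 = 1, a2 = 1, b1 = -1, b2 = 2,
                    tau1 = 0.02, tau2 = 0.01)), "tau2 > tau1")
})

test_that("imaginary-axis scan finds Hopf points and rejects stable models", {
  w <- hopf_scan(lin_of(-7, 3, pi / 20, 3 * pi / 20), omega_max = 50)
  expect_true(any(abs(Im(w) - 10) < 1e-6))

  w2 <- hopf_scan(lin_of(-1, 0, pi / 2, pi / 2), omega_max = 10)
  expect_true(any(abs(Im(w2) - 1) < 1e-6))

  expect_length(hopf_scan(lin_of(-1, 0, 0.01, 0.01), omega_max = 50), 0)
})

test_that("sign of a1 + a2 predicts simulated decay/growth at small delays", {
  set.seed(7)
  for (i in 1:50) {
    repeat {
      m <- random_linear_model()
      if (abs(m$a1 + m$a2) > 0.5) break
    }
    traj <- dde_integrate(m, 1, t_end = 2, h = 0.005)
    head_rms <- sqrt(mean(traj$x[traj$t <= 0.5]^2))
    tail_rms <- sqrt(mean(traj$x[traj$t >= 1.5]^2))
    expect_identical(tail_rms > head_rms, m$a1 + m$a2 > 0,
                     label = sprintf("a1=%g a2=%g", m$a1, m$a2))
  }
})

test_that("rightmost root's real part matches the simulated growth rate", {
  check_rate <- function(model, t_end, h, t_min) {
    lam <- rightmost_root(linearize_model(model, "zero"))$lambda
    traj <- dde_integrate(model, 1, t_end, h)
    rate <- measured_growth_rate(traj, t_min)
    expect_lt(abs(rate - Re(lam)), 0.1 * abs(Re(lam)))
  }
  check_rate(two_delay_model(a1 = -1, a2 = 0, tau1 = 1, tau2 = 1),
             t_end = 60, h = 0.02, t_min = 10)
  check_rate(two_delay_model(a1 = -3, a2 = -5, tau1 = 0.1, tau2 = 0.3),
             t_end = 40, h = 0.01, t_min = 10)
  check_rate(two_delay_model(a1 = 0.5, a2 = 0.3, tau1 = 0.1, tau2 = 0.2),
             t_end = 12, h = 0.01, t_min = 2)
})

test_that("bisection on the rightmost root recovers the feedback threshold", {
  cs <- critical_feedback_sum(a2 = -1, tau1 = 1e-4, tau2 = 1e-4,
                              interval = c(0.5, 1.5), tol = 1e-6)
  expect_lt(abs(cs$critical_sum), 1e-3)
  expect_error(critical_feedback_sum(interval = c(2, 3)),
               "does not change sign")
})
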