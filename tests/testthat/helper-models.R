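# shared fixtures and oracles, all built in code

# cubic model with a guaranteed non-zero fixed point (b1 < 0 < b2)
random_cubic_model <- function() {
  repeat {
    a1 <- runif(1, -2, 2); a2 <- runif(1, -2, 2)
    b1 <- runif(1, -2, -0.1); b2 <- runif(1, 0.1, 2)
    if (abs(b1 + b2) > 0.05 && (a1 + a2) / (b1 + b2) > 0.01) break
  }
  two_delay_model(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                  tau1 = runif(1, 0, 1), tau2 = runif(1, 0, 1))
}

random_linear_model <- function(tau_min = 0.01, tau_max = 0.05,
                                a_min = -2, a_max = 2) {
  two_delay_model(a1 = runif(1, a_min, a_max), a2 = runif(1, a_min, a_max),
                  tau1 = runif(1, tau_min, tau_max),
                  tau2 = runif(1, tau_min, tau_max))
}

# empirical exponential growth rate of a trajectory tail: slope of
# log-amplitude, using |x| peaks when the signal oscillates
measured_growth_rate <- function(traj, t_min) {
  sel <- traj$t >= t_min
  t <- traj$t[sel]
  x <- abs(traj$x[sel])
  n <- length(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(pk) >= 5L) {
    unname(stats::coef(stats::lm(log(x[pk]) ~ t[pk]))[2])
  } else {
    unname(stats::coef(stats::lm(log(x) ~ t))[2])
  }
}

# mixed relative error: |a - b| / max(1, |b|)
rel_err <- function(a, b) abs(a - b) / pmax(1, abs(b))
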