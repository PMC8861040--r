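#' Taylor reduction of the linear two-delay model
#'
#' Expanding `x(t - tau)` about zero delay to second order turns the
#' linear model `dx/dt = a1 x(t-tau1) + a2 x(t-tau2)` into the damped
#' harmonic oscillator
#' \deqn{\ddot x + \mu \dot x + \beta x = 0}
#' with
#' `mu = -2 (1 + a1 tau1 + a2 tau2) / (a1 tau1^2 + a2 tau2^2)` and
#' `beta = 2 (a1 + a2) / (a1 tau1^2 + a2 tau2^2)`.
#' The truncation is exactly second order; no remainder is estimated, and
#' for delays that are not small the reduced ODE can disagree
#' qualitatively with the delay model (e.g. predict negative damping
#' where the delay model decays) — the coefficients are reported as-is so
#' such divergences are visible.
#'
#' @param model a linear [two_delay_model()] (`b1 = b2 = 0`).
#' @return An object of class `reduced_ode`: list with `mu`, `beta`,
#'   `alpha` (`NULL` for the linear reduction) and the diagnostic
#'   denominator `denom = a1 tau1^2 + a2 tau2^2`.
#' @export
reduce_linear <- function(model) {
  stopifnot(inherits(model, "two_delay_model"))
  if (!is_linear_model(model))
    stop("reduce_linear requires a linear model (b1 = b2 = 0)")
  denom <- model$a1 * model$tau1^2 + model$a2 * model$tau2^2
  if (denom == 0)
    stop("Taylor reduction degenerate: a1*tau1^2 + a2*tau2^2 = 0")
  g <- 1 + model$a1 * model$tau1 + model$a2 * model$tau2
  structure(list(mu = -2 * g / denom,
                 beta = 2 * (model$a1 + model$a2) / denom,
                 alpha = NULL, denom = denom),
            class = "reduced_ode")
}

#' Taylor reduction of the two-delay Van der Pol model
#'
#' For the canonical cubic signs `b1 = -1, b2 = 1` (cubic term
#' `-x^2 (x(t-tau2) - x(t-tau1))`), expanding the linear part to second
#' order and collapsing `x(t-tau2) - x(t-tau1)` to
#' `(tau2 - tau1) dx/dt` (mean value step) yields the Van der Pol form
#' \deqn{\ddot x + \mu (x^2 - \alpha) \dot x + \beta x = 0}
#' with `alpha = (1 + a1 tau1 + a2 tau2) / (tau2 - tau1)`,
#' `mu = 2 (tau2 - tau1) / (a1 tau1^2 + a2 tau2^2)` and `beta` as in
#' [reduce_linear()]. No reduced form exists for general cubic
#' coefficients; other models are rejected.
#'
#' @param model a [two_delay_model()] with `b1 = -1`, `b2 = 1`, shared
#'   delays, and `tau1 != tau2`.
#' @return A `reduced_ode` with `mu`, `beta`, `alpha`, `denom`.
#' @export
reduce_vdp <- function(model) {
  stopifnot(inherits(model, "two_delay_model"))
  if (!(model$b1 == -1 && model$b2 == 1) || !has_shared_delays(model))
    stop(paste("reduce_vdp requires the canonical Van der Pol form",
               "b1 = -1, b2 = 1 with shared delays"))
  if (model$tau1 == model$tau2)
    stop("alpha undefined: tau1 = tau2")
  denom <- model$a1 * model$tau1^2 + model$a2 * model$tau2^2
  if (denom == 0)
    stop("Taylor reduction degenerate: a1*tau1^2 + a2*tau2^2 = 0")
  g <- 1 + model$a1 * model$tau1 + model$a2 * model$tau2
  dtau <- model$tau2 - model$tau1
  structure(list(mu = 2 * dtau / denom,
                 beta = 2 * (model$a1 + model$a2) / denom,
                 alpha = g / dtau, denom = denom),
            class = "reduced_ode")
}

#' @export
print.reduced_ode <- function(x, ...) {
  if (is.null(x$alpha)) {
    cat(sprintf("Reduced ODE: x'' + %g x' + %g x = 0\n", x$mu, x$beta))
  } else {
    cat(sprintf("Reduced ODE: x'' + %g (x^2 - %g) x' + %g x = 0\n",
                x$mu, x$alpha, x$beta))
  }
  cat(sprintf("  denominator a1*tau1^2 + a2*tau2^2 = %g\n", x$denom))
  invisible(x)
}

#' Delays of the RLC phase-shift representation
#'
#' An AC current `I = Imax cos(2 pi f t)` satisfies
#' `dI/dt = -2 pi f I(t - 1/(4f))` (quarter-period lag, capacitor branch)
#' and `I = Imax sin(2 pi f t)` satisfies
#' `dI/dt = +2 pi f I(t - 3/(4f))` (inductor branch), so the series RLC
#' circuit maps onto the two-delay model with `tau1 = 1/(4f)` and
#' `tau2 = 3/(4f)`; note `tau2 = 3 tau1` exactly.
#'
#' @param f oscillation frequency (> 0), 1/time.
#' @return Named numeric vector `c(tau1, tau2)`.
#' @export
rlc_delays <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0)
    stop("frequency f must be positive")
  c(tau1 = 1 / (4 * f), tau2 = 3 / (4 * f))
}

#' Residual of the RLC delay identities
#'
#' Evaluates, with exact derivatives, the two trigonometric identities
#' behind [rlc_delays()] on a time grid:
#' `dI/dt + 2 pi f I(t - 1/(4f))` for `I = cos(2 pi f t)` and
#' `dI/dt - 2 pi f I(t - 3/(4f))` for `I = sin(2 pi f t)`.
#' Both are identically zero; the returned maxima are rounding noise.
#'
#' @param f frequency (> 0).
#' @param t_grid evaluation times.
#' @return List with `capacitor`, `inductor` (max absolute residual of
#'   each branch) and `max`.
#' @export
rlc_identity_residual <- function(f, t_grid = seq(0, 2, by = 0.01)) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0)
    stop("frequency f must be positive")
  w <- 2 * pi * f
  tau <- rlc_delays(f)
  r_cap <- -w * sin(w * t_grid) + w * cos(w * (t_grid - tau[["tau1"]]))
  r_ind <- w * cos(w * t_grid) - w * sin(w * (t_grid - tau[["tau2"]]))
  list(capacitor = max(abs(r_cap)), inductor = max(abs(r_ind)),
       max = max(abs(c(r_cap, r_ind))))
}

#' Simulate a reduced second-order oscillator
#'
#' RK4 integration of `x'' + mu x' + beta x = 0` (linear reduction) or
#' `x'' + mu (x^2 - alpha) x' + beta x = 0` (Van der Pol reduction) as a
#' first-order pair, with the same blow-up guard as [dde_integrate()].
#'
#' @param coeffs a `reduced_ode` from [reduce_linear()] / [reduce_vdp()],
#'   or a list with fields `mu`, `beta` and optionally `alpha`.
#' @param x0,v0 initial displacement and velocity.
#' @param t_end,h horizon and step (> 0).
#' @param blowup abort threshold on `|x|`.
#' @return A `dde_trajectory` whose `dx` field holds the velocity.
#' @export
simulate_reduced_ode <- function(coeffs, x0, v0, t_end, h, blowup = 1e8) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be positive")
  if (t_end <= 0) stop("t_end must be positive")
  mu <- coeffs$mu; beta <- coeffs$beta; alpha <- coeffs$alpha
  acc <- if (is.null(alpha)) {
    function(x, v) -mu * v - beta * x
  } else {
    function(x, v) -mu * (x^2 - alpha) * v - beta * x
  }
  n <- ceiling(t_end / h - 1e-9)
  tt <- numeric(n + 1L); xx <- numeric(n + 1L); vv <- numeric(n + 1L)
  tt[1] <- 0; xx[1] <- x0; vv[1] <- v0
  t <- 0; x <- x0; v <- v0
  i <- 1L
  while (t < t_end - 1e-12) {
    hh <- min(h, t_end - t)
    k1x <- v;                 k1v <- acc(x, v)
    k2x <- v + hh / 2 * k1v;  k2v <- acc(x + hh / 2 * k1x, k2x)
    k3x <- v + hh / 2 * k2v;  k3v <- acc(x + hh / 2 * k2x, k3x)
    k4x <- v + hh * k3v;      k4v <- acc(x + hh * k3x, k4x)
    x <- x + hh / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v <- v + hh / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    t <- t + hh
    if (!is.finite(x) || abs(x) > blowup) {
      cond <- structure(
        class = c("twodelay_blowup", "error", "condition"),
        list(message = sprintf(
               "solution blew up (|x| > %g) at t = %g", blowup, t),
             call = sys.call(-1), time = t))
      stop(cond)
    }
    i <- i + 1L
    tt[i] <- t; xx[i] <- x; vv[i] <- v
  }
  structure(list(t = tt[1:i], x = xx[1:i], dx = vv[1:i],
                 h = h, t_end = tt[i], model = NULL),
            class = "dde_trajectory")
}
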