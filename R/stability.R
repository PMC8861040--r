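#' Characteristic function of a linearized delay model
#'
#' For the linearization `dx/dt = c0 x(t) + sum_i c_i x(t - tau_i)` the
#' exponential ansatz `x = e^(lambda t)` gives the transcendental
#' characteristic equation
#' \deqn{\lambda = c_0 + \sum_i c_i e^{-\lambda \tau_i}.}
#' `char_residual()` returns the defect
#' `lambda - c0 - sum_i c_i exp(-lambda tau_i)`; a root has residual 0.
#'
#' @param lin a `dde_linearization` from [linearize_model()].
#' @param lam complex value(s) at which to evaluate.
#' @return Complex residual(s), vectorised over `lam`.
#' @export
char_residual <- function(lin, lam) {
  lam <- as.complex(lam)
  res <- lam - lin$c0
  for (j in seq_along(lin$coef))
    res <- res - lin$coef[j] * exp(-lam * lin$tau[j])
  res
}

char_derivative <- function(lin, lam) {
  d <- rep(1 + 0i, length(lam))
  for (j in seq_along(lin$coef))
    d <- d + lin$coef[j] * lin$tau[j] * exp(-lam * lin$tau[j])
  d
}

newton_polish <- function(lin, seeds, maxit = 60L, step_cap = 5) {
  lam <- as.complex(seeds)
  for (it in seq_len(maxit)) {
    g <- char_residual(lin, lam)
    gp <- char_derivative(lin, lam)
    step <- g / gp
    bad <- !is.finite(Re(step)) | !is.finite(Im(step))
    step[bad] <- 0
    big <- Mod(step) > step_cap
    step[big] <- step[big] / Mod(step[big]) * step_cap
    lam <- lam - step
  }
  lam
}

#' Rightmost characteristic root
#'
#' Locates the characteristic root with maximal real part by Newton
#' iteration started from a grid of seeds covering a search box, keeping
#' every converged root (residual below `tol`). Conjugate pairs are
#' reported with non-negative imaginary part (`omega >= 0`). With all
#' delays zero the equation is linear and the root is exactly
#' `c0 + sum(c_i)`.
#'
#' @param lin a `dde_linearization`.
#' @param search_real,search_imag real/imaginary intervals of the seed
#'   box (defaults cover all shipped reference cases).
#' @param n_real,n_imag seed grid resolution.
#' @param tol residual threshold for a converged root.
#' @return An object of class `char_root`: list with `lambda` (the
#'   rightmost root), `residual`, and `roots` (all distinct converged
#'   roots, sorted by decreasing real part).
#' @export
rightmost_root <- function(lin, search_real = c(-20, 5),
                           search_imag = c(0, 50),
                           n_real = 13L, n_imag = 21L, tol = 1e-9) {
  if (all(lin$tau == 0)) {
    lam <- complex(real = lin$c0 + sum(lin$coef), imaginary = 0)
    return(structure(list(lambda = lam, residual = 0, roots = lam),
                     class = "char_root"))
  }
  seeds <- outer(seq(search_real[1], search_real[2], length.out = n_real),
                 1i * seq(search_imag[1], search_imag[2],
                          length.out = n_imag), `+`)
  lam <- newton_polish(lin, as.vector(seeds))
  res <- Mod(char_residual(lin, lam))
  lam <- lam[is.finite(res) & res <= tol]
  if (length(lam) == 0L)
    stop("no characteristic root located from any seed in the search box")
  lam <- complex(real = Re(lam), imaginary = abs(Im(lam)))
  roots <- lam[1]
  for (z in lam[-1])
    if (all(Mod(roots - z) > 1e-6)) roots <- c(roots, z)
  roots <- roots[order(-Re(roots), Im(roots))]
  structure(list(lambda = roots[1],
                 residual = Mod(char_residual(lin, roots[1])),
                 roots = roots),
            class = "char_root")
}

#' @export
print.char_root <- function(x, ...) {
  cat(sprintf("Rightmost characteristic root: %.6g %+.6gi (residual %.2g)\n",
              Re(x$lambda), Im(x$lambda), x$residual))
  cat(sprintf("  %d distinct root(s) located in the search box\n",
              length(x$roots)))
  invisible(x)
}

#' Small-delay stability verdict at a fixed point
#'
#' Combines the closed-form small-delay sign conditions with the computed
#' rightmost characteristic root of the linearization:
#' * zero fixed point: asymptotically stable for very small delays iff
#'   `a1 + a2 < 0`;
#' * non-zero fixed point: asymptotically stable for small delays
#'   (`tau2 > tau1`) iff `a1 + a2 > 0`, via the approximate real root
#'   `-2 (a1 + a2)` of its characteristic equation;
#' * reduced-ODE condition set (stability of the second-order Taylor
#'   reduction of the associated linear model about zero):
#'   `a1 tau1^2 + a2 tau2^2 < 0`, `1 + a1 tau1 + a2 tau2 > 0`,
#'   `a1 + a2 < 0`.
#'
#' The verdict itself always comes from the sign of the rightmost root's
#' real part, with a `marginal` band of plus/minus 1e-6 so that exact
#' Hopf points classify as marginal rather than by floating-point luck.
#'
#' @param model a [two_delay_model()].
#' @param point fixed point (value, kind string, or row of
#'   [fixed_points()]).
#' @param ... passed to [rightmost_root()].
#' @return An object of class `stability_verdict`: list with
#'   `small_delay_stable`, `reduced_ode_conditions` (named logicals),
#'   `rightmost` (a `char_root`), `verdict`
#'   (`"stable"`, `"marginal"`, `"unstable"`), `point`, and the
#'   linearization.
#' @export
small_delay_verdict <- function(model, point = "zero", ...) {
  lin <- linearize_model(model, point)
  asum <- model$a1 + model$a2
  small_delay_stable <- if (lin$point == 0) asum < 0 else asum > 0
  denom <- model$a1 * model$tau1^2 + model$a2 * model$tau2^2
  conds <- c(denom_negative = denom < 0,
             damping_term_positive = 1 + model$a1 * model$tau1 +
               model$a2 * model$tau2 > 0,
             feedback_sum_negative = asum < 0)
  rm <- rightmost_root(lin, ...)
  re <- Re(rm$lambda)
  verdict <- if (re > 1e-6) "unstable" else if (re < -1e-6) "stable"
             else "marginal"
  structure(list(point = lin$point,
                 small_delay_stable = small_delay_stable,
                 reduced_ode_conditions = conds,
                 rightmost = rm, verdict = verdict,
                 linearization = lin),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("Stability at fixed point x* = %g\n", x$point))
  cat(sprintf("  verdict:                %s\n", x$verdict))
  cat(sprintf("  rightmost root:         %.6g %+.6gi\n",
              Re(x$rightmost$lambda), Im(x$rightmost$lambda)))
  cat(sprintf("  small-delay condition:  %s\n",
              if (x$small_delay_stable) "satisfied" else "violated"))
  cat("  reduced-ODE conditions:",
      paste(sprintf("%s=%s", names(x$reduced_ode_conditions),
                    x$reduced_ode_conditions), collapse = ", "), "\n")
  invisible(x)
}

#' Approximate real root at the non-zero fixed point
#'
#' For the cubic feedback model at its non-zero fixed point, with
#' `tau2 > tau1` and a negative real root, the delayed terms of the
#' characteristic equation nearly cancel and the root is approximately
#' \deqn{\lambda \approx -2 (a_1 + a_2).}
#' The exact characteristic residual at that value is returned as a
#' quality diagnostic; the approximation is never silently substituted
#' for the true rightmost root.
#'
#' @param model a [two_delay_model()] with `tau2 > tau1` and a non-zero
#'   fixed point.
#' @return List with `lambda` (the approximation) and `residual`
#'   (modulus of the characteristic residual there).
#' @export
approx_root_parkinson <- function(model) {
  if (model$tau2 <= model$tau1)
    stop("approximation requires tau2 > tau1")
  lam <- -2 * (model$a1 + model$a2)
  res <- tryCatch(
    Mod(char_residual(linearize_model(model, "positive"), lam)),
    error = function(e) NA_real_)  # no non-zero fixed point to linearize at
  list(lambda = lam, residual = res)
}

#' Scan for purely imaginary characteristic roots (Hopf points)
#'
#' Evaluates the characteristic residual along the imaginary axis,
#' refines every sign change of its real or imaginary part by bisection,
#' polishes with complex Newton iteration, and keeps the roots that land
#' on the axis (|Re| <= 1e-8) with residual below `tol`. A conjugate
#' pair crossing the axis signals a Hopf point; an empty result means no
#' imaginary-axis root up to `omega_max`.
#'
#' @param lin a `dde_linearization`.
#' @param omega_max upper bound of the scanned angular frequency (> 0).
#' @param n scan grid resolution.
#' @param tol residual threshold.
#' @return Complex vector of roots `i omega` with `omega > 0` (possibly
#'   empty).
#' @export
hopf_scan <- function(lin, omega_max, n = 4000L, tol = 1e-9) {
  if (!is.numeric(omega_max) || omega_max <= 0)
    stop("omega_max must be positive")
  w <- seq(0, omega_max, length.out = n + 1L)[-1]
  g <- char_residual(lin, 1i * w)
  cand <- c()
  for (part in list(Re, Im)) {
    v <- part(g)
    flips <- which(v[-length(v)] * v[-1] < 0)
    for (k in flips) {
      r <- stats::uniroot(function(om) part(char_residual(lin, 1i * om)),
                          c(w[k], w[k + 1]), tol = 1e-12)
      cand <- c(cand, r$root)
    }
    cand <- c(cand, w[which(v == 0)])
  }
  if (length(cand) == 0L) return(complex(0))
  lam <- newton_polish(lin, 1i * cand, maxit = 40L)
  res <- Mod(char_residual(lin, lam))
  keep <- is.finite(res) & res <= tol & abs(Re(lam)) <= 1e-8 &
    Im(lam) > 1e-8 & Im(lam) <= omega_max * (1 + 1e-6)
  lam <- complex(real = 0, imaginary = Im(lam[keep]))
  if (length(lam) == 0L) return(complex(0))
  out <- lam[1]
  for (z in lam[-1])
    if (all(Mod(out - z) > 1e-6 * max(1, Mod(z)))) out <- c(out, z)
  out[order(Im(out))]
}

#' Critical total feedback of the linear model in the small-delay limit
#'
#' Bisection on `a1` (with `a2` and both delays fixed) against the sign
#' of the rightmost characteristic root's real part. In the small-delay
#' limit the zero fixed point of the linear two-delay model loses
#' asymptotic stability exactly where the total feedback `a1 + a2`
#' crosses 0, so the returned critical sum recovers that threshold.
#'
#' @param a2 fixed second feedback coefficient.
#' @param tau1,tau2 fixed delays.
#' @param interval search interval for `a1`; the rightmost root's real
#'   part must change sign across it.
#' @param tol bisection tolerance on `a1`.
#' @return List with `a1` (critical value), `critical_sum` (`a1 + a2`),
#'   and `iterations`.
#' @export
critical_feedback_sum <- function(a2 = -1, tau1 = 1e-4, tau2 = 1e-4,
                                  interval = c(0.5, 1.5), tol = 1e-6) {
  re_at <- function(a1) {
    m <- two_delay_model(a1 = a1, a2 = a2, tau1 = tau1, tau2 = tau2)
    Re(rightmost_root(linearize_model(m, "zero"))$lambda)
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- re_at(lo); fhi <- re_at(hi)
  if (sign(flo) == sign(fhi))
    stop("rightmost root's real part does not change sign on the interval")
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- re_at(mid)
    it <- it + 1L
    if (fm == 0) { lo <- mid; hi <- mid; break }
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  a1 <- (lo + hi) / 2
  list(a1 = a1, critical_sum = a1 + a2, iterations = it)
}
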