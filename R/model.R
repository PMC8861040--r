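#' Two-delay cubic feedback model
#'
#' Constructs the scalar delay differential equation
#' \deqn{dx/dt = a_1 x(t-\tau_1) + a_2 x(t-\tau_2)
#'   - x(t)^2 \left(b_1 x(t-\tau_1^c) + b_2 x(t-\tau_2^c)\right)}
#' which contains three named special cases:
#' * `b1 = b2 = 0`: the linear two-delay model (associated linear model),
#' * `b1 = -1, b2 = 1`: the two-delay representation of the Van der Pol
#'   oscillator,
#' * general `b1 b2 < 0` with `|b1|` close to `|b2|`: the cubic feedback
#'   model of parkinsonian tremor, where `a1`, `a2` act as negative or
#'   positive feedback on the symptom amplitude.
#'
#' The cubic term normally reuses the delays of the linear term.
#' `tau1_cubic`/`tau2_cubic` allow a different pair of delays in the cubic
#' term; two of the shipped reference cases (see [case_registry()]) are
#' printed that way.
#'
#' @param a1,a2 linear feedback coefficients (1/time) on `x(t - tau1)` and
#'   `x(t - tau2)`.
#' @param b1,b2 cubic feedback coefficients (1/(amplitude^2 * time)).
#' @param tau1,tau2 non-negative delays (time) of the linear term.
#' @param tau1_cubic,tau2_cubic delays of the cubic term; default to the
#'   linear delays.
#' @return An object of class `two_delay_model`.
#' @examples
#' vdp <- two_delay_model(a1 = -0.9, a2 = 0.2, b1 = -1, b2 = 1,
#'                        tau1 = pi / 2, tau2 = 3 * pi / 2)
#' fixed_points(vdp)
#' @export
two_delay_model <- function(a1, a2, b1 = 0, b2 = 0, tau1, tau2,
                            tau1_cubic = tau1, tau2_cubic = tau2) {
  pars <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
            tau1 = tau1, tau2 = tau2,
            tau1_cubic = tau1_cubic, tau2_cubic = tau2_cubic)
  if (!all(is.finite(pars)))
    stop("all model parameters must be finite numbers")
  if (tau1 < 0 || tau2 < 0 || tau1_cubic < 0 || tau2_cubic < 0)
    stop("delays must be non-negative")
  structure(
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
         tau1 = tau1, tau2 = tau2,
         tau1_cubic = tau1_cubic, tau2_cubic = tau2_cubic),
    class = "two_delay_model")
}

#' @export
print.two_delay_model <- function(x, ...) {
  cat("Two-delay model: dx/dt =",
      sprintf("%g x(t-%g) + %g x(t-%g)", x$a1, x$tau1, x$a2, x$tau2))
  if (x$b1 != 0 || x$b2 != 0)
    cat(sprintf(" - x^2 (%g x(t-%g) + %g x(t-%g))",
                x$b1, x$tau1_cubic, x$b2, x$tau2_cubic))
  cat("\n")
  if (x$b1 != 0 && x$b2 != 0)
    cat(sprintf("  |b1|/|b2| = %g (cubic feedback balance)\n",
                abs(x$b1) / abs(x$b2)))
  invisible(x)
}

is_linear_model <- function(model) model$b1 == 0 && model$b2 == 0

has_shared_delays <- function(model) {
  model$tau1_cubic == model$tau1 && model$tau2_cubic == model$tau2
}

model_delays <- function(model) {
  c(model$tau1, model$tau2, model$tau1_cubic, model$tau2_cubic)
}

#' History function for a delay differential equation
#'
#' A history prescribes the solution for `t <= 0`; the initial state is
#' `history(0)`. All reference cases use constant histories.
#'
#' @param value a single number (constant history) or a function of time
#'   defined on `[-max(delays), 0]`.
#' @return An object of class `dde_history`: a function of `t` with
#'   attributes `is_constant` and (when constant) `constant`.
#' @examples
#' h <- dde_history(2)
#' h(-0.5)
#' @export
dde_history <- function(value) {
  if (inherits(value, "dde_history")) return(value)
  if (is.function(value)) {
    f <- value
    is_const <- FALSE
    const <- NA_real_
  } else if (is.numeric(value) && length(value) == 1L && is.finite(value)) {
    const <- as.numeric(value)
    f <- function(t) rep_len(const, length(t))
    is_const <- TRUE
  } else {
    stop("history must be a finite number or a function of time")
  }
  structure(f, class = "dde_history",
            is_constant = is_const, constant = const)
}

#' Right-hand side of the two-delay model
#'
#' Evaluates
#' `a1*x1 + a2*x2 - x^2*(b1*x1c + b2*x2c)` where `x` is the current state,
#' `x1`, `x2` are the states at the linear delays and `x1c`, `x2c` at the
#' cubic delays (defaulting to `x1`, `x2`).
#'
#' @param model a [two_delay_model()].
#' @param x current state.
#' @param x1,x2 delayed states at `t - tau1`, `t - tau2`.
#' @param x1c,x2c delayed states of the cubic term.
#' @return The rate dx/dt. Vectorised over the state arguments.
#' @export
dde_rhs <- function(model, x, x1, x2, x1c = x1, x2c = x2) {
  if (!all(is.finite(c(x, x1, x2, x1c, x2c))))
    stop("non-finite state passed to dde_rhs")
  model$a1 * x1 + model$a2 * x2 - x^2 * (model$b1 * x1c + model$b2 * x2c)
}

#' Fixed points of the two-delay model
#'
#' The origin is always an equilibrium. When `b1 + b2 != 0` and
#' `(a1 + a2) / (b1 + b2) > 0` the cubic model has in addition the pair
#' `x* = +/- sqrt((a1 + a2) / (b1 + b2))`. The dynamics are odd-symmetric,
#' so both signs are genuine equilibria and both are returned, tagged by
#' kind. The Van der Pol special case (`b1 = -1, b2 = 1`) has `b1 + b2 = 0`
#' and therefore only the zero fixed point.
#'
#' @param model a [two_delay_model()].
#' @return A data frame with columns `value` and `kind`
#'   (`"zero"`, `"positive"`, `"negative"`).
#' @export
fixed_points <- function(model) {
  out <- data.frame(value = 0, kind = "zero", stringsAsFactors = FALSE)
  bsum <- model$b1 + model$b2
  asum <- model$a1 + model$a2
  if (bsum != 0 && asum / bsum > 0) {
    v <- sqrt(asum / bsum)
    out <- rbind(out,
                 data.frame(value = v, kind = "positive"),
                 data.frame(value = -v, kind = "negative"))
  }
  out
}

#' Linearize the model about a fixed point
#'
#' About the origin the cubic term has zero gradient, so the linearization
#' is the associated linear model: coefficients `a1` at delay `tau1` and
#' `a2` at delay `tau2`, no instantaneous term. About a non-zero fixed
#' point `x*` (shared delays) the linearization is
#' \deqn{d\xi/dt = \delta\,\xi(t-\tau_1) - \delta\,\xi(t-\tau_2)
#'   - 2(a_1+a_2)\,\xi(t)}
#' with `delta = (a1*b2 - a2*b1) / (b1 + b2)`. The general denominator
#' `b1 + b2` is used; in the Van der Pol sign convention `b1 = -1` it
#' coincides with the commonly printed `b2 - 1`.
#'
#' When the cubic delays differ from the linear ones, the non-zero-point
#' linearization carries one term per distinct delay
#' (`a_i` at the linear delays, `-x*^2 b_i` at the cubic delays) and no
#' single `delta` is defined.
#'
#' @param model a [two_delay_model()].
#' @param point a fixed-point value, a kind string
#'   (`"zero"`, `"positive"`, `"negative"`), or one row of
#'   [fixed_points()].
#' @return An object of class `dde_linearization`: a list with the
#'   instantaneous coefficient `c0`, vectors `coef` and `tau` of delayed
#'   terms, convenience fields `c1`, `c2`, `tau1`, `tau2` when there are
#'   exactly two delayed terms, `delta` (or `NA`), and `point`.
#' @export
linearize_model <- function(model, point = "zero") {
  fp <- fixed_points(model)
  if (is.data.frame(point)) point <- point$value[1]
  if (is.character(point)) {
    hit <- match(point, fp$kind)
    if (is.na(hit))
      stop(sprintf("model has no '%s' fixed point", point))
    v <- fp$value[hit]
  } else {
    v <- as.numeric(point)
    if (min(abs(fp$value - v)) > 1e-8)
      stop(sprintf("%g is not a fixed point of the model", v))
  }

  if (v == 0) {
    lin <- new_linearization(c0 = 0,
                             coef = c(model$a1, model$a2),
                             tau = c(model$tau1, model$tau2),
                             delta = NA_real_, point = 0)
    return(lin)
  }

  asum <- model$a1 + model$a2
  c0 <- -2 * asum  # equals -2 x*^2 (b1 + b2)
  if (has_shared_delays(model)) {
    delta <- (model$a1 * model$b2 - model$a2 * model$b1) /
      (model$b1 + model$b2)
    lin <- new_linearization(c0 = c0,
                             coef = c(delta, -delta),
                             tau = c(model$tau1, model$tau2),
                             delta = delta, point = v)
  } else {
    v2 <- v^2
    coef <- c(model$a1, model$a2, -v2 * model$b1, -v2 * model$b2)
    tau <- c(model$tau1, model$tau2, model$tau1_cubic, model$tau2_cubic)
    agg <- tapply(coef, tau, sum)
    lin <- new_linearization(c0 = c0,
                             coef = as.numeric(agg),
                             tau = as.numeric(names(agg)),
                             delta = NA_real_, point = v)
  }
  lin
}

new_linearization <- function(c0, coef, tau, delta, point) {
  lin <- list(c0 = c0, coef = coef, tau = tau, delta = delta, point = point)
  if (length(coef) == 2L) {
    lin$c1 <- coef[1]
    lin$c2 <- coef[2]
    lin$tau1 <- tau[1]
    lin$tau2 <- tau[2]
  }
  structure(lin, class = "dde_linearization")
}

#' @export
print.dde_linearization <- function(x, ...) {
  terms <- paste(sprintf("%g x(t-%g)", x$coef, x$tau), collapse = " + ")
  cat(sprintf("Linearization about x* = %g:\n  dx/dt = %s%s\n",
              x$point, terms,
              if (x$c0 != 0) sprintf(" + %g x(t)", x$c0) else ""))
  if (!is.na(x$delta)) cat(sprintf("  delta = %g\n", x$delta))
  invisible(x)
}

#' Finite-difference Jacobian of the right-hand side
#'
#' Central finite differences of [dde_rhs()] in each of its three state
#' arguments (current, first-delay, second-delay), evaluated at
#' `(x0, x0, x0)`. Serves as an independent oracle for
#' [linearize_model()] on shared-delay models.
#'
#' @param model a [two_delay_model()].
#' @param x0 state at which to differentiate.
#' @param step finite-difference step (> 0).
#' @return Numeric vector `c(c0, c1, c2)` of partial derivatives.
#' @export
numerical_jacobian <- function(model, x0, step = 1e-6) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be positive")
  f <- function(x, x1, x2) dde_rhs(model, x, x1, x2)
  c0 <- (f(x0 + step, x0, x0) - f(x0 - step, x0, x0)) / (2 * step)
  c1 <- (f(x0, x0 + step, x0) - f(x0, x0 - step, x0)) / (2 * step)
  c2 <- (f(x0, x0, x0 + step) - f(x0, x0, x0 - step)) / (2 * step)
  c(c0 = c0, c1 = c1, c2 = c2)
}
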