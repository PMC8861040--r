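---
title: "Two-delay oscillator models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-delay oscillator models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twodelay)
```

## The model family

Everything in this package revolves around one scalar delay differential
equation (DDE) in the tremor/oscillator family,

$$\frac{dx}{dt} = a_1\,x(t-\tau_1) + a_2\,x(t-\tau_2)
  - x(t)^2\bigl(b_1\,x(t-\tau_1) + b_2\,x(t-\tau_2)\bigr),$$

created by `two_delay_model()`. The state $x$ is an oscillation
amplitude (a current in the RLC reading, a tremor amplitude in the
neurological reading); $a_1, a_2$ (1/time) are delayed linear feedback
gains — negative values act as symptom-reducing (negative) feedback,
positive values as symptom-increasing (positive) feedback; $b_1, b_2$
(1/(amplitude²·time)) shape the cubic saturation; and $\tau_1, \tau_2
\ge 0$ (time) are the feedback latencies. Three sub-families matter:

* **linear** (`b1 = b2 = 0`): the associated linear model, whose exact
  dynamics are governed by a transcendental characteristic equation;
* **Van der Pol form** (`b1 = -1, b2 = 1`): the cubic term becomes
  $-x^2\{x(t-\tau_2) - x(t-\tau_1)\}$, a delayed difference that plays
  the role of the classical nonlinear damping. Since $b_1+b_2=0$ the
  origin is the only fixed point;
* **tremor feedback model** (general $b_1 b_2 < 0$, $|b_1|\approx|b_2|$):
  supports a non-zero fixed point
  $x^* = \pm\sqrt{(a_1+a_2)/(b_1+b_2)}$ at which symptoms can stabilize
  even under net positive feedback.

An AC circuit provides the delay interpretation: a cosine current obeys
$dI/dt = -2\pi f\,I(t - 1/(4f))$ and a sine current
$dI/dt = +2\pi f\,I(t - 3/(4f))$ exactly, so a quarter- and a
three-quarter-period lag stand in for the capacitive and inductive
phase shifts (`rlc_delays()`, `rlc_identity_residual()`).

Two reference cases print a cubic delay different from the linear ones;
the model type therefore carries optional `tau1_cubic`/`tau2_cubic`
fields. They default to the linear delays and everything specific to
the shared-delay theory (the Van der Pol reduction, the
$\delta$-linearization) requires them to coincide.

## Fixed points and linearization

`fixed_points()` returns the origin always, and the pair $\pm x^*$ when
the ratio $(a_1+a_2)/(b_1+b_2)$ is positive. The source narrative only
writes the positive root; because the vector field is odd, both signs
are equilibria, and we return both with `kind` tags so reports stay
unambiguous.

`linearize_model()` is analytic. About the origin the cubic gradient
vanishes and the linearization is the associated linear model. About
$x^*$ (shared delays) it is

$$\frac{d\xi}{dt} = \delta\,\xi(t-\tau_1) - \delta\,\xi(t-\tau_2)
  - 2(a_1+a_2)\,\xi(t), \qquad
  \delta = \frac{a_1 b_2 - a_2 b_1}{b_1 + b_2}.$$

A word on the denominator: the derivation is sometimes quoted with
$b_2 - 1$ in place of $b_1 + b_2$. The two coincide exactly in the
Van der Pol sign convention $b_1 = -1$, and only there; we implement the
general form, which is what the finite-difference oracle
(`numerical_jacobian()`, central differences, default step $10^{-6}$)
confirms for arbitrary coefficients. With distinct cubic delays the
non-zero-point linearization instead carries one term per distinct
delay ($a_i$ at the linear delays, $-x^{*2} b_i$ at the cubic delays)
and no single $\delta$ is reported.

## The integrator

`dde_integrate()` is a fixed-step classical Runge–Kutta (RK4) method of
steps with cubic Hermite dense output: every mesh node stores the state
and its derivative, and delayed lookups interpolate the completed mesh
(or evaluate the history when $s - \tau \le 0$). Design choices:

* **Fixed step, not an adaptive pair.** All shipped cases are smooth,
  small and non-stiff; a fixed step makes every run bit-reproducible,
  which the CLI promises, and accuracy is a matter of step refinement.
* **Step constraint `h <= min positive delay`.** Then every delayed
  lookup lands in the history or in completed steps and no implicit
  overlap handling is needed. Zero delays read the current stage state,
  so the family degenerates gracefully to an ODE.
* **Initial point convention** `x(0) = history(0)`; no jump-start
  discontinuities are supported.
* **Blow-up guard**: $|x| > 10^8$ aborts with an error condition of
  class `twodelay_blowup` carrying the failure time. Unstable parameter
  sets (including one shipped case, see below) escape in finite time
  and the guard converts that into a diagnosable error rather than an
  overflow.
* **Breakpoints.** DDE solutions lose one order of smoothness at the
  propagated points $k_1\tau_1 + k_2\tau_2$, which are generally not on
  the mesh. The practical effect is that `convergence_order()` observes
  an order between 3 and 4 on problems with active delays (3.86 on the
  cosine closed form at `h = 0.01`); we assert only $\ge 3$, and exact
  integration (`exact` flag) on polynomial solutions.

Accuracy anchors used in the tests: the cosine solution of
$dx/dt = -x(t-\pi/2)$ is reproduced to $1.3\times10^{-10}$ at
`h = 0.01`; the piecewise-polynomial solution of $dx/dt = 2x(t-1)$
with unit history gives $x(1) = 3$, $x(2) = 7$ to $10^{-12}$; and an
independent adaptive delay integrator (deSolve's `dede` at tolerance
$10^{-10}$) agrees to $4\times10^{-8}$ on the damped two-delay case.

## Taylor reduction to second-order oscillators

For small delays, expanding $x(t-\tau)$ to second order collapses the
linear model onto the damped harmonic oscillator
$\ddot x + \mu\dot x + \beta x = 0$ with

$$\mu = \frac{-2(1 + a_1\tau_1 + a_2\tau_2)}{a_1\tau_1^2 + a_2\tau_2^2},
\qquad
\beta = \frac{2(a_1 + a_2)}{a_1\tau_1^2 + a_2\tau_2^2},$$

(`reduce_linear()`), and — adding the mean-value collapse of the delayed
difference, $x(t-\tau_2) - x(t-\tau_1) \approx (\tau_2-\tau_1)\dot x$ —
the Van der Pol form onto
$\ddot x + \mu(x^2-\alpha)\dot x + \beta x = 0$ with
$\alpha = (1 + a_1\tau_1 + a_2\tau_2)/(\tau_2-\tau_1)$ and
$\mu = 2(\tau_2-\tau_1)/(a_1\tau_1^2 + a_2\tau_2^2)$ (`reduce_vdp()`).
The truncation is exactly second order; no remainder is estimated, and
the mean-value step carries no error bound. The two reductions are
consistent ($\mu_{vdp}\,\alpha = -\mu_{lin}$, equal $\beta$), which the
tests check on random parameter sets. `reduce_vdp()` deliberately
accepts only the canonical $(b_1,b_2) = (-1,1)$: no reduced form is
defined for the general cubic model, and guessing one would be worse
than refusing.

**Where the reduction is honest about failing.** The reduction is an
asymptotic statement. At the damped case's actual delays
(e.g. $a_1=-10, a_2=3, \tau_1=0.2, \tau_2=0.3$, or $a_1=-3, a_2=-5,
\tau_1=0.1, \tau_2=0.3$) the damping factor $1 + a_1\tau_1 + a_2\tau_2$
is negative, so the reduced ODE predicts growth while the delay model
decays. The `reduce` CLI command therefore prints the reduced-ODE
verdict and the delay-model (rightmost-root) verdict side by side
rather than hiding the disagreement. Quantitatively, tracking the gap
between the DDE's rightmost characteristic root and the dominant root
of $\lambda^2 + \mu\lambda + \beta = 0$ while the delays
$(0.1, 0.3)$ are scaled by $s \in \{1, 1/2, 1/4, 1/8\}$ (for
$a_1=-3,a_2=-5$) gives gaps 2.18, 2.98, 6.03, 0.096: *not* monotone,
because the sign change of $1 + a_1\tau_1 + a_2\tau_2$ at
$s \approx 0.56$ flips the reduced model between qualitatively wrong
regimes, and only past it does the asymptotic agreement bite (the
finest-scale gap is 20–60 times below every coarser one). The test
suite asserts the true asymptotic statement; a strict
monotone-decrease check over that scale range fails and is kept,
failing, as documentation of this limit of the reduction.

## Stability analysis

The exponential ansatz turns the linearization into the transcendental
characteristic equation
$\lambda = c_0 + \sum_i c_i e^{-\lambda\tau_i}$ (`char_residual()`).
`rightmost_root()` runs Newton's iteration from a grid of complex seeds
over a search box (default $\mathrm{Re} \in [-20, 5]$,
$\mathrm{Im} \in [0, 50]$ — all shipped cases have their dominant roots
well inside), keeps every converged root (residual $\le 10^{-9}$,
steps capped at modulus 5 for robustness), dedupes, and returns the
root of maximal real part with $\omega \ge 0$ by conjugate symmetry. A
contour/argument count was considered and rejected as the primary
method — the multi-seed Newton grid is simpler and independently
cross-checked in the tests by simulation: the measured log-amplitude
slope of integrated trajectories matches $\mathrm{Re}\,\lambda$ within
10%. With both delays exactly zero the equation is linear and
$c_0 + \sum c_i$ is returned directly.

`small_delay_verdict()` reports three things side by side and does not
conflate them: (i) the small-delay sign condition — $a_1 + a_2 < 0$ for
the zero point, $a_1 + a_2 > 0$ for the non-zero point (via its
approximate real root $\lambda \approx -2(a_1+a_2)$,
`approx_root_parkinson()`, which always carries the exact residual of
the characteristic equation as a quality diagnostic and is never
substituted for the computed root); (ii) the reduced-ODE condition set
($a_1\tau_1^2 + a_2\tau_2^2 < 0$, $1 + a_1\tau_1 + a_2\tau_2 > 0$,
$a_1 + a_2 < 0$); (iii) the verdict itself, always from the sign of the
rightmost root's real part with a **marginal band of $\pm 10^{-6}$**:
one shipped case is an exact Hopf point ($\lambda = 10i$ solves its
characteristic equation in closed form) and must classify as
`marginal` by design, not as stable or unstable by floating-point luck.
On the narrative side the non-zero point's stability condition is
sometimes quoted with the opposite sign ($a_1+a_2<0$); the derivation
from the characteristic equation gives $a_1+a_2>0$ and that is what we
implement, with the discrepancy noted rather than silently resolved.
Note also a notational clash inherited from the source material: the
damping coefficient of the reduced ODE and the real part of $\lambda$
are both traditionally written $\mu$; here they live in different
objects (`reduced_ode$mu` vs `Re(char_root$lambda)`) and are never
interchanged.

`hopf_scan()` locates purely imaginary roots: it scans
$g(i\omega)$ on a grid ($n = 4000$ points by default), refines every
sign change of the real or imaginary part by bisection, polishes with
complex Newton, and accepts roots with $|\mathrm{Re}\,\lambda| \le
10^{-8}$ and residual $\le 10^{-9}$. An empty result is meaningful (no
axis crossing up to `omega_max`).

## The case registry and the classifier

`case_registry()` ships ten parameter sets exercising the family:
damped decay, an exact Hopf point, limit cycles, slow/fast relaxation
oscillation, and the tremor model's two endings (symptoms vanish at 0;
symptoms stabilize at $x^* = \sqrt 2$). Conventions:

* a printed cubic term $+x^2(p\,x(t-\tau_2) + q\,x(t-\tau_1))$ is
  stored as $b_2 = -p$, $b_1 = -q$; the registry holds the mapped
  coefficients, and the tests pin them;
* cases 9 and 10 print a cubic delay of 5 absent from their linear
  parts; they are stored literally through the cubic-delay fields, not
  "corrected";
* expected labels are attached only where the source narrative states
  the behaviour (cases 1, 2, 3, 8, 9, 10); cases 4–7 ship
  `"unspecified"` and are exercised through invariants only;
* **case 10 as printed diverges.** Its literal coefficients give
  $(a_1+a_2)/(b_1+b_2) = -3 < 0$ — no real non-zero fixed point — and
  the trajectory hits the blow-up guard near $t \approx 51.5$, while
  the narrative attributes convergence to $\sqrt 2$ to it. The
  registry keeps the literal parameters plus a `note`; the
  $\sqrt2$ behaviour is demonstrated (tests, acceptance script) with
  the same linear part and a cubic pair satisfying the model's own
  constraints ($b_1 = -1$, $b_2 = 1.15$: $b_1b_2<0$,
  $|b_1| \approx |b_2|$, $x^* = \sqrt 2$ exactly);
* default horizons: 40 time units when all delays are below 1,
  otherwise 30× the largest delay — long enough that every shipped
  transient has settled.

`classify_trajectory()` turns a trajectory into one of
`decays_to_zero`, `converges_to_constant`, `sustained_oscillation`,
`growing`: the tail (last 25% by default) is split in two windows;
amplitudes below `tol` (default 2% of the initial amplitude) mean
settling, a window-amplitude ratio within $[0.9, 1.1]$ means a
sustained oscillation, above 1.1 growth. The period comes from the
mean spacing of zero crossings of the centred tail, and
`relaxation_flag` marks fast–slow waveforms by the derivative crest
factor $\max|\dot x|/(2\pi A/T) > 2$ — a sinusoid scores 1, the shipped
relaxation case scores well above 2. The thresholds are classification
conventions, not fitted quantities; they are deliberately coarse so
that labels are stable under step-size changes.

## Problem sizes and determinism

The test suite and the acceptance script run fixed-step integrations of
at most $2\times10^4$ steps (the 200-time-unit tremor endpoint at
`h = 0.01`) and characteristic-root searches over a few hundred Newton
seeds; the full suite completes in well under a minute on one core.
Everything is deterministic: random parameter draws in property tests
use fixed seeds, and identical CLI invocations produce byte-identical
CSV output (full `%.17g` precision).

## What the shipped cases do and do not establish

The registry cases are constructed inputs: constant histories, exact
printed coefficients, noise-free integration. Passing them shows that
the solver, the algebra (fixed points, linearization, reductions,
characteristic roots) and the classifier agree with closed forms and
with each other — it does not validate the family as a quantitative
model of any physiological recording. Real tremor data would bring
measurement noise, nonstationary parameters, and state-dependent
latencies, none of which are represented here (and distributed or
state-dependent delays, more than two delay channels, neutral terms,
stiff dynamics, chaos detection and two-parameter Hopf continuation
are explicitly out of scope).
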