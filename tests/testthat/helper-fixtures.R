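# Shared fixtures (built once per test run) and independent numerical
# oracles. Oracles are deliberately implemented with different numerics
# than the package (midpoint Riemann sums, explicit sums of squares,
# closed-form antiderivatives) so that agreement is evidence, not
# tautology.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

fx_sched <- function() fx("sched", function() default_schedule())
fx_input <- function() fx("input", function()
  make_input_function(schedule = fx_sched()))

# reference region: white-matter-like, VT = 5
REF_TRUTH <- list(K1 = 0.25, k2 = 0.05, VB = 0)
fx_ref0 <- function() fx("ref0", function()
  make_reference_tac(REF_TRUTH, fx_input(), fx_sched()))

# canonical blood-free target: K1 0.3, k2 0.015 -> VT 20, DVR 4, BPND 3
TARGET_TRUTH <- list(K1 = 0.3, k2 = 0.015, VB = 0)
fx_tac0 <- function() fx("tac0", function()
  make_tissue_tac(TARGET_TRUTH, fx_input(), fx_sched()))

# Midpoint-Riemann convolution oracle: integral f(s) exp(-theta(t-s)) ds
# accumulated at fine steps, independent of the piecewise-linear
# closed-form engine.
riemann_conv <- function(time, curve, theta, dt = 0.002) {
  t_end <- time[length(time)]
  s <- seq(0, t_end, by = dt)
  f <- stats::approx(time, curve, xout = pmin(s + dt / 2, t_end))$y
  y <- numeric(length(s))
  decay <- exp(-theta * dt)
  half <- exp(-theta * dt / 2)
  for (i in seq_along(s)[-1]) y[i] <- y[i - 1] * decay + f[i - 1] * half * dt
  stats::approx(s, y, xout = time, rule = 2)$y
}

# Closed-form integral of the bolus plasma model over [0, T]
feng_integral <- function(p, T) {
  U <- T - p$t0
  if (U <= 0) return(0)
  e1 <- function(l) (exp(l * U) - 1) / l                 # int exp(l u)
  ramp <- (exp(p$l1 * U) * (U / p$l1 - 1 / p$l1^2) + 1 / p$l1^2)
  p$A1 * ramp - (p$A2 + p$A3) * e1(p$l1) + p$A2 * e1(p$l2) + p$A3 * e1(p$l3)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# trapezoid integral of a sampled curve from 0 up to time `upto`
trapz_upto <- function(time, values, upto) {
  keep <- time <= upto + 1e-12
  t <- time[keep]; v <- values[keep]
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
}
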