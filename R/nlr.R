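# Weighted non-linear regression: the regional gold standards.
#
# fit_1t2kvb() fits the reversible one-tissue compartment model with blood
# volume against the metabolite-corrected plasma input; fit_srtm() fits the
# simplified reference tissue model operational equation
#   C(t) = R1 C'(t) + R1 (k2' - k2a) [C' (*) exp(-k2a t)](t).
# Both minimise the count-weighted residual sum of squares with a bounded
# Levenberg-Marquardt optimiser and fall back to a deterministic
# multi-start lattice when a fit fails to converge.

new_kinetic_fit <- function(model, par, extra, wrss, converged, iterations,
                            start, flags = list()) {
  structure(c(list(model = model, par = par, wrss = wrss,
                   converged = converged, iterations = iterations,
                   start = start, flags = flags), extra),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, wrss %.4g, %d iter)\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              x$wrss, x$iterations))
  print(round(unlist(x$par), 5))
  invisible(x)
}

check_tac <- function(values) {
  if (!all(is.finite(values))) stop("non-finite values in TAC")
  if (all(values == 0)) stop("degenerate TAC: all zeros")
}

resolve_weights <- function(weights, schedule) {
  if (is.null(weights)) weights <- frame_weights(schedule)$weight
  if (is.data.frame(weights)) weights <- weights$weight
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  # only relative weights matter; normalise for optimiser conditioning
  if (sum(weights) > 0) weights <- weights / mean(weights[weights > 0])
  weights
}

# Bounded Levenberg-Marquardt from the user start plus a deterministic
# lattice of dispersed starts; the lowest-WRSS solution wins. Bounded LM
# can stall on a bound from an unlucky start while still reporting
# convergence, so the lattice always runs.
run_nlslm <- function(resid_fn, start, lower, upper, starts = NULL) {
  one <- function(s) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }
  cands <- Filter(Negate(is.null), lapply(c(list(start), starts), one))
  cands <- Filter(function(f) all(is.finite(f$fvec)), cands)
  if (!length(cands)) return(NULL)
  cands[[which.min(vapply(cands, function(f) f$deviance, numeric(1)))]]
}

#' Fit the one-tissue compartment model with blood volume (1T2k_VB)
#'
#' Estimates K1, k2 and the fractional blood volume VB by minimising the
#' weighted residual sum of squares between the observed TAC and
#' `(1 - VB) K1 [Cp (*) exp(-k2 t)] + VB C_WB`, and reports VT = K1/k2.
#'
#' @param tac a `tissue_tac` (or list with `values` and `schedule`).
#' @param input an input function covering the schedule; its `whole_blood`
#'   curve is required for the blood term. If absent, VB is fixed at 0
#'   with a warning.
#' @param weights per-frame weights (1/sigma^2); default from
#'   [frame_weights()] on the TAC's schedule.
#' @param start,lower,upper named numeric `(K1, k2, VB)`: start values and
#'   box bounds.
#' @param fit_vb logical; fix VB at `start["VB"]` when FALSE.
#' @param scale_vb logical; `(1 - VB)` scaling of the tissue term.
#' @param sampling frame sampling convention, see [frame_sample()].
#' @return a `kinetic_fit` with parameters `K1`, `k2`, `VB` and derived
#'   `VT`, plus WRSS, convergence flag and iteration count.
#' @export
fit_1t2kvb <- function(tac, input, weights = NULL,
                       start = c(K1 = 0.2, k2 = 0.05, VB = 0.05),
                       lower = c(K1 = 0, k2 = 1e-4, VB = 0),
                       upper = c(K1 = 2, k2 = 1, VB = 0.2),
                       fit_vb = TRUE, scale_vb = TRUE,
                       sampling = "average") {
  obs <- tac$values; sched <- tac$schedule
  check_tac(obs)
  if (!all(is.finite(input$plasma_parent))) stop("non-finite input function")
  w <- resolve_weights(weights, sched)
  sw <- sqrt(w)

  no_blood <- is.null(input$whole_blood)
  if (no_blood) {
    warning("no whole-blood curve supplied; VB fixed at 0")
    fit_vb <- FALSE; start["VB"] <- 0
  }
  wb_frames <- if (no_blood) rep(0, nrow(sched))
               else frame_sample(input$time, input$whole_blood, sched, sampling)
  tis_frames <- function(k2) frame_sample(
    input$time, convolve_exp(input$plasma_parent, k2, input$time),
    sched, sampling)

  model <- function(K1, k2, VB)
    (if (scale_vb) (1 - VB) else 1) * K1 * tis_frames(k2) + VB * wb_frames

  if (fit_vb) {
    resid <- function(p) sw * (obs - model(p[1], p[2], p[3]))
    starts <- lapply(list(c(0.1, 0.01, 0.03), c(0.1, 0.1, 0.05),
                          c(0.5, 0.02, 0.05), c(0.5, 0.2, 0.1),
                          c(0.05, 0.5, 0.02)),
                     function(s) stats::setNames(s, c("K1", "k2", "VB")))
    fit <- run_nlslm(resid, start, lower, upper, starts)
    if (is.null(fit)) stop("1T2k_VB fit failed")
    p <- stats::setNames(as.numeric(fit$par), c("K1", "k2", "VB"))
  } else {
    VBfix <- unname(start["VB"])
    resid <- function(p) sw * (obs - model(p[1], p[2], VBfix))
    starts <- lapply(list(c(0.1, 0.01), c(0.1, 0.1), c(0.5, 0.02),
                          c(0.5, 0.2), c(0.05, 0.5)),
                     function(s) stats::setNames(s, c("K1", "k2")))
    fit <- run_nlslm(resid, start[c("K1", "k2")], lower[c("K1", "k2")],
                     upper[c("K1", "k2")], starts)
    if (is.null(fit)) stop("1T2k_VB fit failed")
    p <- c(stats::setNames(as.numeric(fit$par), c("K1", "k2")), VB = VBfix)
  }
  new_kinetic_fit(
    model = "1T2k_VB",
    par = as.list(p),
    extra = list(VT = unname(p["K1"] / p["k2"])),
    wrss = fit$deviance, converged = fit$info %in% 1:4,
    iterations = fit$niter, start = start,
    flags = list(vb_fixed = !fit_vb, scale_vb = scale_vb))
}

# Reference TAC reconstructed on a uniform fine grid: piecewise linear
# through knots at the frame mid-times (anchored at 0, linearly
# extrapolated to scan end), with the knot values refined so that the
# frame averages of the reconstruction reproduce the observed frame
# values. Frame values are time-averages, so a curve that merely passes
# through them is biased wherever the TAC is curved (the bolus peak); a
# few fixed-point corrections remove most of that bias.
tac_to_fine <- function(values, schedule, dt = 0.01, refine = 3) {
  mids <- frame_mid(schedule)
  t_end <- scan_end(schedule)
  n <- length(values)
  tg <- seq(0, t_end, by = dt)
  if (tg[length(tg)] < t_end) tg <- c(tg, t_end)
  knots_t <- c(0, mids, t_end)
  v <- values
  rebuild <- function(v) {
    slope <- (v[n] - v[n - 1]) / (mids[n] - mids[n - 1])
    stats::approx(knots_t, c(0, v, v[n] + slope * (t_end - mids[n])),
                  xout = tg)$y
  }
  fine <- rebuild(v)
  for (i in seq_len(refine)) {
    avg <- frame_sample(tg, fine, schedule)
    v <- v + (values - avg)
    fine <- rebuild(v)
  }
  list(time = tg, values = fine)
}

#' Fit the simplified reference tissue model (SRTM)
#'
#' Estimates relative delivery R1, the reference efflux rate k2' and the
#' target apparent efflux rate k2a from the operational equation
#' `C = R1 C' + R1 (k2' - k2a) [C' (*) exp(-k2a t)]`, and reports
#' BPND = R1 k2'/k2a - 1 and DVR = BPND + 1.
#'
#' When the reference efflux rate coincides with the target's apparent
#' efflux rate the `(k2' - k2a)` term vanishes and k2' and k2a become
#' jointly non-identifiable; such fits are flagged `ill_conditioned`.
#'
#' @param tac,reference_tac target and reference `tissue_tac`s on the same
#'   schedule.
#' @param weights per-frame weights; default [frame_weights()].
#' @param start,lower,upper named numeric `(R1, k2p, k2a)`.
#' @param fine_dt grid step (minutes) for the reference-curve convolution.
#' @return a `kinetic_fit` with `R1`, `k2p`, `k2a`, derived `BPND`, `DVR`,
#'   and flag `ill_conditioned`.
#' @export
fit_srtm <- function(tac, reference_tac, weights = NULL,
                     start = c(R1 = 1, k2p = 0.05, k2a = 0.03),
                     lower = c(R1 = 0, k2p = 1e-4, k2a = 1e-4),
                     upper = c(R1 = 5, k2p = 1, k2a = 1),
                     fine_dt = 0.01) {
  obs <- tac$values; sched <- tac$schedule
  check_tac(obs)
  ref <- reference_tac$values
  if (all(ref == 0)) stop("reference TAC is all zeros")
  w <- resolve_weights(weights, sched)
  sw <- sqrt(w)
  fine <- tac_to_fine(ref, sched, fine_dt)

  conv_frames <- function(k2a) frame_sample(
    fine$time, convolve_exp(fine$values, k2a, fine$time), sched)
  model <- function(R1, k2p, k2a)
    R1 * ref + R1 * (k2p - k2a) * conv_frames(k2a)
  resid <- function(p) sw * (obs - model(p[1], p[2], p[3]))

  starts <- lapply(list(c(0.8, 0.02, 0.01), c(1, 0.1, 0.05),
                        c(1.5, 0.05, 0.01), c(0.5, 0.2, 0.1),
                        c(2, 0.01, 0.005)),
                   function(s) stats::setNames(s, c("R1", "k2p", "k2a")))
  fit <- run_nlslm(resid, start, lower, upper, starts)
  if (is.null(fit)) stop("SRTM fit failed")
  p <- stats::setNames(as.numeric(fit$par), c("R1", "k2p", "k2a"))

  # identifiability probe on (k2' - k2a): when the reference efflux rate
  # equals the target apparent efflux rate the washout term vanishes and
  # k2' and k2a are only constrained jointly -- detectable as a
  # near-perfect correlation of their estimates (or a rank-deficient
  # curvature matrix), with the fitted difference collapsing towards 0.
  ill <- abs(p["k2p"] - p["k2a"]) < 0.05 * p["k2p"]
  if (!ill) {
    H <- fit$hessian
    if (is.matrix(H) && all(is.finite(H))) {
      if (rcond(H) < 1e-12) ill <- TRUE
      else {
        corr <- try(stats::cov2cor(solve(H)), silent = TRUE)
        if (!inherits(corr, "try-error") && is.finite(corr[2, 3]) &&
            abs(corr[2, 3]) > 0.995) ill <- TRUE
      }
    }
  }

  new_kinetic_fit(
    model = "SRTM",
    par = as.list(p),
    extra = list(BPND = unname(p["R1"] * p["k2p"] / p["k2a"] - 1),
                 DVR = unname(p["R1"] * p["k2p"] / p["k2a"])),
    wrss = fit$deviance, converged = fit$info %in% 1:4,
    iterations = fit$niter, start = start,
    flags = list(ill_conditioned = unname(ill)))
}
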