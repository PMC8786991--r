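# Linearized graphical and multilinear estimators.
#
# Frame "time" for t* filtering and for the tissue integrals is the frame
# mid-time; tissue integrals are accumulated by trapezoid over the mid-times
# with a zero anchor at t = 0, plasma integrals on the input fine grid.
# For a reversible one-tissue tracer the underlying identities are exact:
#   int_0^T C  = VT int_0^T Cp - C(T)/k2                      (Logan)
#   int_0^T C  = DVR [int_0^T C' + C'(T)/k2'] - C(T)/k2       (ref. Logan)
# and their multilinear rearrangements (the MRTM family), in which the
# noise-carrying TAC moves out of the regression denominator.

new_linear_fit <- function(method, tstar, coef, params, r2, n_frames,
                           ok = TRUE, flags = list()) {
  structure(list(method = method, tstar = tstar, coef = coef,
                 params = params, r2 = r2, n_frames = n_frames, ok = ok,
                 flags = flags),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("%s (t* = %g min, %d frames, r^2 = %.4f)%s\n", x$method,
              x$tstar, x$n_frames, x$r2, if (x$ok) "" else " [FAILED]"))
  print(round(unlist(x$params), 4))
  invisible(x)
}

# trapezoid running integral of a frame-sampled TAC at its mid-times,
# anchored at (0, 0)
tac_cumint <- function(values, schedule) {
  mids <- frame_mid(schedule)
  tt <- c(0, mids); vv <- c(0, values)
  cumsum(c(0, (vv[-1] + vv[-length(vv)]) / 2 * diff(tt)))[-1]
}

ols_fit <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  fit <- try(stats::lm.wfit(X, y, w), silent = TRUE)
  if (inherits(fit, "try-error") || any(is.na(fit$coefficients)) ||
      fit$rank < ncol(X))
    return(NULL)
  res <- fit$residuals
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  list(coef = fit$coefficients,
       r2 = if (tss > 0) max(0, 1 - sum(w * res^2) / tss) else NA_real_)
}

linear_frames <- function(schedule, tstar, min_frames) {
  use <- which(frame_mid(schedule) >= tstar)
  if (length(use) < min_frames)
    stop(sprintf("only %d frames with mid-time >= %g min (need >= %d)",
                 length(use), tstar, min_frames))
  use
}

#' Plasma-input Logan graphical analysis
#'
#' Ordinary least squares of `int_0^T C dt / C(T)` on
#' `int_0^T Cp dt / C(T)` over frames with mid-time at or after `tstar`;
#' the slope is the total volume of distribution VT.
#'
#' @param tac a `tissue_tac`.
#' @param input an input function (metabolite-corrected plasma parent).
#' @param tstar start time of the linear segment, minutes (default 10, the
#'   standard setting for a fast-equilibrating 11C tracer over a 60-min
#'   scan).
#' @param weights optional per-frame weights; only used when
#'   `weighted = TRUE`.
#' @param weighted logical; weight the linearized regression (default
#'   FALSE: graphical fits are conventionally unweighted).
#' @return a `linear_fit` with `params$VT`, intercept, and the r^2 of the
#'   linearized regression.
#' @export
logan_vt <- function(tac, input, tstar = 10, weights = NULL,
                     weighted = FALSE) {
  sched <- tac$schedule
  check_tac(tac$values)
  if (tstar >= scan_end(sched)) stop("tstar is beyond the scan")
  use <- linear_frames(sched, tstar, 3)
  C <- tac$values[use]
  if (any(C <= 0)) stop("non-positive tissue activity in the Logan window")
  mids <- frame_mid(sched)[use]
  y <- tac_cumint(tac$values, sched)[use] / C
  x <- cum_integral_at(input$time, input$plasma_parent, mids) / C
  w <- if (weighted) resolve_weights(weights, sched)[use] else NULL
  fit <- ols_fit(cbind(x = x, intercept = 1), y, w)
  if (is.null(fit))
    return(new_linear_fit("Logan", tstar, NULL,
                          list(VT = NA_real_), NA_real_, length(use),
                          ok = FALSE, flags = list(singular = TRUE)))
  new_linear_fit("Logan", tstar, fit$coef,
                 list(VT = unname(fit$coef["x"]),
                      intercept = unname(fit$coef["intercept"])),
                 fit$r2, length(use))
}

#' Reference Logan graphical analysis
#'
#' Regression of `int_0^T C dt / C(T)` on
#' `[int_0^T C' dt + C'(T)/k2'] / C(T)` (the `C'/k2'` term is included only
#' when `k2_prime` is supplied; by default no fixed k2' is used). The slope
#' is the distribution volume ratio DVR; BPND = DVR - 1.
#'
#' @inheritParams logan_vt
#' @param reference_tac reference-region `tissue_tac`.
#' @param tstar default 30 min, the standard reference-Logan setting for
#'   this tracer class.
#' @param k2_prime optional reference efflux rate, min^-1.
#' @export
rlogan_dvr <- function(tac, reference_tac, tstar = 30, k2_prime = NULL,
                       weights = NULL, weighted = FALSE) {
  sched <- tac$schedule
  check_tac(tac$values)
  if (all(reference_tac$values == 0)) stop("reference TAC is all zeros")
  if (tstar >= scan_end(sched)) stop("tstar is beyond the scan")
  use <- linear_frames(sched, tstar, 3)
  C <- tac$values[use]
  if (any(C <= 0))
    stop("non-positive tissue activity in the reference-Logan window")
  refint <- tac_cumint(reference_tac$values, sched)[use]
  if (!is.null(k2_prime)) refint <- refint + reference_tac$values[use] / k2_prime
  y <- tac_cumint(tac$values, sched)[use] / C
  x <- refint / C
  w <- if (weighted) resolve_weights(weights, sched)[use] else NULL
  fit <- ols_fit(cbind(x = x, intercept = 1), y, w)
  if (is.null(fit))
    return(new_linear_fit("RLogan", tstar, NULL,
                          list(DVR = NA_real_, BPND = NA_real_), NA_real_,
                          length(use), ok = FALSE,
                          flags = list(singular = TRUE)))
  dvr <- unname(fit$coef["x"])
  new_linear_fit("RLogan", tstar, fit$coef,
                 list(DVR = dvr, BPND = dvr - 1,
                      intercept = unname(fit$coef["intercept"])),
                 fit$r2, length(use),
                 flags = list(k2_prime_fixed = !is.null(k2_prime)))
}

#' Multilinear reference tissue models (MRTMo, MRTM1, MRTM2, MRTM3, MRTM4)
#'
#' Multilinear rearrangements of reference-tissue graphical analysis:
#' \describe{
#'   \item{MRTMo}{`intC/C = b1 intC'/C + b2 C'/C + b3`; DVR = b1,
#'     k2' = b1/b2, R1 = -b2/b3.}
#'   \item{MRTM1}{`C = b1 intC' + b2 intC + b3 C'`; DVR = -b1/b2,
#'     k2' = b1/b3, R1 = b3.}
#'   \item{MRTM2}{`C = b1 (intC' + C'/k2') + b2 intC` with k2' fixed;
#'     DVR = -b1/b2, R1 = b1/k2'.}
#'   \item{MRTM3, MRTM4}{shipped as the MRTM1 / MRTM2 operational forms
#'     with count-weighted regression switched on. These two labels cover
#'     software-specific variants whose operational equations are not
#'     publicly documented; they are clearly non-canonical approximations
#'     and excluded from validation claims.}
#' }
#' All fits use frames with mid-time at or after `tstar`.
#'
#' @inheritParams rlogan_dvr
#' @param variant one of `"MRTMo"`, `"MRTM1"`, `"MRTM2"`, `"MRTM3"`,
#'   `"MRTM4"`.
#' @param k2_prime reference efflux rate, min^-1; required for MRTM2/MRTM4.
#' @param weighted logical; default FALSE for MRTMo/1/2, forced TRUE for
#'   MRTM3/4.
#' @return a `linear_fit`; a singular design matrix yields a flagged
#'   failure result (`ok = FALSE`) rather than an error.
#' @export
mrtm <- function(tac, reference_tac, tstar = 10,
                 variant = c("MRTMo", "MRTM1", "MRTM2", "MRTM3", "MRTM4"),
                 k2_prime = NULL, weights = NULL, weighted = FALSE) {
  variant <- match.arg(variant)
  sched <- tac$schedule
  check_tac(tac$values)
  if (all(reference_tac$values == 0)) stop("reference TAC is all zeros")
  form <- switch(variant, MRTM3 = "MRTM1", MRTM4 = "MRTM2", variant)
  if (variant %in% c("MRTM3", "MRTM4")) weighted <- TRUE
  if (form == "MRTM2" && is.null(k2_prime))
    stop(variant, " requires k2_prime")
  use <- linear_frames(sched, tstar, if (form == "MRTM2") 3 else 4)
  C <- tac$values[use]
  Cr <- reference_tac$values[use]
  iC <- tac_cumint(tac$values, sched)[use]
  iCr <- tac_cumint(reference_tac$values, sched)[use]
  w <- if (weighted) resolve_weights(weights, sched)[use] else NULL

  fail <- function() new_linear_fit(
    variant, tstar, NULL,
    list(DVR = NA_real_, BPND = NA_real_, R1 = NA_real_, k2p = NA_real_),
    NA_real_, length(use), ok = FALSE, flags = list(singular = TRUE))

  if (form == "MRTMo") {
    if (any(C <= 0)) stop("non-positive tissue activity in the fit window")
    fit <- ols_fit(cbind(x1 = iCr / C, x2 = Cr / C, intercept = 1), iC / C, w)
    if (is.null(fit)) return(fail())
    b <- fit$coef
    params <- list(DVR = unname(b["x1"]), BPND = unname(b["x1"]) - 1,
                   k2p = unname(b["x1"] / b["x2"]),
                   R1 = unname(-b["x2"] / b["intercept"]))
  } else if (form == "MRTM1") {
    fit <- ols_fit(cbind(x1 = iCr, x2 = iC, x3 = Cr), C, w)
    if (is.null(fit)) return(fail())
    b <- fit$coef
    dvr <- unname(-b["x1"] / b["x2"])
    params <- list(DVR = dvr, BPND = dvr - 1,
                   k2p = unname(b["x1"] / b["x3"]), R1 = unname(b["x3"]),
                   k2 = unname(-b["x2"]))
  } else {                              # MRTM2 form
    fit <- ols_fit(cbind(x1 = iCr + Cr / k2_prime, x2 = iC), C, w)
    if (is.null(fit)) return(fail())
    b <- fit$coef
    dvr <- unname(-b["x1"] / b["x2"])
    params <- list(DVR = dvr, BPND = dvr - 1, k2p = k2_prime,
                   R1 = unname(b["x1"] / k2_prime), k2 = unname(-b["x2"]))
  }
  new_linear_fit(variant, tstar, fit$coef, params, fit$r2, length(use),
                 flags = list(weighted = weighted,
                              canonical = !(variant %in% c("MRTM3", "MRTM4"))))
}
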