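# Basis-function estimators: receptor parametric mapping (RPM), SRTM2 with
# a data-driven fixed k2', and plasma-input spectral analysis (SA) with a
# blood-volume component.
#
# All three share the same machinery: a logarithmic grid of exponential
# rates, basis curves precomputed once per (curve, grid) by closed-form
# convolution and frame binning, and per-basis weighted linear
# sub-problems. Precomputing the bases once and solving all voxels against
# them is numerically identical to per-voxel computation and is what makes
# voxel-wise fitting tractable.

#' Logarithmic basis-rate grid
#'
#' @param theta_min,theta_max rate bounds, min^-1 (0 < min < max). Defaults
#'   0.01-0.1 min^-1, the standard setting for this tracer class.
#' @param count number of log-spaced rates (>= 2); 30 for RPM/SRTM2, 50 for
#'   spectral analysis by default.
#' @return numeric vector of rates with class `basis_grid`.
#' @export
basis_grid <- function(theta_min = 0.01, theta_max = 0.1, count = 30) {
  if (!(theta_min > 0 && theta_max > theta_min)) stop("need 0 < min < max")
  if (count < 2) stop("count must be >= 2")
  structure(exp(seq(log(theta_min), log(theta_max), length.out = count)),
            class = "basis_grid")
}

# Frame-binned basis curves conv(curve, theta_i) for a curve given on a
# fine grid. Returns frames x count matrix.
basis_matrix_fine <- function(time, curve, grid, schedule) {
  vapply(as.numeric(grid), function(th)
    frame_sample(time, convolve_exp(curve, th, time), schedule),
    numeric(nrow(schedule)))
}

# Same for a frame-sampled reference TAC (reconstructed piecewise-linearly
# through its mid-times first).
basis_matrix_ref <- function(ref_values, grid, schedule, fine_dt = 0.01) {
  fine <- tac_to_fine(ref_values, schedule, fine_dt)
  basis_matrix_fine(fine$time, fine$values, grid, schedule)
}

as_tac_matrix <- function(x) {
  if (inherits(x, "tissue_tac")) matrix(x$values, ncol = 1)
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), ncol = 1)
}

# Core RPM solver on a frames x nvox matrix. For each candidate theta
# (= k2a) solve the weighted 2-coefficient problem
#   C = R1 C' + phi [C' (*) exp(-theta t)],
# keep the theta minimising WRSS per voxel, then
#   k2' = phi/R1 + theta,  BPND = R1 k2'/theta - 1.
rpm_core <- function(Y, ref, w, grid, bases, nonneg_r1 = FALSE) {
  nv <- ncol(Y); nth <- length(grid)
  best_wrss <- rep(Inf, nv)
  best <- list(theta = rep(NA_real_, nv), R1 = rep(NA_real_, nv),
               phi = rep(NA_real_, nv), idx = rep(NA_integer_, nv))
  any_ok <- FALSE
  for (i in seq_len(nth)) {
    X <- cbind(ref, bases[, i])
    XtW <- t(X * w)
    A <- XtW %*% X
    if (!is.finite(rcond(A)) || rcond(A) < 1e-12) next
    any_ok <- TRUE
    coef <- solve(A, XtW %*% Y)                      # 2 x nv
    if (nonneg_r1) {
      negs <- which(coef[1, ] < 0)
      if (length(negs)) {
        b <- bases[, i]
        coef[1, negs] <- 0
        coef[2, negs] <- colSums(w * b * Y[, negs, drop = FALSE]) /
          sum(w * b^2)
      }
    }
    res <- Y - X %*% coef
    wrss <- colSums(w * res^2)
    upd <- which(wrss < best_wrss)
    if (length(upd)) {
      best_wrss[upd] <- wrss[upd]
      best$theta[upd] <- grid[i]
      best$R1[upd] <- coef[1, upd]
      best$phi[upd] <- coef[2, upd]
      best$idx[upd] <- i
    }
  }
  if (!any_ok) return(NULL)
  k2p <- best$phi / best$R1 + best$theta
  bp <- best$phi / best$theta + best$R1 - 1          # = R1 k2'/theta - 1
  data.frame(R1 = best$R1, k2p = k2p, k2a = best$theta, BPND = bp,
             DVR = bp + 1, wrss = best_wrss,
             at_edge = best$idx %in% c(1L, length(grid)))
}

#' Receptor parametric mapping (RPM)
#'
#' Basis-function solution of the simplified reference tissue model: for
#' each candidate apparent efflux rate theta on the grid, the model is
#' linear in (R1, phi) and solved by weighted least squares; the grid point
#' with minimal weighted residual sum of squares wins. Estimates whose best
#' rate lies on the grid boundary are flagged `at_edge` (the true rate is
#' outside the grid and the estimate clamps to its edge).
#'
#' @param tac target `tissue_tac`, or a frames x voxels matrix.
#' @param reference_tac reference-region `tissue_tac`.
#' @param weights per-frame weights; default [frame_weights()].
#' @param grid a [basis_grid()] of candidate k2a rates.
#' @param nonneg_r1 logical; constrain R1 >= 0 (off by default).
#' @param fine_dt fine-grid step for the basis convolutions, minutes.
#' @return for a single TAC, a `kinetic_fit` (model `"RPM"`) with `R1`,
#'   `k2p`, `k2a`, `BPND`, `DVR`; for a matrix, a data.frame with one row
#'   per voxel.
#' @export
rpm <- function(tac, reference_tac, weights = NULL,
                grid = basis_grid(0.01, 0.1, 30), nonneg_r1 = FALSE,
                fine_dt = 0.01) {
  sched <- reference_tac$schedule
  ref <- reference_tac$values
  if (all(ref == 0)) stop("reference TAC is all zeros")
  w <- resolve_weights(weights, sched)
  Y <- as_tac_matrix(tac)
  bases <- basis_matrix_ref(ref, grid, sched, fine_dt)
  out <- rpm_core(Y, ref, w, grid, bases, nonneg_r1)
  if (is.null(out)) {
    if (ncol(Y) > 1) stop("all candidate basis fits are singular")
    return(new_kinetic_fit("RPM", list(R1 = NA_real_, k2p = NA_real_,
                                       k2a = NA_real_),
                           list(BPND = NA_real_, DVR = NA_real_), NA_real_,
                           FALSE, length(grid), NULL,
                           flags = list(singular = TRUE)))
  }
  if (inherits(tac, "tissue_tac") || ncol(Y) == 1) {
    return(new_kinetic_fit(
      "RPM", list(R1 = out$R1[1], k2p = out$k2p[1], k2a = out$k2a[1]),
      list(BPND = out$BPND[1], DVR = out$DVR[1]),
      out$wrss[1], TRUE, length(grid), NULL,
      flags = list(at_edge = out$at_edge[1])))
  }
  out
}

#' SRTM2: two-pass basis fitting with a fixed reference efflux rate
#'
#' Pass 1 runs [rpm()] on every voxel; the reference efflux rate is then
#' fixed at `k2p_star`, the median voxel k2' over voxels with
#' `BPND > bp_threshold` (default 3, selecting voxels dominated by specific
#' signal). Pass 2 refits every voxel with a single linear coefficient per
#' basis rate,
#'   `C = R1 [C' + (k2'* - theta) C' (*) exp(-theta t)]`,
#' which reduces the parameters from three to two and stabilises the fits.
#' If no voxel exceeds the threshold, the median is taken over voxels with
#' `BPND > 0` instead and a prominent warning is emitted.
#'
#' @inheritParams rpm
#' @param tac target `tissue_tac` or frames x voxels matrix.
#' @param bp_threshold BPND threshold for the k2' median pool (>= 0).
#' @param k2_prime optional externally fixed k2' (skips pass 1).
#' @return list of class `srtm2_fit`: `k2p_star`, `fallback` flag, and
#'   `voxels`, a data.frame with per-voxel `R1`, `k2a`, `BPND`, `DVR`,
#'   `wrss`, `at_edge`. For a single TAC the fields are also exposed as a
#'   one-row data.frame.
#' @export
srtm2 <- function(tac, reference_tac, weights = NULL,
                  grid = basis_grid(0.01, 0.1, 30), bp_threshold = 3,
                  k2_prime = NULL, fine_dt = 0.01) {
  if (bp_threshold < 0) stop("bp_threshold must be >= 0")
  sched <- reference_tac$schedule
  ref <- reference_tac$values
  if (all(ref == 0)) stop("reference TAC is all zeros")
  w <- resolve_weights(weights, sched)
  Y <- as_tac_matrix(tac)
  bases <- basis_matrix_ref(ref, grid, sched, fine_dt)

  fallback <- FALSE
  pass1 <- NULL
  if (is.null(k2_prime)) {
    pass1 <- rpm_core(Y, ref, w, grid, bases)
    if (is.null(pass1)) stop("all candidate basis fits are singular")
    pool <- which(pass1$BPND > bp_threshold & is.finite(pass1$k2p))
    if (!length(pool)) {
      fallback <- TRUE
      pool <- which(pass1$BPND > 0 & is.finite(pass1$k2p))
      if (!length(pool)) pool <- which(is.finite(pass1$k2p))
      warning(sprintf(
        paste("SRTM2: no voxel has BPND > %g; fixing k2' from the median",
              "over voxels with BPND > 0 instead -- interpret with care"),
        bp_threshold))
    }
    # median with midpoint-of-two convention (stats::median does this)
    k2_prime <- stats::median(pass1$k2p[pool])
  }

  nv <- ncol(Y); nth <- length(grid)
  best_wrss <- rep(Inf, nv)
  R1b <- rep(NA_real_, nv); thb <- rep(NA_real_, nv); idxb <- rep(NA_integer_, nv)
  for (i in seq_len(nth)) {
    X1 <- ref + (k2_prime - grid[i]) * bases[, i]
    den <- sum(w * X1^2)
    if (den <= 0) next
    R1 <- colSums(w * X1 * Y) / den
    res <- Y - outer(X1, R1)
    wrss <- colSums(w * res^2)
    upd <- which(wrss < best_wrss)
    if (length(upd)) {
      best_wrss[upd] <- wrss[upd]; R1b[upd] <- R1[upd]
      thb[upd] <- grid[i]; idxb[upd] <- i
    }
  }
  vox <- data.frame(R1 = R1b, k2a = thb, BPND = R1b * k2_prime / thb - 1,
                    wrss = best_wrss,
                    at_edge = idxb %in% c(1L, length(grid)))
  vox$DVR <- vox$BPND + 1
  structure(list(k2p_star = k2_prime, fallback = fallback, voxels = vox,
                 pass1 = pass1, grid = grid, bp_threshold = bp_threshold),
            class = "srtm2_fit")
}

#' @export
print.srtm2_fit <- function(x, ...) {
  cat(sprintf("SRTM2 fit: %d voxel(s), k2'* = %.4f min^-1%s\n",
              nrow(x$voxels), x$k2p_star,
              if (x$fallback) " [threshold fallback]" else ""))
  invisible(x)
}

#' Plasma-input spectral analysis with a blood-volume component
#'
#' Non-negative weighted least squares of the TAC on the basis set
#' `{Cp (*) exp(-beta_i t)}` plus the whole-blood curve as an additional
#' non-negative regressor whose coefficient is the fractional blood volume.
#' The non-negative spectrum `alpha_i >= 0` gives `VT = sum(alpha/beta)`
#' and `K1 = sum(alpha)`.
#'
#' @param tac a `tissue_tac`.
#' @param input an input function (plasma parent and whole blood on a fine
#'   grid).
#' @param weights per-frame weights; default [frame_weights()].
#' @param grid a [basis_grid()] of spectral rates (default 50 log-spaced
#'   rates over 0.01-0.1 min^-1).
#' @param vb_regressor `"whole_blood"` (physiological convention, default)
#'   or `"plasma_total"`: the curve whose coefficient is read as VB.
#' @param scale_vb logical; when TRUE (default, the package-wide 1T2k_VB
#'   convention) the measured tissue signal is `(1 - VB)` times the tissue
#'   response, so the spectrum totals are divided by `(1 - VB_est)` to put
#'   VT and K1 on the same scale as the compartment fit.
#' @param basis_cache optional precomputed frame-binned basis matrix from
#'   `basis_matrix_fine()` (internal use by the voxel-wise driver).
#' @return a `spectral_result`: components (`beta`, `alpha`), `VB`, `VT`,
#'   `K1`, `wrss`, and flag `zero_spectrum` when no component is retained.
#' @export
spectral_analysis <- function(tac, input, weights = NULL,
                              grid = basis_grid(0.01, 0.1, 50),
                              vb_regressor = c("whole_blood", "plasma_total"),
                              scale_vb = TRUE, basis_cache = NULL) {
  vb_regressor <- match.arg(vb_regressor)
  sched <- tac$schedule
  w <- resolve_weights(weights, sched)
  bases <- if (is.null(basis_cache))
    basis_matrix_fine(input$time, input$plasma_parent, grid, sched)
  else basis_cache
  vb_curve <- frame_sample(input$time, input[[vb_regressor]], sched)
  A <- cbind(bases, vb_curve)
  sw <- sqrt(w)
  nn <- pracma::lsqnonneg(A * sw, tac$values * sw)
  alpha <- nn$x[seq_along(grid)]
  vb <- nn$x[length(nn$x)]
  keep <- alpha > 0
  tis_scale <- if (scale_vb && vb < 1) 1 / (1 - vb) else 1
  structure(list(beta = as.numeric(grid)[keep], alpha = alpha[keep],
                 spectrum = alpha, VB = vb,
                 VT = sum(alpha / as.numeric(grid)) * tis_scale,
                 K1 = sum(alpha) * tis_scale,
                 wrss = nn$resid.norm,
                 zero_spectrum = !any(keep) && vb == 0,
                 grid = grid, vb_regressor = vb_regressor),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf(
    "spectral analysis: %d component(s), VT = %.3f mL/cm^3, K1 = %.4f, VB = %.4f%s\n",
    length(x$beta), x$VT, x$K1, x$VB,
    if (x$zero_spectrum) " [zero spectrum]" else ""))
  invisible(x)
}
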