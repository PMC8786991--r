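# Validation and repeatability statistics: regression agreement with the
# gold standard, percent bias, test-retest repeatability (TRT), absolute
# TRT, and the two-way absolute-agreement average-measures intraclass
# correlation coefficient.

#' Agreement of parametric estimates with a gold standard
#'
#' Ordinary least squares of `y` on `x` with intercept; r^2 is the squared
#' Pearson correlation. Used to compare regional or voxel parametric
#' estimates against their non-linear regression gold standard.
#'
#' @param x gold-standard values.
#' @param y parametric estimates, paired with `x`.
#' @param through_origin logical; force a zero intercept (off by default:
#'   agreement lines are fitted with a free intercept).
#' @return list of class `agreement_result`: `r2`, `slope`, `intercept`,
#'   `n`.
#' @export
agreement <- function(x, y, through_origin = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs")
  if (stats::var(x) == 0) stop("zero variance in x")
  if (through_origin) {
    slope <- sum(x * y) / sum(x^2)
    intercept <- 0
  } else {
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
  }
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  structure(list(r2 = r2, slope = slope, intercept = intercept, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement: r^2 = %.3f, slope = %.3f, intercept = %.3f (n = %d)\n",
              x$r2, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Test-retest repeatability
#'
#' Per unit (region or voxel): `TRT = (retest - test)/(retest + test) * 200`
#' and `absolute TRT = |retest - test|/(retest + test) * 200`, summarised
#' by their group mean and SD. Pairs with a non-positive sum are excluded
#' with a warning (the normalisation is undefined there).
#'
#' @param test,retest paired positive values.
#' @return list of class `trt_result`: `trt`, `abs_trt` (per unit),
#'   `mean_trt`, `sd_trt`, `mean_abs_trt`, `sd_abs_trt`, `n`,
#'   `n_excluded`.
#' @export
trt <- function(test, retest) {
  if (length(test) != length(retest)) stop("test and retest lengths differ")
  ok <- is.finite(test) & is.finite(retest) & (test + retest) > 0
  n_exc <- sum(!ok)
  if (n_exc > 0)
    warning(n_exc, " pair(s) with non-positive sum excluded from TRT")
  t1 <- test[ok]; t2 <- retest[ok]
  tr <- (t2 - t1) / (t2 + t1) * 200
  at <- abs(t2 - t1) / (t2 + t1) * 200
  structure(list(trt = tr, abs_trt = at,
                 mean_trt = mean(tr), sd_trt = stats::sd(tr),
                 mean_abs_trt = mean(at), sd_abs_trt = stats::sd(at),
                 n = length(tr), n_excluded = n_exc),
            class = "trt_result")
}

#' @export
print.trt_result <- function(x, ...) {
  cat(sprintf("TRT: mean %.2f%% (SD %.2f), absolute %.2f%% (SD %.2f), n = %d\n",
              x$mean_trt, x$sd_trt, x$mean_abs_trt, x$sd_abs_trt, x$n))
  invisible(x)
}

#' Percent bias of a parametric estimate against the conventional method
#'
#' `(parametric - conventional) / conventional * 100`, signed.
#' @param parametric,conventional values (conventional must be non-zero).
#' @export
bias <- function(parametric, conventional) {
  if (any(conventional == 0)) stop("conventional value must be non-zero")
  (parametric - conventional) / conventional * 100
}

#' Two-way absolute-agreement average-measures ICC
#'
#' Intraclass correlation from the two-way (subjects x sessions) mixed-
#' effects ANOVA decomposition, absolute-agreement definition, average of
#' k measurements:
#' `ICC(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)`,
#' with the standard F-based confidence interval for the average-measures
#' absolute-agreement form. Values are reported as computed (an ICC at or
#' below 0 indicates within-subject variance exceeding between-subject
#' variance and is not clipped).
#'
#' @param data numeric matrix or data.frame, subjects in rows, the two
#'   sessions in columns (no missing cells; >= 3 subjects).
#' @param conf_level confidence level for the interval.
#' @return list of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   variance components (`ms_rows`, `ms_cols`, `ms_error`), `n`, `k`.
#' @export
icc_2way <- function(data, conf_level = 0.95) {
  m <- as.matrix(data)
  if (any(!is.finite(m))) stop("missing or non-finite cells (no imputation)")
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects")
  if (k != 2) stop("expected exactly 2 sessions")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((m - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  a <- (k * icc_1) / (n * (1 - icc_1))
  b <- 1 + (k * icc_1 * (n - 1)) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  # Spearman-Brown step up to average measures
  lo <- lo1 * k / (1 + lo1 * (k - 1))
  up <- up1 * k / (1 + up1 * (k - 1))
  structure(list(icc = icc_k, ci_lower = lo, ci_upper = up,
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.3f [%.3f, %.3f] (n = %d)\n",
              x$k, x$icc, x$ci_lower, x$ci_upper, x$n))
  invisible(x)
}

#' Voxel-wise absolute test-retest repeatability maps
#'
#' For each subject the voxel-wise absolute TRT is computed from the test
#' and retest maps (assumed pre-aligned on a common grid), then averaged
#' across subjects into a mean map and an SD map.
#'
#' @param test_maps,retest_maps lists of `parametric_map`s (or bare
#'   arrays), one per subject, all on the same grid.
#' @return list with `mean_map`, `sd_map` (arrays, NaN outside the common
#'   mask), `n_subjects`. With a single subject the SD map is all-NaN and
#'   a warning is emitted.
#' @export
trt_map <- function(test_maps, retest_maps) {
  if (length(test_maps) != length(retest_maps))
    stop("need one retest map per test map")
  ns <- length(test_maps)
  if (ns == 0) stop("no maps supplied")
  get_arr <- function(m) if (inherits(m, "parametric_map")) m$values else m
  get_mask <- function(m) if (inherits(m, "parametric_map")) m$mask else
    is.finite(m)
  dims <- dim(get_arr(test_maps[[1]]))
  mask <- get_mask(test_maps[[1]])
  per_subject <- lapply(seq_len(ns), function(i) {
    a <- get_arr(test_maps[[i]]); b <- get_arr(retest_maps[[i]])
    if (!identical(dim(a), dims) || !identical(dim(b), dims))
      stop("maps are not on a common grid")
    out <- abs(b - a) / (b + a) * 200
    out[!mask | !is.finite(out) | (a + b) <= 0] <- NaN
    out
  })
  stack <- array(unlist(per_subject), c(dims, ns))
  mean_map <- apply(stack, 1:3, function(v) mean(v))
  if (ns == 1) {
    warning("single subject: SD map is undefined (all NaN)")
    sd_map <- array(NaN, dims)
  } else {
    sd_map <- apply(stack, 1:3, function(v) stats::sd(v))
  }
  mean_map[!mask] <- NaN; sd_map[!mask] <- NaN
  list(mean_map = mean_map, sd_map = sd_map, n_subjects = ns)
}

#' Tidy repeatability table for a set of methods
#'
#' Convenience assembler: given per-method test and retest value vectors
#' (e.g. regional estimates pooled across subjects), returns one row per
#' method with mean/SD TRT, mean/SD absolute TRT and the ICC with its CI.
#'
#' @param results named list; each element a list with `test` and `retest`
#'   numeric vectors of per-subject values.
#' @export
repeatability_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    tr <- trt(r$test, r$retest)
    ic <- icc_2way(cbind(r$test, r$retest))
    data.frame(method = nm, mean_trt = tr$mean_trt, sd_trt = tr$sd_trt,
               mean_abs_trt = tr$mean_abs_trt, sd_abs_trt = tr$sd_abs_trt,
               icc = ic$icc, icc_lower = ic$ci_lower,
               icc_upper = ic$ci_upper, n = tr$n)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
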