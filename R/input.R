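# Synthetic arterial input functions.
#
# The plasma model is a Feng-type bolus: a linear rise times a fast
# exponential plus two slower exponential tails,
#   C(t) = (A1*u - A2 - A3) exp(l1*u) + A2 exp(l2*u) + A3 exp(l3*u),
# u = t - t0 (0 before t0). It is non-negative for sensible coefficients,
# integrable in closed form, and the de-facto standard for input-function
# simulation. The metabolite parent fraction declines from 1 with an
# exponential approach to a plateau; whole blood is total plasma divided by
# a plasma-to-whole-blood ratio curve.

#' Default bolus-model coefficients
#'
#' Amplitudes in kBq/mL (A1 in kBq/mL/min), rates in min^-1, delay `t0` in
#' minutes. Scaled for a ~350 MBq bolus of a 11C tracer: plasma peak of
#' roughly 70 kBq/mL at ~45 s, late plasma of a few kBq/mL. `pf_inf` and
#' `pf_tau` set the parent-fraction plateau and time constant; `pwb_ratio`
#' is the (constant) plasma-to-whole-blood activity ratio.
#'
#' @return named list of model coefficients accepted by
#'   [make_input_function()].
#' @export
default_input_params <- function() {
  list(A1 = 600, l1 = -4, A2 = 15, l2 = -0.25, A3 = 12, l3 = -0.015,
       t0 = 0.5, pf_inf = 0.25, pf_tau = 20, pwb_ratio = 1.3)
}

feng_curve <- function(t, p) {
  u <- pmax(t - p$t0, 0)
  on <- as.numeric(t > p$t0)
  on * ((p$A1 * u - p$A2 - p$A3) * exp(p$l1 * u) +
          p$A2 * exp(p$l2 * u) + p$A3 * exp(p$l3 * u))
}

#' Generate a synthetic input function
#'
#' Evaluates the bolus model, the parent-fraction curve and the
#' plasma-to-whole-blood ratio on a fine time grid covering the scan
#' (1-s spacing over the early bolus, 3-s after), and derives the
#' metabolite-corrected plasma parent curve as total plasma times parent
#' fraction.
#'
#' @param params model coefficients, see [default_input_params()]. Partial
#'   lists are completed with the defaults.
#' @param schedule a [frame_schedule()]; the grid covers `[0, scan end]`.
#' @param fine_dt,early_dt grid spacings in minutes (after / before
#'   `early_end` minutes).
#' @param early_end end of the finely sampled bolus window, minutes.
#' @return An `input_function`: list with `time`, `plasma_total`,
#'   `plasma_parent`, `whole_blood`, `parent_fraction`,
#'   `plasma_to_wholeblood` (all on the fine grid) and `params`.
#' @export
make_input_function <- function(params = list(), schedule = default_schedule(),
                                fine_dt = 0.05, early_dt = 1 / 60,
                                early_end = 5) {
  p <- utils::modifyList(default_input_params(), params)
  t_end <- scan_end(schedule)
  if (p$t0 < 0) stop("bolus delay t0 must be >= 0")
  early_end <- min(early_end, t_end)
  time <- c(seq(0, early_end, by = early_dt),
            if (early_end < t_end) seq(early_end + fine_dt, t_end, by = fine_dt))
  if (time[length(time)] < t_end) time <- c(time, t_end)

  plasma_total <- feng_curve(time, p)
  if (any(plasma_total < -1e-9 * max(abs(plasma_total))))
    stop(sprintf(
      "bolus coefficients produce negative plasma at t = %.2f min (min %.3g)",
      time[which.min(plasma_total)], min(plasma_total)))
  plasma_total <- pmax(plasma_total, 0)
  if (max(plasma_total) <= 0) stop("bolus coefficients give an all-zero curve")

  pf <- p$pf_inf + (1 - p$pf_inf) * exp(-time / p$pf_tau)
  ratio <- rep_len(p$pwb_ratio, length(time))
  out <- list(time = time,
              plasma_total = plasma_total,
              plasma_parent = plasma_total * pf,
              whole_blood = plasma_total / ratio,
              parent_fraction = pf,
              plasma_to_wholeblood = ratio,
              params = p)
  class(out) <- "input_function"
  out
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("input_function: %d grid points over [0, %.1f] min, peak plasma %.1f kBq/mL\n",
              length(x$time), max(x$time), max(x$plasma_total)))
  invisible(x)
}

# Linear interpolation of an input-function curve at arbitrary times
# (0 outside the grid on the left, last value held on the right).
input_interp <- function(input, curve, t) {
  stats::approx(input$time, input[[curve]], xout = t, rule = 2,
                yleft = 0)$y
}

#' Write / read an input function as TSV
#'
#' Columns `time_min`, `plasma_parent_kBq_ml`, `whole_blood_kBq_ml`,
#' `parent_fraction`; generator parameters go to a JSON sidecar
#' (`<path>.json`).
#' @param input an `input_function`.
#' @param path TSV file path.
#' @export
write_input_tsv <- function(input, path) {
  df <- data.frame(time_min = input$time,
                   plasma_parent_kBq_ml = input$plasma_parent,
                   whole_blood_kBq_ml = input$whole_blood,
                   parent_fraction = input$parent_fraction)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(input$params, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_input_tsv
#' @export
read_input_tsv <- function(path) {
  df <- utils::read.delim(path)
  pf <- df$parent_fraction
  out <- list(time = df$time_min,
              plasma_total = ifelse(pf > 0, df$plasma_parent_kBq_ml / pf, 0),
              plasma_parent = df$plasma_parent_kBq_ml,
              whole_blood = df$whole_blood_kBq_ml,
              parent_fraction = pf,
              plasma_to_wholeblood = ifelse(df$whole_blood_kBq_ml > 0,
                                            df$plasma_parent_kBq_ml /
                                              pf / df$whole_blood_kBq_ml, NA),
              params = NULL)
  class(out) <- "input_function"
  out
}
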