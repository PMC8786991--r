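# Tidy result rows and TSV export for regional fit results.

#' One-row summary of any fit object
#'
#' Accepts a `kinetic_fit`, `linear_fit`, `spectral_result` or `srtm2_fit`
#' (single voxel) and returns a one-row data.frame of its parameter
#' estimates with method provenance, suitable for row-binding into a
#' region x session results table.
#'
#' @param fit a fit object.
#' @param region,session optional provenance columns.
#' @export
tidy_fit <- function(fit, region = NA_character_, session = NA_integer_) {
  base <- data.frame(region = region, session = session)
  if (inherits(fit, "kinetic_fit")) {
    p <- c(fit$par, fit[intersect(names(fit), c("VT", "BPND", "DVR"))])
    cbind(base, data.frame(method = fit$model, as.list(unlist(p)),
                           wrss = fit$wrss, converged = fit$converged))
  } else if (inherits(fit, "linear_fit")) {
    cbind(base, data.frame(method = fit$method, as.list(unlist(fit$params)),
                           tstar = fit$tstar, r2 = fit$r2,
                           n_frames = fit$n_frames, ok = fit$ok))
  } else if (inherits(fit, "spectral_result")) {
    cbind(base, data.frame(method = "SA", VT = fit$VT, K1 = fit$K1,
                           VB = fit$VB, n_components = length(fit$beta),
                           wrss = fit$wrss))
  } else if (inherits(fit, "srtm2_fit")) {
    v <- fit$voxels[1, ]
    cbind(base, data.frame(method = "SRTM2", BPND = v$BPND, DVR = v$DVR,
                           R1 = v$R1, k2a = v$k2a, k2p_star = fit$k2p_star,
                           fallback = fit$fallback))
  } else stop("unsupported fit object")
}

#' Write a regional fit-results table as TSV
#' @param rows data.frame (e.g. row-bound [tidy_fit()] results).
#' @param path output path.
#' @export
write_fits_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
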