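# Voxel-wise parametric imaging: regional TAC extraction, applying any
# estimator over a masked 4D image, map clamping, and NIfTI / TSV I/O.
#
# Voxel fits are independent; basis methods run vectorised across the
# voxel matrix (bit-identical to per-voxel computation), linearized and
# NLR methods loop with per-voxel failure capture. Failed voxels become
# NaN and are counted in the map metadata, never imputed.

new_parametric_map <- function(values, parameter, method, mask,
                               metadata = list()) {
  structure(list(values = values, parameter = parameter, method = method,
                 mask = mask, metadata = metadata),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("%s %s map: %d in-mask voxels, median %.3f (%d NaN)\n",
              x$method, x$parameter, sum(x$mask),
              stats::median(v, na.rm = TRUE), sum(is.nan(v))))
  invisible(x)
}

#' In-mask values of a parametric map
#' @param map a `parametric_map`.
#' @param finite drop non-finite values.
#' @export
map_values <- function(map, finite = FALSE) {
  v <- map$values[map$mask]
  if (finite) v <- v[is.finite(v)]
  v
}

as_dynamic_array <- function(dynamic_image) {
  if (inherits(dynamic_image, "pet_phantom")) dynamic_image$image
  else dynamic_image
}

#' Extract regional time-activity curves from a labelled dynamic image
#'
#' The regional TAC is the unweighted mean over in-region voxels, frame by
#' frame. Empty regions are omitted with a warning; labels missing from the
#' lookup table are kept under their numeric name with a warning.
#'
#' @param dynamic_image 4D array (x, y, z, frame) or a `pet_phantom`.
#' @param label_image 3D integer array of region labels (0 = background).
#' @param schedule a [frame_schedule()] matching the 4th dimension.
#' @param region_names optional named lookup, `names(region_names)` =
#'   label as character, values = region name.
#' @return a `region_table`: list with `regions` (data.frame `label`,
#'   `region`, `n_voxels`) and `tacs` (named list of `tissue_tac`).
#' @export
extract_tacs <- function(dynamic_image, label_image, schedule,
                         region_names = NULL) {
  img <- as_dynamic_array(dynamic_image)
  if (inherits(dynamic_image, "pet_phantom") && missing(label_image))
    label_image <- dynamic_image$labels
  dims <- dim(img)
  if (length(dims) != 4) stop("dynamic image must be 4D")
  if (!identical(dims[1:3], dim(label_image)))
    stop(sprintf("spatial grid mismatch: image %s vs labels %s",
                 paste(dims[1:3], collapse = "x"),
                 paste(dim(label_image), collapse = "x")))
  if (dims[4] != nrow(schedule))
    stop("frame count mismatch between image and schedule")
  flat <- matrix(img, prod(dims[1:3]), dims[4])
  labvec <- as.integer(label_image)
  labs <- sort(unique(labvec[labvec != 0]))
  tacs <- list(); rows <- list()
  for (lab in labs) {
    idx <- which(labvec == lab)
    nm <- if (!is.null(region_names) && !is.null(region_names[[as.character(lab)]]))
      region_names[[as.character(lab)]]
    else {
      if (!is.null(region_names))
        warning("label ", lab, " absent from region lookup; keeping numeric name")
      as.character(lab)
    }
    vals <- if (length(idx) == 1) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
    tacs[[nm]] <- structure(list(values = vals, schedule = schedule,
                                 provenance = list(label = lab,
                                                   n_voxels = length(idx))),
                            class = "tissue_tac")
    rows[[nm]] <- data.frame(label = lab, region = nm, n_voxels = length(idx))
  }
  structure(list(regions = do.call(rbind, c(rows, make.row.names = FALSE)),
                 tacs = tacs),
            class = "region_table")
}

make_tac_obj <- function(values, schedule) {
  structure(list(values = values, schedule = schedule, provenance = list()),
            class = "tissue_tac")
}

voxel_loop <- function(Y, schedule, fitter, outputs) {
  nv <- ncol(Y)
  res <- matrix(NaN, nv, length(outputs), dimnames = list(NULL, outputs))
  failures <- 0L
  for (j in seq_len(nv)) {
    f <- tryCatch(fitter(make_tac_obj(Y[, j], schedule)),
                  error = function(e) NULL)
    if (is.null(f)) { failures <- failures + 1L; next }
    p <- c(f$params, f$par, f[setdiff(names(f), c("params", "par"))])
    for (o in outputs) if (!is.null(p[[o]])) res[j, o] <- p[[o]]
  }
  list(values = res, failures = failures)
}

#' Fit an estimator voxel-by-voxel and produce parametric maps
#'
#' Every in-mask voxel is fitted independently with the chosen method;
#' failures yield NaN and are counted in the map metadata. Maps carry the
#' method settings, the fixed k2' (SRTM2), and failure counts as
#' provenance.
#'
#' @param dynamic_image 4D array or `pet_phantom`.
#' @param mask logical/0-1 3D array of voxels to fit; for a phantom,
#'   defaults to all labelled voxels.
#' @param method one of `"logan"`, `"rlogan"`, `"mrtmo"`, `"mrtm1"`,
#'   `"mrtm2"`, `"mrtm3"`, `"mrtm4"`, `"rpm"`, `"srtm2"`, `"sa"`,
#'   `"1t2kvb"`, `"srtm"`.
#' @param schedule a [frame_schedule()]; defaults to the phantom's.
#' @param input input function (required for `logan`, `sa`, `1t2kvb`).
#' @param reference_tac reference-region `tissue_tac` (for reference
#'   methods); if `NULL`, computed as the mean TAC over `reference_mask`.
#' @param reference_mask logical 3D array defining the reference region.
#' @param weights per-frame weights; default [frame_weights()].
#' @param settings named list of method settings (`tstar`, `grid`,
#'   `bp_threshold`, `k2_prime`, ...), passed through to the estimator.
#' @return named list of `parametric_map` objects, one per parameter the
#'   method produces.
#' @export
fit_voxelwise <- function(dynamic_image, mask = NULL, method, schedule = NULL,
                          input = NULL, reference_tac = NULL,
                          reference_mask = NULL, weights = NULL,
                          settings = list()) {
  method <- tolower(method)
  img <- as_dynamic_array(dynamic_image)
  if (inherits(dynamic_image, "pet_phantom")) {
    if (is.null(schedule)) schedule <- dynamic_image$schedule
    if (is.null(input)) input <- dynamic_image$input
    if (is.null(mask)) mask <- dynamic_image$labels != 0
  }
  if (is.null(schedule)) stop("schedule is required")
  mask <- array(as.logical(mask), dim(img)[1:3])
  nvox <- sum(mask)
  if (nvox == 0) stop("empty mask")

  needs_plasma <- method %in% c("logan", "sa", "1t2kvb")
  needs_ref <- method %in% c("rlogan", "mrtmo", "mrtm1", "mrtm2", "mrtm3",
                             "mrtm4", "rpm", "srtm2", "srtm")
  if (needs_plasma && is.null(input))
    stop("method '", method, "' requires a plasma input function")
  if (needs_ref && is.null(reference_tac)) {
    if (is.null(reference_mask))
      stop("method '", method, "' requires a reference TAC or reference mask")
    lab <- array(0L, dim(mask)); lab[reference_mask != 0] <- 1L
    reference_tac <- extract_tacs(img, lab, schedule)$tacs[[1]]
  }

  flat <- matrix(img, prod(dim(img)[1:3]), dim(img)[4])
  Y <- t(flat[which(mask), , drop = FALSE])           # frames x voxels
  s <- settings
  metadata <- c(list(method = method), s)
  failures <- 0L

  if (method == "rpm") {
    grid <- s$grid %||% basis_grid(0.01, 0.1, 30)
    vox <- rpm(Y, reference_tac, weights, grid,
               nonneg_r1 = isTRUE(s$nonneg_r1))
    res <- as.matrix(vox[, c("BPND", "DVR", "R1", "k2a")])
  } else if (method == "srtm2") {
    grid <- s$grid %||% basis_grid(0.01, 0.1, 30)
    fit <- srtm2(Y, reference_tac, weights, grid,
                 bp_threshold = s$bp_threshold %||% 3,
                 k2_prime = s$k2_prime)
    res <- as.matrix(fit$voxels[, c("BPND", "DVR", "R1", "k2a")])
    metadata$k2p_star <- fit$k2p_star
    metadata$fallback <- fit$fallback
  } else if (method == "sa") {
    grid <- s$grid %||% basis_grid(0.01, 0.1, 50)
    bases <- basis_matrix_fine(input$time, input$plasma_parent, grid, schedule)
    out <- voxel_loop(Y, schedule, function(tt)
      spectral_analysis(tt, input, weights, grid,
                        vb_regressor = s$vb_regressor %||% "whole_blood",
                        basis_cache = bases),
      c("VT", "K1", "VB"))
    res <- out$values; failures <- out$failures
  } else if (method == "logan") {
    out <- voxel_loop(Y, schedule, function(tt)
      logan_vt(tt, input, tstar = s$tstar %||% 10,
               weights = weights, weighted = isTRUE(s$weighted)),
      "VT")
    res <- out$values; failures <- out$failures
  } else if (method == "rlogan") {
    out <- voxel_loop(Y, schedule, function(tt)
      rlogan_dvr(tt, reference_tac, tstar = s$tstar %||% 30,
                 k2_prime = s$k2_prime, weights = weights,
                 weighted = isTRUE(s$weighted)),
      c("DVR", "BPND"))
    res <- out$values; failures <- out$failures
  } else if (method %in% c("mrtmo", "mrtm1", "mrtm2", "mrtm3", "mrtm4")) {
    variant <- sub("mrtmo", "MRTMo", sub("mrtm", "MRTM", method))
    out <- voxel_loop(Y, schedule, function(tt)
      mrtm(tt, reference_tac, tstar = s$tstar %||% 10, variant = variant,
           k2_prime = s$k2_prime, weights = weights,
           weighted = isTRUE(s$weighted)),
      c("DVR", "BPND", "R1", "k2p"))
    res <- out$values; failures <- out$failures
  } else if (method == "1t2kvb") {
    out <- voxel_loop(Y, schedule, function(tt)
      fit_1t2kvb(tt, input, weights), c("VT", "K1", "VB"))
    res <- out$values; failures <- out$failures
  } else if (method == "srtm") {
    out <- voxel_loop(Y, schedule, function(tt)
      fit_srtm(tt, reference_tac, weights), c("BPND", "DVR", "R1"))
    res <- out$values; failures <- out$failures
  } else stop("unknown method: ", method)

  metadata$n_failures <- failures
  metadata$n_voxels <- nvox
  lapply(stats::setNames(colnames(res), colnames(res)), function(param) {
    vol <- array(NaN, dim(mask))
    vol[which(mask)] <- res[, param]
    new_parametric_map(vol, param, method, mask, metadata)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp a parametric map to physiological bounds
#'
#' @param map a `parametric_map`.
#' @param lower,upper bounds (either may be `NULL`).
#' @param policy `"clip"` (set to the bound) or `"nan"`.
#' @return the clamped map; the number of affected voxels is recorded in
#'   `metadata$n_clamped`.
#' @export
clamp_map <- function(map, lower = NULL, upper = NULL,
                      policy = c("clip", "nan")) {
  policy <- match.arg(policy)
  v <- map$values
  out_lo <- if (!is.null(lower)) map$mask & !is.na(v) & v < lower else FALSE
  out_hi <- if (!is.null(upper)) map$mask & !is.na(v) & v > upper else FALSE
  n <- sum(out_lo) + sum(out_hi)
  if (policy == "clip") {
    if (!is.null(lower)) v[out_lo] <- lower
    if (!is.null(upper)) v[out_hi] <- upper
  } else {
    v[out_lo | out_hi] <- NaN
  }
  map$values <- v
  map$metadata$n_clamped <- n
  map$metadata$clamp <- list(lower = lower, upper = upper, policy = policy)
  map
}

#' Write / read NIfTI images
#'
#' Thin wrappers around RNifti. `write_map_nifti()` stores the value grid
#' (out-of-mask voxels NaN) with a JSON sidecar holding the map metadata;
#' `write_phantom_nifti()` writes the 4D dynamic image, the label image and
#' the TSV/JSON companions of a phantom into a directory.
#'
#' @param map a `parametric_map`.
#' @param path output `.nii.gz` path.
#' @export
write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$values), path)
  meta <- c(list(parameter = map$parameter, method = map$method), map$metadata)
  meta <- meta[vapply(meta, function(x)
    is.null(x) || is.atomic(x) || is.list(x), logical(1))]
  meta$grid <- if (!is.null(map$metadata$grid)) as.numeric(map$metadata$grid)
  jsonlite::write_json(meta, paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_map_nifti
#' @param phantom a `pet_phantom`.
#' @param dir output directory (created if needed).
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(phantom$image),
                     file.path(dir, "dynamic.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$labels * 1.0),
                     file.path(dir, "labels.nii.gz"))
  write_schedule_tsv(phantom$schedule, file.path(dir, "schedule.tsv"))
  write_input_tsv(phantom$input, file.path(dir, "input.tsv"))
  write_truth_tsv(phantom$truth, file.path(dir, "truth.tsv"),
                  meta = list(seed = phantom$seed,
                              noise_level = phantom$spec$noise_level,
                              voxel_size_mm = phantom$spec$voxel_size_mm))
  invisible(dir)
}

#' @rdname write_map_nifti
#' @export
read_dynamic_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}
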