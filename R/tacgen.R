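# Synthetic tissue kinetics: ground truth, regional TACs, noise, phantoms
# and paired test-retest sessions.
#
# The forward model everywhere is the reversible one-tissue compartment
# model with fractional blood volume,
#   C(t) = (1 - VB) K1 [Cp (*) exp(-k2 t)](t) + VB C_WB(t),
# with Cp the metabolite-corrected plasma parent curve and C_WB whole
# blood. Defaults describe a synaptic-density-type 11C tracer: grey-matter
# VT 15-20 mL/cm^3, a white-matter reference region (centrum semi-ovale
# like) with VT ~5, K1 0.2-0.4 mL cm^-3 min^-1, VB ~5%.

#' Ground-truth kinetic parameter table
#'
#' One row per region with the generating parameters and all derived
#' quantities: VT = K1/k2, and (relative to the single reference region)
#' DVR = VT/VT_ref, BPND = DVR - 1, R1 = K1/K1_ref, and the apparent efflux
#' rate k2a = k2/DVR.
#'
#' @param regions data.frame with columns `region` (name), `label` (positive
#'   integer, unique), `K1` (mL cm^-3 min^-1), `k2` (min^-1), `VB`
#'   (fraction in `[0, 1)`), and logical `is_reference` (exactly one TRUE).
#' @return a `ground_truth` data.frame with derived columns `VT`, `DVR`,
#'   `BPND`, `R1`, `k2a`.
#' @export
ground_truth <- function(regions) {
  need <- c("region", "label", "K1", "k2", "VB", "is_reference")
  if (!all(need %in% names(regions)))
    stop("regions must have columns: ", paste(need, collapse = ", "))
  if (any(regions$K1 < 0) || any(regions$k2 <= 0))
    stop("need K1 >= 0 and k2 > 0")
  if (any(regions$VB < 0 | regions$VB >= 1)) stop("VB must be in [0, 1)")
  if (sum(regions$is_reference) != 1)
    stop("exactly one region must be the reference")
  if (anyDuplicated(regions$label)) stop("labels must be unique")
  if (any(regions$label <= 0)) stop("labels must be positive (0 = background)")
  out <- regions
  out$VT <- out$K1 / out$k2
  ref <- out[out$is_reference, ]
  out$DVR <- out$VT / ref$VT
  out$BPND <- out$DVR - 1
  out$R1 <- out$K1 / ref$K1
  out$k2a <- out$k2 / out$DVR
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Default three-region ground truth
#'
#' Two grey-matter-like target regions and a white-matter reference region
#' with lower distribution volume, physiologically plausible for a
#' synaptic-density tracer.
#' @export
default_truth <- function() {
  ground_truth(data.frame(
    region = c("grey_high", "grey_low", "white_ref"),
    label = 1:3,
    K1 = c(0.35, 0.30, 0.25),
    k2 = c(0.0175, 0.020, 0.050),
    VB = c(0.05, 0.05, 0.05),
    is_reference = c(FALSE, FALSE, TRUE)))
}

# Noiseless model curve on the input fine grid for one parameter set.
model_curve_1t <- function(K1, k2, VB, input, scale_vb = TRUE) {
  conv <- convolve_exp(input$plasma_parent, k2, input$time)
  tis <- (if (scale_vb) (1 - VB) else 1) * K1 * conv
  tis + VB * input$whole_blood
}

#' Simulate a noiseless tissue time-activity curve
#'
#' Forward-models the one-tissue compartment model with blood volume for one
#' parameter set and bins the model curve into the frames of `schedule`.
#'
#' @param truth one row of a [ground_truth()] table, or any list with
#'   `K1`, `k2`, `VB`.
#' @param input an [make_input_function()] result covering the schedule.
#' @param schedule a [frame_schedule()].
#' @param scale_vb logical; scale the tissue term by `(1 - VB)` (default
#'   TRUE, the common 1T2k_VB convention).
#' @param sampling frame sampling convention, see [frame_sample()].
#' @return a `tissue_tac`: list with `values` (kBq/mL per frame),
#'   `schedule`, and `provenance` (generating parameters).
#' @export
make_tissue_tac <- function(truth, input, schedule, scale_vb = TRUE,
                            sampling = "average") {
  K1 <- truth$K1; k2 <- truth$k2; VB <- truth$VB
  if (is.null(K1) || is.null(k2) || is.null(VB))
    stop("truth must provide K1, k2, VB")
  if (K1 < 0 || k2 <= 0 || VB < 0 || VB >= 1) stop("invalid kinetic parameters")
  curve <- model_curve_1t(K1, k2, VB, input, scale_vb)
  vals <- frame_sample(input$time, curve, schedule, sampling)
  vals <- pmax(vals, 0)
  structure(list(values = vals, schedule = schedule,
                 provenance = list(K1 = K1, k2 = k2, VB = VB,
                                   VT = K1 / k2, scale_vb = scale_vb,
                                   sampling = sampling)),
            class = "tissue_tac")
}

#' Simulate the reference-region time-activity curve
#'
#' Identical forward model to [make_tissue_tac()]; additionally records the
#' reference efflux rate k2' in the provenance and, when `k2a_targets` is
#' given, flags the degenerate configuration in which k2' (reference efflux)
#' coincides with a target region's apparent efflux rate k2a -- the regime
#' in which the (k2' - k2a) term of the simplified reference tissue model
#' becomes non-identifiable.
#'
#' @inheritParams make_tissue_tac
#' @param k2a_targets optional numeric vector of target-region apparent
#'   efflux rates to compare k2' against.
#' @param degeneracy_tol relative tolerance for flagging k2' == k2a.
#' @export
make_reference_tac <- function(truth, input, schedule, scale_vb = TRUE,
                               sampling = "average", k2a_targets = NULL,
                               degeneracy_tol = 0.05) {
  tac <- make_tissue_tac(truth, input, schedule, scale_vb, sampling)
  tac$provenance$k2_prime <- truth$k2
  tac$provenance$K1_prime <- truth$K1
  if (!is.null(k2a_targets)) {
    tac$provenance$degenerate_with_k2a <-
      any(abs(truth$k2 - k2a_targets) <= degeneracy_tol * truth$k2)
  }
  tac
}

#' Add count-structured frame noise to a TAC
#'
#' Adds independent zero-mean Gaussian noise whose per-frame standard
#' deviation is proportional to the count-based frame sigma (sqrt of
#' sigma^2 = dcf^2 T / L^2), globally scaled so that the stated reference
#' frame attains the target coefficient of variation relative to the
#' noiseless value there. Frames with zero trues have zero model variance
#' and receive no noise.
#'
#' @param tac a `tissue_tac` (noiseless values).
#' @param level target COV (SD / value) at the reference frame; >= 0.
#' @param seed integer seed; noise is reproducible given the seed.
#' @param ref_frame frame index at which `level` is attained; default the
#'   frame with the largest noiseless value.
#' @return a `tissue_tac` with noisy `values` (can be negative, as in
#'   reconstructed PET data) and noise settings in provenance.
#' @export
add_noise <- function(tac, level, seed, ref_frame = NULL) {
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(tac)
  sched <- tac$schedule
  sig <- sqrt(frame_weights(sched)$sigma2)
  if (is.null(ref_frame)) ref_frame <- which.max(tac$values)
  if (sig[ref_frame] <= 0)
    stop("reference frame has zero count variance; pick another frame")
  sd <- level * abs(tac$values[ref_frame]) * sig / sig[ref_frame]
  noisy <- tac
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  noisy$values <- tac$values + stats::rnorm(length(sd), 0, sd)
  noisy$provenance$noise <- list(level = level, seed = seed,
                                 ref_frame = ref_frame)
  noisy
}

#' Specify a digital phantom
#'
#' @param labels 3D integer array of region labels; 0 = background. Every
#'   non-zero label must have a row in `truth`.
#' @param truth a [ground_truth()] table.
#' @param voxel_size_mm voxel edge length, mm (isotropic).
#' @param noise_level target COV at the reference frame (see [add_noise()]).
#' @param ref_frame reference frame for the noise scaling; `NULL` = each
#'   region's own peak frame.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(labels, truth, voxel_size_mm = 2,
                         noise_level = 0.05, ref_frame = NULL) {
  labs <- sort(unique(as.integer(labels[labels != 0])))
  missing <- setdiff(labs, truth$label)
  if (length(missing))
    stop("labels without ground truth: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, truth = truth,
                 voxel_size_mm = voxel_size_mm, noise_level = noise_level,
                 ref_frame = ref_frame),
            class = "phantom_spec")
}

#' Three-slab label image
#'
#' Splits a box into three slabs along x, one per label, with a one-voxel
#' background border: a desk-scale stand-in for a segmented brain volume.
#' @param dim integer length-3 grid dimensions.
#' @export
slab_labels <- function(dim = c(20, 20, 10)) {
  labels <- array(0L, dim)
  inner_x <- 2:(dim[1] - 1); inner_y <- 2:(dim[2] - 1); inner_z <- 2:(dim[3] - 1)
  cuts <- round(seq(1, dim[1] - 1, length.out = 4))
  for (r in 1:3) {
    xs <- intersect((cuts[r] + 1):cuts[r + 1], inner_x)
    labels[xs, inner_y, inner_z] <- r
  }
  labels
}

#' Generate a 4D dynamic phantom
#'
#' Every voxel's TAC is its label's noiseless model TAC plus independent
#' Gaussian frame noise (see [add_noise()]); background voxels are zero on
#' every frame.
#'
#' @param spec a [phantom_spec()].
#' @param input an input function covering the schedule.
#' @param schedule a [frame_schedule()].
#' @param seed integer seed for the voxel noise.
#' @return a `pet_phantom`: list with `image` (4D array x,y,z,frame),
#'   `labels`, `truth`, `schedule`, `input`, `spec`, `seed`.
#' @export
make_phantom <- function(spec, input, schedule, seed = 1) {
  labels <- spec$labels
  dims <- dim(labels)
  nf <- nrow(schedule)
  img <- array(0, c(dims, nf))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sig <- sqrt(frame_weights(schedule)$sigma2)
  flat <- matrix(0, prod(dims), nf)
  labvec <- as.integer(labels)
  for (lab in sort(unique(labvec[labvec != 0]))) {
    truth <- spec$truth[spec$truth$label == lab, ]
    tac <- make_tissue_tac(truth, input, schedule)
    idx <- which(labvec == lab)
    m <- matrix(rep(tac$values, each = length(idx)), length(idx), nf)
    if (spec$noise_level > 0) {
      rf <- spec$ref_frame
      if (is.null(rf)) rf <- which.max(tac$values)
      sd <- spec$noise_level * tac$values[rf] * sig / sig[rf]
      m <- m + matrix(stats::rnorm(length(idx) * nf), length(idx), nf) %*%
        diag(sd, nf)
    }
    flat[idx, ] <- m
  }
  img[] <- flat
  structure(list(image = img, labels = labels, truth = spec$truth,
                 schedule = schedule, input = input, spec = spec,
                 seed = seed),
            class = "pet_phantom")
}

# Scale one named parameter of a truth table by (1 + effect); derived
# columns are recomputed. An effect on VT is realised by scaling k2 down,
# leaving delivery K1 unchanged.
apply_effect <- function(truth, effect) {
  t2 <- as.data.frame(truth)
  for (nm in names(effect)) {
    f <- 1 + effect[[nm]]
    if (nm == "VT") t2$k2 <- t2$k2 / f
    else if (nm %in% c("K1", "k2", "VB")) t2[[nm]] <- t2[[nm]] * f
    else stop("effect must name K1, k2, VB or VT")
  }
  ground_truth(t2[c("region", "label", "K1", "k2", "VB", "is_reference")])
}

#' Generate a paired test-retest session
#'
#' Two phantom datasets sharing the frame schedule and input-function
#' family. Session-2 ground truth is the session-1 truth with the named
#' parameters scaled by `(1 + effect)`; noise draws are independent between
#' sessions, and the input-function amplitudes may be jittered between
#' sessions to emulate day-to-day delivery differences.
#'
#' @param spec a [phantom_spec()] (session-1 truth lives here).
#' @param effect named list/vector of fractional changes applied to
#'   session 2, e.g. `c(VT = -0.25)`; empty for a null pair.
#' @param seeds integer length-2, noise seeds for the two sessions.
#' @param schedule a [frame_schedule()] shared by both sessions.
#' @param input_params input-model coefficients for session 1 (defaults
#'   used when omitted).
#' @param input_jitter fractional SD of the multiplicative jitter applied
#'   to the bolus amplitudes for session 2 (0 = identical input).
#' @return list with elements `session1`, `session2` (each a
#'   `pet_phantom`) and `effect`.
#' @export
make_trt_pair <- function(spec, effect = list(), seeds = c(1, 2),
                          schedule = default_schedule(),
                          input_params = list(), input_jitter = 0) {
  input1 <- make_input_function(input_params, schedule)
  p2 <- utils::modifyList(default_input_params(), input_params)
  if (input_jitter > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seeds[2] + 10000L)
    for (nm in c("A1", "A2", "A3"))
      p2[[nm]] <- p2[[nm]] * exp(stats::rnorm(1, 0, input_jitter))
  }
  input2 <- make_input_function(p2, schedule)
  spec2 <- spec
  if (length(effect)) spec2$truth <- apply_effect(spec$truth, effect)
  list(session1 = make_phantom(spec, input1, schedule, seed = seeds[1]),
       session2 = make_phantom(spec2, input2, schedule, seed = seeds[2]),
       effect = effect)
}

#' Simulate a test-retest cohort of phantom subjects
#'
#' Each subject gets its own ground truth (the base truth with independent
#' lognormal jitter on K1 and k2, emulating between-subject physiological
#' spread) and a paired session dataset via [make_trt_pair()]. All seeds
#' derive deterministically from `seed`.
#'
#' @param n_subjects number of subjects.
#' @param labels 3D label array for every subject's phantom.
#' @param truth base [ground_truth()] table.
#' @param effect named fractional between-session change (see
#'   [make_trt_pair()]); empty for a null cohort.
#' @param noise_level per-voxel COV at the reference frame.
#' @param subject_cv lognormal coefficient of variation of the per-subject
#'   K1 and k2 jitter (0 disables it).
#' @param schedule shared [frame_schedule()].
#' @param seed master seed.
#' @return list of per-subject lists (`session1`, `session2`, `truth`).
#' @export
simulate_trt_cohort <- function(n_subjects = 8, labels = slab_labels(c(10, 10, 5)),
                                truth = default_truth(), effect = list(),
                                noise_level = 0.05, subject_cv = 0.1,
                                schedule = default_schedule(), seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  jit <- matrix(stats::rnorm(2 * n_subjects * nrow(truth), 0, subject_cv),
                ncol = 2 * nrow(truth))
  lapply(seq_len(n_subjects), function(s) {
    t_s <- as.data.frame(truth)
    if (subject_cv > 0) {
      nr <- nrow(t_s)
      t_s$K1 <- t_s$K1 * exp(jit[s, seq_len(nr)])
      t_s$k2 <- t_s$k2 * exp(jit[s, nr + seq_len(nr)])
    }
    t_s <- ground_truth(t_s[c("region", "label", "K1", "k2", "VB",
                              "is_reference")])
    spec <- phantom_spec(labels, t_s, noise_level = noise_level)
    pair <- make_trt_pair(spec, effect = effect,
                          seeds = c(seed * 1000L + 2L * s,
                                    seed * 1000L + 2L * s + 1L),
                          schedule = schedule)
    c(pair, list(truth = t_s))
  })
}

#' Write a ground-truth table as TSV with a JSON sidecar
#' @param truth a [ground_truth()] table.
#' @param path TSV path.
#' @param meta named list stored in the JSON sidecar (seeds, generator
#'   settings).
#' @export
write_truth_tsv <- function(truth, path, meta = list()) {
  utils::write.table(as.data.frame(truth), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
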