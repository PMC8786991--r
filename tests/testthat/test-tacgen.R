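test_that("ground-truth derived ratios hold to machine precision", {
  tr <- default_truth()
  expect_equal(tr$VT, tr$K1 / tr$k2, tolerance = 1e-15)
  ref <- tr[tr$is_reference, ]
  expect_equal(tr$DVR, tr$VT / ref$VT, tolerance = 1e-15)
  expect_equal(tr$BPND, tr$DVR - 1, tolerance = 1e-15)
  expect_equal(tr$R1, tr$K1 / ref$K1, tolerance = 1e-15)
  expect_equal(tr$k2a, tr$k2 / tr$DVR, tolerance = 1e-15)
  expect_error(ground_truth(within(as.data.frame(tr),
                                   is_reference <- FALSE)),
               "reference")
})

test_that("blood-volume term: VB = 0 removes any whole-blood dependence", {
  sched <- fx_sched()
  inp_a <- fx_input()
  inp_b <- make_input_function(list(pwb_ratio = 3), sched)  # different blood
  t0 <- list(K1 = 0.3, k2 = 0.06, VB = 0)
  expect_equal(make_tissue_tac(t0, inp_a, sched)$values,
               make_tissue_tac(t0, inp_b, sched)$values, tolerance = 1e-12)
  # K1 = 0, VB = 0 -> all-zero TAC
  expect_equal(make_tissue_tac(list(K1 = 0, k2 = 0.06, VB = 0),
                               inp_a, sched)$values,
               rep(0, 19))
})

test_that("forward model matches a high-resolution Riemann oracle within 0.5%", {
  sched <- fx_sched(); inp <- fx_input()
  truth <- list(K1 = 0.3, k2 = 0.06, VB = 0.05)
  tac <- make_tissue_tac(truth, inp, sched)
  conv <- riemann_conv(inp$time, inp$plasma_parent, truth$k2, dt = 0.002)
  model <- (1 - truth$VB) * truth$K1 * conv + truth$VB * inp$whole_blood
  # independent frame averaging: dense trapezoids per frame
  oracle <- vapply(seq_len(nrow(sched)), function(i) {
    a <- sched$start[i]; b <- a + sched$duration[i]
    (trapz_upto(inp$time, model, b) - trapz_upto(inp$time, model, a)) /
      (b - a)
  }, numeric(1))
  late <- frame_mid(sched) > 1     # skip near-zero pre-bolus frames
  expect_lt(max(rel_err(tac$values[late], oracle[late])), 0.005)
})

test_that("tissue component is exactly linear in K1 when VB = 0", {
  sched <- fx_sched(); inp <- fx_input()
  a <- make_tissue_tac(list(K1 = 0.2, k2 = 0.04, VB = 0), inp, sched)
  b <- make_tissue_tac(list(K1 = 0.6, k2 = 0.04, VB = 0), inp, sched)
  expect_equal(b$values, 3 * a$values, tolerance = 1e-12)
})

test_that("reference TAC records k2' and flags the degenerate configuration", {
  sched <- fx_sched(); inp <- fx_input()
  tr <- default_truth()
  target <- tr[1, ]; ref <- tr[3, ]
  # identical truths -> identical TACs
  expect_equal(make_reference_tac(target, inp, sched)$values,
               make_tissue_tac(target, inp, sched)$values)
  r <- make_reference_tac(ref, inp, sched, k2a_targets = tr$k2a[1:2])
  expect_equal(r$provenance$k2_prime, ref$k2)
  expect_false(r$provenance$degenerate_with_k2a)
  rd <- make_reference_tac(list(K1 = 0.25, k2 = tr$k2a[1], VB = 0.05),
                           inp, sched, k2a_targets = tr$k2a[1:2])
  expect_true(rd$provenance$degenerate_with_k2a)
  # SO-like reference (lower VT) implies DVR > 1 for grey matter
  expect_true(all(tr$DVR[!tr$is_reference] > 1))
})

test_that("noise is reproducible, zero at level 0, and hits the target COV", {
  tac <- fx_tac0()
  expect_equal(add_noise(tac, 0, seed = 1)$values, tac$values)
  expect_error(add_noise(tac, -0.1, seed = 1), ">= 0")
  n1 <- add_noise(tac, 0.1, seed = 11)
  expect_equal(n1$values, add_noise(tac, 0.1, seed = 11)$values)
  expect_false(isTRUE(all.equal(n1$values,
                                add_noise(tac, 0.1, seed = 12)$values)))
  # Monte-Carlo check of the COV scaling at the reference frame
  ref_frame <- which.max(tac$values)
  reps <- vapply(1:1000, function(s)
    add_noise(tac, 0.1, seed = s)$values[ref_frame], numeric(1))
  cov <- stats::sd(reps) / tac$values[ref_frame]
  expect_gt(cov, 0.095)
  expect_lt(cov, 0.105)
})

test_that("phantom voxels replicate their label TAC (noise-free) and average to it (noisy)", {
  sched <- fx_sched(); inp <- fx_input()
  tr <- default_truth()
  lab1 <- array(1L, c(4, 4, 2))
  ph0 <- make_phantom(phantom_spec(lab1, tr, noise_level = 0), inp, sched)
  flat <- matrix(ph0$image, 32, 19)
  expect_equal(flat, matrix(rep(flat[1, ], each = 32), 32, 19),
               tolerance = 1e-12)
  expect_equal(flat[1, ], make_tissue_tac(tr[1, ], inp, sched)$values,
               tolerance = 1e-12)

  labs <- slab_labels(c(20, 20, 10))
  ph <- make_phantom(phantom_spec(labs, tr, noise_level = 0.05), inp, sched,
                     seed = 5)
  flat <- matrix(ph$image, prod(dim(labs)), 19)
  for (l in 1:3) {
    idx <- which(as.integer(labs) == l)
    truth_tac <- make_tissue_tac(tr[tr$label == l, ], inp, sched)$values
    est <- colMeans(flat[idx, ])
    se <- apply(flat[idx, ], 2, stats::sd) / sqrt(length(idx))
    expect_true(all(abs(est - truth_tac) < 5 * se + 1e-9),
                label = paste("label", l, "mean TAC within 5 SE"))
  }
  # background voxels stay zero
  expect_equal(max(abs(flat[as.integer(labs) == 0, ])), 0)
  # label without truth entry is rejected
  bad <- labs; bad[1, 1, 1] <- 9L
  expect_error(phantom_spec(bad, tr), "without ground truth")
})

test_that("test-retest pairs scale truth and reproduce the null", {
  tr <- default_truth()
  spec <- phantom_spec(slab_labels(c(6, 6, 3)), tr, noise_level = 0)
  pair <- make_trt_pair(spec, effect = list(), seeds = c(3, 3))
  expect_equal(pair$session1$image, pair$session2$image)

  pair2 <- make_trt_pair(spec, effect = c(VT = -0.25), seeds = c(3, 4))
  expect_equal(pair2$session2$truth$VT, 0.75 * tr$VT, tolerance = 1e-12)
  expect_equal(pair2$session2$truth$K1, tr$K1)   # VT effect via k2

  # null cohort: whole-brain AUC-based TRT centred on zero
  cohort <- simulate_trt_cohort(n_subjects = 8,
                                labels = slab_labels(c(8, 8, 4)),
                                noise_level = 0.05, seed = 2)
  auc <- function(ph) {
    rt <- extract_tacs(ph, ph$labels, ph$schedule)
    mean(vapply(rt$tacs, function(tt)
      sum(tt$values * tt$schedule$duration), numeric(1)))
  }
  t1 <- vapply(cohort, function(s) auc(s$session1), numeric(1))
  t2 <- vapply(cohort, function(s) auc(s$session2), numeric(1))
  expect_lt(abs(trt(t1, t2)$mean_trt), 2)
})
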