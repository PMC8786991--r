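test_that("RPM: identity target gives R1 = 1, BPND = 0", {
  ref <- fx_ref0()
  fit <- rpm(ref, ref)
  expect_equal(fit$par$R1, 1, tolerance = 1e-6)
  expect_equal(fit$BPND, 0, tolerance = 1e-6)
})

test_that("RPM recovers an in-grid simulation and converges under grid doubling", {
  sched <- fx_sched(); inp <- fx_input()
  # k2' = 0.06, R1 = 1.2, BPND = 3: the target follows an apparent
  # one-tissue model with rate k2a = 0.018, inside the default grid
  ref <- make_reference_tac(list(K1 = 0.25, k2 = 0.06, VB = 0), inp, sched)
  tac <- make_tissue_tac(list(K1 = 0.3, k2 = 0.018, VB = 0), inp, sched)
  errs <- vapply(c(30, 60, 120), function(cnt)
    rel_err(rpm(tac, ref, grid = basis_grid(0.01, 0.1, cnt))$BPND, 3),
    numeric(1))
  # spacing-limited at 30 bases (log step ~8%, half-step ~4%); refinement
  # reduces the error relative to the coarse grid
  expect_lt(errs[1], 0.05)
  expect_lt(errs[2], errs[1] + 1e-9)
  expect_lt(errs[3], errs[1] + 1e-9)
  fit <- rpm(tac, ref)
  expect_lt(rel_err(fit$par$R1, 1.2), 0.02)
  expect_false(fit$flags$at_edge)
})

test_that("RPM flags estimates clamped at the grid boundary", {
  sched <- fx_sched(); inp <- fx_input()
  ref <- fx_ref0()
  # low-binding target: k2a = 0.24, above the 0.1 upper grid bound
  tac <- make_tissue_tac(list(K1 = 0.3, k2 = 0.12, VB = 0), inp, sched)
  fit <- rpm(tac, ref)
  expect_true(fit$flags$at_edge)
  expect_equal(fit$par$k2a, 0.1, tolerance = 1e-9)
})

test_that("SRTM2 two-pass is internally consistent on a homogeneous input", {
  ref <- fx_ref0(); tac <- fx_tac0()
  p1 <- rpm(tac, ref)
  s2 <- suppressWarnings(srtm2(tac, ref))
  # k2'* is that voxel's own pass-1 k2'; pass-2 BPND matches pass 1
  expect_equal(s2$k2p_star, p1$par$k2p, tolerance = 1e-9)
  expect_lt(rel_err(s2$voxels$BPND[1], p1$BPND), 0.01)
})

test_that("SRTM2 with the true k2' fixed recovers BPND across the truth grid", {
  sched <- fx_sched(); inp <- fx_input()
  ref <- fx_ref0()
  for (vt in c(10, 15, 20)) {
    tac <- make_tissue_tac(list(K1 = 0.3, k2 = 0.3 / vt, VB = 0), inp, sched)
    s2 <- srtm2(tac, ref, k2_prime = 0.05)
    expect_lt(rel_err(s2$voxels$BPND[1], vt / 5 - 1), 0.05,
              label = paste("VT", vt))
    expect_false(s2$fallback)
  }
})

test_that("SRTM2 threshold fallback triggers iff no voxel exceeds the threshold", {
  sched <- fx_sched(); inp <- fx_input()
  ref <- fx_ref0()
  # true BPND = 2 (VT 15 vs 5): below the default threshold of 3
  tac <- make_tissue_tac(list(K1 = 0.3, k2 = 0.02, VB = 0), inp, sched)
  expect_warning(s2 <- srtm2(tac, ref, bp_threshold = 3), "BPND > 3")
  expect_true(s2$fallback)
  expect_silent(s2b <- srtm2(tac, ref, bp_threshold = 1))
  expect_false(s2b$fallback)
})

test_that("spectral analysis reads a pure blood signal as VB only", {
  sched <- fx_sched(); inp <- fx_input()
  wb <- frame_sample(inp$time, inp$whole_blood, sched)
  tac <- structure(list(values = 0.05 * wb, schedule = sched),
                   class = "tissue_tac")
  sa <- spectral_analysis(tac, inp)
  expect_equal(sa$VB, 0.05, tolerance = 1e-6)
  expect_equal(sa$VT, 0, tolerance = 1e-8)
  expect_equal(sa$K1, 0, tolerance = 1e-8)
})

test_that("spectral analysis recovers a single on-grid component", {
  sched <- fx_sched(); inp <- fx_input()
  # grid built so that k2 = 0.06 is exactly a node
  g <- basis_grid(0.015, 0.24, 9)
  expect_equal(as.numeric(g)[5], 0.06, tolerance = 1e-12)
  tac <- make_tissue_tac(list(K1 = 0.3, k2 = 0.06, VB = 0), inp, sched)
  sa <- spectral_analysis(tac, inp, grid = g)
  expect_lt(rel_err(sa$VT, 5), 0.01)
  expect_lt(rel_err(sa$K1, 0.3), 0.02)
})

test_that("off-grid spectral components split across nodes with bounded error", {
  sched <- fx_sched(); inp <- fx_input()
  tac <- make_tissue_tac(list(K1 = 0.3, k2 = 0.055, VB = 0), inp, sched)
  err <- vapply(c(50, 100), function(cnt) {
    sa <- spectral_analysis(tac, inp, grid = basis_grid(0.01, 0.1, cnt))
    c(rel_err(sa$VT, 0.3 / 0.055), rel_err(sa$K1, 0.3))
  }, numeric(2))
  expect_lt(err[1, 1], 0.03)            # VT at 50 bases
  expect_lt(err[2, 1], 0.05)            # K1 at 50 bases
  expect_lte(err[1, 2], err[1, 1] + 1e-9)
})

test_that("spectrum is non-negative and VT superposes for summed kinetics", {
  sched <- fx_sched(); inp <- fx_input()
  a <- make_tissue_tac(list(K1 = 0.2, k2 = 0.02, VB = 0), inp, sched)
  b <- make_tissue_tac(list(K1 = 0.15, k2 = 0.08, VB = 0), inp, sched)
  both <- a; both$values <- a$values + b$values
  sa <- spectral_analysis(both, inp)
  expect_true(all(sa$spectrum >= 0))
  expect_lt(rel_err(sa$VT, 0.2 / 0.02 + 0.15 / 0.08), 0.03)
  # all-noise (negative) TAC yields a flagged zero spectrum
  junk <- a; junk$values <- -abs(sin(1:19))
  sj <- spectral_analysis(junk, inp)
  expect_true(sj$zero_spectrum)
  expect_equal(sj$VT, 0)
})

test_that("basis methods are invariant to joint rescaling of all curves", {
  sched <- fx_sched(); inp <- fx_input()
  ref <- fx_ref0(); tac <- fx_tac0()
  c0 <- 2.9
  ref2 <- ref; ref2$values <- c0 * ref$values
  tac2 <- tac; tac2$values <- c0 * tac$values
  inp2 <- inp
  for (nm in c("plasma_total", "plasma_parent", "whole_blood"))
    inp2[[nm]] <- c0 * inp[[nm]]
  expect_equal(rpm(tac2, ref2)$BPND, rpm(tac, ref)$BPND, tolerance = 1e-9)
  expect_equal(spectral_analysis(tac2, inp2)$VT,
               spectral_analysis(tac, inp)$VT, tolerance = 1e-9)
})

test_that("RPM matches NLR SRTM on noise-free data up to grid discretisation", {
  sched <- fx_sched(); inp <- fx_input()
  ref <- make_reference_tac(list(K1 = 0.25, k2 = 0.06, VB = 0), inp, sched)
  tac <- make_tissue_tac(list(K1 = 0.3, k2 = 0.018, VB = 0), inp, sched)
  nlr <- fit_srtm(tac, ref)
  gap30 <- abs(rpm(tac, ref, grid = basis_grid(0.01, 0.1, 30))$BPND - nlr$BPND)
  gap120 <- abs(rpm(tac, ref, grid = basis_grid(0.01, 0.1, 120))$BPND - nlr$BPND)
  expect_lt(gap120, gap30 + 1e-9)
  expect_lt(gap120 / nlr$BPND, 0.01)
})
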