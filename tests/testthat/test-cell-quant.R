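test_that("frame quantification is the normalized compartment split", {
  f <- matrix(0, 10, 10)
  nuc <- matrix(FALSE, 10, 10); nuc[4:6, 4:6] <- TRUE
  cell <- matrix(FALSE, 10, 10); cell[2:9, 2:9] <- TRUE
  f[cell] <- (1000 - 300) / (sum(cell) - sum(nuc))
  f[nuc] <- 300 / sum(nuc)
  q <- quantify_frame(f, mask_pair(nuc, cell))
  expect_equal(unname(q["N_norm"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(q["C_norm"]), 0.7, tolerance = 1e-12)
  expect_equal(unname(sum(q)), 1)
})

test_that("nucleus equal to cell gives (1, 0) and an invalid ratio flag", {
  f <- matrix(5, 6, 6)
  m <- matrix(TRUE, 6, 6)
  q <- quantify_frame(f, mask_pair(m, m))
  expect_equal(unname(q), c(1, 0))
  stack <- structure(list(frames = list(f), times = 0, phases = "recovery",
                          nucleus_mask = m, cell_mask = m),
                     class = "frame_stack")
  tc <- build_timecourse(stack)
  expect_false(tc$valid[1])
  expect_true(is.infinite(tc$ratio[1]))
})

test_that("mask validation catches empty and escaping nuclei", {
  m0 <- matrix(FALSE, 5, 5)
  m1 <- matrix(TRUE, 5, 5)
  expect_error(mask_pair(m0, m1), "empty")
  nuc <- m0; nuc[1, 1] <- TRUE
  cell <- m0; cell[3:5, 3:5] <- TRUE
  expect_error(mask_pair(nuc, cell), "contained")
  expect_error(quantify_frame(matrix(0, 5, 5), mask_pair(m1, m1)), "zero")
})

test_that("background correction removes a constant offset", {
  bgreg <- matrix(FALSE, 8, 8); bgreg[1, ] <- TRUE
  expect_equal(background_correct(matrix(7, 8, 8), bgreg), matrix(0, 8, 8))
  sig <- matrix(runif(64), 8, 8); sig[1, ] <- 0
  expect_equal(background_correct(sig + 3, bgreg), sig, tolerance = 1e-12)
  expect_error(background_correct(sig, matrix(FALSE, 8, 8)), "empty")
})

test_that("noiseless rendered stacks quantify back to the exact truth", {
  spec <- cell_sim_spec(noise_cv = 0)
  st <- gen_frames(spec, shot_noise = FALSE, background = c(0, 0, 0))
  tc <- build_timecourse(st)
  expect_equal(tc$N_norm, st$truth$N_frac, tolerance = 1e-6)
  # amount ratio = (area_N / area_C) x concentration ratio
  rec <- tc$phase == "recovery"
  A_n <- sum(st$nucleus_mask)
  A_c <- sum(st$cell_mask & !st$nucleus_mask)
  truth_ratio <- (A_n / A_c) * st$truth$N_conc[rec] / st$truth$C_conc[rec]
  expect_equal(tc$ratio[rec], truth_ratio, tolerance = 1e-6)
})

test_that("quantification is invariant to background plane and gain", {
  spec <- cell_sim_spec(noise_cv = 0)
  flat <- gen_frames(spec, shot_noise = FALSE, background = c(0, 0, 0))
  offs <- gen_frames(spec, shot_noise = FALSE, background = c(25, 0, 0))
  bgreg <- matrix(FALSE, 96, 96); bgreg[1:3, ] <- TRUE
  bgreg[offs$cell_mask] <- FALSE
  tc0 <- build_timecourse(flat)
  tc1 <- build_timecourse(offs, background_region = bgreg)
  ok <- tc0$valid & tc1$valid
  expect_lt(max(abs(tc1$ratio[ok] - tc0$ratio[ok]) /
                pmax(tc0$ratio[ok], 0.05)), 0.01)
  # global gain cancels in the normalization
  gained <- flat
  gained$frames <- lapply(flat$frames, function(f) 3.7 * f)
  expect_equal(build_timecourse(gained)$ratio, tc0$ratio, tolerance = 1e-12)
})

test_that("shot-noise stacks recover the ratio within a few percent RMS", {
  spec <- cell_sim_spec(noise_cv = 0)
  st <- gen_frames(spec, background = c(0, 0, 0))  # Poisson noise on
  tc <- build_timecourse(st)
  A_n <- sum(st$nucleus_mask)
  A_c <- sum(st$cell_mask & !st$nucleus_mask)
  truth <- (A_n / A_c) * st$truth$N_conc / st$truth$C_conc
  keep <- truth > 0.05
  rms <- sqrt(mean(((tc$ratio[keep] - truth[keep]) / truth[keep])^2))
  expect_lt(rms, 0.02)
})

test_that("stacks roundtrip through TIFF/PNG/CSV on disk", {
  dir <- withr::local_tempdir()
  st <- gen_frames(cell_sim_spec(noise_cv = 0), shot_noise = FALSE)
  write_frame_stack(st, dir)
  back <- read_frame_stack(dir)
  expect_equal(back$times, st$times)
  expect_identical(back$nucleus_mask, st$nucleus_mask)
  tc0 <- build_timecourse(st)
  tc1 <- build_timecourse(back)
  expect_equal(tc1$ratio, tc0$ratio, tolerance = 1e-4)
})

test_that("geometry constructor rejects a nucleus touching the cell edge", {
  expect_error(frame_geometry(nucleus_center = c(80, 48),
                              nucleus_axes = c(16, 13)), "inside")
  expect_silent(frame_geometry())
})

test_that("a stack without masks errors by mask name", {
  st <- gen_frames(cell_sim_spec(noise_cv = 0), shot_noise = FALSE)
  st$nucleus_mask <- NULL
  expect_error(build_timecourse(st), "nucleus")
})
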