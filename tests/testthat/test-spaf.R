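test_that("patch_mask builds clipped unions of squares around anchors", {
  empty <- matrix(FALSE, 9, 9)
  expect_identical(patch_mask(empty, 3), empty)

  one <- empty; one[5, 5] <- TRUE
  pm <- patch_mask(one, 3)
  expect_identical(sum(pm), 9L)
  expect_true(all(pm[4:6, 4:6]))

  # wp = 2 must cover exactly the 2x2 residue loop of its anchor
  pm2 <- patch_mask(one, 2)
  expect_identical(sum(pm2), 4L)
  expect_true(all(pm2[5:6, 5:6]))

  # clipping at the border
  corner <- empty; corner[1, 1] <- TRUE
  expect_identical(sum(patch_mask(corner, 5)), 9L)  # 3x3 survives the clip

  # overlapping squares merge: count equals the brute-force set union
  two <- empty; two[4, 4] <- TRUE; two[4, 6] <- TRUE
  pm5 <- patch_mask(two, 5)
  anchors <- which(two, arr.ind = TRUE)
  expect_identical(sum(pm5), length(bf_patch_union(anchors, 5, 9, 9)))
})

test_that("spaf_step only rewrites patch pixels and equals the mask blend", {
  p <- vortex_phase(30, 30, data.frame(row = 15.5, col = 15.5, charge = 1))
  none <- matrix(FALSE, 30, 30)
  expect_identical(spaf_step(p, none, wf = 3, wp = 3), p)

  fpr <- fpr_mask(residue_map(p))
  out <- spaf_step(p, fpr, wf = 3, wp = 3)
  pm <- patch_mask(fpr, 3)
  expect_identical(out[!pm], p[!pm])          # bit-identical outside
  # blend identity: masked pixels carry the globally filtered values
  filt <- global_paf(p, 3)
  expect_identical(out[pm], filt[pm])
})

test_that("spaf returns residue-free input unchanged with a length-1 trace", {
  g <- gaussian_phase(50, 70, height = 20, sigma = 10)
  fit <- spaf(g$wrapped)
  expect_identical(fit$status, "residue-free")
  expect_identical(nrow(fit$trace), 1L)
  expect_identical(fit$phase, g$wrapped)
  expect_identical(fit$trace$n_residues, 0L)
})

test_that("spaf removes a close vortex pair and touches only nearby pixels", {
  p <- vortex_phase(60, 60, data.frame(row = c(30.5, 30.5), col = c(28.5, 31.5),
                                       charge = c(1, -1)))
  fit <- spaf(p)
  expect_identical(fit$status, "residue-free")
  expect_identical(residue_count(fit$phase), 0L)
  # pixels beyond the realized patch + filter reach are untouched
  reach <- max(fit$trace$wp) + max(fit$trace$wf_rows) + 2
  rows <- abs(seq_len(60) - 30.5) > reach
  cols <- abs(seq_len(60) - 30) > reach + 2
  expect_identical(fit$phase[rows, ], p[rows, ])
  expect_identical(fit$phase[, cols], p[, cols])
})

test_that("spaf trace starts at the input residue count and escalates monotonically", {
  sim <- simulated_phase(rows = 80, cols = 100, sigma = 18, seed = 3)
  fit <- spaf(sim$noisy)
  tr <- fit$trace
  expect_identical(tr$n_residues[1], residue_count(sim$noisy))
  expect_identical(tr$iteration, seq_len(nrow(tr)))
  # (wp, wf) non-decreasing lexicographically
  key <- tr$wp * 1000 + tr$wf_rows
  expect_true(all(diff(key) >= 0))
  expect_true(all(tr$wf_rows >= fit$config$wf_start & tr$wf_rows <= fit$config$wf_max))
  expect_true(all(tr$wp >= fit$config$wp_start & tr$wp <= fit$config$wp_max))
})

test_that("every spaf iteration changes only pixels inside its patch mask", {
  sim <- simulated_phase(rows = 60, cols = 80, sigma = 15, seed = 21)
  fit <- spaf(sim$noisy)
  expect_true(replay_spaf_locality(fit))
})

test_that("spaf is idempotent at its fixpoint", {
  # a charge-balanced pair: net topological charge zero, so removable
  p <- vortex_phase(40, 40, data.frame(row = c(20.5, 20.5), col = c(19.5, 21.5),
                                       charge = c(1, -1)))
  fit <- spaf(p)
  expect_identical(fit$status, "residue-free")
  again <- spaf(fit$phase)
  expect_identical(again$phase, fit$phase)
  expect_identical(nrow(again$trace), 1L)
})

test_that("spaf honors caps and reports non-convergence via status", {
  set.seed(99)
  p <- matrix(runif(30 * 30, -pi, pi), 30, 30)  # pure noise: very hard
  fit <- spaf(p, wf_max = 3, wp_max = 2, max_iterations = 10)
  expect_true(fit$status %in% c("cap-reached", "max-iter", "residue-free"))
  expect_identical(fit$n_residues, fit$trace$n_residues[nrow(fit$trace)])
  # a nonzero target stops early
  sim <- simulated_phase(rows = 60, cols = 80, sigma = 15, seed = 4)
  tol_fit <- spaf(sim$noisy, target_residues = 50)
  expect_identical(tol_fit$status, "residue-free")
  expect_lte(tol_fit$n_residues, 50L)
})

test_that("spaf methods expose the fit coherently", {
  p <- vortex_phase(40, 40, data.frame(row = c(20.5, 20.5), col = c(18.5, 22.5),
                                       charge = c(1, -1)))
  fit <- spaf(p)
  expect_identical(fitted(fit), fit$phase)
  expect_true(all(residuals(fit) == 0L))
  s <- summary(fit)
  expect_identical(s$residues_final, 0L)
  expect_gt(s$pixels_touched, 0)
  expect_output(print(fit), "residue-free")
  expect_output(print(s), "pixels modified")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("escalation mode 'always' still converges on an easy map", {
  p <- vortex_phase(40, 40, data.frame(row = c(20.5, 20.5), col = c(19.5, 21.5),
                                       charge = c(1, -1)))
  fit <- spaf(p, escalation = "always")
  expect_identical(fit$status, "residue-free")
  expect_identical(residue_count(fit$phase), 0L)
})
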