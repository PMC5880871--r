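# registration tests run on the small phantom configuration; the full-size
# study replication lives in the acceptance suite

test_that("rigid registration of an image with itself stays at the identity", {
  case <- small_case()
  fixed <- case$series$phases[[5]]
  rig <- register_rigid(fixed, fixed, eta = 2)
  expect_lt(max(abs(rig$translation)), 0.05)
  expect_lt(max(abs(rig$angles)), 0.005)
  expect_lte(attr(rig, "final_distance"), attr(rig, "initial_distance"))
})

test_that("rigid registration recovers a planted world translation", {
  cfg <- small_config(noise_sigma = 0, translation_mm = 0, bump_amp_mm = 0,
                      seed = 5L)
  case <- generate_phantom_case(cfg)
  fixed <- case$series$phases[[5]]
  t_true <- c(6, -4, 9)
  A2 <- fixed$affine
  A2[1:3, 4] <- A2[1:3, 4] + t_true
  moving <- new_volume(fixed$data, A2) # same anatomy, shifted world frame
  rig <- register_rigid(fixed, moving, eta = 2)
  expect_lt(max(abs(rig$translation - t_true)), 0.5)
  expect_lt(max(abs(rig$angles)), 0.02)
})

test_that("masked preregistration beats unmasked on liver-local motion", {
  cfg <- small_config(translation_mm = 0, n_bumps = 1L, bump_amp_mm = 12,
                      bump_sigma_mm = 30, noise_sigma = 1, sigma_A = 0,
                      p_B = 0, p_uncertain = 0, seed = 21L)
  case <- generate_phantom_case(cfg)
  fixed <- case$series$phases[[5]]
  mask <- segment_liver(case$series)
  rigid_mean_ld <- function(rig, lm) {
    mapped <- apply_rigid(rig, as.matrix(lm[, c("fx", "fy", "fz")]))
    d <- sqrt(rowSums((mapped - as.matrix(lm[, c("mx", "my", "mz")]))^2))
    mean(tapply(d, paste(lm$pair_id, lm$landmark_id), min))
  }
  ld_masked <- ld_unmasked <- numeric(0)
  for (p in 1:2) {
    lm <- case$landmarks[case$landmarks$pair_id == paste0("p", p), ]
    moving <- case$series$phases[[p]]
    masked <- register_rigid(fixed, moving, eta = 2, mask = mask)
    unmasked <- register_rigid(fixed, moving, eta = 2)
    ld_masked <- c(ld_masked, rigid_mean_ld(masked, lm))
    ld_unmasked <- c(ld_unmasked, rigid_mean_ld(unmasked, lm))
  }
  expect_lte(mean(ld_masked), mean(ld_unmasked))
})

test_that("deformable registration of an image with itself stays near zero", {
  case <- small_case()
  fixed <- case$series$phases[[5]]
  fld <- register_deformable(fixed, fixed, eta = 2)
  expect_lte(mean(sqrt(rowSums(matrix(fld$u, ncol = 3)^2))), 0.1)
})

test_that("an overwhelming regularizer forces the field to zero", {
  case <- small_case()
  fld <- register_deformable(case$series$phases[[5]], case$series$phases[[1]],
                             eta = 2, reg = reg_params(alpha = 1e6))
  expect_lte(mean(sqrt(rowSums(matrix(fld$u, ncol = 3)^2))), 0.1)
})

test_that("deformable registration improves landmark distances substantially", {
  case <- small_case()
  fixed <- case$series$phases[[5]]
  lds_b <- lds_a <- numeric(0)
  for (p in 1:2) {
    lm <- case$landmarks[case$landmarks$pair_id == paste0("p", p), ]
    rig <- register_rigid(fixed, case$series$phases[[p]], eta = 2)
    fld <- register_deformable(fixed, case$series$phases[[p]], eta = 2,
                               init = rig)
    diag <- attr(fld, "diagnostics")
    expect_lte(diag$J, diag$J0) # objective never worse than the zero field
    lds_b <- c(lds_b, landmark_distances(lm))
    lds_a <- c(lds_a, landmark_distances(lm, fld))
  }
  expect_lt(mean(lds_a), 0.5 * mean(lds_b))
})

test_that("the full pipeline emits one result per moving phase", {
  case <- small_case()
  res <- run_motion_correction(case$series, "RMwop", eta = 2,
                               reg = reg_params(levels = 2L, max_iter = 20L))
  expect_named(res, c("p1", "p2", "p3", "p4"))
  expect_s3_class(res$p1$field, "dce_field")
  expect_equal(dim(res$p1$warped$data), case$series$phases[[1]]$dim)
  expect_true(all(vapply(res, function(r) r$foldings, numeric(1)) >= 0))
})

test_that("zero-motion series yields near-zero fields in all variants", {
  cfg <- small_config(translation_mm = 0, bump_amp_mm = 0, seed = 6L)
  case <- generate_phantom_case(cfg)
  for (variant in c("FM", "RMwop")) {
    res <- run_motion_correction(case$series, variant, eta = 2,
                                 reg = reg_params(levels = 2L, max_iter = 20L))
    # sub-voxel residual: with no planted motion only noise can be fitted
    for (r in res)
      expect_lt(mean(sqrt(rowSums(matrix(r$field$u, ncol = 3)^2))), 1.0)
  }
})

test_that("method ordering on a scaled-down batch: both variants beat the
          uncorrected series, full method reported against no-prereg", {
  case <- small_case()
  lds <- list(before = numeric(0), FM = numeric(0), RMwop = numeric(0))
  for (variant in c("FM", "RMwop")) {
    res <- run_motion_correction(case$series, variant)
    for (p in 1:2) {
      lm <- case$landmarks[case$landmarks$pair_id == paste0("p", p), ]
      if (variant == "FM") lds$before <- c(lds$before, landmark_distances(lm))
      lds[[variant]] <- c(lds[[variant]],
                          landmark_distances(lm, res[[paste0("p", p)]]$field))
    }
  }
  expect_gt(mean(lds$before), mean(lds$RMwop))
  expect_gt(mean(lds$before), mean(lds$FM))
  # the full-method-vs-no-preregistration gap is expected only on average
  # over many cases; report it rather than hard-assert
  message(sprintf("mean LD: before %.2f, FM %.2f, RMwop %.2f",
                  mean(lds$before), mean(lds$FM), mean(lds$RMwop)))
})

test_that("rigid parameters validate and compose correctly", {
  tr <- rigid_transform(c(0.1, -0.2, 0.3), c(5, -3, 2), c(10, 10, 10))
  R <- dcemoco:::rotation_matrix(tr$angles)
  expect_equal(det(R), 1, tolerance = 1e-12)
  pts <- matrix(rnorm(15), ncol = 3)
  mapped <- apply_rigid(tr, pts)
  # distances are preserved by the rigid map
  expect_equal(as.numeric(dist(mapped)), as.numeric(dist(pts)),
               tolerance = 1e-12)
  expect_error(reg_params(alpha = -1), "alpha")
  expect_error(reg_params(levels = 0), "levels")
})
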