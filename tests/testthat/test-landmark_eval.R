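test_that("annotation planning halves the pairs and swaps for phase 2", {
  pairs <- make_pair_index(26)
  ids <- paste(pairs$case_id, pairs$pair_id)
  expect_equal(length(ids), 104L)
  plan <- plan_annotation(ids, L = 10L, seed = 1L)
  expect_equal(length(plan$phase1$A1), 52L)
  expect_equal(length(plan$phase1$A2), 52L)
  expect_setequal(c(plan$phase1$A1, plan$phase1$A2), ids)
  expect_identical(plan$phase2$A1, plan$phase1$A2)
  expect_identical(plan$phase2$A2, plan$phase1$A1)
  # determinism and odd splits
  expect_identical(plan_annotation(ids, seed = 1L), plan)
  p3 <- plan_annotation(c("a", "b", "c"), seed = 2L)
  expect_equal(abs(length(p3$phase1$A1) - length(p3$phase1$A2)), 1L)
  expect_error(plan_annotation(c("a"), seed = 1), "at least 2")
  expect_error(plan_annotation(ids, annotators = "A1"), "2 annotators")
})

test_that("sample sizing reproduces the analytic bounds", {
  expect_equal(required_pairs(3.07, 0.7925), 61L)
  expect_equal(required_pairs(1.9, 0.7925), 23L)
  expect_equal(required_pairs(2.5, 5), 1L)
  expect_error(required_pairs(-1, 1), "positive")
  # monotone: non-increasing in d, non-decreasing in s
  s <- 2.3
  ds <- seq(0.3, 3, by = 0.3)
  np <- vapply(ds, function(d) required_pairs(s, d), integer(1))
  expect_true(all(diff(np) <= 0))
  ss <- seq(0.5, 4, by = 0.25)
  np2 <- vapply(ss, function(s) required_pairs(s, 0.8), integer(1))
  expect_true(all(diff(np2) >= 0))
})

test_that("the CI half-width is a quarter of the voxel diagonal", {
  expect_equal(ci_halfwidth(3.17), 0.7925)
})

test_that("landmark distances use the closest-of-two rule", {
  lm <- toy_landmarks()
  # landmark 1: both annotators exact -> 0; landmark 2: min(|(1,0,0)|,|(3,0,0)|)
  # landmark 3: min(|(0,1,0)|, |(0,4,0)|)
  d <- landmark_distances(lm)
  expect_equal(unname(d), c(0, 1, 1))
  # the min contract: never above either single-annotator distance
  for (a in c("A1", "A2")) {
    sub <- lm[lm$annotator_id == a, ]
    da <- sqrt(rowSums((sub[, c("fx", "fy", "fz")] - sub[, c("mx", "my", "mz")])^2))
    expect_true(all(d <= da + 1e-12))
  }
})

test_that("a planted gross error is neutralized by the closer annotator", {
  lm <- toy_landmarks()
  lm$mx[lm$annotator_id == "A2"] <- lm$mx[lm$annotator_id == "A2"] + 50
  d <- landmark_distances(lm)
  sub <- lm[lm$annotator_id == "A1", ]
  d1 <- sqrt(rowSums((sub[, c("fx", "fy", "fz")] - sub[, c("mx", "my", "mz")])^2))
  expect_equal(unname(d), unname(d1))
})

test_that("distances with no field equal distances with a zero field", {
  case <- small_case()
  lm <- case$landmarks[case$landmarks$pair_id == "p1", ]
  geom <- case$series$phases[[1]]
  expect_equal(landmark_distances(lm, NULL),
               landmark_distances(lm, zero_field(geom)))
})

test_that("uncertain landmarks are excluded from distances", {
  lm <- toy_landmarks()
  lm$uncertain[lm$landmark_id == "lm02"] <- TRUE
  expect_equal(length(landmark_distances(lm)), 2L)
  expect_equal(length(inter_observer_distances(lm)), 2L)
})

test_that("the ground-truth field maps phantom landmarks exactly", {
  cfg <- small_config(sigma_A = 0, p_B = 0, p_uncertain = 0, seed = 8L)
  case <- generate_phantom_case(cfg)
  for (p in c(1L, 3L)) {
    lm <- case$landmarks[case$landmarks$pair_id == paste0("p", p), ]
    d <- landmark_distances(lm, case$gt_fields[[p]])
    expect_lt(max(d), 0.1)
  }
})

test_that("inter-observer distances follow the 3-4-5 triangle", {
  lm <- toy_landmarks()[1:2, ]
  lm$mx[2] <- lm$mx[1] + 3
  lm$my[2] <- lm$my[1] + 4
  expect_equal(unname(inter_observer_distances(lm)), 5)
  lm_same <- toy_landmarks()
  lm_same[lm_same$annotator_id == "A2", c("mx", "my", "mz")] <-
    lm_same[lm_same$annotator_id == "A1", c("mx", "my", "mz")]
  expect_true(all(inter_observer_distances(lm_same) == 0))
  expect_error(inter_observer_distances(toy_landmarks()[1:3, ]),
               "exactly 2 annotators")
})

test_that("distance summaries report ordered quantiles", {
  s <- summarize_distances(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  expect_true(s$min <= s$median && s$median <= s$q75 &&
                s$q75 <= s$q90 && s$q90 <= s$q99 && s$q99 <= s$max)
  cs <- summarize_distances(rep(2.5, 10))
  expect_true(all(unlist(cs[1, 1:7]) == 2.5))
  set.seed(44)
  su <- summarize_distances(runif(1000))
  expect_lt(abs(su$q90 - 0.9), 0.03)
  expect_error(summarize_distances(numeric(0)), "empty")
})

test_that("Wilcoxon comparison reproduces the exact small-sample null", {
  # n = 6 uniformly signed differences: exact two-sided p = 2/2^6
  a <- c(5, 6, 7, 8, 9, 10)
  b <- a - c(1, 2, 3, 4, 5, 6) * 0.1
  res <- compare_methods(a, b)
  expect_equal(res$p, 0.03125)
  expect_true(res$significant)
  # independent enumeration of all 2^6 sign assignments
  ranks <- rank(abs(a - b))
  vmax <- sum(ranks)
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  vdist <- as.matrix(signs) %*% ranks
  p_enum <- 2 * min(mean(vdist >= res$statistic), mean(vdist <= res$statistic))
  expect_equal(res$p, p_enum)
})

test_that("Wilcoxon comparison handles ties, zeros and identical samples", {
  expect_equal(compare_methods(1:5, 1:5)$p, 1)
  expect_false(compare_methods(1:5, 1:5)$significant)
  # zeros dropped: equivalent to testing only the non-zero pairs
  a <- c(1, 2, 3, 4, 4, 5)
  b <- c(1, 2, 2, 3, 5, 4)
  res <- compare_methods(a, b)
  expect_equal(res$n, 4L)
  # large-sample branch agrees with the standard implementation
  set.seed(55)
  x <- rnorm(60)
  y <- x + rnorm(60, 0.3)
  got <- compare_methods(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(got$p, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("a consistently better method is detected as significant", {
  set.seed(66)
  good <- abs(rnorm(80, 1.5, 0.5))
  degraded <- good + abs(rnorm(80, 1.0, 0.5))
  res <- compare_methods(degraded, good)
  expect_true(res$significant)
})

test_that("bounding-box extents are reported per anatomical axis", {
  lm <- toy_landmarks()[c(1, 3, 5), ]
  lm$fx <- c(0, 0, 0); lm$fy <- c(5, 5, 5); lm$fz <- c(0, 100, 50)
  ext <- landmark_bbox_extents(lm)
  expect_equal(ext$per_group$CC, 100)
  expect_equal(ext$per_group$LR, 0)
  expect_equal(ext$per_group$AP, 0)
  one <- landmark_bbox_extents(toy_landmarks()[1, ])
  expect_true(all(one$per_group[, c("LR", "AP", "CC")] == 0))
  # phantom landmarks live inside the liver ellipsoid
  case <- small_case()
  ext2 <- landmark_bbox_extents(case$landmarks)
  axes <- 2 * case$anatomy$liver_a
  expect_lte(ext2$per_group$LR, axes[1])
  expect_lte(ext2$per_group$AP, axes[2])
  expect_lte(ext2$per_group$CC, axes[3])
})

test_that("NCC snap recovers an exact voxel offset and flags flat boxes", {
  vol <- toy_volume(c(24, 24, 16), seed = 77)
  expect_equal(
    attr(ncc_snap(vol, vol, voxel_to_world(c(12, 12, 8), vol$affine),
                  box = c(8, 8, 8), search_radius_mm = 8), "shift_voxels"),
    c(0, 0, 0), ignore_attr = TRUE)
  # moving = fixed content shifted by (2, 1, 0) voxels
  shift <- c(2L, 1L, 0L)
  mdata <- array(0, vol$dim)
  mdata[(1 + shift[1]):vol$dim[1], (1 + shift[2]):vol$dim[2], ] <-
    vol$data[1:(vol$dim[1] - shift[1]), 1:(vol$dim[2] - shift[2]), ]
  moving <- new_volume(mdata, vol$affine)
  ctr <- c(12, 12, 8)
  refined <- ncc_snap(vol, moving, voxel_to_world(ctr, vol$affine),
                      box = c(8, 8, 8), search_radius_mm = 10)
  expect_equal(attr(refined, "shift_voxels"), -shift, ignore_attr = TRUE)
  expect_equal(as.numeric(refined),
               voxel_to_world(ctr - shift, vol$affine)[1, ],
               ignore_attr = TRUE)
  flat <- new_volume(array(1, vol$dim), vol$affine)
  expect_error(ncc_snap(vol, flat, voxel_to_world(ctr, vol$affine),
                        box = c(8, 8, 8)), "zero-variance")
})
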