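#' Configuration for the synthetic abdominal phantom
#'
#' The phantom emulates a 5-phase hepatic DCE-MRI: an elliptical body cross
#' section containing a liver placed anterior-right and a spleen
#' posterior-left (RAS+ world axes), with a few bright intrahepatic vessels.
#' Tissue intensities follow a phase enhancement table shaped like a
#' hepatobiliary-agent exam: the spleen and vessels peak in the arterial /
#' portal-venous phases while the liver parenchyma enhances monotonically
#' toward the late-venous phase. Each of the four moving phases carries its
#' own breath-hold motion: a global translation (craniocaudally dominant)
#' plus a sum of smooth Gaussian displacement bumps. Two simulated annotators
#' re-locate landmarks with small isotropic type-A noise and, with
#' probability `p_B`, one gross type-B mislabel.
#'
#' @param dim grid size (voxels), default 64 x 64 x 40.
#' @param spacing voxel spacing mm, default 2 x 2 x 3.
#' @param noise_sigma additive Gaussian intensity noise (image units).
#' @param translation_mm max per-axis global translation (z scaled by
#'   `z_scale` to mimic dominant craniocaudal breathing motion).
#' @param z_scale craniocaudal amplification of the global translation.
#' @param bump_amp_mm max per-axis amplitude of each Gaussian motion bump.
#' @param bump_sigma_mm bump width; the worst-case displacement-gradient
#'   bound `sqrt(3) * n_bumps * bump_amp_mm / (bump_sigma_mm * sqrt(e)) <
#'   0.95` (and `bump_amp_mm / bump_sigma_mm < 0.5`) is enforced so
#'   ground-truth maps are fold-free.
#' @param n_bumps Gaussian bumps per moving phase.
#' @param n_landmarks landmarks per image pair (L).
#' @param sigma_A type-A annotator noise sd, mm.
#' @param p_B per-landmark probability of a gross type-B error.
#' @param gross_range_mm magnitude range of type-B offsets, mm.
#' @param p_uncertain probability that a landmark is flagged uncertain.
#' @param n_vessels bright vessel blobs inside the liver.
#' @param n_texture parenchymal texture blobs inside the liver (the
#'   phase-independent inhomogeneity of real liver tissue).
#' @param texture_amp max texture amplitude, image units.
#' @param edge_width_mm width of the smooth tissue boundaries.
#' @param seed RNG seed making the phantom deterministic.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(dim = c(64L, 64L, 40L), spacing = c(2, 2, 3),
                           noise_sigma = 1.5,
                           translation_mm = 6, z_scale = 2,
                           bump_amp_mm = 5, bump_sigma_mm = 25, n_bumps = 2L,
                           n_landmarks = 10L, sigma_A = 1, p_B = 0.03,
                           gross_range_mm = c(10, 20), p_uncertain = 0.05,
                           n_vessels = 8L, n_texture = 40L, texture_amp = 15,
                           edge_width_mm = 3, seed = 1L) {
  cfg <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
              noise_sigma = noise_sigma, translation_mm = translation_mm,
              z_scale = z_scale, bump_amp_mm = bump_amp_mm,
              bump_sigma_mm = bump_sigma_mm, n_bumps = as.integer(n_bumps),
              n_landmarks = as.integer(n_landmarks), sigma_A = sigma_A,
              p_B = p_B, gross_range_mm = gross_range_mm,
              p_uncertain = p_uncertain, n_vessels = as.integer(n_vessels),
              n_texture = as.integer(n_texture), texture_amp = texture_amp,
              edge_width_mm = edge_width_mm, seed = as.integer(seed))
  # enhancement table: additive intensity per tissue and phase
  cfg$enhancement <- rbind(
    body   = c(60, 60, 60, 60, 60),
    liver  = c(30, 40, 55, 65, 80),
    spleen = c(25, 70, 55, 45, 35),
    vessel = c(5, 90, 60, 35, 20))
  colnames(cfg$enhancement) <- c("native", "arterial", "portal-venous",
                                 "equilibrium", "late-venous")
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_landmarks < 1L) stop("need at least one landmark per pair")
  if (cfg$p_B < 0 || cfg$p_B > 1) stop("p_B must be in [0, 1]")
  # fold-free ground truth: a bump a*exp(-r^2/(2 s^2)) has max gradient norm
  # |a|/(s*sqrt(e)); the worst-case sum over bumps must stay below 1
  if (cfg$bump_amp_mm / cfg$bump_sigma_mm >= 0.5)
    stop("bump amplitude / sigma must be < 0.5")
  worst <- sqrt(3) * cfg$bump_amp_mm * cfg$n_bumps /
    (cfg$bump_sigma_mm * sqrt(exp(1)))
  if (worst >= 0.95)
    stop("motion config violates the fold-free bound: worst-case displacement ",
         "gradient ", signif(worst, 3), " must be < 0.95")
  invisible(cfg)
}

# --- analytic anatomy -------------------------------------------------------

# geometry of the phantom organs in world mm, derived from the grid extent.
# Vessels and parenchymal texture blobs give the liver interior the feature
# density of real hepatic anatomy; without them the deformation would be
# unobservable from the images and landmarks would have nothing distinct to
# sit on.
phantom_anatomy <- function(cfg) {
  extent <- (cfg$dim - 1) * cfg$spacing
  ctr <- extent / 2
  liver_c <- ctr + c(0.28, 0.14, -0.04) * extent
  liver_a <- c(0.34, 0.27, 0.30) * extent
  vc <- matrix(runif(3 * cfg$n_vessels, -0.75, 0.75), ncol = 3)
  tex_n <- cfg$n_texture
  tc <- matrix(runif(3 * tex_n, -0.9, 0.9), ncol = 3)
  list(body_c = ctr, body_a = c(0.46, 0.42, 0.60) * extent,
       liver_c = liver_c, liver_a = liver_a,
       spleen_c = ctr + c(-0.30, -0.24, 0.05) * extent,
       spleen_a = c(0.13, 0.11, 0.16) * extent,
       vessel_c = sweep(sweep(vc, 2, liver_a, "*"), 2, liver_c, "+"),
       vessel_r = runif(cfg$n_vessels, 3, 6),
       tex_c = sweep(sweep(tc, 2, liver_a, "*"), 2, liver_c, "+"),
       tex_s = runif(tex_n, 3, 8),
       tex_a = runif(tex_n, -cfg$texture_amp, cfg$texture_amp))
}

# sum of isotropic Gaussian blobs, evaluated only inside each blob's 3-sigma
# box (the blobs are local, so this keeps phantom generation fast)
gaussian_blobs <- function(pts, centers, sigmas, amps) {
  val <- numeric(nrow(pts))
  for (k in seq_len(nrow(centers))) {
    s3 <- 3 * sigmas[k]
    sel <- abs(pts[, 1] - centers[k, 1]) < s3 &
           abs(pts[, 2] - centers[k, 2]) < s3 &
           abs(pts[, 3] - centers[k, 3]) < s3
    if (!any(sel)) next
    r2 <- (pts[sel, 1] - centers[k, 1])^2 + (pts[sel, 2] - centers[k, 2])^2 +
          (pts[sel, 3] - centers[k, 3])^2
    val[sel] <- val[sel] + amps[k] * exp(-r2 / (2 * sigmas[k]^2))
  }
  val
}

# smooth ellipsoid membership in [0, 1]; w = edge width in mm
smooth_inside <- function(pts, center, axes, w) {
  m <- sqrt(((pts[, 1] - center[1]) / axes[1])^2 +
            ((pts[, 2] - center[2]) / axes[2])^2 +
            ((pts[, 3] - center[3]) / axes[3])^2)
  # approximate signed distance to the ellipsoid surface
  d <- (1 - m) * min(axes)
  stats::plogis(d / (w / 4))
}

# phantom intensity at arbitrary world points for one phase (1..5)
phantom_intensity <- function(pts, phase, anatomy, cfg) {
  enh <- cfg$enhancement[, phase]
  w <- cfg$edge_width_mm
  liver_w <- smooth_inside(pts, anatomy$liver_c, anatomy$liver_a, w)
  val <- enh["body"] * smooth_inside(pts, anatomy$body_c, anatomy$body_a, w)
  val <- val + enh["liver"] * liver_w
  val <- val + enh["spleen"] * smooth_inside(pts, anatomy$spleen_c, anatomy$spleen_a, w)
  if (nrow(anatomy$vessel_c))
    val <- val + enh["vessel"] * liver_w *
      gaussian_blobs(pts, anatomy$vessel_c, anatomy$vessel_r / 2,
                     rep(1, nrow(anatomy$vessel_c)))
  # phase-independent parenchymal inhomogeneity, confined to the liver
  if (nrow(anatomy$tex_c))
    val <- val + liver_w * gaussian_blobs(pts, anatomy$tex_c, anatomy$tex_s,
                                          anatomy$tex_a)
  val
}

# --- analytic ground-truth motion ------------------------------------------

# per-phase motion parameters; u(x) = t + sum_k a_k exp(-|x - c_k|^2 / (2 s^2))
phantom_motion <- function(cfg, anatomy) {
  lapply(seq_len(4L), function(p) {
    t <- runif(3, -cfg$translation_mm, cfg$translation_mm) * c(1, 1, cfg$z_scale)
    centers <- matrix(runif(3 * cfg$n_bumps, -0.6, 0.6), ncol = 3)
    centers <- sweep(sweep(centers, 2, anatomy$liver_a, "*"), 2, anatomy$liver_c, "+")
    amps <- matrix(runif(3 * cfg$n_bumps, -cfg$bump_amp_mm, cfg$bump_amp_mm), ncol = 3)
    list(t = t, centers = centers, amps = amps, sigma = cfg$bump_sigma_mm)
  })
}

# evaluate one phase's ground-truth displacement at world points (N x 3 mm)
motion_displacement <- function(motion, pts) {
  u <- matrix(rep(motion$t, each = nrow(pts)), ncol = 3)
  for (k in seq_len(nrow(motion$centers))) {
    r2 <- (pts[, 1] - motion$centers[k, 1])^2 +
          (pts[, 2] - motion$centers[k, 2])^2 +
          (pts[, 3] - motion$centers[k, 3])^2
    g <- exp(-r2 / (2 * motion$sigma^2))
    u <- u + outer(g, motion$amps[k, ])
  }
  u
}

# invert y = x + u(x) for given y by fixed-point iteration (contractive since
# the fold-free bound keeps the displacement gradient well below 1)
invert_motion <- function(motion, pts, tol = 0.05, max_iter = 50L) {
  x <- pts
  for (i in seq_len(max_iter)) {
    xn <- pts - motion_displacement(motion, x)
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  x
}

# --- case generation --------------------------------------------------------

#' Generate one synthetic phantom case
#'
#' Builds a 5-phase series with known per-phase ground-truth motion, the
#' ground-truth liver mask and a two-annotator landmark set. The moving
#' phases are the fixed-phase anatomy (with the phase's own enhancement)
#' observed through the inverse ground-truth map, so a perfect registration
#' of phase p onto the late-venous phase recovers exactly the stored
#' `gt_fields[[p]]`. Deterministic given `cfg$seed`.
#'
#' @param cfg a [phantom_config()].
#' @param case_id case identifier used in the landmark table.
#' @return A `phantom_case` list: `series` (a `dce_series`, fixed phase =
#'   late-venous), `gt_fields` (one `dce_field` per moving phase),
#'   `gt_liver` (binary `dce_volume`), `landmarks` (data frame), `cfg`.
#' @export
generate_phantom_case <- function(cfg = phantom_config(), case_id = "case01") {
  validate_phantom_config(cfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  anatomy <- phantom_anatomy(cfg)
  motions <- phantom_motion(cfg, anatomy)
  geom <- new_volume(array(0, cfg$dim), make_affine(cfg$spacing))
  pts <- grid_world_coords(geom)

  # fixed (late-venous) phase: anatomy sampled directly
  fixed_data <- phantom_intensity(pts, 5L, anatomy, cfg)
  phases <- vector("list", 5L)
  gt_fields <- vector("list", 4L)
  for (p in 1:4) {
    xinv <- invert_motion(motions[[p]], pts)
    mov <- phantom_intensity(xinv, p, anatomy, cfg)
    phases[[p]] <- new_volume(array(mov + rnorm(length(mov), 0, cfg$noise_sigma),
                                    cfg$dim), geom$affine)
    gt_fields[[p]] <- new_field(array(motion_displacement(motions[[p]], pts),
                                      c(cfg$dim, 3L)), geom)
  }
  phases[[5L]] <- new_volume(array(fixed_data +
                                     rnorm(length(fixed_data), 0, cfg$noise_sigma),
                                   cfg$dim), geom$affine)

  m <- sqrt(((pts[, 1] - anatomy$liver_c[1]) / anatomy$liver_a[1])^2 +
            ((pts[, 2] - anatomy$liver_c[2]) / anatomy$liver_a[2])^2 +
            ((pts[, 3] - anatomy$liver_c[3]) / anatomy$liver_a[3])^2)
  gt_liver <- new_volume(array(as.numeric(m <= 1), cfg$dim), geom$affine)

  case <- structure(list(series = dce_series(phases, fixed_index = 5L),
                         gt_fields = gt_fields, gt_liver = gt_liver,
                         motions = motions, anatomy = anatomy,
                         case_id = case_id, cfg = cfg),
                    class = "phantom_case")
  case$landmarks <- sample_landmarks(case, cfg)
  case
}

#' Sample two-annotator landmarks for a phantom case
#'
#' Fixed-image points are drawn from high-gradient voxels inside the
#' ground-truth liver (vessel and capsule neighborhoods, which is where human
#' annotators find distinct structures). Each annotator's moving point is the
#' ground-truth mapped point plus isotropic type-A noise; with probability
#' `p_B` one randomly chosen annotator commits a gross type-B error.
#'
#' @param case a `phantom_case`.
#' @param cfg a [phantom_config()] (controls L, noise and seed).
#' @return Landmark `data.frame` in the [read_landmarks()] layout.
#' @export
sample_landmarks <- function(case, cfg = case$cfg) {
  liv <- case$gt_liver$data > 0
  if (!any(liv)) stop("empty ground-truth liver mask")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed + 7919L)

  fx <- case$series$phases[[case$series$fixed_index]]
  g <- cpp_gradient(as.numeric(fx$data), fx$dim, fx$spacing)
  gm <- sqrt(rowSums(g^2))
  cand <- which(as.vector(liv) & gm >= quantile(gm[as.vector(liv)], 0.6))
  if (length(cand) < cfg$n_landmarks)
    stop("fewer high-gradient liver voxels than requested landmarks")
  pts_all <- grid_world_coords(fx)

  rows <- list()
  for (p in 1:4) {
    idx <- sample(cand, cfg$n_landmarks)
    fpts <- pts_all[idx, , drop = FALSE]
    true_m <- fpts + motion_displacement(case$motions[[p]], fpts)
    for (l in seq_len(cfg$n_landmarks)) {
      unc <- runif(1) < cfg$p_uncertain
      gross_a <- if (runif(1) < cfg$p_B) sample(1:2, 1) else 0L
      for (a in 1:2) {
        mpt <- true_m[l, ] + rnorm(3, 0, cfg$sigma_A)
        if (a == gross_a) {
          dir <- rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          mpt <- mpt + dir * runif(1, cfg$gross_range_mm[1], cfg$gross_range_mm[2])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case$case_id, pair_id = paste0("p", p),
          landmark_id = sprintf("lm%02d", l),
          fx = fpts[l, 1], fy = fpts[l, 2], fz = fpts[l, 3],
          annotator_id = paste0("A", a),
          mx = mpt[1], my = mpt[2], mz = mpt[3],
          uncertain = unc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a batch of phantom cases
#'
#' @param n_cases number of cases (default 26, the dataset shape the
#'   evaluation framework was designed around: 26 cases x 4 pairs).
#' @param cfg base [phantom_config()]; each case gets a seed derived from
#'   `cfg$seed` and its index.
#' @return List of `phantom_case` objects.
#' @export
generate_phantom_batch <- function(n_cases = 26L, cfg = phantom_config()) {
  lapply(seq_len(n_cases), function(i) {
    ci <- cfg
    ci$seed <- as.integer((cfg$seed * 1009L + i * 131L) %% .Machine$integer.max)
    generate_phantom_case(ci, case_id = sprintf("case%02d", i))
  })
}
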