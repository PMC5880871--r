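#' Rigid transform (Euler angles + translation about a center)
#'
#' Maps fixed-domain world points into the moving domain:
#' `T(y) = R (y - center) + center + translation`, with
#' `R = Rz(az) Ry(ay) Rx(ax)` a proper rotation.
#'
#' @param angles rotation angles (rad) about x, y, z.
#' @param translation translation, mm.
#' @param center rotation center, world mm.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to world points
#' @param transform a [rigid_transform()].
#' @param world N x 3 matrix of world mm points.
#' @return N x 3 matrix of transformed points.
#' @export
apply_rigid <- function(transform, world) {
  world <- matrix(world, ncol = 3)
  R <- rotation_matrix(transform$angles)
  sweep(sweep(world, 2, transform$center, "-") %*% t(R), 2,
        transform$center + transform$translation, "+")
}

# resample `moving` through a rigid transform onto `geometry`'s grid:
# out(x) = moving(T(x))
warp_rigid <- function(moving, geometry, transform, fill = 0) {
  w <- apply_rigid(transform, grid_world_coords(geometry))
  v <- world_to_voxel(w, moving$affine)
  s <- cpp_trilinear(as.numeric(moving$data), moving$dim, v, fill, FALSE)
  new_volume(array(s$value, geometry$dim), geometry$affine)
}

# binary mask downsampling: block mean > 0.25 keeps the region generous
downsample_mask <- function(mask, factor) {
  m <- downsample_volume(mask, factor)
  new_volume(array(as.numeric(m$data > 0.25), m$dim), m$affine)
}

# separable 1-2-1 (binomial) smoothing with replicated boundaries. Used on
# both rigid-stage images: without it, any resampling transform smooths the
# image noise and thereby lowers NGF relative to the un-resampled identity,
# biasing the stage away from the identity on already-aligned pairs.
smooth_volume_121 <- function(vol) {
  a <- vol$data
  d <- dim(a)
  if (d[1] > 1) a <- (a[c(1, seq_len(d[1] - 1)), , , drop = FALSE] + 2 * a +
                        a[c(seq_len(d[1] - 1) + 1, d[1]), , , drop = FALSE]) / 4
  if (d[2] > 1) a <- (a[, c(1, seq_len(d[2] - 1)), , drop = FALSE] + 2 * a +
                        a[, c(seq_len(d[2] - 1) + 1, d[2]), , drop = FALSE]) / 4
  if (d[3] > 1) a <- (a[, , c(1, seq_len(d[3] - 1)), drop = FALSE] + 2 * a +
                        a[, , c(seq_len(d[3] - 1) + 1, d[3]), drop = FALSE]) / 4
  new_volume(a, vol$affine)
}

#' Registration solver parameters
#'
#' @param alpha curvature regularization weight (>= 0), applied to the
#'   volume-normalized curvature energy.
#' @param levels multi-resolution depth (coarsest factor `2^(levels-1)`).
#' @param max_iter iteration cap per level.
#' @param grad_tol,step_tol stopping tolerances (projected-gradient norm and
#'   relative objective change).
#' @return A `reg_params` list.
#' @export
reg_params <- function(alpha = 200, levels = 3L, max_iter = 50L,
                       grad_tol = 1e-5, step_tol = 1e-4) {
  if (levels < 1L) stop("levels must be >= 1")
  if (grad_tol <= 0 || step_tol <= 0) stop("tolerances must be positive")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(alpha = alpha, levels = as.integer(levels),
                 max_iter = as.integer(max_iter),
                 grad_tol = grad_tol, step_tol = step_tol),
            class = "reg_params")
}

#' Rigid NGF registration
#'
#' Minimizes the NGF distance between `fixed` and the rigidly transformed
#' `moving` over 6 degrees of freedom (Euler angles and translation about
#' the mask/image centroid), coarse-to-fine over a resolution pyramid, with
#' Nelder-Mead at each level. With `mask`, the distance mean is evaluated
#' over mask voxels only, which focuses the alignment on the liver and makes
#' it robust to substantial variation of liver position within the series.
#'
#' @param fixed,moving `dce_volume`s with overlapping fields of view.
#' @param eta NGF edge parameter.
#' @param mask optional binary `dce_volume` on the fixed grid.
#' @param factors pyramid downsampling factors, coarse to fine. The default
#'   stops at half resolution: the rigid stage only needs to capture the
#'   coarse respiratory-state difference that the deformable stage then
#'   refines.
#' @param max_iter Nelder-Mead iteration cap at the coarsest level (halved at
#'   each finer level).
#' @param improvement_margin minimum relative NGF improvement over the
#'   identity for a transform to be accepted; below it the identity is
#'   returned (the stage targets coarse misalignment only).
#' @return A [rigid_transform()] with attributes `initial_distance` and
#'   `final_distance` (`final <= initial`).
#' @export
register_rigid <- function(fixed, moving, eta = 2, mask = NULL,
                           factors = c(4, 2), max_iter = 400L,
                           improvement_margin = 0.03) {
  sel_full <- if (is.null(mask)) NULL else mask$data > 0
  center <- if (is.null(mask)) colMeans(grid_world_coords(fixed)) else
    colMeans(grid_world_coords(fixed)[as.vector(sel_full), , drop = FALSE])

  par <- rep(0, 6)
  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- smooth_volume_121(smooth_volume_121(
      if (f > 1) downsample_volume(fixed, f) else fixed))
    mv <- smooth_volume_121(smooth_volume_121(
      if (f > 1) downsample_volume(moving, f) else moving))
    mk <- if (is.null(mask)) NULL else if (f > 1) downsample_mask(mask, f) else mask
    ctx <- list(world = grid_world_coords(fx),
                gF = cpp_gradient(as.numeric(fx$data), fx$dim, fx$spacing),
                dim = fx$dim, spacing = fx$spacing,
                mov = as.numeric(mv$data), mov_dim = mv$dim,
                mov_affine = mv$affine,
                sel = if (is.null(mk)) rep(TRUE, prod(fx$dim)) else as.vector(mk$data > 0))
    if (!any(ctx$sel)) stop("mask is empty at pyramid level ", f)
    # freeze the FOV-overlap selection at the level's starting transform so
    # the objective stays continuous during the solve
    tr0 <- rigid_transform(par[1:3], par[4:6], center)
    v0 <- world_to_voxel(apply_rigid(tr0, ctx$world), ctx$mov_affine)
    ctx$sel <- ctx$sel & cpp_trilinear(ctx$mov, ctx$mov_dim, v0, 0, FALSE, TRUE)$inside
    if (!any(ctx$sel)) stop("no field-of-view overlap at pyramid level ", f)
    fn <- function(par) {
      tr <- rigid_transform(par[1:3], par[4:6], center)
      w <- apply_rigid(tr, ctx$world)
      v <- world_to_voxel(w, ctx$mov_affine)
      s <- cpp_trilinear(ctx$mov, ctx$mov_dim, v, 0, FALSE, TRUE)
      gM <- cpp_gradient(s$value, ctx$dim, ctx$spacing)
      val <- cpp_ngf(ctx$gF, gM, eta, ctx$sel, FALSE)$value
      if (!is.finite(val)) stop("rigid optimizer diverged: non-finite objective")
      val
    }
    maxit <- max(50L, as.integer(max_iter / 2^(li - 1)))
    if (li == 1) {
      # translation-only pre-stage stabilizes the coarse solve
      fnt <- function(t3) fn(c(par[1:3], t3))
      optt <- optim(par[4:6], fnt, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-7,
                                   parscale = rep(5, 3)))
      par[4:6] <- optt$par
    }
    opt <- optim(par, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7,
                                parscale = c(rep(0.05, 3), rep(5, 3))))
    # keep the level's result only if it improves on its starting point
    if (opt$value <= fn(par)) par <- opt$par
    final_dist <- fn(par)
  }
  # contract: never worse than the identity (evaluated at the finest level).
  # The preregistration exists to remove coarse respiratory-state
  # differences; a relative improvement margin keeps it from chasing the
  # small distance reductions that any resampling of a well-aligned pair
  # produces, which would displace an already-aligned series.
  ident <- fn(rep(0, 6))
  if (final_dist > ident * (1 - improvement_margin)) {
    par <- rep(0, 6)
    final_dist <- ident
  }
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "initial_distance") <- ident
  attr(out, "final_distance") <- final_dist
  out
}

#' Deformable NGF registration with curvature regularization
#'
#' Minimizes `J[u] = NGF(F, M(x + u)) + alpha * S[u] / V` over a dense
#' displacement field on the fixed grid (discretize-then-optimize), where
#' `S` is the curvature energy and `V` the fixed-domain volume so that
#' `alpha` is grid-independent. The solve is multi-level: the field is
#' estimated on a coarse grid first and trilinearly prolongated to each
#' finer level; each level runs L-BFGS-B with exact analytic gradients. An
#' optional rigid `init` is composed into the moving image before the
#' deformable solve and into the returned field afterwards.
#'
#' @param fixed,moving `dce_volume`s.
#' @param eta NGF edge parameter, > 0.
#' @param reg a [reg_params()].
#' @param init optional [rigid_transform()] preregistration.
#' @return A `dce_field` mapping fixed-domain points into the moving domain
#'   (rigid part composed in), with a `diagnostics` attribute (final `J`,
#'   `D`, `S`, per-level iteration counts).
#' @export
register_deformable <- function(fixed, moving, eta = 2, reg = reg_params(),
                                init = NULL) {
  stopifnot(eta > 0)
  mov_eff <- if (is.null(init)) moving else warp_rigid(moving, fixed, init)

  factors <- 2^((reg$levels:1) - 1)
  u <- NULL
  iters <- integer(0)
  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- if (f > 1) downsample_volume(fixed, f) else fixed
    mv <- if (f > 1) downsample_volume(mov_eff, f) else mov_eff
    if (any(fx$dim < 4L))
      stop("pyramid level grid ", paste(fx$dim, collapse = "x"),
           " is smaller than the solver stencil; reduce levels")
    ctx <- make_deform_context(fx, mv, eta, reg$alpha)
    u0 <- if (is.null(u)) rep(0, 3 * ctx$n) else
      as.numeric(prolongate_field(u, fx))
    ctx <- freeze_selection(ctx, u0)
    cache <- new.env(parent = emptyenv())
    evalf <- function(p) {
      if (!is.null(cache$par) && identical(p, cache$par)) return(cache$res)
      res <- deform_objective(p, ctx)
      if (!is.finite(res$value)) stop("deformable solve diverged: non-finite objective")
      cache$par <- p
      cache$res <- res
      res
    }
    opt <- optim(u0, fn = function(p) evalf(p)$value,
                 gr = function(p) evalf(p)$grad, method = "L-BFGS-B",
                 control = list(maxit = reg$max_iter,
                                factr = reg$step_tol / .Machine$double.eps,
                                pgtol = reg$grad_tol))
    iters <- c(iters, opt$counts[1])
    u <- new_field(array(opt$par, c(fx$dim, 3L)), fx)
    res_level <- evalf(opt$par)
  }
  # contract: J(u) <= J(0) on the finest grid
  ctx <- make_deform_context(fixed, mov_eff, eta, reg$alpha)
  ctx <- freeze_selection(ctx, rep(0, 3 * ctx$n))
  res0 <- deform_objective(rep(0, 3 * ctx$n), ctx)
  resu <- deform_objective(as.numeric(u$u), ctx)
  if (resu$value > res0$value) {
    u <- zero_field(fixed)
    resu <- res0
  }
  out <- if (is.null(init)) u else compose_rigid_into_field(u, init, fixed)
  attr(out, "diagnostics") <- list(J = resu$value, D = resu$D, S = resu$S,
                                   J0 = res0$value, iterations = iters)
  out
}

# trilinear prolongation of a coarse field onto a finer geometry (mm values
# are resolution-independent, so components are interpolated directly)
prolongate_field <- function(field, geometry) {
  w <- grid_world_coords(geometry)
  v <- world_to_voxel(w, field$affine)
  # clamp to the coarse domain so boundary voxels extrapolate constantly
  for (c in 1:3) v[, c] <- pmin(pmax(v[, c], 0), field$dim[c] - 1)
  n <- prod(field$dim)
  uc <- matrix(field$u, nrow = n)
  out <- matrix(0, nrow(v), 3)
  for (c in 1:3)
    out[, c] <- cpp_trilinear(uc[, c], field$dim, v, 0, FALSE)$value
  array(out, c(geometry$dim, 3L))
}

# total map phi(x) = T(x + u_def(x)); returned as displacement on the fixed grid
compose_rigid_into_field <- function(field, transform, fixed) {
  w <- grid_world_coords(fixed)
  n <- prod(fixed$dim)
  phi_def <- w + matrix(field$u, nrow = n)
  phi <- apply_rigid(transform, phi_def)
  new_field(array(phi - w, c(fixed$dim, 3L)), fixed)
}

#' Warp a moving volume through a displacement field
#'
#' Samples `moving` trilinearly at `phi(x) = x + u(x)` for every fixed-grid
#' voxel center.
#'
#' @param moving a `dce_volume`.
#' @param field a `dce_field` on the fixed grid.
#' @param fill out-of-field-of-view value.
#' @return A `dce_volume` on the fixed grid.
#' @export
warp_volume <- function(moving, field, fill = 0) {
  geom <- new_volume(array(0, field$dim), field$affine)
  w <- grid_world_coords(geom)
  n <- prod(field$dim)
  phi <- w + matrix(field$u, nrow = n)
  v <- world_to_voxel(phi, moving$affine)
  s <- cpp_trilinear(as.numeric(moving$data), moving$dim, v, fill, FALSE)
  new_volume(array(s$value, field$dim), field$affine)
}

#' Run the full motion-correction pipeline on a series
#'
#' Registers every earlier phase onto the fixed (late-venous) phase. Three
#' variants: `"FM"` (full method: coarse liver segmentation, mask-restricted
#' rigid preregistration, then deformable registration), `"RMwom"` (rigid
#' preregistration without masking, then deformable), `"RMwop"` (deformable
#' only).
#'
#' @param series a [dce_series()].
#' @param variant `"FM"`, `"RMwom"` or `"RMwop"`.
#' @param eta NGF edge parameter.
#' @param reg a [reg_params()].
#' @param seg_params a [segmentation_params()] (FM only).
#' @return Named list (one entry per moving phase, `"p<i>"`): each with
#'   `field` (total `dce_field`), `warped` (`dce_volume`), `foldings`
#'   (count), `rigid` (or `NULL`) and `diagnostics`.
#' @export
run_motion_correction <- function(series, variant = c("FM", "RMwom", "RMwop"),
                                  eta = 2, reg = reg_params(),
                                  seg_params = segmentation_params()) {
  variant <- match.arg(variant)
  fixed <- series$phases[[series$fixed_index]]
  mask <- if (variant == "FM") segment_liver(series, seg_params) else NULL
  moving_idx <- setdiff(seq_along(series$phases), series$fixed_index)
  results <- list()
  for (p in moving_idx) {
    moving <- series$phases[[p]]
    rigid <- if (variant %in% c("FM", "RMwom"))
      register_rigid(fixed, moving, eta = eta, mask = mask) else NULL
    field <- register_deformable(fixed, moving, eta = eta, reg = reg,
                                 init = rigid)
    fold <- detect_foldings(field)
    results[[paste0("p", p)]] <- list(
      field = field, warped = warp_volume(moving, field),
      foldings = fold$count, rigid = rigid,
      diagnostics = attr(field, "diagnostics"))
  }
  results
}
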