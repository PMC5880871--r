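#' Plan a two-annotator landmark annotation
#'
#' The image pairs are randomly divided into two halves; in phase 1 each
#' annotator defines L landmarks per pair on their half, in phase 2 the
#' halves are swapped and each annotator re-annotates the other annotator's
#' fixed-image landmarks. Every pair is thus annotated by both annotators
#' exactly once each.
#'
#' @param pairs character vector of pair identifiers (>= 2).
#' @param L landmarks per pair.
#' @param annotators two annotator identifiers.
#' @param seed RNG seed for the half-split.
#' @return An `annotation_plan`: `L`, `pairs`, `phase1`, `phase2` (named
#'   lists mapping annotator to pair subset).
#' @export
plan_annotation <- function(pairs, L = 10L, annotators = c("A1", "A2"),
                            seed = 1L) {
  if (length(annotators) != 2L) stop("the scheme needs exactly 2 annotators")
  if (length(pairs) < 2L) stop("need at least 2 pairs")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample(pairs)
  h1 <- sort(perm[seq_len(ceiling(length(pairs) / 2))])
  h2 <- sort(setdiff(pairs, h1))
  phase1 <- setNames(list(h1, h2), annotators)
  phase2 <- setNames(list(h2, h1), annotators)
  structure(list(L = as.integer(L), pairs = pairs, phase1 = phase1,
                 phase2 = phase2),
            class = "annotation_plan")
}

#' Number of pairs required for a target confidence interval
#'
#' `N = ceiling((2 * s_pooled / d)^2)`: the number of (single-annotation)
#' pairs needed so that the 95% confidence interval around the mean landmark
#' distance after registration has half-width `d` mm, given the pooled
#' standard deviation `s_pooled` of the landmark distance after registration.
#'
#' @param s_pooled pooled sd of post-registration landmark distance, mm (> 0).
#' @param d CI half-width, mm (> 0).
#' @return Integer number of pairs.
#' @export
required_pairs <- function(s_pooled, d) {
  if (s_pooled <= 0 || d <= 0) stop("s_pooled and d must be positive")
  as.integer(ceiling(round((2 * s_pooled / d)^2, 9)))
}

#' CI half-width from the mean voxel diagonal
#'
#' The evaluation targets a 95% CI smaller than half the mean voxel
#' diagonal, i.e. a half-width of a quarter of the diagonal.
#'
#' @param voxel_diagonal_mm mean voxel diagonal, mm.
#' @return Half-width `d` in mm.
#' @export
ci_halfwidth <- function(voxel_diagonal_mm) voxel_diagonal_mm / 4

#' Closest-of-two landmark distances
#'
#' For each landmark, the distance between the mapped fixed-image point
#' `phi(fixed)` and the closer of the annotators' moving-image points.
#' Taking the closer annotation compensates for gross type-B errors
#' (annotation of a wrong but similar-looking structure): evaluation is
#' "in doubt for the algorithm". With `field = NULL` the identity map is
#' used (the before-registration case). Uncertain landmarks are dropped.
#'
#' @param landmarks landmark data frame ([read_landmarks()] layout).
#' @param field optional `dce_field`; `phi(fixed)` uses trilinear
#'   interpolation of the displacement.
#' @return Numeric vector of mm distances, one per (case, pair, landmark),
#'   with names `case\rpair\rlandmark`.
#' @export
landmark_distances <- function(landmarks, field = NULL) {
  lm <- drop_uncertain(validate_landmarks(landmarks))
  if (!nrow(lm)) return(numeric(0))
  mapped <- map_points(field, as.matrix(lm[, c("fx", "fy", "fz")]))
  d <- sqrt(rowSums((mapped - as.matrix(lm[, c("mx", "my", "mz")]))^2))
  key <- paste(lm$case_id, lm$pair_id, lm$landmark_id, sep = "\r")
  vapply(split(d, factor(key, levels = unique(key))), min, numeric(1))
}

#' Inter-observer distances
#'
#' Distance between the two annotators' moving-image points for the same
#' landmark; an estimate of the annotation ground-truth quality.
#'
#' @param landmarks landmark data frame with exactly two annotators per
#'   landmark.
#' @param exclude_uncertain drop landmarks flagged uncertain (default TRUE).
#' @return Numeric vector of mm distances, one per landmark.
#' @export
inter_observer_distances <- function(landmarks, exclude_uncertain = TRUE) {
  lm <- validate_landmarks(landmarks)
  if (exclude_uncertain) lm <- drop_uncertain(lm)
  if (!nrow(lm)) return(numeric(0))
  key <- paste(lm$case_id, lm$pair_id, lm$landmark_id, sep = "\r")
  sp <- split(lm, factor(key, levels = unique(key)))
  vapply(sp, function(g) {
    if (nrow(g) != 2L)
      stop("landmark ", g$landmark_id[1], " does not have exactly 2 annotators")
    sqrt(sum((g[1, c("mx", "my", "mz")] - g[2, c("mx", "my", "mz")])^2))
  }, numeric(1))
}

#' Summary statistics of a landmark-distance sample
#'
#' Mean, median, minimum and the 75/90/99/100% quantiles (linear
#' interpolation between order statistics), in mm.
#'
#' @param distances numeric vector of mm distances (n >= 1).
#' @return An `ld_summary` one-row data frame with columns `mean, median,
#'   min, q75, q90, q99, max, n`.
#' @export
summarize_distances <- function(distances) {
  if (!length(distances)) stop("cannot summarize an empty distance sample")
  q <- quantile(distances, c(0.75, 0.90, 0.99), names = FALSE, type = 7)
  out <- data.frame(mean = mean(distances), median = median(distances),
                    min = min(distances), q75 = q[1], q90 = q[2], q99 = q[3],
                    max = max(distances), n = length(distances))
  class(out) <- c("ld_summary", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-landmark distance
#' differences. Zero differences are dropped (Wilcoxon's original
#' treatment); the null distribution is exact for n <= 25 without ties and a
#' normal approximation with continuity correction otherwise. If all
#' differences are zero, `p = 1`.
#'
#' @param distances_a,distances_b paired mm distances, same length and
#'   landmark order.
#' @param alpha significance threshold (default 0.05).
#' @return List with `statistic` (V, sum of positive ranks), `n` (non-zero
#'   pairs), `p` and `significant`.
#' @export
compare_methods <- function(distances_a, distances_b, alpha = 0.05) {
  if (length(distances_a) != length(distances_b))
    stop("paired samples must have the same length")
  d <- distances_a - distances_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, n = 0L, p = 1, significant = FALSE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    p <- 2 * min(psignrank(V, n), psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sig2) # continuity correction
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = V, n = n, p = p, significant = p < alpha)
}

#' Bounding-box extents of fixed-image landmarks
#'
#' World-axis-aligned bounding-box edge lengths of the fixed-image landmark
#' points, per group (by default per case), reported on the anatomical axes
#' (LR = left-right, AP = anterior-posterior, CC = craniocaudal), plus the
#' mean/min/max of each extent across groups.
#'
#' @param landmarks landmark data frame.
#' @param group column to group by (default `"case_id"`).
#' @return List with `per_group` (data frame of LR/AP/CC extents in mm) and
#'   `summary` (mean/min/max per axis).
#' @export
landmark_bbox_extents <- function(landmarks, group = "case_id") {
  lm <- validate_landmarks(landmarks)
  if (!nrow(lm)) stop("empty landmark table")
  sp <- split(lm, lm[[group]])
  per <- do.call(rbind, lapply(sp, function(g) {
    data.frame(group = g[[group]][1],
               LR = diff(range(g$fx)), AP = diff(range(g$fy)),
               CC = diff(range(g$fz)))
  }))
  rownames(per) <- NULL
  sm <- sapply(per[, c("LR", "CC", "AP")],
               function(v) c(mean = mean(v), min = min(v), max = max(v)))
  list(per_group = per, summary = sm)
}

#' NCC snap refinement of a landmark
#'
#' Extracts a small box around a moving-image landmark and finds the
#' integer-voxel translation that maximizes the normalized cross-correlation
#' of the box within the fixed image (the "snap local" aid of landmark
#' annotation tools). Ties are broken by the smallest shift norm, then
#' lexicographically.
#'
#' @param fixed,moving `dce_volume`s on one grid.
#' @param moving_pt world mm point in the moving image.
#' @param box in-plane and through-plane half-extent specification: a
#'   length-3 integer vector of box sizes in voxels (typical in-plane sizes
#'   8/16/32, through-plane 8/16).
#' @param search_radius_mm search window radius in mm.
#' @return The refined fixed-domain world point, with attributes
#'   `shift_voxels` and `ncc`.
#' @export
ncc_snap <- function(fixed, moving, moving_pt, box = c(16L, 16L, 8L),
                     search_radius_mm = 10) {
  if (!identical(fixed$dim, moving$dim)) stop("images must share one grid")
  box <- rep_len(as.integer(box), 3L)
  half <- box %/% 2L
  ctr <- round(world_to_voxel(moving_pt, moving$affine))[1, ] # 0-based
  lo <- ctr - half
  hi <- lo + box - 1L
  if (any(lo < 0) || any(hi > moving$dim - 1L))
    stop("box outside the moving image bounds")
  patch <- moving$data[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L]
  pv <- as.numeric(patch) - mean(patch)
  pn <- sqrt(sum(pv^2))
  if (pn < .Machine$double.eps * length(pv))
    stop("zero-variance box: NCC is undefined, not snapping")
  rad <- pmax(floor(search_radius_mm / fixed$spacing), 0L)
  shifts <- as.matrix(expand.grid(sx = -rad[1]:rad[1], sy = -rad[2]:rad[2],
                                  sz = -rad[3]:rad[3]))
  best <- NULL
  for (s in seq_len(nrow(shifts))) {
    sl <- lo + shifts[s, ]
    sh <- sl + box - 1L
    if (any(sl < 0) || any(sh > fixed$dim - 1L)) next
    w <- fixed$data[(sl[1]:sh[1]) + 1L, (sl[2]:sh[2]) + 1L, (sl[3]:sh[3]) + 1L]
    wv <- as.numeric(w) - mean(w)
    wn <- sqrt(sum(wv^2))
    if (wn < .Machine$double.eps * length(wv)) next
    ncc <- sum(pv * wv) / (pn * wn)
    cand <- list(ncc = ncc, shift = shifts[s, ],
                 norm = sum((shifts[s, ] * fixed$spacing)^2))
    if (is.null(best) || ncc > best$ncc + 1e-12 ||
        (abs(ncc - best$ncc) <= 1e-12 &&
         (cand$norm < best$norm - 1e-12 ||
          (abs(cand$norm - best$norm) <= 1e-12 &&
           paste(cand$shift, collapse = ",") < paste(best$shift, collapse = ","))))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("search window entirely outside the fixed image")
  refined_vox <- ctr + best$shift
  out <- voxel_to_world(refined_vox, fixed$affine)[1, ]
  attr(out, "shift_voxels") <- unname(best$shift)
  attr(out, "ncc") <- best$ncc
  out
}
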