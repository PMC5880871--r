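#' Detect foldings in a displacement field
#'
#' Every grid cell (the box spanned by 8 neighboring voxel centers) is split
#' into eight equally sized tetrahedra, one per cell corner: the corner plus
#' its three edge-adjacent corners (each tetrahedron has volume cell/6). A
#' tetrahedron is folded iff the sign of its signed volume after deforming
#' the corners with `phi(x) = x + u(x)` differs from the undeformed sign, or
#' is zero. A folded tetrahedron means the deformation locally reverses
#' orientation, i.e. non-physical self-overlap of tissue.
#'
#' @param field a `dce_field` with at least 2 nodes per axis.
#' @param max_locations cap on the number of reported fold locations.
#' @return A `folding_report` list: `count`, `total_tetrahedra`
#'   (`= 8 * number of cells`), and `locations` (data frame of cell indices,
#'   0-based, and corner index 0-7).
#' @export
detect_foldings <- function(field, max_locations = 10000L) {
  n <- prod(field$dim)
  u <- matrix(field$u, nrow = n)
  res <- cpp_foldings(u, field$dim, field$affine, as.integer(max_locations))
  loc <- as.data.frame(res$locations)
  names(loc) <- c("cell_i", "cell_j", "cell_k", "corner")
  structure(list(count = res$count, total_tetrahedra = res$total,
                 locations = loc),
            class = "folding_report")
}

#' @export
print.folding_report <- function(x, ...) {
  cat("<folding_report> ", x$count, " folded of ", x$total_tetrahedra,
      " tetrahedra\n", sep = "")
  invisible(x)
}
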