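#' Truncated signed-distance level sets
#'
#' A `cortrec_levelset` wraps a [volume()] whose values are signed Euclidean
#' distances (mm) to a surface: negative inside (below the surface), zero on
#' the boundary, positive outside, clamped to `+/- truncation`.
#'
#' @param vol a [volume()] of signed distances.
#' @param truncation band half-width in mm; values are clamped to this.
#' @return An object of class `cortrec_levelset` with fields `volume`,
#'   `truncation` and `sign` (always `"negative-inside"`).
#' @export
level_set <- function(vol, truncation) {
  stopifnot(inherits(vol, "cortrec_volume"), truncation > 0)
  structure(list(volume = vol, truncation = truncation, sign = "negative-inside"),
            class = "cortrec_levelset")
}

#' @export
print.cortrec_levelset <- function(x, ...) {
  cat(sprintf("<cortrec_levelset> %s voxels, truncation %.3g mm, negative inside\n",
              paste(dim(x$volume$data), collapse = "x"), x$truncation))
  invisible(x)
}

#' Encode a closed mesh as a truncated signed-distance level set
#'
#' Each voxel centre receives the exact Euclidean distance (mm) to the
#' nearest point on the mesh, negated inside the mesh (ray-parity inside
#' test with watertight traversal), clamped to `+/- truncation`. The zero
#' level set of the result embeds the input surface to sub-voxel accuracy.
#'
#' @param mesh a closed, oriented [surface_mesh()].
#' @param grid a [volume()] supplying the target grid and affine (its data
#'   values are ignored).
#' @param truncation band half-width in mm (default 8, wide enough for the
#'   cortical ribbon while keeping regression targets bounded).
#' @return A [level_set()].
#' @export
encode_levelset <- function(mesh, grid, truncation = 8) {
  stopifnot(inherits(mesh, "cortrec_mesh"), inherits(grid, "cortrec_volume"))
  if (!is_edge_manifold(mesh)) {
    stopf("mesh has boundary or non-manifold edges: inside/outside is undefined")
  }
  vidx <- world_to_voxel(grid, mesh$vertices)
  phi <- cpp_signed_distance(mesh$vertices, vidx, mesh$faces,
                             as.integer(dim(grid$data)), grid$affine, truncation)
  level_set(volume(phi, grid$affine), truncation)
}

trilinear_sample <- function(arr, idx, outside = NA_real_) {
  d <- dim(arr)
  i0 <- floor(idx)
  fr <- idx - i0
  out <- rep(outside, nrow(idx))
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  for (c in 1:3) i0[, c] <- pmin(pmax(i0[, c], 0), d[c] - 2)  # upper-face points clamp down
  fr <- idx[ok, , drop = FALSE] - i0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
         (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
         (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
    acc <- acc + w * arr[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  }
  out[ok] <- acc
  out
}

#' Resample a level set onto another grid
#'
#' Trilinear interpolation of the signed-distance values at the target voxel
#' centres; the sign convention is preserved and target voxels falling
#' outside the source domain are set to `+truncation` (outside).
#'
#' @param ls a [level_set()].
#' @param target_grid a [volume()] supplying the target grid and affine.
#' @return A [level_set()] on the target grid.
#' @export
resample_levelset <- function(ls, target_grid) {
  stopifnot(inherits(ls, "cortrec_levelset"), inherits(target_grid, "cortrec_volume"))
  td <- dim(target_grid$data)
  ijk <- as.matrix(expand.grid(i = 0:(td[1] - 1), j = 0:(td[2] - 1), k = 0:(td[3] - 1)))
  world <- voxel_to_world(target_grid, ijk)
  src_idx <- world_to_voxel(ls$volume, world)
  sd <- dim(ls$volume$data)
  inside_src <- src_idx[, 1] >= 0 & src_idx[, 1] <= sd[1] - 1 &
                src_idx[, 2] >= 0 & src_idx[, 2] <= sd[2] - 1 &
                src_idx[, 3] >= 0 & src_idx[, 3] <= sd[3] - 1
  if (!any(inside_src)) stopf("target grid does not overlap the source level set")
  vals <- trilinear_sample(ls$volume$data, src_idx, outside = ls$truncation)
  level_set(volume(array(vals, td), target_grid$affine), ls$truncation)
}

#' Split a binary mask into left and right hemisphere masks
#'
#' Connected components of the mask are grouped into two hemispheres and
#' assigned left/right by their world-x centroids (RAS convention, +x =
#' right). With more than `n_components` components, the largest ones are
#' kept and each smaller component is merged into the nearest kept component
#' by centroid distance (with a warning). Fewer components than requested is
#' an error.
#'
#' @param mask a binary [volume()].
#' @param n_components number of hemispheres expected (default 2).
#' @param connectivity voxel connectivity for component labelling (6 or 26).
#' @return A named list `list(left = , right = )` of binary volumes whose
#'   union equals the input mask.
#' @export
hemisphere_split <- function(mask, n_components = 2, connectivity = 26) {
  stopifnot(inherits(mask, "cortrec_volume"))
  m <- mask$data != 0
  if (!any(m)) stopf("empty mask: no foreground voxels")
  lab <- cpp_components(as.logical(m), as.integer(dim(m)), as.integer(connectivity))
  ncomp <- max(lab)
  if (ncomp < n_components) {
    stopf("mask has %d connected component(s), expected %d", ncomp, n_components)
  }
  d <- dim(m)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1)))
  centroid <- function(l) {
    sel <- lab == l
    colMeans(voxel_to_world(mask, ijk[as.vector(sel), , drop = FALSE]))
  }
  cents <- t(vapply(seq_len(ncomp), centroid, numeric(3)))
  assign <- seq_len(ncomp)
  if (ncomp > n_components) {
    warnf("mask has %d components; merging %d smaller component(s) into the nearest kept ones",
          ncomp, ncomp - n_components)
    # labels are ordered by decreasing size, so components 1..n are kept
    for (l in (n_components + 1):ncomp) {
      dists <- sqrt(rowSums((cents[seq_len(n_components), , drop = FALSE] -
                               matrix(cents[l, ], n_components, 3, byrow = TRUE))^2))
      assign[l] <- which.min(dists)
    }
  }
  kept_x <- vapply(seq_len(n_components), function(l) {
    mean(cents[assign == l, 1])
  }, numeric(1))
  ord <- order(kept_x)  # ascending world x: first is left
  left_label <- ord[1]
  right_label <- ord[length(ord)]
  arr_for <- function(l) {
    lab_v <- as.vector(lab)
    sel <- lab_v > 0 & assign[pmax(lab_v, 1L)] == l
    volume(array(as.numeric(sel), d), mask$affine)
  }
  list(left = arr_for(left_label), right = arr_for(right_label))
}
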