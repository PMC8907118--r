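# Quantitative evaluation of reconstructed surfaces: mesh quality, surface
# displacement, cortical thickness, sulcal depth, parcellation Dice and
# test-retest instability.

#' Triangle mesh quality
#'
#' Per-triangle quality `Q = 4*sqrt(3)*A / (e1^2 + e2^2 + e3^2)` with `A` the
#' triangle area and `e_i` its edge lengths: 1 for an equilateral triangle,
#' 0 for a degenerate (collinear) one. The summary is the unweighted mean
#' over triangles.
#'
#' @param mesh a [surface_mesh()]. Faces with repeated vertices are rejected
#'   by the constructor; numerically collinear faces score 0.
#' @return A list with `q` (per triangle) and `q_mean`.
#' @export
triangle_quality <- function(mesh) {
  stopifnot(inherits(mesh, "cortrec_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- rowSums((v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE])^2)
  e2 <- rowSums((v[f[, 3], , drop = FALSE] - v[f[, 2], , drop = FALSE])^2)
  e3 <- rowSums((v[f[, 1], , drop = FALSE] - v[f[, 3], , drop = FALSE])^2)
  if (any(e1 == 0 | e2 == 0 | e3 == 0)) stopf("zero-length edge in mesh")
  a <- face_geometry(mesh)$area
  q <- 4 * sqrt(3) * a / (e1 + e2 + e3)
  list(q = q, q_mean = mean(q))
}

#' Vertex-to-surface displacement between two meshes
#'
#' For each vertex of `mesh_a`, the Euclidean distance to the closest point
#' on any triangle of `mesh_b` (point-to-surface, not point-to-vertex). With
#' `symmetric = TRUE` the mean of the two per-vertex means is also returned.
#' Both meshes must live in the same world frame.
#'
#' @param mesh_a,mesh_b [surface_mesh()] objects.
#' @param symmetric also evaluate b -> a and report the symmetric mean.
#' @return A numeric per-vertex vector (on `mesh_a`); with
#'   `symmetric = TRUE`, a list with `a_to_b`, `b_to_a` and `symmetric_mean`.
#' @export
surface_displacement <- function(mesh_a, mesh_b, symmetric = FALSE) {
  stopifnot(inherits(mesh_a, "cortrec_mesh"), inherits(mesh_b, "cortrec_mesh"))
  ab <- cpp_closest_on_mesh(mesh_a$vertices, mesh_b$vertices, mesh_b$faces)$dist
  if (!symmetric) return(ab)
  ba <- cpp_closest_on_mesh(mesh_b$vertices, mesh_a$vertices, mesh_a$faces)$dist
  list(a_to_b = ab, b_to_a = ba, symmetric_mean = (mean(ab) + mean(ba)) / 2)
}

#' Cortical thickness between white and pial surfaces
#'
#' Per white-surface vertex, the shortest (point-to-surface) distance to the
#' pial surface; by default the symmetric variant, averaging with the
#' pial-to-white direction resampled onto the white vertices, which is closer
#' to the usual thickness definition. Meshes need not share vertex counts.
#'
#' @param white,pial [surface_mesh()] objects in the same frame.
#' @param symmetric average the two directions (default `TRUE`).
#' @return Per-vertex thickness (mm) on the white surface, non-negative.
#' @export
cortical_thickness <- function(white, pial, symmetric = TRUE) {
  wp <- cpp_closest_on_mesh(white$vertices, pial$vertices, pial$faces)$dist
  if (!symmetric) return(wp)
  pw <- cpp_closest_on_mesh(pial$vertices, white$vertices, white$faces)$dist
  pw_on_white <- map_to_common_space(pw, pial, white)
  (wp + pw_on_white) / 2
}

#' Sulcal depth relative to a smoothed midsurface
#'
#' The hypothetical "midsurface" between gyri and sulci is operationalised
#' as a heavily smoothed copy of the mesh: `smoothing_iters` implicit
#' (backward-Euler) Laplacian steps with cotangent weights and a lumped
#' mass matrix, rescaled about its centroid so the mean signed depth
#' vanishes (the midsurface bisects gyri and sulci by construction). The
#' smoothed copy keeps the input's vertex correspondence, and depth is the
#' per-vertex displacement to the midsurface measured along the midsurface
#' vertex normal: positive when the vertex lies inside the midsurface (a
#' sulcus), negative when outside (a gyrus). `smoothing_iters = 0` makes
#' the midsurface the mesh itself and all depths 0.
#'
#' @param mesh a closed [surface_mesh()].
#' @param smoothing_iters implicit smoothing iterations for the midsurface
#'   (default 50).
#' @return Per-vertex signed depth in mm.
#' @export
sulcal_depth <- function(mesh, smoothing_iters = 50) {
  stopifnot(inherits(mesh, "cortrec_mesh"))
  if (smoothing_iters == 0) return(rep(0, nrow(mesh$vertices)))
  mid <- midsurface(mesh, smoothing_iters)
  signed_depth_to(mesh, mid)
}

# Heavily smoothed, volume-matched copy of a mesh (see sulcal_depth).
midsurface <- function(mesh, iterations) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  e <- mesh_edges(mesh)
  mean_edge <- mean(sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2)))
  tau <- mean_edge^2
  # cotangent Laplacian of the input mesh (clamped, area-free graph form)
  cot_at <- function(a, b, cc) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    pmax(rowSums(u * w) / pmax(sqrt(rowSums(cr^2)), 1e-300), 0)
  }
  ii <- c(f[, 2], f[, 3], f[, 1])
  jj <- c(f[, 3], f[, 1], f[, 2])
  ww <- c(cot_at(f[, 1], f[, 2], f[, 3]),
          cot_at(f[, 2], f[, 3], f[, 1]),
          cot_at(f[, 3], f[, 1], f[, 2])) / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  # implicit mean-curvature-flow step (M + tau K) v_new = M v_old with the
  # lumped mass matrix M (one third of incident face areas) and the stiffness
  # K = D - W; symmetric SPD, factorised once
  areas <- face_geometry(mesh)$area
  mass <- numeric(n)
  for (k in 1:3) {
    mass <- mass + unname(tapply(areas, factor(f[, k], levels = seq_len(n)),
                                 sum, default = 0)) / 3
  }
  mass <- as.numeric(mass)
  mass[mass == 0] <- mean(mass[mass > 0])
  K <- Matrix::Diagonal(n, x = Matrix::rowSums(W)) - W
  S <- Matrix::Diagonal(n, x = mass) + tau * Matrix::forceSymmetric(K)
  ch <- Matrix::Cholesky(S)
  for (it in seq_len(iterations)) {
    v <- as.matrix(Matrix::solve(ch, mass * v))
  }
  mid <- surface_mesh(v, f)
  # calibrate the scale so the mean signed offset to the input vanishes:
  # the midsurface bisects gyri and sulci by construction
  for (pass in 1:3) {
    d <- signed_depth_to(mesh, mid)
    md <- mean(d)
    ctr <- colMeans(mid$vertices)
    r_eff <- mean(sqrt(rowSums(sweep(mid$vertices, 2, ctr)^2)))
    if (abs(md) < 1e-9 * r_eff) break
    mid <- surface_mesh(sweep((1 - md / r_eff) * sweep(mid$vertices, 2, ctr),
                              2, ctr, "+"), f)
  }
  mid
}

# signed per-vertex depth of mesh relative to its smoothed copy `mid`
# (same vertex correspondence): the offset to the midsurface projected onto
# the outward midsurface vertex normal. Positive inside the midsurface
# (sulcal), negative outside (gyral); tangential smoothing drift does not
# contribute.
signed_depth_to <- function(mesh, mid) {
  n <- vertex_normals(mid)
  rowSums(n * (mid$vertices - mesh$vertices))
}

#' Dice coefficient of parcellations
#'
#' Vertex-set overlap `2|A n B| / (|A| + |B|)` per region. Regions absent
#' from both maps are reported as `NA` ("missing"), not 0.
#'
#' @param labels_a,labels_b [label_map()] objects over the same vertices.
#' @param region a single region id, or `NULL` for all regions in either map.
#' @return A named numeric vector of Dice values in `[0, 1]` (or `NA`).
#' @export
dice_coefficient <- function(labels_a, labels_b, region = NULL) {
  stopifnot(inherits(labels_a, "cortrec_labels"), inherits(labels_b, "cortrec_labels"))
  if (length(labels_a$labels) != length(labels_b$labels)) {
    stopf("vertex count mismatch: %d vs %d", length(labels_a$labels), length(labels_b$labels))
  }
  regions <- region %||% sort(union(unique(labels_a$labels), unique(labels_b$labels)))
  out <- vapply(regions, function(r) {
    na <- sum(labels_a$labels == r)
    nb <- sum(labels_b$labels == r)
    if (na + nb == 0) return(NA_real_)
    2 * sum(labels_a$labels == r & labels_b$labels == r) / (na + nb)
  }, numeric(1))
  stats::setNames(out, regions)
}

#' Test-retest instability of per-vertex measures
#'
#' The per-vertex sample standard deviation (n-1 denominator) of a
#' morphometric across repeated sessions. Lower instability means higher
#' test-retest reliability.
#'
#' @param maps list of >= 2 equal-length per-vertex numeric vectors, one per
#'   session.
#' @return Per-vertex standard deviation.
#' @export
instability <- function(maps) {
  if (!is.list(maps) || length(maps) < 2) stopf("need at least 2 session maps")
  len <- lengths(maps)
  if (length(unique(len)) != 1) stopf("session maps differ in length")
  m <- do.call(cbind, maps)
  apply(m, 1, sd)
}

#' Test-retest instability of a parcellation
#'
#' Per-region standard deviation of the session-level Dice coefficients
#' against the session-averaged parcellation (per-vertex majority vote over
#' sessions).
#'
#' @param label_list list of >= 2 [label_map()] objects over the same
#'   vertices.
#' @return Named per-region standard deviations.
#' @export
parcellation_instability <- function(label_list) {
  if (length(label_list) < 2) stopf("need at least 2 session parcellations")
  labs <- vapply(label_list, function(l) l$labels, integer(length(label_list[[1]]$labels)))
  consensus <- apply(labs, 1, function(x) {
    tb <- table(x)
    as.integer(names(tb)[which.max(tb)])
  })
  consensus <- label_map(consensus)
  dice <- lapply(label_list, dice_coefficient, labels_b = consensus)
  regions <- sort(unique(unlist(lapply(dice, names))))
  out <- vapply(regions, function(r) {
    vals <- vapply(dice, function(d) if (r %in% names(d)) d[[r]] else NA_real_, numeric(1))
    sd(vals, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, regions)
}

#' Resample per-vertex values between meshes in a shared frame
#'
#' Each target vertex takes the value at its closest point on the source
#' mesh, barycentrically interpolated within the hit triangle.
#'
#' @param values per-vertex numeric vector on `source`.
#' @param source,target [surface_mesh()] objects in the same world frame.
#' @return Per-vertex values on `target`.
#' @export
map_to_common_space <- function(values, source, target) {
  stopifnot(inherits(source, "cortrec_mesh"), inherits(target, "cortrec_mesh"))
  if (length(values) != nrow(source$vertices)) {
    stopf("values length %d does not match source vertex count %d",
          length(values), nrow(source$vertices))
  }
  hit <- cpp_closest_on_mesh(target$vertices, source$vertices, source$faces)
  f <- source$faces[hit$face, , drop = FALSE]
  rowSums(hit$bary * cbind(values[f[, 1]], values[f[, 2]], values[f[, 3]]))
}
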