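# Shared fixtures: tiny meshes, analytic level sets, phantom configurations,
# and lazily trained tiny networks reused across test files.

# a tetrahedron with non-integer coordinates (avoids voxel-centre degeneracies)
tetra_mesh <- function(offset = c(0.37, 0.21, 0.11), scale = 1) {
  surface_mesh(
    sweep(scale * rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 2, offset, "+"),
    rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

sphere_mesh <- function(radius = 1, centre = c(0, 0, 0), subdivisions = 3) {
  ico <- cortrec:::icosphere(subdivisions)
  surface_mesh(sweep(radius * ico$vertices, 2, centre, "+"), ico$faces)
}

# centred grid volume: n^3 voxels of size h, world origin at the grid centre
grid_volume <- function(n = 32, h = 1) {
  aff <- rbind(cbind(diag(h, 3), -(n - 1) / 2 * h), c(0, 0, 0, 1))
  volume(array(0, c(n, n, n)), aff)
}

# analytic signed-distance level set of a sphere on a centred grid
sphere_levelset <- function(radius, n = 28, h = 1, truncation = 8) {
  g <- grid_volume(n, h)
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  w <- t(g$affine %*% rbind(t(idx), 1))[, 1:3]
  phi <- sqrt(rowSums(w^2)) - radius
  level_set(volume(array(pmin(pmax(phi, -truncation), truncation), c(n, n, n)),
                   g$affine), truncation)
}

# study conditions for the learning-path checks: 1 mm single-hemisphere
# regression phantoms and 2 mm two-hemisphere segmentation phantoms
reg_phantom_params <- function() {
  phantom_params(grid_shape = c(32, 32, 32), voxel_size = 1, base_radius = 8,
                 fold_amplitude = 1.6, fold_degree = 6,
                 cortical_thickness_true = 2.4, noise_sd = 5,
                 bias_field_amplitude = 0.05, n_hemispheres = 1)
}

seg_phantom_params <- function() {
  phantom_params(grid_shape = c(48, 32, 32), voxel_size = 2, base_radius = 9,
                 fold_amplitude = 1.8, fold_degree = 4,
                 cortical_thickness_true = 2.5, noise_sd = 5,
                 bias_field_amplitude = 0.05, n_hemispheres = 2)
}

reg_sample <- function(seed, params = reg_phantom_params()) {
  ph <- generate_phantom(params, seed)
  img <- normalize_intensity(ph$image)$data
  mask <- as.numeric(ph$tissue_labels$data == 2)
  list(input = array(c(img, mask), c(dim(img), 2)),
       target = ph$white_levelset$lh$volume$data / params$truncation,
       phantom = ph)
}

seg_sample <- function(seed, params = seg_phantom_params()) {
  ph <- generate_phantom(params, seed)
  img <- normalize_intensity(ph$image)$data
  cls <- array(1L, dim(img))
  cls[ph$tissue_labels$data == 2] <- 2L
  cls[ph$tissue_labels$data == 4] <- 3L
  list(input = array(img, c(dim(img), 1)), target = cls, phantom = ph)
}

# 2 mm per-hemisphere regression samples (same frame as the segmentation
# phantoms), for the end-to-end pipeline
reg2_sample <- function(seed, params = seg_phantom_params()) {
  ph <- generate_phantom(params, seed)
  img <- normalize_intensity(ph$image)$data
  out <- list()
  for (h in c("lh", "rh")) {
    wm_code <- if (h == "lh") 2L else 4L
    mask <- as.numeric(ph$tissue_labels$data == wm_code)
    out[[h]] <- list(input = array(c(img, mask), c(dim(img), 2)),
                     target = ph$white_levelset[[h]]$volume$data / params$truncation)
  }
  out
}

# Trained tiny models are expensive; train once per session and cache.
.model_cache <- new.env(parent = emptyenv())

trained_reg_model <- function() {
  if (is.null(.model_cache$reg)) {
    ds <- lapply(1:16, reg_sample)
    net <- build_network(net_config(3, 8, in_channels = 2, out_channels = 1,
                                    patch_size = c(32, 32, 32), head = "regression",
                                    head_bias = 1),
                         seed = 1)
    .model_cache$reg <- train_network(net, ds,
      train_config(batch_size = 2, max_epochs = 35, convergence_window = 35, seed = 1))
  }
  .model_cache$reg
}

trained_seg_model <- function() {
  if (is.null(.model_cache$seg)) {
    ds <- lapply(1:16, seg_sample)
    net <- build_network(net_config(4, 8, in_channels = 1, out_channels = 3,
                                    patch_size = c(48, 32, 32), head = "segmentation"),
                         seed = 1)
    .model_cache$seg <- train_network(net, ds,
      train_config(batch_size = 2, max_epochs = 20, convergence_window = 20, seed = 1,
                   class_weights = c(1, 20, 20)))
  }
  .model_cache$seg
}

trained_reg2_model <- function() {
  if (is.null(.model_cache$reg2)) {
    ds <- unlist(lapply(1:16, reg2_sample), recursive = FALSE)  # 32 hemisphere tasks
    net <- build_network(net_config(3, 8, in_channels = 2, out_channels = 1,
                                    patch_size = c(48, 32, 32), head = "regression",
                                    head_bias = 1),
                         seed = 1)
    .model_cache$reg2 <- train_network(net, ds,
      train_config(batch_size = 2, max_epochs = 15, convergence_window = 15, seed = 1))
  }
  .model_cache$reg2
}

# Independent simple-point oracle: rebuild the Freudenthal link of a voxel
# from first principles (enumerate the tetrahedra of the 8 incident cubes),
# and test whether the full link subcomplexes spanned by foreground and
# background are both nonempty, connected disks (Euler characteristic 1).
r_simple_point <- function(mask, dims, v) {  # v is a 0-based voxel index
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tets_in_cube <- lapply(perms, function(p) {
    c1 <- c(0, 0, 0); c1[p[1]] <- 1
    c2 <- c1; c2[p[2]] <- 1
    rbind(c(0, 0, 0), c1, c2, c(1, 1, 1))
  })
  link_tris <- list()
  for (mx in -1:0) for (my in -1:0) for (mz in -1:0) {
    for (tet in tets_in_cube) {
      corners <- sweep(tet, 2, v + c(mx, my, mz), "+")
      hit <- which(corners[, 1] == v[1] & corners[, 2] == v[2] & corners[, 3] == v[3])
      if (length(hit) == 1) {
        link_tris[[length(link_tris) + 1]] <- corners[-hit, , drop = FALSE]
      }
    }
  }
  allv <- do.call(rbind, link_tris)
  key <- apply(allv, 1, paste, collapse = ",")
  verts <- allv[!duplicated(key), , drop = FALSE]
  vid <- stats::setNames(seq_len(nrow(verts)), key[!duplicated(key)])
  tris <- t(vapply(link_tris, function(tr) {
    sort(unname(vid[apply(tr, 1, paste, collapse = ",")]))
  }, integer(3)))
  tris <- tris[!duplicated(tris), , drop = FALSE]
  edges <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  edges <- edges[!duplicated(edges), , drop = FALSE]
  in_fg <- apply(verts, 1, function(p) {
    all(p >= 0 & p < dims) && mask[p[1] + 1, p[2] + 1, p[3] + 1]
  })
  disk <- function(sel) {
    if (!any(sel)) return(FALSE)
    ids <- which(sel)
    E <- edges[sel[edges[, 1]] & sel[edges[, 2]], , drop = FALSE]
    TT <- tris[sel[tris[, 1]] & sel[tris[, 2]] & sel[tris[, 3]], , drop = FALSE]
    g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    if (nrow(E) > 0) {
      g <- igraph::add_edges(g, as.vector(t(matrix(match(as.vector(E), ids),
                                                   ncol = 2))))
    }
    if (igraph::components(g)$no != 1) return(FALSE)
    (length(ids) - nrow(E) + nrow(TT)) == 1
  }
  disk(in_fg) && disk(!in_fg)
}

# independent point-to-triangle distance for oracle comparisons: project onto
# the triangle plane, fall back to the three edge segments
oracle_point_tri_dist <- function(p, a, b, cc) {
  n <- pracma_cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                                        u[3] * v[1] - u[1] * v[3],
                                        u[1] * v[2] - u[2] * v[1])
  nrm <- pracma_cross(b - a, cc - a)
  seg_dist <- function(p, u, v) {
    t <- sum((p - u) * (v - u)) / sum((v - u)^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * (v - u)))^2))
  }
  n2 <- sum(nrm^2)
  if (n2 > 0) {
    q <- p - nrm * sum((p - a) * nrm) / n2
    # barycentric test of the projection
    v0 <- b - a; v1 <- cc - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) return(sqrt(sum((p - q)^2)))
  }
  min(seg_dist(p, a, b), seg_dist(p, b, cc), seg_dist(p, cc, a))
}

oracle_closest_dist <- function(p, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(f) {
    oracle_point_tri_dist(p, mesh$vertices[mesh$faces[f, 1], ],
                          mesh$vertices[mesh$faces[f, 2], ],
                          mesh$vertices[mesh$faces[f, 3], ])
  }, numeric(1)))
}

# independent inside test: Moller-Trumbore ray casting along +x
oracle_inside <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  hits <- 0L
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    e1 <- b - a; e2 <- cc - a
    dirv <- c(1, 0, 0)
    h <- c(dirv[2] * e2[3] - dirv[3] * e2[2],
           dirv[3] * e2[1] - dirv[1] * e2[3],
           dirv[1] * e2[2] - dirv[2] * e2[1])
    det <- sum(e1 * h)
    if (abs(det) < 1e-14) next
    s <- p - a
    u <- sum(s * h) / det
    if (u < 0 || u > 1) next
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    vv <- sum(dirv * q) / det
    if (vv < 0 || u + vv > 1) next
    t <- sum(e2 * q) / det
    if (t > 0) hits <- hits + 1L
  }
  hits %% 2L == 1L
}
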