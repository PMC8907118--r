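test_that("sphere level set has the analytic centre value and zero at vertices", {
  sph <- sphere_mesh(radius = 10, centre = c(0.3, 0.1, 0.2), subdivisions = 3)
  g <- grid_volume(27, 1)  # odd: voxel centres on integer world coordinates
  ls <- encode_levelset(sph, g, truncation = 12)
  ctr <- round(world_idx <- solve(g$affine) %*% c(0.3, 0.1, 0.2, 1))[1:3]
  cval <- ls$volume$data[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1]
  expect_lt(abs(cval - (-10)), 0.5)
  # a voxel centre placed exactly on a mesh vertex gets distance 0
  vtx <- sph$vertices[1, ]
  g2 <- volume(array(0, c(5, 5, 5)),
               rbind(cbind(diag(3), vtx - 2), c(0, 0, 0, 1)))
  ls2 <- encode_levelset(sph, g2, truncation = 12)
  expect_lt(abs(ls2$volume$data[3, 3, 3]), 1e-9)
})

test_that("encoding matches a brute-force distance and inside-test oracle", {
  set.seed(42)
  ico <- cortrec:::icosphere(2)
  r <- 6 * (1 + 0.25 * sin(3 * ico$vertices[, 1]) * cos(2 * ico$vertices[, 2]))
  mesh <- surface_mesh(ico$vertices * r, ico$faces)
  g <- grid_volume(20, 1)
  trunc <- 6
  ls <- encode_levelset(mesh, g, truncation = trunc)
  idx <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  pick <- sample(nrow(idx), 150)
  for (row in pick) {
    ijk <- idx[row, ]
    p <- (g$affine %*% c(ijk, 1))[1:3]
    d <- oracle_closest_dist(p, mesh)
    s <- if (oracle_inside(p, mesh)) -1 else 1
    expected <- s * min(d, trunc)
    expect_lt(abs(ls$volume$data[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] - expected), 1e-6)
  }
})

test_that("open meshes cannot be encoded", {
  tet <- tetra_mesh()
  open <- surface_mesh(tet$vertices, tet$faces[-1, ])
  expect_error(encode_levelset(open, grid_volume(8)), "boundary|manifold")
})

test_that("level-set gradient magnitude is ~1 inside the band", {
  ph <- generate_phantom(phantom_params(noise_sd = 0, bias_field_amplitude = 0), seed = 5)
  ls <- ph$white_levelset$lh
  phi <- ls$volume$data
  h <- voxel_size(ls$volume)
  gx <- (phi[3:48, , ] - phi[1:46, , ]) / (2 * h[1])
  gy <- (phi[, 3:48, ] - phi[, 1:46, ]) / (2 * h[2])
  gz <- (phi[, , 3:48] - phi[, , 1:46]) / (2 * h[3])
  gm <- sqrt(gx[, 2:47, 2:47]^2 + gy[2:47, , 2:47]^2 + gz[2:47, 2:47, ]^2)
  band <- abs(phi[2:47, 2:47, 2:47]) < ls$truncation - max(h)
  frac_ok <- mean(gm[band] >= 0.8 & gm[band] <= 1.2)
  expect_gte(frac_ok, 0.99)
})

test_that("resampling: identity, planar exactness, down/up RMS error", {
  ls <- sphere_levelset(radius = 8, n = 24, h = 1, truncation = 6)
  id <- resample_levelset(ls, ls$volume)
  expect_equal(id$volume$data, ls$volume$data, tolerance = 1e-12)
  # planar level set phi = z - c stays exactly planar under 2x upsampling
  g <- grid_volume(12, 1)
  idx <- as.matrix(expand.grid(0:11, 0:11, 0:11))
  w <- t(g$affine %*% rbind(t(idx), 1))[, 1:3]
  plane <- level_set(volume(array(w[, 3] - 1.3, c(12, 12, 12)), g$affine), 20)
  fine <- grid_volume(23, 0.5)
  up <- resample_levelset(plane, fine)
  widx <- as.matrix(expand.grid(0:22, 0:22, 0:22))
  wup <- t(fine$affine %*% rbind(t(widx), 1))[, 1:3]
  expect_lt(max(abs(as.vector(up$volume$data) - (wup[, 3] - 1.3))), 1e-10)
  # sphere: downsample then upsample, RMS error inside band < h/2
  coarse <- grid_volume(12, 2)
  down <- resample_levelset(ls, coarse)
  back <- resample_levelset(down, ls$volume)
  band <- abs(ls$volume$data) < 4
  rms <- sqrt(mean((back$volume$data[band] - ls$volume$data[band])^2))
  expect_lt(rms, 0.5)
  # disjoint grids error
  far <- volume(array(0, c(8, 8, 8)),
                rbind(cbind(diag(3), c(500, 500, 500)), c(0, 0, 0, 1)))
  expect_error(resample_levelset(ls, far), "overlap")
})

test_that("translation of the grid affine translates the zero crossing exactly", {
  ls <- sphere_levelset(radius = 7, n = 20, h = 1)
  s1 <- extract_surface(ls, correct = FALSE)
  t <- c(3.5, -1.25, 0.75)
  aff2 <- ls$volume$affine
  aff2[1:3, 4] <- aff2[1:3, 4] + t
  ls2 <- level_set(volume(ls$volume$data, aff2), ls$truncation)
  s2 <- extract_surface(ls2, correct = FALSE)
  expect_equal(s2$vertices, sweep(s1$vertices, 2, t, "+"), tolerance = 1e-12)
})

test_that("sign flip yields the same surface with inverted orientation", {
  ls <- sphere_levelset(radius = 7, n = 20, h = 1)
  s1 <- extract_surface(ls, correct = FALSE)
  lsf <- level_set(volume(-ls$volume$data, ls$volume$affine), ls$truncation)
  s2 <- extract_surface(lsf, correct = FALSE)
  # identical vertex sets (creation order may differ)
  key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = "/"))
  expect_identical(key(s2$vertices), key(s1$vertices))
  expect_gt(mesh_volume(s1), 0)
  expect_lt(mesh_volume(s2), 0)
})

test_that("hemisphere_split assigns left/right by world-x centroid", {
  g <- grid_volume(40, 1.5)
  idx <- as.matrix(expand.grid(0:39, 0:39, 0:39))
  w <- t(g$affine %*% rbind(t(idx), 1))[, 1:3]
  m <- array(0, c(40, 40, 40))
  m[sqrt(rowSums(sweep(w, 2, c(-20, 0, 0))^2)) < 8] <- 1
  m[sqrt(rowSums(sweep(w, 2, c(20, 0, 0))^2)) < 8] <- 1
  split <- hemisphere_split(volume(m, g$affine))
  expect_true(all(split$left$data + split$right$data == m))
  lw <- w[as.vector(split$left$data) > 0, ]
  rw <- w[as.vector(split$right$data) > 0, ]
  expect_lt(mean(lw[, 1]), 0)
  expect_gt(mean(rw[, 1]), 0)
  expect_error(hemisphere_split(volume(array(0, c(8, 8, 8)), diag(4))), "empty")
  # single blob: fewer components than requested
  m1 <- array(0, c(40, 40, 40))
  m1[18:22, 18:22, 18:22] <- 1
  expect_error(hemisphere_split(volume(m1, g$affine)), "1 connected component")
  # three blobs: two largest kept, smallest merged with a warning
  m3 <- m
  m3[1:2, 1:2, 1:2] <- 1
  expect_warning(s3 <- hemisphere_split(volume(m3, g$affine)), "merging")
  expect_equal(sum(s3$left$data) + sum(s3$right$data), sum(m3))
})
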