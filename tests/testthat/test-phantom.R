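test_that("zero fold amplitude gives an exact sphere", {
  p <- phantom_params(grid_shape = c(40, 40, 40), base_radius = 12, fold_amplitude = 0,
                      noise_sd = 0, bias_field_amplitude = 0)
  ph <- generate_phantom(p, seed = 3)
  r <- sqrt(rowSums(ph$white_mesh$lh$vertices^2))
  expect_lt(max(abs(r - 12)), 0.5 * p$voxel_size)
})

test_that("noiseless, bias-free, non-partial-volume images are piecewise constant", {
  p <- phantom_params(grid_shape = c(36, 36, 36), base_radius = 10, fold_amplitude = 2,
                      noise_sd = 0, bias_field_amplitude = 0, partial_volume = FALSE)
  ph <- generate_phantom(p, seed = 4)
  expect_true(all(ph$image$data %in% p$intensity_means))
})

test_that("the same seed reproduces a bit-identical phantom", {
  p <- phantom_params(grid_shape = c(36, 36, 36), base_radius = 10, fold_amplitude = 2)
  a <- generate_phantom(p, seed = 11)
  b <- generate_phantom(p, seed = 11)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$white_mesh$lh$vertices, b$white_mesh$lh$vertices)
  expect_identical(a$white_levelset$lh$volume$data, b$white_levelset$lh$volume$data)
  c <- generate_phantom(p, seed = 12)
  expect_false(identical(a$image$data, c$image$data))
})

test_that("parameter invariants are enforced", {
  expect_error(phantom_params(base_radius = 4, fold_amplitude = 2.5), "fold_amplitude")
  expect_error(phantom_params(voxel_size = 3, cortical_thickness_true = 2.5),
               "thickness")
  expect_error(generate_phantom(phantom_params(grid_shape = c(20, 20, 20)), 1),
               "grid too small")
})

test_that("white level set evaluated at pial vertices recovers the true thickness", {
  p <- phantom_params(grid_shape = c(42, 42, 42), base_radius = 11, fold_amplitude = 2.5,
                      cortical_thickness_true = 2.5, noise_sd = 0)
  ph <- generate_phantom(p, seed = 6)
  pial_v <- ph$pial_mesh$lh$vertices
  idx <- cortrec:::world_to_voxel(ph$white_levelset$lh$volume, pial_v)
  vals <- cortrec:::trilinear_sample(ph$white_levelset$lh$volume$data, idx)
  expect_lt(max(abs(vals - 2.5)), 1.5 * p$voxel_size)
  # every white vertex lies strictly inside the pial surface
  widx <- cortrec:::world_to_voxel(ph$pial_levelset$lh$volume, ph$white_mesh$lh$vertices)
  wvals <- cortrec:::trilinear_sample(ph$pial_levelset$lh$volume$data, widx)
  expect_true(all(wvals < 0))
})

test_that("WM voxel volume approximates the white-mesh enclosed volume", {
  p <- phantom_params(grid_shape = c(66, 66, 66), voxel_size = 0.5, base_radius = 10,
                      fold_amplitude = 2, cortical_thickness_true = 2.5,
                      noise_sd = 0, bias_field_amplitude = 0)
  ph <- generate_phantom(p, seed = 8)
  vox_vol <- sum(ph$tissue_labels$data == 2) * prod(voxel_size(ph$tissue_labels))
  mesh_vol <- mesh_volume(ph$white_mesh$lh)
  expect_lt(abs(vox_vol - mesh_vol) / mesh_vol, 0.05)
})

test_that("two-hemisphere phantoms are disjoint and tagged left/right", {
  ph <- generate_phantom(seg_phantom_params(), seed = 2)
  expect_named(ph$white_mesh, c("lh", "rh"))
  expect_lt(max(ph$white_mesh$lh$vertices[, 1]), min(ph$white_mesh$rh$vertices[, 1]))
  lab <- ph$tissue_labels$data
  expect_setequal(unique(as.vector(lab)), c(0, 1, 2, 3, 4))
  split <- hemisphere_split(volume(array(as.numeric(lab %in% c(2, 4)), dim(lab)),
                                   ph$tissue_labels$affine))
  expect_true(all(split$left$data[lab == 2] == 1))
  expect_true(all(split$right$data[lab == 4] == 1))
})

test_that("sessions share ground truth and differ only by noise realisation", {
  p <- phantom_params(grid_shape = c(32, 32, 32), base_radius = 8, fold_amplitude = 1.6,
                      cortical_thickness_true = 2.4, bias_field_amplitude = 0)
  expect_error(phantom_sessions(p, 1, n_sessions = 1), "n_sessions")
  s0 <- phantom_sessions(p, seed = 3, n_sessions = 3, session_noise_sd = 0)
  expect_identical(s0[[1]]$image$data, s0[[2]]$image$data)
  expect_identical(s0[[1]]$white_mesh$lh, s0[[3]]$white_mesh$lh)
  sN <- phantom_sessions(p, seed = 3, n_sessions = 3, session_noise_sd = 4)
  expect_identical(sN[[1]]$white_levelset$lh$volume$data,
                   sN[[2]]$white_levelset$lh$volume$data)
  expect_false(identical(sN[[1]]$image$data, sN[[2]]$image$data))
  # ground-truth thickness instability across sessions is exactly zero
  th <- lapply(sN, function(ph) cortical_thickness(ph$white_mesh$lh, ph$pial_mesh$lh))
  expect_true(all(instability(th) == 0))
})

test_that("session noise monotonically increases reconstructed-thickness instability", {
  # model-free session reconstruction: white/pial surfaces extracted from the
  # intensity field thresholded midway between tissue means
  p <- phantom_params(grid_shape = c(32, 32, 32), base_radius = 8, fold_amplitude = 1.6,
                      cortical_thickness_true = 2.4, bias_field_amplitude = 0)
  recon_instab <- function(noise_sd, seed) {
    sess <- phantom_sessions(p, seed, n_sessions = 3, session_noise_sd = noise_sd)
    truth_white <- sess[[1]]$white_mesh$lh
    th <- lapply(sess, function(ph) {
      img <- ph$image$data
      white_f <- (p$intensity_means[2] + p$intensity_means[3]) / 2 - img
      pial_f <- (p$intensity_means[1] + p$intensity_means[2]) / 2 - img
      w <- extract_surface(level_set(volume(white_f, ph$image$affine), 100))
      pl <- extract_surface(level_set(volume(pial_f, ph$image$affine), 100))
      d <- cortical_thickness(w, pl, symmetric = FALSE)
      map_to_common_space(d, w, truth_white)
    })
    mean(instability(th))
  }
  levels <- c(1, 5, 12)
  means <- vapply(levels, function(ns) {
    mean(vapply(1:5, function(sd) recon_instab(ns, sd), numeric(1)))
  }, numeric(1))
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
})

test_that("geodesic parcellations are complete, contiguous and deterministic", {
  sph <- sphere_mesh(radius = 10, subdivisions = 3)
  one <- phantom_parcellation(sph, n_regions = 1)
  expect_true(all(one$labels == 1L))
  par <- phantom_parcellation(sph, n_regions = 34, seed = 5)
  expect_equal(length(par$labels), nrow(sph$vertices))
  expect_equal(sort(unique(par$labels)), 1:34)
  expect_true(all(table(par$labels) > 0))
  d <- dice_coefficient(par, par)
  expect_true(all(d == 1))
  par2 <- phantom_parcellation(sph, n_regions = 34, seed = 5)
  expect_identical(par$labels, par2$labels)
  # disconnected mesh errors
  two <- surface_mesh(rbind(sph$vertices, sph$vertices + 50),
                      rbind(sph$faces, sph$faces + nrow(sph$vertices)))
  expect_error(phantom_parcellation(two, 4), "disconnected")
  expect_error(phantom_parcellation(sph, nrow(sph$vertices) + 1), "exceeds")
})
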