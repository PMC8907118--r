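test_that("triangle quality matches the analytic cases", {
  equi <- surface_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 3 * sqrt(3) / 2, 0),
                             c(1.5, sqrt(3) / 2, 2)),
                       rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4)))
  q <- triangle_quality(equi)$q
  expect_equal(q[1], 1, tolerance = 1e-12)
  # collinear triangle degenerates to Q = 0
  collin <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0)),
                         rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_equal(triangle_quality(collin)$q[1], 0)
  # right triangle with legs 1,1: Q = sqrt(3)/2
  right <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                        rbind(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_equal(triangle_quality(right)$q[1], sqrt(3) / 2, tolerance = 1e-12)
  # mean is the unweighted mean
  expect_equal(triangle_quality(equi)$q_mean, mean(q))
})

test_that("Q is invariant under rigid motion and uniform scaling", {
  m <- sphere_mesh(radius = 3, subdivisions = 2)
  q0 <- triangle_quality(m)$q
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- surface_mesh(sweep(5.3 * m$vertices %*% t(R), 2, c(4, -2, 9), "+"), m$faces)
  expect_equal(triangle_quality(m2)$q, q0, tolerance = 1e-9)
})

test_that("surface displacement: zero on identity, closed form on spheres", {
  m <- sphere_mesh(radius = 10, subdivisions = 3)
  expect_true(all(surface_displacement(m, m) == 0))
  outer_m <- sphere_mesh(radius = 12, subdivisions = 3)
  d <- surface_displacement(outer_m, m)
  expect_lt(abs(mean(d) - 2), 0.1)
  sym <- surface_displacement(outer_m, m, symmetric = TRUE)
  expect_lt(abs(sym$symmetric_mean - 2), 0.12)
})

test_that("accelerated closest-point queries match a brute-force oracle", {
  set.seed(31)
  m <- sphere_mesh(radius = 4, subdivisions = 1)  # 80 faces
  pts <- matrix(runif(3 * 25, -6, 6), ncol = 3)
  fast <- cortrec:::cpp_closest_on_mesh(pts, m$vertices, m$faces)$dist
  slow <- apply(pts, 1, oracle_closest_dist, mesh = m)
  expect_lt(max(abs(fast - slow)), 1e-9)
})

test_that("displacement obeys the triangle-type inequality on phantom trios", {
  p <- phantom_params(grid_shape = c(32, 32, 32), base_radius = 8, fold_amplitude = 1.6,
                      cortical_thickness_true = 2.4)
  a <- generate_phantom(p, 21)$white_mesh$lh
  b <- generate_phantom(p, 22)$white_mesh$lh
  cm <- generate_phantom(p, 23)$white_mesh$lh
  ac <- mean(surface_displacement(a, cm))
  ab <- mean(surface_displacement(a, b))
  bc <- max(surface_displacement(b, cm))
  expect_lte(ac, ab + bc + 1e-9)
})

test_that("cortical thickness recovers phantom ground truth", {
  p <- phantom_params(grid_shape = c(42, 42, 42), base_radius = 11,
                      fold_amplitude = 2.5, cortical_thickness_true = 2.5)
  ph <- generate_phantom(p, seed = 13)
  th <- cortical_thickness(ph$white_mesh$lh, ph$pial_mesh$lh)
  expect_lt(abs(mean(th) - 2.5), 0.2)
  expect_true(all(th >= 0))
  # white == pial: zero everywhere
  expect_true(all(cortical_thickness(ph$white_mesh$lh, ph$white_mesh$lh) == 0))
  # scale equivariance
  dbl <- function(m) surface_mesh(2 * m$vertices, m$faces)
  th2 <- cortical_thickness(dbl(ph$white_mesh$lh), dbl(ph$pial_mesh$lh))
  expect_equal(th2, 2 * th, tolerance = 1e-9)
})

test_that("sulcal depth vanishes on a sphere and tracks fold amplitude", {
  sph <- sphere_mesh(radius = 10, subdivisions = 4)
  expect_true(all(sulcal_depth(sph, 0) == 0))
  d <- sulcal_depth(sph, 50)
  expect_lt(max(abs(d)), 1e-3 * 10)
  for (seed in 1:5) {
    p <- phantom_params(grid_shape = c(42, 42, 42), base_radius = 11,
                        fold_amplitude = 2.5, fold_degree = 6)
    m <- generate_phantom(p, seed)$white_mesh$lh
    r <- sqrt(rowSums(m$vertices^2))
    amp <- max(abs(r - 11))  # achieved amplitude (self-fold retries may reduce it)
    dep <- sulcal_depth(m, 80)
    expect_gt(max(abs(dep)), 0.5 * amp)
    expect_lt(max(abs(dep)), 1.5 * amp)
    # sign convention: radially innermost vertices are sulcal (positive)
    expect_gt(mean(dep[r < quantile(r, 0.05)]), 0)
    expect_lt(mean(dep[r > quantile(r, 0.95)]), 0)
    # mean depth vanishes relative to the surface scale
    expect_lt(abs(mean(dep)), 0.05 * sqrt(mean(r^2)))
  }
})

test_that("Dice follows the overlap formula with NA for missing regions", {
  a <- label_map(c(rep(1L, 60), rep(2L, 40)))
  b <- label_map(c(rep(1L, 30), rep(2L, 70)))
  d <- dice_coefficient(a, b)
  expect_equal(unname(d["1"]), 2 * 30 / (60 + 30))
  expect_equal(unname(d["2"]), 2 * 40 / (40 + 70))
  expect_true(all(dice_coefficient(a, a) == 1))
  disj <- dice_coefficient(label_map(rep(1L, 10)), label_map(rep(2L, 10)))
  expect_equal(unname(disj[c("1", "2")]), c(0, 0))
  expect_true(is.na(dice_coefficient(a, b, region = 9L)))
  expect_error(dice_coefficient(a, label_map(1L)), "mismatch")
})

test_that("instability is the per-vertex sample standard deviation", {
  m1 <- rep(1, 5)
  m2 <- rep(1, 5)
  expect_true(all(instability(list(m1, m2)) == 0))
  m2[3] <- 1 + 4
  expect_equal(instability(list(m1, m2))[3], 4 / sqrt(2))
  expect_error(instability(list(m1)), "at least 2")
  expect_error(instability(list(m1, rep(1, 4))), "length")
})

test_that("parcellation instability is zero for identical sessions", {
  sph <- sphere_mesh(radius = 8, subdivisions = 2)
  par <- phantom_parcellation(sph, 6, seed = 2)
  inst <- parcellation_instability(list(par, par, par))
  expect_true(all(inst == 0))
})

test_that("map_to_common_space: identity, constants, and linear-field bound", {
  src <- sphere_mesh(radius = 10, subdivisions = 3)
  tgt <- sphere_mesh(radius = 10, subdivisions = 2)
  vals <- src$vertices[, 1]
  expect_equal(map_to_common_space(vals, src, src), vals, tolerance = 1e-9)
  expect_true(all(map_to_common_space(rep(3.3, nrow(src$vertices)), src, tgt) == 3.3))
  got <- map_to_common_space(vals, src, tgt)
  e <- mesh_edges(src)
  mean_edge <- mean(sqrt(rowSums((src$vertices[e[, 1], ] - src$vertices[e[, 2], ])^2)))
  expect_lt(max(abs(got - tgt$vertices[, 1])), mean_edge)
  expect_error(map_to_common_space(vals[-1], src, tgt), "length")
})

test_that("truth-vs-truth metric suite is conservative", {
  p <- phantom_params(grid_shape = c(32, 32, 32), base_radius = 8, fold_amplitude = 1.6,
                      cortical_thickness_true = 2.4)
  ph <- generate_phantom(p, seed = 17)
  m <- ph$white_mesh$lh
  q <- triangle_quality(m)
  expect_true(all(q$q > 0 & q$q <= 1))
  expect_true(all(surface_displacement(m, m) == 0))
  par <- phantom_parcellation(m, 8, seed = 1)
  expect_true(all(dice_coefficient(par, par) == 1))
  expect_true(all(instability(list(sulcal_depth(m, 10), sulcal_depth(m, 10))) == 0))
})
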