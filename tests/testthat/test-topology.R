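make_world <- function(n, h = 1) {
  g <- grid_volume(n, h)
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  list(grid = g, w = t(g$affine %*% rbind(t(idx), 1))[, 1:3])
}

test_that("a clean sphere level set passes through correction unchanged", {
  ls <- sphere_levelset(radius = 9, n = 28)
  out <- correct_topology(ls)
  expect_identical(out$volume$data, ls$volume$data)
  expect_equal(attr(out, "n_flipped"), 0)
  expect_equal(attr(out, "n_filled"), 0)
})

test_that("a solid torus is corrected to genus 0", {
  mw <- make_world(28)
  phi <- sqrt((sqrt(mw$w[, 1]^2 + mw$w[, 2]^2) - 8)^2 + mw$w[, 3]^2) - 3
  ls <- level_set(volume(array(phi, c(28, 28, 28)), mw$grid$affine), 8)
  expect_equal(mesh_euler(extract_surface(ls, correct = FALSE)), 0L)  # genus 1
  lsc <- correct_topology(ls)
  surf <- extract_surface(lsc, correct = FALSE)
  expect_equal(mesh_euler(surf), 2L)
  expect_true(is_edge_manifold(surf))
  expect_true(is_oriented(surf))
})

test_that("interior cavities are filled", {
  mw <- make_world(28)
  r <- sqrt(rowSums(mw$w^2))
  phi <- pmax(r - 10, 4 - r)  # spherical shell: cavity of radius 4
  ls <- level_set(volume(array(phi, c(28, 28, 28)), mw$grid$affine), 8)
  lsc <- correct_topology(ls)
  expect_gt(attr(lsc, "n_filled"), 0)
  expect_true(all(lsc$volume$data[r < 3.5] < 0))
  expect_equal(mesh_euler(extract_surface(lsc, correct = FALSE)), 2L)
})

test_that("correction is idempotent at the region level", {
  mw <- make_world(24)
  phi <- sqrt((sqrt(mw$w[, 1]^2 + mw$w[, 2]^2) - 7)^2 + mw$w[, 3]^2) - 2.5
  ls <- level_set(volume(array(phi, c(24, 24, 24)), mw$grid$affine), 8)
  c1 <- correct_topology(ls)
  c2 <- correct_topology(c1)
  expect_identical(c2$volume$data < 0, c1$volume$data < 0)
})

test_that("correction requires a nonempty foreground", {
  g <- grid_volume(8)
  ls <- level_set(volume(array(1, c(8, 8, 8)), g$affine), 8)
  expect_error(correct_topology(ls), "negative")
})

test_that("planar level sets extract with exact linear interpolation", {
  n <- 10
  g <- volume(array(0, c(n, n, n)), diag(4))  # identity affine: world == index
  phi <- array(rep(0:(n - 1), each = n * n), c(n, n, n)) - 5.5  # phi = z - 5.5
  ls <- level_set(volume(phi, g$affine), 20)
  surf <- extract_surface(ls, correct = FALSE)
  expect_true(all(abs(surf$vertices[, 3] - 5.5) < 1e-12))
})

test_that("an extracted sphere matches closed-form area and volume within 2%", {
  ls <- sphere_levelset(radius = 8, n = 24, h = 1, truncation = 10)
  surf <- extract_surface(ls)
  expect_lt(abs(mesh_area(surf) - 4 * pi * 64) / (4 * pi * 64), 0.02)
  expect_lt(abs(mesh_volume(surf) - 4 / 3 * pi * 512) / (4 / 3 * pi * 512), 0.02)
})

test_that("simple-point decisions agree with exhaustive relabelling", {
  # two-route oracle: (a) exact equivalence against an independent R
  # reconstruction of the link complex; (b) soundness against exhaustive
  # labelling — an accepted point never changes component counts, the Euler
  # characteristics of the full region/background subcomplexes, or the
  # number of enclosed background components. (The converse direction is
  # not decidable from Betti numbers alone: an addition can create one loop
  # while filling another.)
  set.seed(7)
  dims <- c(5L, 5L, 5L)
  summarise <- function(mask) {
    fg <- cortrec:::cpp_subcomplex_counts(mask, dims)
    bg <- cortrec:::cpp_subcomplex_counts(!mask, dims)
    bglab <- cortrec:::cpp_components(!mask, dims, 14L)
    border <- array(FALSE, dims)
    border[c(1, 5), , ] <- TRUE; border[, c(1, 5), ] <- TRUE; border[, , c(1, 5)] <- TRUE
    enclosed <- if (max(bglab) == 0) 0L else
      length(setdiff(unique(bglab[bglab > 0]), unique(bglab[border & bglab > 0])))
    c(max(cortrec:::cpp_components(mask, dims, 14L)),
      fg[["V"]] - fg[["E"]] + fg[["F"]] - fg[["T"]],
      max(bglab),
      bg[["V"]] - bg[["E"]] + bg[["F"]] - bg[["T"]],
      enclosed)
  }
  interior <- array(FALSE, dims)
  interior[2:4, 2:4, 2:4] <- TRUE
  n_checked <- 0
  n_simple <- 0
  for (trial in 1:40) {
    mask <- array(runif(prod(dims)) < 0.45, dims)
    if (!any(mask)) next
    base <- summarise(as.logical(mask))
    cand <- which(!mask & interior)
    if (length(cand) == 0) next
    for (vx in sample(cand, min(8, length(cand)))) {
      ijk <- as.integer(arrayInd(vx, dims) - 1L)
      got <- cortrec:::cpp_is_simple(as.logical(mask), dims, ijk)
      expect_identical(got, r_simple_point(mask, dims, ijk),
                       info = sprintf("trial %d voxel %s", trial, paste(ijk, collapse = ",")))
      if (got) {
        m2 <- mask
        m2[vx] <- TRUE
        expect_identical(summarise(as.logical(m2)), base,
                         info = sprintf("soundness: trial %d voxel %s", trial,
                                        paste(ijk, collapse = ",")))
        n_simple <- n_simple + 1
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 150)
  expect_gt(n_simple, 30)
})

test_that("phantom extraction over a seed sweep always yields genus-0 manifolds", {
  for (seed in 1:6) {
    ph <- generate_phantom(phantom_params(grid_shape = c(38, 38, 38), base_radius = 10,
                                          fold_amplitude = 2.5, noise_sd = 0,
                                          bias_field_amplitude = 0), seed)
    surf <- extract_surface(ph$white_levelset$lh)
    expect_equal(mesh_euler(surf), 2L)
    expect_true(is_edge_manifold(surf))
    expect_true(is_oriented(surf))
  }
})
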