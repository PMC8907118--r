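# Synthetic brain-like phantoms: folded nested surfaces with exactly known
# geometry, tissue-label volumes and T1-like intensities, so every pipeline
# stage can be validated without real MRI.

# --- icosphere ---------------------------------------------------------------

icosphere <- function(subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- matrix(m, 1)
      nv <<- nv + 1L
      mid_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(cc, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    v <- v / sqrt(rowSums(v^2))
    f <- newf
  }
  list(vertices = v, faces = f)
}

# --- real spherical harmonics ------------------------------------------------

# associated Legendre P_l^m(x) for all l in m..lmax, one m at a time
assoc_legendre <- function(lmax, m, x) {
  P <- matrix(0, length(x), lmax + 1)
  pmm <- (-1)^m * exp(lfactorial(2 * m) - m * log(2) - lfactorial(m)) * (1 - x^2)^(m / 2)
  P[, m + 1] <- pmm
  if (lmax > m) P[, m + 2] <- x * (2 * m + 1) * pmm
  if (lmax > m + 1) {
    for (l in (m + 2):lmax) {
      P[, l + 1] <- ((2 * l - 1) * x * P[, l] - (l + m - 1) * P[, l - 1]) / (l - m)
    }
  }
  P
}

# real orthonormal spherical harmonic Y_lm at directions (theta polar, phi azimuth)
real_sph_harm <- function(l, m, theta, phi) {
  am <- abs(m)
  N <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  P <- assoc_legendre(l, am, cos(theta))[, l + 1]
  if (m > 0) sqrt(2) * N * P * cos(m * phi)
  else if (m < 0) sqrt(2) * N * P * sin(am * phi)
  else N * P
}

# --- parameters --------------------------------------------------------------

#' Phantom generator parameters
#'
#' Defaults describe a single-hemisphere blob in a 48^3 grid of 1 mm voxels:
#' a sphere of radius 14 mm with band-limited spherical-harmonic folding of
#' amplitude 3 mm (degrees 2..6), cortical thickness 2.5 mm, T1-like tissue
#' means (background 10, grey 70, white 110), additive Gaussian noise of
#' standard deviation 5 and a +/-5 percent multiplicative smooth bias field.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param voxel_size isotropic voxel edge in mm.
#' @param base_radius mean radius of the inner ("white") surface, mm.
#' @param fold_amplitude maximum radial excursion of the folding, mm; must be
#'   below `base_radius / 2`.
#' @param fold_degree spherical-harmonic band limit of the folding.
#' @param cortical_thickness_true true white-to-pial offset along vertex
#'   normals, mm; must exceed one voxel.
#' @param intensity_means length-3 vector (background, GM, WM).
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param bias_field_amplitude fractional amplitude of the multiplicative
#'   smooth bias field.
#' @param n_hemispheres 1 or 2 (two disjoint blobs offset along world x).
#' @param truncation level-set truncation, mm.
#' @param partial_volume emulate the MRI partial-volume effect: boundary
#'   voxels take volume-fraction mixtures of the tissue means (fractions
#'   derived from the exact signed distances), which is what encodes
#'   sub-voxel surface position in real T1w intensities. `FALSE` gives a
#'   strictly piecewise-constant image.
#' @return A `cortrec_phantom_params` list.
#' @export
phantom_params <- function(grid_shape = c(48, 48, 48), voxel_size = 1,
                           base_radius = 14, fold_amplitude = 3, fold_degree = 6,
                           cortical_thickness_true = 2.5,
                           intensity_means = c(10, 70, 110), noise_sd = 5,
                           bias_field_amplitude = 0.05, n_hemispheres = 1,
                           truncation = 8, partial_volume = TRUE) {
  if (fold_amplitude >= base_radius / 2) stopf("fold_amplitude must be < base_radius/2")
  if (cortical_thickness_true <= voxel_size) {
    stopf("cortical_thickness_true must exceed the voxel size")
  }
  if (!n_hemispheres %in% c(1, 2)) stopf("n_hemispheres must be 1 or 2")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 base_radius = base_radius, fold_amplitude = fold_amplitude,
                 fold_degree = as.integer(fold_degree),
                 cortical_thickness_true = cortical_thickness_true,
                 intensity_means = intensity_means, noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 n_hemispheres = as.integer(n_hemispheres),
                 truncation = truncation,
                 partial_volume = isTRUE(partial_volume)),
            class = "cortrec_phantom_params")
}

phantom_affine <- function(params) {
  h <- params$voxel_size
  shift <- -(params$grid_shape - 1) / 2 * h
  rbind(cbind(diag(h, 3), shift), c(0, 0, 0, 1))
}

# folded white-surface mesh centred at `centre`, using the "harmonics" stream
phantom_white_mesh <- function(params, seed, hemi, amplitude) {
  subdiv <- max(3, ceiling(log2(1.05 * params$base_radius / params$voxel_size)))
  ico <- icosphere(subdiv)
  d <- ico$vertices
  pert <- rep(0, nrow(d))
  if (amplitude > 0 && params$fold_degree >= 2) {
    theta <- acos(pmin(pmax(d[, 3], -1), 1))
    phi <- atan2(d[, 2], d[, 1])
    raw <- rep(0, nrow(d))
    with_stream(seed, paste0("harmonics_", hemi), {
      for (l in 2:params$fold_degree) {
        for (m in -l:l) {
          cf <- rnorm(1) / l
          raw <- raw + cf * real_sph_harm(l, m, theta, phi)
        }
      }
    })
    pert <- amplitude * raw / max(abs(raw))
  }
  r <- params$base_radius + pert
  list(mesh = surface_mesh(d * r, ico$faces), directions = d)
}

hemi_centres <- function(params) {
  if (params$n_hemispheres == 1) return(list(lh = c(0, 0, 0)))
  r_tot <- params$base_radius + params$fold_amplitude + params$cortical_thickness_true
  cx <- r_tot + 2 * params$voxel_size  # 4-voxel gap between blobs
  list(lh = c(-cx, 0, 0), rh = c(cx, 0, 0))
}

translate_mesh <- function(mesh, shift) {
  surface_mesh(sweep(mesh$vertices, 2, shift, "+"), mesh$faces)
}

#' Generate a synthetic brain phantom
#'
#' Builds, deterministically for a fixed `(params, seed)`: a folded inner
#' ("white") surface as a radially perturbed sphere (random spherical
#' harmonics up to `fold_degree`, scaled to `fold_amplitude`); an outer
#' ("pial") surface displaced outward along vertex normals by the true
#' cortical thickness; exact truncated signed-distance level sets of both;
#' tissue labels (per-hemisphere GM/WM codes); and a T1-like intensity image
#' (tissue mean x smooth multiplicative bias field + Gaussian noise). If the
#' normal offset folds the pial surface onto itself the fold amplitude is
#' reduced and the construction retried (at most 3 attempts).
#'
#' Meshes and level sets are stored as named lists with one entry per
#' hemisphere (`"lh"`, and `"rh"` for two-hemisphere phantoms). Tissue label
#' codes: left GM 1, left WM 2, right GM 3, right WM 4.
#'
#' @param params a [phantom_params()].
#' @param seed integer master seed; named sub-streams make the harmonic
#'   coefficients, noise and bias field independently reproducible.
#' @return A `cortrec_phantom` with fields `image`, `tissue_labels`,
#'   `white_mesh`, `pial_mesh`, `white_levelset`, `pial_levelset`, `params`,
#'   `seed`.
#' @export
generate_phantom <- function(params = phantom_params(), seed = 1) {
  stopifnot(inherits(params, "cortrec_phantom_params"))
  aff <- phantom_affine(params)
  grid <- volume(array(0, params$grid_shape), aff)
  half_extent <- (params$grid_shape - 1) / 2 * params$voxel_size
  centres <- hemi_centres(params)
  r_tot <- params$base_radius + params$fold_amplitude + params$cortical_thickness_true
  for (h in names(centres)) {
    need <- abs(centres[[h]]) + r_tot + 3 * params$voxel_size
    if (any(need > half_extent)) {
      stopf("grid too small: need half extent %s mm, have %s mm",
            paste(signif(need, 4), collapse = "/"),
            paste(signif(half_extent, 4), collapse = "/"))
    }
  }
  hemis <- list()
  for (h in names(centres)) {
    amp <- params$fold_amplitude
    for (attempt in 1:3) {
      built <- phantom_white_mesh(params, seed, h, amp)
      white0 <- built$mesh
      nrm <- vertex_normals(white0)
      pial0 <- surface_mesh(white0$vertices + params$cortical_thickness_true * nrm,
                            white0$faces)
      # reject if the offset flipped any face (local self-folding)
      fw <- face_geometry(white0)$normal2
      fp <- face_geometry(pial0)$normal2
      if (all(rowSums(fw * fp) > 0)) break
      if (attempt == 3) stopf("pial offset self-intersects even at reduced amplitude")
      amp <- amp * 0.7
    }
    white <- translate_mesh(white0, centres[[h]])
    pial <- translate_mesh(pial0, centres[[h]])
    hemis[[h]] <- list(
      white = white, pial = pial,
      white_ls = encode_levelset(white, grid, params$truncation),
      pial_ls = encode_levelset(pial, grid, params$truncation))
  }
  # tissue labels from the exact level sets
  lab <- array(0, params$grid_shape)
  for (hi in seq_along(hemis)) {
    wls <- hemis[[hi]]$white_ls$volume$data
    pls <- hemis[[hi]]$pial_ls$volume$data
    offset <- 2L * (hi - 1L)
    lab[wls < 0] <- 2L + offset
    lab[wls >= 0 & pls < 0] <- 1L + offset
  }
  # intensities: tissue mean x bias field + noise; with partial_volume,
  # boundary voxels mix tissue means by volume fractions estimated from the
  # exact signed distances (fraction ~ 0.5 - phi/h, clamped to [0, 1])
  means <- params$intensity_means
  if (params$partial_volume) {
    h <- params$voxel_size
    frac <- function(phi) pmin(pmax(0.5 - phi / h, 0), 1)
    f_pial <- array(0, params$grid_shape)
    f_wm <- array(0, params$grid_shape)
    for (hi in seq_along(hemis)) {
      f_pial <- f_pial + frac(hemis[[hi]]$pial_ls$volume$data)
      f_wm <- f_wm + frac(hemis[[hi]]$white_ls$volume$data)
    }
    f_pial <- pmin(f_pial, 1)
    f_wm <- pmin(f_wm, f_pial)
    img <- means[1] * (1 - f_pial) + means[2] * (f_pial - f_wm) + means[3] * f_wm
    img <- array(img, params$grid_shape)
  } else {
    img <- array(means[1], params$grid_shape)
    img[lab %in% c(1L, 3L)] <- means[2]
    img[lab %in% c(2L, 4L)] <- means[3]
  }
  img <- img * phantom_bias_field(params, seed, "bias")
  if (params$noise_sd > 0) {
    img <- img + with_stream(seed, "noise",
                             array(rnorm(length(img), 0, params$noise_sd),
                                   params$grid_shape))
  }
  structure(list(
    image = volume(img, aff),
    tissue_labels = volume(lab, aff),
    white_mesh = lapply(hemis, `[[`, "white"),
    pial_mesh = lapply(hemis, `[[`, "pial"),
    white_levelset = lapply(hemis, `[[`, "white_ls"),
    pial_levelset = lapply(hemis, `[[`, "pial_ls"),
    params = params, seed = seed), class = "cortrec_phantom")
}

phantom_bias_field <- function(params, seed, stream) {
  a <- params$bias_field_amplitude
  if (a <= 0) return(1)
  sh <- params$grid_shape
  with_stream(seed, stream, {
    idx <- lapply(sh, function(n) (0:(n - 1)) / n)
    g <- array(0, sh)
    for (q in 1:3) {
      k <- runif(3, 0.5, 1.5)
      ph <- runif(3, 0, 2 * pi)
      g <- g + outer(outer(cos(2 * pi * k[1] * idx[[1]] + ph[1]),
                           cos(2 * pi * k[2] * idx[[2]] + ph[2])),
                     cos(2 * pi * k[3] * idx[[3]] + ph[3]))
    }
    g <- g / max(abs(g))
    1 + a * g
  })
}

#' @export
print.cortrec_phantom <- function(x, ...) {
  cat(sprintf("<cortrec_phantom> %s voxels, %d hemisphere(s), seed %d\n",
              paste(dim(x$image$data), collapse = "x"),
              x$params$n_hemispheres, x$seed))
  invisible(x)
}

#' Repeated-session phantoms with shared ground truth
#'
#' Emulates a test-retest design: all sessions share the identical surfaces
#' and level sets; only the noise and bias-field realisations differ between
#' sessions.
#'
#' @param params a [phantom_params()].
#' @param seed master seed.
#' @param n_sessions number of repeated "scans" (>= 2).
#' @param session_noise_sd noise sd applied per session (replaces
#'   `params$noise_sd`).
#' @return A list of `n_sessions` phantoms differing only in `image`.
#' @export
phantom_sessions <- function(params = phantom_params(), seed = 1, n_sessions = 10,
                             session_noise_sd = params$noise_sd) {
  if (n_sessions < 2) stopf("n_sessions must be >= 2")
  base_params <- params
  base_params$noise_sd <- 0
  base_params$bias_field_amplitude <- 0
  base <- generate_phantom(base_params, seed)
  clean <- base$image$data
  lapply(seq_len(n_sessions), function(s) {
    ph <- base
    img <- clean * phantom_bias_field(params, seed, sprintf("bias_s%03d", s))
    if (session_noise_sd > 0) {
      img <- img + with_stream(seed, sprintf("noise_s%03d", s),
                               array(rnorm(length(img), 0, session_noise_sd),
                                     dim(img)))
    }
    ph$image <- volume(img, base$image$affine)
    ph$params$noise_sd <- session_noise_sd
    ph$params$bias_field_amplitude <- params$bias_field_amplitude
    ph$session <- s
    ph
  })
}

#' Geodesic parcellation of a mesh into contiguous regions
#'
#' Farthest-point seeding on the mesh edge graph followed by nearest-seed
#' geodesic assignment, producing `n_regions` contiguous, nonempty regions.
#' Used to supply label maps for Dice evaluation.
#'
#' @param mesh a connected [surface_mesh()].
#' @param n_regions number of regions (2..N; 1 labels everything 1).
#' @param seed seed for the initial farthest-point start vertex.
#' @return A [label_map()] with ids `1..n_regions`.
#' @export
phantom_parcellation <- function(mesh, n_regions = 34, seed = 1) {
  stopifnot(inherits(mesh, "cortrec_mesh"))
  n <- nrow(mesh$vertices)
  if (n_regions > n) stopf("n_regions exceeds vertex count")
  if (n_regions < 1) stopf("n_regions must be >= 1")
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::components(g)$no != 1) stopf("mesh is disconnected")
  if (n_regions == 1) return(label_map(rep(1L, n)))
  start <- with_stream(seed, "parcellation", sample.int(n, 1))
  seeds <- integer(n_regions)
  seeds[1] <- start
  mind <- as.vector(igraph::distances(g, v = start))
  for (r in 2:n_regions) {
    seeds[r] <- which.max(mind)
    mind <- pmin(mind, as.vector(igraph::distances(g, v = seeds[r])))
  }
  D <- igraph::distances(g, v = seeds)
  label_map(max.col(-t(D), ties.method = "first"))
}
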