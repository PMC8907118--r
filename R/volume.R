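#' 3D scalar volumes with a voxel-to-world affine
#'
#' A `cortrec_volume` is a 3D array together with a 4x4 voxel-to-world affine
#' transform in millimetres. Voxel indices are 0-based with the voxel centre
#' at integer coordinates, so the world position of voxel `(i,j,k)` is
#' `affine %*% c(i,j,k,1)`. Voxel sizes are the column norms of the affine's
#' linear part.
#'
#' @param data numeric 3D array.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @return An object of class `cortrec_volume` with fields `data` and
#'   `affine`.
#' @examples
#' v <- volume(array(0, c(8, 8, 8)), diag(4))
#' voxel_size(v)
#' @export
volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stopf("volume data must be a 3D array")
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) stopf("affine must be a 4x4 matrix")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < 1e-12) stopf("affine is not invertible")
  structure(list(data = data, affine = affine), class = "cortrec_volume")
}

#' @rdname volume
#' @param x a `cortrec_volume`.
#' @export
voxel_size <- function(x) {
  stopifnot(inherits(x, "cortrec_volume"))
  sqrt(colSums(x$affine[1:3, 1:3]^2))
}

#' @export
dim.cortrec_volume <- function(x) dim(x$data)

#' @export
print.cortrec_volume <- function(x, ...) {
  cat(sprintf("<cortrec_volume> %s voxels, voxel size %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_size(x), 4), collapse = " x ")))
  invisible(x)
}

# world coordinates (n x 3, mm) of 0-based voxel indices (n x 3)
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  t(vol$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel indices of world coordinates
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  t(solve(vol$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti}. A write/read round trip preserves the
#' data bit-exactly (float64 on disk) and the affine to better than 1e-6 mm.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume()]; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("malformed NIfTI file %s: %s", path, conditionMessage(e)))
  if (length(dim(img)) != 3L) stopf("expected a 3D NIfTI image, got %dD", length(dim(img)))
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE), class = NULL)
  volume(array(as.numeric(img), dim = dim(img)), unname(aff[1:4, 1:4]))
}

#' @rdname read_volume
#' @param vol a [volume()].
#' @param datatype on-disk NIfTI datatype; `"double"` (default) round-trips
#'   bit-exactly, `"float"` halves the file size.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "cortrec_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Min-max plus z-score intensity normalization
#'
#' Rescales intensities affinely so the minimum maps to 0 and the maximum to
#' 255, then standardises the rescaled values to mean 0 and standard
#' deviation 1. This is the only intensity preprocessing the reconstruction
#' pipeline applies. Both steps are equivariant under positive affine maps
#' of the input, so the operation is idempotent.
#'
#' @param vol a [volume()].
#' @return A [volume()] with mean 0 and standard deviation 1.
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "cortrec_volume"))
  x <- vol$data
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stopf("cannot normalize a constant image (zero variance)")
  }
  x <- (x - rng[1]) / diff(rng) * 255
  x <- (x - mean(x)) / sd(x)
  volume(x, vol$affine)
}
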