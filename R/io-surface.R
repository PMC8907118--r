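# Surface, overlay and label-map readers/writers.
#
# FreeSurfer binary formats are big-endian by convention and are written here
# without the optional volume-geometry footer; readers ignore trailing bytes.
# OFF and PLY are plain ASCII with coordinates printed at %.17g, so doubles
# round-trip bit-exactly.

FS_TRIANGLE_MAGIC <- c(255L, 255L, 254L)
FS_CURV_MAGIC <- c(255L, 255L, 255L)

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = "off",
         ply = "ply",
         "freesurfer")
}

#' Read and write triangle surface meshes
#'
#' Supported formats: FreeSurfer binary triangle surface (`"freesurfer"`,
#' big-endian, no volume-geometry footer), ASCII `"off"` and ASCII `"ply"`.
#' When `format` is `NULL` it is guessed from the file extension (`.off`,
#' `.ply`, anything else FreeSurfer).
#'
#' @param path file path.
#' @param format one of `"freesurfer"`, `"off"`, `"ply"`, or `NULL` to guess.
#' @return `read_surface` returns a [surface_mesh()]; `write_surface`
#'   returns `path` invisibly.
#' @export
read_surface <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||% guess_format(path)
  switch(format,
         freesurfer = read_fs_surface(path),
         off = read_off(path),
         ply = read_ply(path),
         stopf("unknown surface format '%s'", format))
}

#' @rdname read_surface
#' @param mesh a [surface_mesh()].
#' @export
write_surface <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "cortrec_mesh"))
  format <- format %||% guess_format(path)
  switch(format,
         freesurfer = write_fs_surface(mesh, path),
         off = write_off(mesh, path),
         ply = write_ply(mesh, path),
         stopf("unknown surface format '%s'", format))
  invisible(path)
}

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  if (!identical(as.integer(magic), FS_TRIANGLE_MAGIC)) {
    stopf("%s: magic number %s is not a FreeSurfer triangle surface",
          path, paste(magic, collapse = " "))
  }
  # comment line terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", 1)
    if (length(ch) == 0) stopf("%s: truncated header", path)
    if (prev == as.raw(10) && ch == as.raw(10)) break
    prev <- ch
  }
  vnum <- readBin(con, "integer", 1, size = 4, endian = "big")
  fnum <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (is.na(vnum) || vnum <= 0 || fnum <= 0) stopf("%s: bad vertex/face count", path)
  v <- readBin(con, "numeric", 3 * vnum, size = 4, endian = "big")
  f <- readBin(con, "integer", 3 * fnum, size = 4, endian = "big")
  surface_mesh(matrix(v, ncol = 3, byrow = TRUE),
               matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(FS_TRIANGLE_MAGIC), con)
  writeBin(charToRaw("created by cortrec\n\n"), con)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") stopf("%s: missing OFF magic line", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (nv <= 0 || nf <= 0) stopf("%s: empty OFF mesh", path)
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stopf("%s: only triangle faces supported", path)
  surface_mesh(v, fl[, 2:4] + 1L)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1]) != "ply") stopf("%s: missing ply magic line", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stopf("%s: no end_header", path)
  hdr <- trimws(lines[1:hdr_end])
  if (!any(grepl("^format ascii", hdr))) stopf("%s: only ascii PLY supported", path)
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1 || nv <= 0 || nf <= 0) {
    stopf("%s: bad or empty vertex/face elements", path)
  }
  body <- lines[(hdr_end + 1):length(lines)]
  v <- matrix(scan(text = body[1:nv], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = body[(nv + 1):(nv + nf)], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stopf("%s: only triangle faces supported", path)
  surface_mesh(v, fl[, 2:4] + 1L)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

#' Read and write per-vertex scalar overlays
#'
#' Overlays (displacement, thickness, sulcal-depth maps, ...) are stored
#' either in the FreeSurfer "curv" new-format binary (big-endian float32) or
#' as plain one-value-per-line text. `NA`/`NaN` entries are preserved (mask
#' semantics). Text overlays round-trip doubles exactly; binary overlays are
#' float32 on disk.
#'
#' @param path file path; `.txt` selects the text format, anything else the
#'   binary curv format, unless `format` is given.
#' @param format `"curv"`, `"text"`, or `NULL` to guess from the extension.
#' @return `read_overlay` returns a numeric vector.
#' @export
read_overlay <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  format <- format %||% (if (tolower(tools::file_ext(path)) == "txt") "text" else "curv")
  if (format == "text") {
    x <- scan(path, what = double(), quiet = TRUE, na.strings = "NA")
    if (length(x) == 0) stopf("%s: empty overlay", path)
    return(x)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  if (!identical(as.integer(magic), FS_CURV_MAGIC)) {
    stopf("%s: magic number %s is not a new-format curv file",
          path, paste(magic, collapse = " "))
  }
  vnum <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 4, endian = "big")  # fnum, vals_per_vertex
  readBin(con, "numeric", vnum, size = 4, endian = "big")
}

#' @rdname read_overlay
#' @param values numeric per-vertex vector (non-empty).
#' @export
write_overlay <- function(values, path, format = NULL) {
  if (length(values) == 0) stopf("empty overlay")
  format <- format %||% (if (tolower(tools::file_ext(path)) == "txt") "text" else "curv")
  if (format == "text") {
    writeLines(sprintf("%.17g", values), path)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(FS_CURV_MAGIC), con)
  writeBin(c(length(values), 0L, 1L), con, size = 4, endian = "big")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
  invisible(path)
}

#' Per-vertex label maps (parcellations)
#'
#' A label map assigns one non-negative integer region id to each vertex,
#' with an id-to-name table. On disk: one integer per line, plus a separate
#' tab-separated two-column (id, name) table.
#'
#' @param labels integer vector of region ids (>= 0).
#' @param names named character vector or data.frame mapping ids to region
#'   names; every id present in `labels` must be covered.
#' @return A `cortrec_labels` object with fields `labels` and `names`.
#' @export
label_map <- function(labels, names = NULL) {
  labels <- as.integer(labels)
  if (any(labels < 0)) stopf("label ids must be >= 0")
  ids <- sort(unique(labels))
  if (is.null(names)) {
    names <- stats::setNames(sprintf("region_%03d", ids), ids)
  } else if (is.data.frame(names)) {
    names <- stats::setNames(as.character(names[[2]]), names[[1]])
  }
  missing <- setdiff(ids, as.integer(base::names(names)))
  if (length(missing)) stopf("ids missing from name table: %s", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = names), class = "cortrec_labels")
}

#' @rdname label_map
#' @param path labels file (one id per line); the name table goes to/from
#'   `paste0(path, ".names.tsv")`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "cortrec_labels"))
  writeLines(as.character(labels$labels), path)
  utils::write.table(data.frame(id = base::names(labels$names),
                                name = unname(labels$names)),
                     paste0(path, ".names.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname label_map
#' @export
read_labels <- function(path) {
  ids <- as.integer(readLines(path))
  npath <- paste0(path, ".names.tsv")
  nm <- NULL
  if (file.exists(npath)) {
    tab <- utils::read.table(npath, sep = "\t", header = TRUE, colClasses = c("integer", "character"))
    nm <- stats::setNames(tab$name, tab$id)
  }
  label_map(ids, nm)
}
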