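#' Voxel volume containers
#'
#' `scalar_volume()` wraps a 3-D grid of physical scalars (dose in mGy,
#' photon energy fluence in J/cm^2, mass density in g/cm^3, or an
#' interaction-coefficient map in cm^2/g); `label_volume()` wraps a 3-D
#' integer grid of tissue labels.  Both carry a per-axis voxel `spacing` and
#' a world-space `origin`, all in millimetres.
#'
#' The geometric convention used throughout the package is that `origin` is
#' the corner of the grid: the world position of the centre of voxel
#' `(i, j, k)` (0-based) is `origin + (c(i, j, k) + 0.5) * spacing`.  The
#' third array axis is the axial (longitudinal, z) direction; 2-D
#' operations act on axial slices `values[, , k]`.
#'
#' @param values 3-D numeric array; scalar volumes must be finite and
#'   non-negative.
#' @param labels 3-D array of non-negative integers.
#' @param spacing Numeric length-3, strictly positive voxel size per axis, mm.
#' @param origin Numeric length-3, world position of the grid corner, mm.
#' @return An object of class `scalar_volume` or `label_volume` (both also
#'   inherit `voxel_volume`): a list with elements `values`, `spacing`,
#'   `origin`.
#' @examples
#' v <- scalar_volume(array(1, c(4, 4, 2)), spacing = c(1, 1, 5))
#' voxel_centers(v)[1, ]
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vol <- new_volume(values, spacing, origin, "scalar_volume")
  if (!all(is.finite(vol$values))) {
    stop("scalar volume values must be finite", call. = FALSE)
  }
  if (any(vol$values < 0)) {
    stop("scalar volume values must be non-negative", call. = FALSE)
  }
  vol
}

#' @rdname scalar_volume
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!all(is.finite(labels)) || any(labels != round(labels)) ||
      any(labels < 0)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  new_volume(labels, spacing, origin, "label_volume")
}

new_volume <- function(values, spacing, origin, class) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three strictly positive numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("origin must be three finite numbers (mm)", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = c(class, "voxel_volume"))
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (inherits(x, "label_volume")) {
    tb <- table(x$values)
    cat("labels:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
        "\n")
  } else {
    cat(sprintf("range: [%g, %g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) {
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' World coordinates of all voxel centers
#'
#' @param vol A `voxel_volume`.
#' @return An `n x 3` matrix of world positions (mm), voxels in array order
#'   (first axis fastest).
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$values)
  i <- (seq_len(d[1]) - 0.5) * vol$spacing[1] + vol$origin[1]
  j <- (seq_len(d[2]) - 0.5) * vol$spacing[2] + vol$origin[2]
  k <- (seq_len(d[3]) - 0.5) * vol$spacing[3] + vol$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

#' Read and write voxel volumes
#'
#' Lossless round trip of values, spacing and origin for MetaImage
#' (`.mhd` header + `.raw` little-endian data) and NIfTI (`.nii`, `.nii.gz`)
#' files.  Label volumes are stored as 32-bit integers, scalar volumes as
#' 32-bit floats.  For NIfTI the affine is diagonal (no rotation); files with
#' rotational xforms are rejected rather than silently mis-registered.
#'
#' @param path File path; the extension selects the format.
#' @param vol A `scalar_volume` or `label_volume`.
#' @param type For `read_volume`, `"scalar"` or `"label"`.
#' @return `read_volume` returns a volume object; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, type = c("scalar", "label")) {
  type <- match.arg(type)
  ext <- volume_format(path)
  raw <- switch(ext,
    mhd = read_mhd(path),
    nii = read_nii(path))
  if (type == "label") {
    label_volume(round(raw$values), raw$spacing, raw$origin)
  } else {
    scalar_volume(raw$values, raw$spacing, raw$origin)
  }
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  ext <- volume_format(path)
  switch(ext,
    mhd = write_mhd(vol, path),
    nii = write_nii(vol, path))
  invisible(path)
}

volume_format <- function(path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) return("mhd")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nii")
  stop(sprintf("unsupported volume format: '%s' (use .mhd, .nii or .nii.gz)",
               basename(path)), call. = FALSE)
}

# -- MetaImage -----------------------------------------------------------

write_mhd <- function(vol, path) {
  is_label <- inherits(vol, "label_volume")
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  d <- dim(vol$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.9g %.9g %.9g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementType = %s", if (is_label) "MET_INT" else "MET_FLOAT"),
    sprintf("ElementDataFile = %s", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (is_label) {
    writeBin(as.integer(vol$values), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(vol$values), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(key) {
    i <- match(tolower(key), tolower(keys))
    if (is.na(i)) stop(sprintf("MHD header missing '%s'", key), call. = FALSE)
    vals[i]
  }
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
  etype <- get("ElementType")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  values <- switch(etype,
    MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8L, endian = "little"),
    MET_INT = readBin(con, "integer", n, size = 4L, endian = "little"),
    MET_SHORT = readBin(con, "integer", n, size = 2L, endian = "little"),
    MET_UCHAR = as.integer(readBin(con, "raw", n)),
    stop(sprintf("unsupported MHD ElementType '%s'", etype), call. = FALSE))
  list(values = array(values, d), spacing = spacing, origin = origin)
}

# -- NIfTI ---------------------------------------------------------------

write_nii <- function(vol, path) {
  is_label <- inherits(vol, "label_volume")
  arr <- vol$values
  storage.mode(arr) <- if (is_label) "integer" else "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  # NIfTI xforms map 0-based voxel indices to voxel-center world positions
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin + 0.5 * vol$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (is_label) "int32" else "float")
  invisible(path)
}

read_nii <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 * max(abs(diag(rot)))) {
    stop("NIfTI volumes with rotational xforms are not supported",
         call. = FALSE)
  }
  spacing <- abs(diag(rot))
  origin <- aff[1:3, 4] - 0.5 * spacing
  list(values = array(as.numeric(img), dim(img)[1:3]),
       spacing = spacing, origin = origin)
}
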