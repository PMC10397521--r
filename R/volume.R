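#' 3D scalar volumes with world geometry
#'
#' A `vol` is the carrier type for every image in the package: T1w, T2w, M0,
#' difference-signal, damage-score and CBF maps. It couples a 3D numeric array
#' with per-axis voxel spacing (mm) and the world coordinate of the first
#' voxel centre, under a fixed RAS axis convention (+x right, +y anterior,
#' +z superior). Undefined voxels are carried as `NA` and are excluded from
#' all means and standard deviations downstream; they are never zero-filled.
#'
#' @param data numeric 3D array. `NaN` values are converted to `NA`.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world mm coordinate of voxel index
#'   `(0,0,0)` (0-based). The default `NULL` centres the grid so the world
#'   origin falls at the grid centre, which places the midsagittal plane at
#'   world x = 0 for symmetric grids.
#' @return An object of class `vol`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  if (is.null(origin)) {
    origin <- -spacing * (dim(data) - 1) / 2
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers (mm)")
  data[is.nan(data)] <- NA_real_
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol")
}

#' @export
print.vol <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  v <- x$data[!is.na(x$data)]
  if (length(v))
    cat(sprintf("  defined voxels: %d, range [%g, %g]\n",
                length(v), min(v), max(v)))
  invisible(x)
}

#' @rdname volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "vol")

#' Test and assert grid alignment of two volumes
#'
#' Two volumes are aligned when they share shape, spacing and origin (within
#' 1e-6 mm). Every voxelwise operation in the package requires alignment and
#' raises an error rather than silently recycling.
#'
#' @param a,b `vol` objects.
#' @return `same_grid()` returns a logical; `assert_aligned()` returns
#'   invisibly or stops.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < 1e-6 &&
    max(abs(a$origin - b$origin)) < 1e-6
}

#' @rdname same_grid
#' @param what label used in the error message.
#' @export
assert_aligned <- function(a, b, what = "volumes") {
  if (!is_volume(a) || !is_volume(b))
    stop("expected vol objects")
  if (!same_grid(a, b))
    stop("alignment error: ", what,
         " differ in shape, spacing or origin")
  invisible(TRUE)
}

#' World coordinates of voxel centres
#'
#' Voxel indices are 0-based; world = origin + index * spacing, per axis.
#'
#' @param vol a `vol`.
#' @param axis axis index 1..3.
#' @return numeric vector of world mm coordinates of voxel centres.
#' @export
axis_coords <- function(vol, axis) {
  vol$origin[axis] + vol$spacing[axis] * (seq_len(dim(vol$data)[axis]) - 1)
}

#' @rdname axis_coords
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @return `voxel_to_world()`: matrix of world coordinates (n x 3).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname axis_coords
#' @param xyz numeric matrix (n x 3) of world mm coordinates.
#' @return `world_to_voxel()`: matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Read and write NIfTI-1 volumes
#'
#' `read_volume()` loads a NIfTI-1 file, reorients the data to the package's
#' RAS convention (so voxel (0,0,0) maps to the same world point regardless
#' of the stored axis order or flips), and returns a [volume()]. Oblique
#' acquisitions (rotation beyond axis permutation/flip) are not supported.
#' `write_volume()` writes a volume with a full qform/sform so a
#' write-then-read round trip reproduces data to floating precision and
#' geometry exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `vol`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("load failure: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("load failure for ", basename(path), ": ",
                         conditionMessage(e), call. = FALSE))
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (max(abs(rot - diag(spacing))) > 1e-4 * max(spacing))
    stop("load failure for ", basename(path),
         ": oblique orientation not supported")
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  volume(arr, spacing = spacing, origin = aff[1:3, 4])
}

#' @rdname read_volume
#' @param vol a `vol` to write.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  arr <- vol$data
  arr[is.na(arr)] <- NaN
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary masks over a volume grid
#'
#' A mask is a `vol` whose data is 0/1, tagged with a role label
#' (lesion, GM, WM, CSF, brain, air, roi, ...). `NA` voxels in the source
#' are treated as outside the mask.
#'
#' @param data 3D array coercible to 0/1, or a logical array.
#' @param spacing,origin as in [volume()].
#' @param label role tag.
#' @return object of class `c("mask", "vol")`.
#' @export
mask <- function(data, spacing = c(1, 1, 1), origin = NULL, label = "roi") {
  data <- array(as.numeric(data), dim = dim(data))
  data[is.na(data)] <- 0
  if (!all(data %in% c(0, 1)))
    stop("mask values must be 0/1")
  v <- volume(data, spacing, origin)
  v$label <- label
  class(v) <- c("mask", "vol")
  v
}

#' @rdname mask
#' @param vol a `vol` whose data is 0/1 (NA allowed, treated as 0).
#' @export
as_mask <- function(vol, label = "roi") {
  mask(vol$data, vol$spacing, vol$origin, label)
}

#' @rdname mask
#' @param x object to test.
#' @export
is_mask <- function(x) inherits(x, "mask")

#' @rdname mask
#' @return `mask_volume_mm3()`: total volume of the mask in mm^3
#'   (voxel count times voxel volume).
#' @export
mask_volume_mm3 <- function(x) {
  sum(x$data) * prod(x$spacing)
}

# logical view of a mask
mask_which <- function(m) m$data > 0
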