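#' Spherical region of interest on a volume grid
#'
#' Builds the mask of voxels whose centre lies within `radius` mm of a world
#' coordinate, e.g. the 15 mm anterior-cingulate sphere or the out-of-head
#' air sphere used by the quality metrics.
#'
#' @param reference `vol` providing the grid.
#' @param center world mm coordinates (length 3).
#' @param radius sphere radius in mm (> 0).
#' @param label role tag for the returned mask.
#' @return a [mask()]. If the sphere misses the grid entirely an empty mask
#'   is returned with a warning.
#' @export
sphere_mask <- function(reference, center, radius, label = "roi") {
  if (!is_volume(reference)) stop("reference must be a vol")
  if (!(radius > 0)) stop("radius must be > 0")
  center <- as.numeric(center)
  d2x <- (axis_coords(reference, 1) - center[1])^2
  d2y <- (axis_coords(reference, 2) - center[2])^2
  d2z <- (axis_coords(reference, 3) - center[3])^2
  dd <- outer(outer(d2x, d2y, "+"), d2z, "+")
  m <- mask(dd <= radius^2, reference$spacing, reference$origin, label)
  if (sum(m$data) == 0)
    warning("sphere at (", paste(center, collapse = ", "),
            ") mm, radius ", radius, " mm contains no voxels")
  m
}

#' Morphological erosion of a mask
#'
#' One iteration removes every voxel that does not have all six face
#' neighbours (6-connectivity) inside the mask, i.e. "eroded by one voxel".
#' Grid boundaries count as outside.
#'
#' @param m a [mask()].
#' @param iterations number of erosion passes (>= 0; 0 is the identity).
#' @return the eroded mask (always a subset of the input).
#' @export
erode_mask <- function(m, iterations = 1) {
  if (!is_mask(m)) stop("m must be a mask")
  if (iterations < 0) stop("iterations must be >= 0")
  a <- m$data > 0
  for (it in seq_len(iterations)) {
    if (!any(a)) break
    keep <- a
    for (ax in 1:3) {
      keep <- keep & shift_logical(a, ax, 1L) & shift_logical(a, ax, -1L)
    }
    a <- keep
  }
  mask(a, m$spacing, m$origin, m$label)
}

# Shift a logical 3D array by `by` voxels along `axis`, padding with FALSE.
# shift_logical(a, ax, +1)[i] == a[i-1]: the neighbour at -1 seen from i.
shift_logical <- function(a, axis, by) {
  d <- dim(a)
  n <- d[axis]
  out <- array(FALSE, d)
  if (abs(by) >= n) return(out)
  to <- from <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    to[[axis]] <- (by + 1):n; from[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    to[[axis]] <- 1:(n + by); from[[axis]] <- (1 - by):n
  }
  do.call(`[<-`, c(list(out), to,
                   list(do.call(`[`, c(list(a), from)))))
}

#' Hemisphere opposite a lesion
#'
#' Splits the brain at the midsagittal plane (world x = 0 under the package
#' convention) and returns the half on the side opposite the lesion's centre
#' of mass. The lesion must lie predominantly (>= `tol` fraction) on one
#' side; a lesion straddling the midline beyond tolerance is an error that
#' reports the voxel fraction per side.
#'
#' @param brain brain [mask()].
#' @param lesion lesion [mask()], aligned with `brain`.
#' @param tol minimum fraction of lesion voxels required on one side.
#' @return the contralesional half of `brain` as a mask.
#' @export
contralesional_hemisphere <- function(brain, lesion, tol = 0.9) {
  assert_aligned(brain, lesion, "brain and lesion masks")
  xw <- axis_coords(brain, 1)
  les_by_x <- apply(lesion$data, 1, sum)
  n_les <- sum(les_by_x)
  if (n_les == 0) stop("lesion mask is empty")
  f_left <- sum(les_by_x[xw < 0]) / n_les
  f_right <- sum(les_by_x[xw > 0]) / n_les
  if (max(f_left, f_right) < tol)
    stop(sprintf(paste0("lesion straddles the midline: %.1f%% of voxels at ",
                        "x<0, %.1f%% at x>0 (need >= %.0f%% on one side)"),
                 100 * f_left, 100 * f_right, 100 * tol))
  contra_side <- if (f_left >= f_right) xw > 0 else xw < 0
  out <- brain$data
  out[!contra_side, , ] <- 0
  mask(out, brain$spacing, brain$origin, "brain")
}

#' Anterior half of a mask
#'
#' Restricts a mask to the anterior half of its own bounding box along the
#' anterior-posterior (world y) axis: voxels with y above the bounding-box
#' midpoint. Used to build the "anterior" reference regions for ratio
#' normalization.
#'
#' @param m a [mask()].
#' @param reference optional mask whose bounding box defines the cut
#'   (defaults to `m` itself); the brain mask is the natural choice.
#' @return the anterior-restricted mask.
#' @export
anterior_half <- function(m, reference = m) {
  assert_aligned(m, reference, "mask and reference")
  yw <- axis_coords(m, 2)
  ref_by_y <- apply(reference$data, 2, sum) > 0
  if (!any(ref_by_y)) stop("reference mask is empty")
  ymid <- (min(yw[ref_by_y]) + max(yw[ref_by_y])) / 2
  out <- m$data
  out[, yw <= ymid, ] <- 0
  mask(out, m$spacing, m$origin, m$label)
}

#' Intersection and difference of aligned masks
#'
#' @param a,b aligned masks.
#' @return a mask.
#' @export
mask_and <- function(a, b) {
  assert_aligned(a, b, "masks")
  mask(a$data * b$data, a$spacing, a$origin, a$label)
}

#' @rdname mask_and
#' @export
mask_minus <- function(a, b) {
  assert_aligned(a, b, "masks")
  mask(pmax(a$data - b$data, 0), a$spacing, a$origin, a$label)
}
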