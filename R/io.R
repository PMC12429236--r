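# NIfTI I/O and preprocessing. On disk NIfTI stores (x, y, z) = (col, row,
# slice); in memory everything is (slice, row, col), so arrays are permuted on
# the way in/out and pixdim is reversed accordingly.

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param as One of `"image"` or `"labels"`; labels are validated against
#'   [label_codes()].
#' @return An [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, as = c("image", "labels")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("cannot read '", path, "': expected 3 dimensions, got ", length(d))
  pd <- RNifti::pixdim(img)[1:3]          # (dx, dy, dz)
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("cannot read '", path, "': non-positive voxel spacing in header")
  vox <- aperm(as.array(img), c(3, 2, 1)) # (slice, row, col)
  spacing <- rev(pd)                      # (dz, dy, dx)
  if (as == "image") image_volume(vox, spacing, meta = list(path = path))
  else label_volume(round(vox), spacing, meta = list(path = path))
}

#' Write a volume as NIfTI
#'
#' Images are stored as float64 and labels as uint8, so that a write/read
#' round trip preserves voxel values exactly.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': parent directory does not exist")
  is_lab <- inherits(vol, "label_volume")
  a <- if (is_lab) vol$labels else vol$voxels
  arr <- aperm(a, c(3, 2, 1))             # back to (x, y, z)
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- rev(vol$spacing_mm)
  RNifti::writeNifti(nim, path, datatype = if (is_lab) "uint8" else "double")
  invisible(path)
}

# interpolation matrix mapping n_old samples to n_new at spacing ratio
# new/old, grids aligned at their physical centers; "linear" rows hold the
# two bilinear weights, "nearest" a single 1
interp_matrix <- function(n_old, n_new, ratio, method) {
  src <- (seq_len(n_new) - (n_new + 1) / 2) * ratio + (n_old + 1) / 2
  src <- pmin(pmax(src, 1), n_old)
  M <- matrix(0, n_new, n_old)
  if (method == "nearest") {
    j <- pmin(pmax(round(src), 1), n_old)
    M[cbind(seq_len(n_new), j)] <- 1
  } else {
    lo <- pmin(floor(src), n_old - 1L)
    w <- src - lo
    M[cbind(seq_len(n_new), lo)] <- M[cbind(seq_len(n_new), lo)] + (1 - w)
    M[cbind(seq_len(n_new), lo + 1L)] <- M[cbind(seq_len(n_new), lo + 1L)] + w
  }
  M
}

#' Resample a volume in-plane
#'
#' Resamples rows/cols to a target in-plane spacing, leaving the slice
#' dimension untouched. Output grid size is `round(extent / target)`, so the
#' physical extent is preserved to within one voxel; grids are aligned at
#' their physical centers. Label volumes must use nearest neighbour.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param target_dy_dx Numeric length-2 `(dy, dx)` target spacing in mm.
#' @param interpolation `"linear"` (images only) or `"nearest"`.
#' @return A volume of the same class with spacing `(dz, target_dy, target_dx)`.
#' @export
resample_inplane <- function(vol, target_dy_dx,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_dy_dx <- as.numeric(target_dy_dx)
  if (length(target_dy_dx) != 2L || any(target_dy_dx <= 0))
    stop("target_dy_dx must be 2 positive numbers")
  is_lab <- inherits(vol, "label_volume")
  if (is_lab && interpolation == "linear")
    stop("label volumes must be resampled with nearest-neighbour interpolation")
  a <- if (is_lab) vol$labels else vol$voxels
  d <- dim(a)
  old <- vol$spacing_mm[2:3]
  n_new <- pmax(1L, as.integer(round(d[2:3] * old / target_dy_dx)))
  Ar <- interp_matrix(d[2], n_new[1], target_dy_dx[1] / old[1], interpolation)
  Ac <- interp_matrix(d[3], n_new[2], target_dy_dx[2] / old[2], interpolation)
  out <- array(0, c(d[1], n_new))
  for (s in seq_len(d[1])) out[s, , ] <- Ar %*% a[s, , ] %*% t(Ac)
  spacing <- c(vol$spacing_mm[1], target_dy_dx)
  if (is_lab) label_volume(round(out), spacing, meta = vol$meta)
  else image_volume(out, spacing, meta = vol$meta)
}

#' Z-score intensity normalization
#'
#' Centers and scales intensities to mean 0 / SD 1 over a region (sample SD).
#' A constant region yields an all-zero output rather than dividing by zero.
#'
#' @param vol An [image_volume()].
#' @param mask Optional logical array selecting the normalization region;
#'   default is the whole volume.
#' @return An [image_volume()] with normalized intensities.
#' @export
znormalize <- function(vol, mask = NULL) {
  v <- vol$voxels
  if (is.null(mask)) {
    region <- as.vector(v)
  } else {
    if (!identical(dim(mask), dim(v))) stop("mask shape must match volume")
    if (!any(mask)) stop("normalization region is empty")
    region <- v[mask]
  }
  if (length(region) == 0L) stop("normalization region is empty")
  mu <- mean(region)
  s <- stats::sd(region)
  out <- if (!is.finite(s) || s == 0) array(0, dim(v)) else (v - mu) / s
  image_volume(out, vol$spacing_mm, meta = vol$meta)
}
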