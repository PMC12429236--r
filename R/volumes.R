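# Core volume containers. Arrays are indexed (slice, row, col), 1-based; the
# "middle slice" of an n-slice stack is floor(n/2) + 1, i.e. the same physical
# slice as the 0-based floor(n/2) convention.

#' Tissue class codes
#'
#' Integer label codes used throughout the package for multiclass short-axis
#' LGE segmentation masks.
#'
#' @return Named integer vector: background = 0, blood = 1, myocardium = 2,
#'   scar = 3, mvo = 4.
#' @export
#' @examples
#' label_codes()["scar"]
label_codes <- function() {
  c(background = 0L, blood = 1L, myocardium = 2L, scar = 3L, mvo = 4L)
}

#' Construct an image volume
#'
#' A 3D intensity stack with voxel spacing; the unit of all pipeline I/O.
#' Voxels are indexed `(slice, row, col)`; `spacing_mm` is `(dz, dy, dx)`.
#'
#' @param voxels 3D numeric array indexed (slice, row, col).
#' @param spacing_mm Numeric length-3 vector `(dz, dy, dx)` in mm, all > 0.
#' @param meta Optional list of opaque metadata (e.g. a NIfTI header),
#'   passed through untouched.
#' @return An object of class `image_volume` with elements `voxels`,
#'   `spacing_mm`, `meta`.
#' @export
#' @examples
#' v <- image_volume(array(0, c(2, 4, 4)), c(8, 1.5, 1.5))
#' voxel_volume_mm3(v)
image_volume <- function(voxels, spacing_mm, meta = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("expected 3 dimensions, got ", length(dim(voxels)))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite numbers (dz, dy, dx)")
  structure(list(voxels = voxels, spacing_mm = spacing_mm, meta = meta),
            class = "image_volume")
}

#' Construct a label volume
#'
#' Integer multiclass mask on the same grid as its paired image; values must
#' lie in `label_codes()`.
#'
#' @param labels 3D integer array indexed (slice, row, col), values in 0..4.
#' @inheritParams image_volume
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_mm, meta = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("expected 3 dimensions, got ", length(dim(labels)))
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L) || any(labels > 4L))
    stop("labels must be integers in {0, 1, 2, 3, 4}")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers (dz, dy, dx)")
  structure(list(labels = labels, spacing_mm = spacing_mm, meta = meta),
            class = "label_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d (slice x row x col), spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = label_codes(),
                      labels = names(label_codes())))
  cat(sprintf("<label_volume> %d x %d x %d (slice x row x col), spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x ")))
  print(tab)
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param vol An `image_volume` or `label_volume`.
#' @return Voxel volume dz*dy*dx in mm^3.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing_mm)

#' Physical volume of a mask or label class, in mL
#'
#' Volume = voxel count x dz*dy*dx / 1000.
#'
#' @param x A logical mask array, a `label_volume`, or an integer array.
#' @param spacing_mm Spacing, required when `x` is a bare array/mask.
#' @param class For label input, the class (code or name) to measure.
#' @return Volume in mL.
#' @export
#' @examples
#' m <- array(c(TRUE, FALSE), c(2, 5, 5))
#' mask_volume_ml(m, spacing_mm = c(10, 2, 2))
mask_volume_ml <- function(x, spacing_mm = NULL, class = NULL) {
  if (inherits(x, "label_volume")) {
    spacing_mm <- x$spacing_mm
    x <- if (is.null(class)) x$labels > 0L else x$labels == resolve_class(class)
  }
  if (is.null(spacing_mm)) stop("spacing_mm required for bare arrays")
  sum(x != 0) * prod(spacing_mm) / 1000
}

# class name or code -> integer code
resolve_class <- function(class) {
  codes <- label_codes()
  if (is.character(class)) {
    if (!class %in% names(codes)) stop("unknown class: ", class)
    return(codes[[class]])
  }
  class <- as.integer(class)
  if (!class %in% codes) stop("unknown class code: ", class)
  class
}

#' Extract a class mask from a label volume
#'
#' @param labels A `label_volume` or integer array.
#' @param class Class code (0..4) or name (see [label_codes()]).
#' @return Logical array of the same shape.
#' @export
class_mask <- function(labels, class) {
  a <- if (inherits(labels, "label_volume")) labels$labels else labels
  a == resolve_class(class)
}

#' Index of the middle slice
#'
#' For an n-slice stack the middle slice is `floor(n/2) + 1` (1-based), the
#' same physical slice as floor(n/2) in a 0-based convention.
#'
#' @param n_slices Number of slices.
#' @return 1-based slice index.
#' @export
middle_slice_index <- function(n_slices) as.integer(floor(n_slices / 2) + 1L)

# ---- small numeric primitives shared by several modules ---------------------

# n x n edge-replicated separable Gaussian blur operator
blur_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  M <- matrix(0, n, n)
  off <- seq(-r, r)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + off, 1L), n)   # replicate edges
    for (k in seq_along(idx)) M[i, idx[k]] <- M[i, idx[k]] + w[k]
  }
  M / rowSums(M)
}

# per-slice (2D) Gaussian blur of a (slice, row, col) array
gauss_blur_slices <- function(vox, sigma) {
  d <- dim(vox)
  Br <- blur_operator(d[2], sigma)
  Bc <- blur_operator(d[3], sigma)
  out <- vox
  for (s in seq_len(d[1])) out[s, , ] <- Br %*% vox[s, , ] %*% t(Bc)
  out
}

# mean over slices z-1, z, z+1 (edge-replicated) of a (slice,row,col) array
slice_neighbor_mean <- function(vox) {
  d <- dim(vox)
  if (d[1] == 1L) return(vox)
  up <- vox[c(1L, seq_len(d[1] - 1L)), , , drop = FALSE]
  dn <- vox[c(seq_len(d[1])[-1L], d[1]), , , drop = FALSE]
  (up + vox + dn) / 3
}

# center of mass (row, col) of a logical matrix
com_2d <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# center of mass (slice, row, col) of a logical 3D array
com_3d <- function(a) {
  idx <- which(a, arr.ind = TRUE)
  colMeans(idx)
}
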