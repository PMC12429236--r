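# Stage 1: localize the LV, compute the center of mass of the middle-slice
# mask, and extract a centered reduced-size stack. The localizer is a
# voxelwise LV/background classifier over multiscale per-slice intensity
# features (a compact stand-in for a full encoder-decoder that preserves the
# stage's contract: probability volume in, crop window out).

#' Localizer training configuration
#'
#' @param hidden Hidden units of the classifier (default 6).
#' @param maxit Optimizer iterations (default 120).
#' @param decay Weight decay (default 1e-4).
#' @param samples_per_case Training voxels sampled per case, class-balanced
#'   (default 3000).
#' @param seed RNG seed controlling sampling and weight initialization.
#' @return List of class `localizer_config`.
#' @export
localizer_config <- function(hidden = 6L, maxit = 120L, decay = 1e-4,
                             samples_per_case = 3000L, seed = 1L) {
  structure(list(hidden = as.integer(hidden), maxit = as.integer(maxit),
                 decay = decay, samples_per_case = as.integer(samples_per_case),
                 seed = as.integer(seed)),
            class = "localizer_config")
}

# per-voxel features: z-scored intensity + per-slice Gaussian pyramid
localizer_features <- function(vol) {
  z <- znormalize(vol)$voxels
  cbind(as.vector(z),
        as.vector(gauss_blur_slices(z, 2)),
        as.vector(gauss_blur_slices(z, 5)))
}

sample_balanced <- function(idx_pos, idx_neg, n_total) {
  n_half <- max(1L, n_total %/% 2L)
  pos <- idx_pos[sample.int(length(idx_pos), min(n_half, length(idx_pos)))]
  neg <- idx_neg[sample.int(length(idx_neg), min(n_half, length(idx_neg)))]
  c(pos, neg)
}

#' Train the LV localizer
#'
#' The target is the whole LV: the union of blood pool, myocardium, scar and
#' MVO labels. Deterministic given `config$seed`.
#'
#' @param cases List of `phantom_case` objects (>= 2).
#' @param config A [localizer_config()].
#' @return Object of class `localizer_model` (with `final_loss` recorded for
#'   reproducibility checks).
#' @export
train_localizer <- function(cases, config = localizer_config()) {
  if (length(cases) < 2L) stop("need at least 2 training cases")
  if (!any(vapply(cases, function(ca) any(ca$labels$labels > 0L), logical(1))))
    stop("training targets are all background: no LV voxels in any case")
  with_seed(config$seed, function() {
    Xs <- list(); ys <- list()
    for (ca in cases) {
      f <- localizer_features(ca$image)
      lv <- as.vector(ca$labels$labels > 0L)
      idx <- sample_balanced(which(lv), which(!lv), config$samples_per_case)
      Xs[[length(Xs) + 1L]] <- f[idx, , drop = FALSE]
      ys[[length(ys) + 1L]] <- lv[idx]
    }
    X <- do.call(rbind, Xs)
    y <- as.numeric(unlist(ys))
    fit <- nnet::nnet(x = X, y = y, size = config$hidden, decay = config$decay,
                      maxit = config$maxit, entropy = TRUE, trace = FALSE,
                      MaxNWts = 5000L)
    structure(list(fit = fit, config = config, final_loss = fit$value,
                   n_features = ncol(X)),
              class = "localizer_model")
  })
}

#' LV probability volume from the localizer
#'
#' @param model A `localizer_model`.
#' @param vol An [image_volume()].
#' @return Numeric array (same grid) of LV probabilities in `[0, 1]`.
#' @export
predict_localizer <- function(model, vol) {
  f <- localizer_features(vol)
  p <- as.numeric(stats::predict(model$fit, f))
  array(p, dim(vol$voxels))
}

#' Construct a crop window
#'
#' @param center_rc Integer `(row, col)` center on the full grid.
#' @param size_rc `(H, W)` window size in voxels, > 0.
#' @return Object of class `crop_window`.
#' @export
crop_window <- function(center_rc, size_rc = c(96L, 96L)) {
  size_rc <- as.integer(size_rc)
  if (any(size_rc <= 0L)) stop("crop size must be > 0")
  structure(list(center_rc = as.integer(round(center_rc)), size_rc = size_rc),
            class = "crop_window")
}

window_ranges <- function(w) {
  start <- w$center_rc - w$size_rc %/% 2L
  list(rows = start[1] + seq_len(w$size_rc[1]) - 1L,
       cols = start[2] + seq_len(w$size_rc[2]) - 1L)
}

#' Locate the LV and derive a centered crop window
#'
#' Binarizes the localizer output at 0.5 and takes the center of mass of the
#' middle-slice mask. Fallback chain for degenerate predictions: empty middle
#' slice -> center of mass of the whole 3D mask; empty 3D mask -> grid center
#' (with a warning).
#'
#' @param model A `localizer_model`.
#' @param vol An [image_volume()].
#' @param size_rc `(H, W)` crop size (default 96 x 96).
#' @return A [crop_window()].
#' @export
locate_crop <- function(model, vol, size_rc = c(96L, 96L)) {
  prob <- predict_localizer(model, vol)
  crop_window(crop_center_from_mask(prob >= 0.5), size_rc)
}

# fallback chain: middle-slice COM -> 3D COM -> grid center (warn)
crop_center_from_mask <- function(mask) {
  d <- dim(mask)
  mid <- middle_slice_index(d[1])
  if (any(mask[mid, , ])) {
    ctr <- com_2d(mask[mid, , ])
  } else if (any(mask)) {
    ctr <- com_3d(mask)[2:3]
  } else {
    warning("empty LV prediction: falling back to the grid center")
    ctr <- (d[2:3] + 1) / 2
  }
  unname(round(ctr))
}

#' Extract a crop window from a volume
#'
#' Out-of-grid area is zero-padded for images and background-labelled for
#' label volumes, so the output always has shape `(n_slices, H, W)`.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param w A [crop_window()].
#' @return A volume of the same class on the cropped grid.
#' @export
apply_crop <- function(vol, w) {
  is_lab <- inherits(vol, "label_volume")
  a <- if (is_lab) vol$labels else vol$voxels
  d <- dim(a)
  rg <- window_ranges(w)
  out <- array(if (is_lab) 0L else 0, c(d[1], w$size_rc))
  rin <- rg$rows >= 1L & rg$rows <= d[2]
  cin <- rg$cols >= 1L & rg$cols <= d[3]
  if (any(rin) && any(cin))
    out[, rin, cin] <- a[, rg$rows[rin], rg$cols[cin]]
  if (is_lab) label_volume(out, vol$spacing_mm, meta = vol$meta)
  else image_volume(out, vol$spacing_mm, meta = vol$meta)
}

#' Map a cropped volume back onto the original grid
#'
#' Exact inverse of [apply_crop()] for in-grid voxels; the area outside the
#' window is zero / background.
#'
#' @param vol Cropped [image_volume()] or [label_volume()].
#' @param w The [crop_window()] used for cropping.
#' @param full_shape `(n_slices, n_rows, n_cols)` of the original grid.
#' @return A volume of the same class on the original grid.
#' @export
uncrop <- function(vol, w, full_shape) {
  is_lab <- inherits(vol, "label_volume")
  a <- if (is_lab) vol$labels else vol$voxels
  rg <- window_ranges(w)
  out <- array(if (is_lab) 0L else 0, full_shape)
  rin <- rg$rows >= 1L & rg$rows <= full_shape[2]
  cin <- rg$cols >= 1L & rg$cols <= full_shape[3]
  if (any(rin) && any(cin))
    out[, rg$rows[rin], rg$cols[cin]] <- a[, rin, cin]
  if (is_lab) label_volume(out, vol$spacing_mm, meta = vol$meta)
  else image_volume(out, vol$spacing_mm, meta = vol$meta)
}

#' Crop a phantom case
#'
#' @param case A `phantom_case`.
#' @param w A [crop_window()]; default centers on the case's true LV axis
#'   (useful for building training crops with known geometry).
#' @return A `phantom_case` on the cropped grid (window recorded in `meta`).
#' @export
crop_case <- function(case, w = NULL) {
  if (is.null(w)) w <- crop_window(round(case$meta$center_rc))
  out <- case
  out$image <- apply_crop(case$image, w)
  out$labels <- apply_crop(case$labels, w)
  out$meta$crop_window <- w
  out
}
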