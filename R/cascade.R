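# Stage 2: error-correcting 2D-3D cascade on the cropped stack. A per-slice
# multiclass segmenter produces candidate masks; a 3D corrector sees the
# image together with the one-hot candidate mask (plus its in-plane and
# through-plane neighborhood context) and outputs refined class
# probabilities. The corrector is trained on deliberately perturbed masks so
# it learns to repair plausible 2D error modes.

CLASS_K <- 5L

#' 2D segmenter configuration
#'
#' @param hidden Hidden units (default 12).
#' @param maxit Optimizer iterations (default 200).
#' @param decay Weight decay (default 1e-4).
#' @param samples_per_case Training voxels per case, class-balanced
#'   (default 1500).
#' @param seed RNG seed.
#' @return List of class `seg2d_config`.
#' @export
seg2d_config <- function(hidden = 12L, maxit = 200L, decay = 1e-4,
                         samples_per_case = 1500L, seed = 2L) {
  structure(list(hidden = as.integer(hidden), maxit = as.integer(maxit),
                 decay = decay, samples_per_case = as.integer(samples_per_case),
                 seed = as.integer(seed)),
            class = "seg2d_config")
}

# per-voxel 2D features on a (LV-centered) cropped stack: multiscale
# per-slice intensities plus normalized radial position
seg2d_features <- function(vol) {
  z <- znormalize(vol)$voxels
  d <- dim(z)
  cr <- (d[2] + 1) / 2; cc <- (d[3] + 1) / 2
  rad <- sqrt(outer((seq_len(d[2]) - cr)^2, (seq_len(d[3]) - cc)^2, "+")) /
    (min(d[2], d[3]) / 2)
  radf <- aperm(array(rad, c(d[2], d[3], d[1])), c(3, 1, 2))
  cbind(as.vector(z),
        as.vector(gauss_blur_slices(z, 1)),
        as.vector(gauss_blur_slices(z, 3)),
        as.vector(gauss_blur_slices(z, 6)),
        as.vector(radf))
}

sample_by_class <- function(labels_vec, n_total) {
  per <- max(1L, n_total %/% CLASS_K)
  unlist(lapply(0:(CLASS_K - 1L), function(cl) {
    idx <- which(labels_vec == cl)
    if (!length(idx)) return(integer(0))
    idx[sample.int(length(idx), min(per, length(idx)))]
  }))
}

fit_multiclass <- function(X, y_vec, hidden, decay, maxit) {
  Y <- nnet::class.ind(factor(y_vec, levels = 0:(CLASS_K - 1L)))
  nnet::nnet(x = X, y = Y, size = hidden, decay = decay, maxit = maxit,
             softmax = TRUE, trace = FALSE, MaxNWts = 10000L)
}

predict_prob_array <- function(fit, feats, d) {
  p <- stats::predict(fit, feats)
  out <- array(0, c(d, CLASS_K))
  for (k in seq_len(CLASS_K)) out[, , , k] <- array(p[, k], d)
  out
}

# per-voxel argmax over the class axis; ties break toward the lower code
argmax_labels <- function(prob4d) {
  d <- dim(prob4d)[1:3]
  m <- matrix(prob4d, prod(d), CLASS_K)
  array(max.col(m, ties.method = "first") - 1L, d)
}

#' Train the per-slice 2D multiclass segmenter
#'
#' Slices are pooled across cases as independent samples. Deterministic given
#' `config$seed`.
#'
#' @param cases List of cropped `phantom_case` objects (>= 2), e.g. from
#'   [crop_case()].
#' @param config A [seg2d_config()].
#' @return Object of class `seg2d_model` (with `final_loss`).
#' @export
train_seg2d <- function(cases, config = seg2d_config()) {
  if (length(cases) < 2L) stop("need at least 2 training cases")
  if (!any(vapply(cases, function(ca) any(ca$labels$labels > 0L), logical(1))))
    stop("training targets are all background")
  with_seed(config$seed, function() {
    Xs <- list(); ys <- list()
    for (ca in cases) {
      f <- seg2d_features(ca$image)
      lv <- as.vector(ca$labels$labels)
      idx <- sample_by_class(lv, config$samples_per_case)
      Xs[[length(Xs) + 1L]] <- f[idx, , drop = FALSE]
      ys[[length(ys) + 1L]] <- lv[idx]
    }
    fit <- fit_multiclass(do.call(rbind, Xs), unlist(ys),
                          config$hidden, config$decay, config$maxit)
    structure(list(fit = fit, config = config, final_loss = fit$value),
              class = "seg2d_model")
  })
}

#' Per-class probability volume from the 2D segmenter
#'
#' @param model A `seg2d_model`.
#' @param vol Cropped [image_volume()].
#' @return 4D array `(slice, row, col, class)`; channels sum to 1 per voxel.
#' @export
predict_seg2d <- function(model, vol) {
  predict_prob_array(model$fit, seg2d_features(vol), dim(vol$voxels))
}

#' Mask perturbation configuration
#'
#' Concretization of "perturbed 2D masks": per-operator probabilities for
#' morphological dilation/erosion of the scar and MVO components, dropping a
#' connected component, inserting a spurious scar blob inside the
#' myocardium, and swapping scar/MVO labels inside the scar core — spanning
#' over-, under- and false-positive segmentation error modes.
#'
#' @param p_dilate,p_erode Per-slice probabilities of dilating/eroding the
#'   scar (and, independently, the MVO) component.
#' @param radius_range Integer range of the morphological disc radius
#'   (voxels, >= 1).
#' @param p_drop Probability of deleting one connected scar component.
#' @param p_blob Probability of inserting a spurious scar blob.
#' @param blob_radius_range Integer radius range of inserted blobs.
#' @param p_swap Probability of a scar/MVO class swap inside the scar core.
#' @param seed Optional seed making a single call deterministic.
#' @return List of class `perturb_config`.
#' @export
perturb_config <- function(p_dilate = 0.25, p_erode = 0.25,
                           radius_range = c(1L, 2L),
                           p_drop = 0.15, p_blob = 0.1,
                           blob_radius_range = c(1L, 3L),
                           p_swap = 0.1, seed = NULL) {
  p <- list(p_dilate = p_dilate, p_erode = p_erode,
            radius_range = as.integer(radius_range),
            p_drop = p_drop, p_blob = p_blob,
            blob_radius_range = as.integer(blob_radius_range),
            p_swap = p_swap, seed = seed)
  probs <- c(p$p_dilate, p$p_erode, p$p_drop, p$p_blob, p$p_swap)
  if (any(probs < 0) || any(probs > 1))
    stop("perturbation probabilities must lie in [0, 1]")
  if (any(p$radius_range < 1L) || any(p$blob_radius_range < 1L))
    stop("perturbation radii must be >= 1")
  structure(p, class = "perturb_config")
}

disc_mask <- function(nr, nc, r0, c0, radius) {
  outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+") <= radius^2
}

sample_int_range <- function(rg) {
  if (rg[1] == rg[2]) rg[1] else sample(seq(rg[1], rg[2]), 1L)
}

#' Perturb a 2D label slice
#'
#' Applies the configured error operators to one label slice. With all
#' probabilities 0 the input is returned unchanged; output codes always stay
#' in `{0..4}`; deterministic when `cfg$seed` (or `seed`) is set.
#'
#' @param slice Integer label matrix (codes 0..4).
#' @param cfg A [perturb_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#' @return Perturbed integer label matrix of the same shape.
#' @export
perturb_mask <- function(slice, cfg = perturb_config(), seed = NULL) {
  seed <- if (!is.null(seed)) seed else cfg$seed
  run <- function() {
    sl <- slice
    storage.mode(sl) <- "integer"
    for (cls in c(3L, 4L)) {
      m <- sl == cls
      if (any(m) && stats::runif(1) < cfg$p_dilate) {
        r <- sample_int_range(cfg$radius_range)
        md <- EBImage::dilate(m * 1, EBImage::makeBrush(2L * r + 1L, "disc")) > 0
        sl[md & !m & sl != 0L] <- cls   # grow into the LV, not into air
        m <- sl == cls
      }
      if (any(m) && stats::runif(1) < cfg$p_erode) {
        r <- sample_int_range(cfg$radius_range)
        me <- EBImage::erode(m * 1, EBImage::makeBrush(2L * r + 1L, "disc")) > 0
        sl[m & !me] <- 2L               # eroded rim reverts to myocardium
        m <- sl == cls
      }
      if (any(m) && stats::runif(1) < cfg$p_drop) {
        lab <- EBImage::bwlabel(m * 1)
        id <- sample.int(max(lab), 1L)
        sl[lab == id] <- 2L
        m <- sl == cls
      }
    }
    if (stats::runif(1) < cfg$p_blob && any(sl == 2L)) {
      myo <- which(sl == 2L, arr.ind = TRUE)
      at <- myo[sample.int(nrow(myo), 1L), ]
      r <- sample_int_range(cfg$blob_radius_range)
      blob <- disc_mask(nrow(sl), ncol(sl), at[1], at[2], r)
      sl[blob & sl == 2L] <- 3L
    }
    core <- sl == 3L | sl == 4L
    if (any(core) && stats::runif(1) < cfg$p_swap) {
      cv <- which(core, arr.ind = TRUE)
      at <- cv[sample.int(nrow(cv), 1L), ]
      r <- sample_int_range(cfg$radius_range)
      patch <- disc_mask(nrow(sl), ncol(sl), at[1], at[2], r) & core
      sl[patch] <- ifelse(sl[patch] == 3L, 4L, 3L)
    }
    sl
  }
  if (!is.null(seed)) with_seed(seed, run) else run()
}

#' 3D corrector configuration
#'
#' @param hidden Hidden units (default 12).
#' @param maxit Optimizer iterations (default 150).
#' @param decay Weight decay (default 1e-4).
#' @param samples_per_case Training voxels per case (default 1500).
#' @param perturbed_truth_ratio Fraction of training cases whose candidate
#'   mask is perturbed ground truth (the rest use frozen 2D predictions).
#' @param seed RNG seed.
#' @return List of class `corrector_config`.
#' @export
corrector_config <- function(hidden = 12L, maxit = 150L, decay = 1e-4,
                             samples_per_case = 1500L,
                             perturbed_truth_ratio = 0.7, seed = 3L) {
  if (perturbed_truth_ratio < 0 || perturbed_truth_ratio > 1)
    stop("perturbed_truth_ratio must lie in [0, 1]")
  structure(list(hidden = as.integer(hidden), maxit = as.integer(maxit),
                 decay = decay, samples_per_case = as.integer(samples_per_case),
                 perturbed_truth_ratio = perturbed_truth_ratio,
                 seed = as.integer(seed)),
            class = "corrector_config")
}

# image features + one-hot candidate mask with in-plane and through-plane
# neighborhood fractions per class
corrector_features <- function(vol, cand_labels) {
  z <- znormalize(vol)$voxels
  d <- dim(z)
  cr <- (d[2] + 1) / 2; cc <- (d[3] + 1) / 2
  rad <- sqrt(outer((seq_len(d[2]) - cr)^2, (seq_len(d[3]) - cc)^2, "+")) /
    (min(d[2], d[3]) / 2)
  radf <- aperm(array(rad, c(d[2], d[3], d[1])), c(3, 1, 2))
  cols <- list(as.vector(z),
               as.vector(gauss_blur_slices(z, 2)),
               as.vector(gauss_blur_slices(z, 6)),
               as.vector(radf))
  for (cl in 0:(CLASS_K - 1L)) {
    oh <- (cand_labels == cl) * 1
    cols[[length(cols) + 1L]] <- as.vector(oh)
    cols[[length(cols) + 1L]] <- as.vector(gauss_blur_slices(oh, 2))
    cols[[length(cols) + 1L]] <- as.vector(slice_neighbor_mean(oh))
  }
  do.call(cbind, cols)
}

#' Train the 3D error-correcting network
#'
#' Candidate masks are drawn per case from perturbed ground truth (with
#' probability `config$perturbed_truth_ratio`) or from the frozen 2D
#' segmenter's predictions, so the corrector learns both to repair injected
#' error modes and to clean up the real 2D output. Deterministic given
#' `config$seed`.
#'
#' @param cases List of cropped `phantom_case` objects (>= 2).
#' @param seg2d A trained `seg2d_model` (frozen).
#' @param perturb_cfg A [perturb_config()].
#' @param config A [corrector_config()].
#' @return Object of class `corrector_model` (with `final_loss`).
#' @export
train_corrector3d <- function(cases, seg2d, perturb_cfg = perturb_config(),
                              config = corrector_config()) {
  if (length(cases) < 2L) stop("need at least 2 training cases")
  if (!any(vapply(cases, function(ca) any(ca$labels$labels > 0L), logical(1))))
    stop("training targets are all background")
  with_seed(config$seed, function() {
    Xs <- list(); ys <- list()
    for (ca in cases) {
      gt <- ca$labels$labels
      if (stats::runif(1) < config$perturbed_truth_ratio) {
        cand <- gt
        for (s in seq_len(dim(gt)[1]))
          cand[s, , ] <- perturb_mask(gt[s, , ], perturb_cfg)
      } else {
        cand <- argmax_labels(predict_seg2d(seg2d, ca$image))
      }
      f <- corrector_features(ca$image, cand)
      lv <- as.vector(gt)
      idx <- sample_by_class(lv, config$samples_per_case)
      Xs[[length(Xs) + 1L]] <- f[idx, , drop = FALSE]
      ys[[length(ys) + 1L]] <- lv[idx]
    }
    fit <- fit_multiclass(do.call(rbind, Xs), unlist(ys),
                          config$hidden, config$decay, config$maxit)
    structure(list(fit = fit, config = config, final_loss = fit$value),
              class = "corrector_model")
  })
}

#' Refined class probabilities from the 3D corrector
#'
#' @param model A `corrector_model`.
#' @param vol Cropped [image_volume()].
#' @param cand_labels Integer candidate label array (same grid), e.g. the
#'   argmax of [predict_seg2d()].
#' @return 4D probability array `(slice, row, col, class)`.
#' @export
predict_corrector <- function(model, vol, cand_labels) {
  predict_prob_array(model$fit, corrector_features(vol, cand_labels),
                     dim(vol$voxels))
}

#' Fully automated infarct segmentation of one LGE stack
#'
#' Runs the whole pipeline: LV localization -> centered crop -> per-slice 2D
#' multiclass segmentation -> argmax -> 3D error correction -> argmax ->
#' mapping back onto the original grid (background outside the crop window).
#' A pure function of the volume and the three trained models.
#'
#' @param vol An [image_volume()] on the grid the models were trained for.
#' @param localizer A `localizer_model`.
#' @param seg2d A `seg2d_model`.
#' @param corrector A `corrector_model`, or `NULL` to stop after the 2D
#'   stage (useful for ablation).
#' @param crop_size `(H, W)` crop size (default 96 x 96).
#' @return A [label_volume()] on the full input grid.
#' @export
predict_pipeline <- function(vol, localizer, seg2d, corrector = NULL,
                             crop_size = c(96L, 96L)) {
  w <- locate_crop(localizer, vol, crop_size)
  cvol <- apply_crop(vol, w)
  cand <- argmax_labels(predict_seg2d(seg2d, cvol))
  out <- if (is.null(corrector)) cand
  else argmax_labels(predict_corrector(corrector, cvol, cand))
  uncrop(label_volume(out, vol$spacing_mm), w, dim(vol$voxels))
}
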