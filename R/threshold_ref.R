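# Semi-automated n-SD threshold reference method: given myocardial contours
# and a remote-myocardium ROI, scar = myocardial voxels with intensity at or
# above remote mean + k * remote SD (k = 5 by default).

#' Remote-myocardium intensity statistics
#'
#' Mean and SD of the image over a remote-myocardium ROI, and the derived
#' scar threshold `mean + k * sd`. Population SD is the default (the choice
#' is a flag, both are defensible).
#'
#' @param image An [image_volume()].
#' @param roi Logical array (same grid) with at least 2 voxels.
#' @param k Number of SDs above the remote mean (default 5).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Object of class `remote_stats`: `mean`, `sd`, `n_voxels`, `k`,
#'   `threshold`, `sd_type`.
#' @export
remote_stats <- function(image, roi, k = 5, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!identical(dim(roi), dim(image$voxels))) stop("roi shape must match image")
  vals <- image$voxels[roi]
  if (length(vals) < 2L) stop("remote ROI must contain at least 2 voxels")
  m <- mean(vals)
  s <- if (sd_type == "sample") stats::sd(vals)
  else sqrt(mean((vals - m)^2))
  remote_stats_values(m, s, length(vals), k = k, sd_type = sd_type)
}

#' Construct remote statistics from known values
#'
#' Useful when the remote mean/SD come from elsewhere (a report, a nominal
#' noise level) rather than from an ROI on this image.
#'
#' @param mean,sd Remote-myocardium intensity mean and SD (`sd >= 0`).
#' @param n_voxels ROI size used (>= 2).
#' @param k Number of SDs above the mean (default 5).
#' @param sd_type Bookkeeping tag (default "population").
#' @return Object of class `remote_stats`.
#' @export
remote_stats_values <- function(mean, sd, n_voxels = 2L, k = 5,
                                sd_type = "population") {
  if (sd < 0) stop("sd must be >= 0")
  if (n_voxels < 2L) stop("n_voxels must be >= 2")
  structure(list(mean = mean, sd = sd, n_voxels = as.integer(n_voxels),
                 k = k, threshold = mean + k * sd, sd_type = sd_type),
            class = "remote_stats")
}

#' @export
print.remote_stats <- function(x, ...) {
  cat(sprintf("remote myocardium: mean %.2f, %s SD %.2f (n = %d) -> %g-SD threshold %.2f\n",
              x$mean, x$sd_type, x$sd, x$n_voxels, x$k, x$threshold))
  invisible(x)
}

#' Threshold-based scar segmentation
#'
#' Scar = myocardial voxels whose intensity is at or above the remote
#' threshold (`>=` by default; configurable). An optional minimum
#' connected-component size filter (in-plane 8-connectivity, off by default)
#' can suppress single-voxel noise.
#'
#' @param image An [image_volume()].
#' @param myocardium Logical array marking the myocardial contour interior.
#' @param stats A [remote_stats()] object.
#' @param rule `">="` (default) or `">"` at the threshold boundary.
#' @param min_component_voxels Minimum per-slice component size kept
#'   (0 = filter off).
#' @return Logical array: the scar voxel set. Attributes `threshold` and
#'   `rule` record the decision.
#' @export
threshold_scar <- function(image, myocardium, stats, rule = c(">=", ">"),
                           min_component_voxels = 0L) {
  rule <- match.arg(rule)
  if (!identical(dim(myocardium), dim(image$voxels)))
    stop("myocardium mask shape must match image")
  if (!any(myocardium)) stop("myocardium mask is empty")
  scar <- if (rule == ">=") myocardium & image$voxels >= stats$threshold
  else myocardium & image$voxels > stats$threshold
  if (min_component_voxels > 0L && any(scar)) {
    for (s in seq_len(dim(scar)[1])) {
      sl <- scar[s, , ]
      if (!any(sl)) next
      lab <- EBImage::bwlabel(sl * 1)
      keep <- which(tabulate(lab[lab > 0]) >= min_component_voxels)
      scar[s, , ] <- array(lab %in% keep, dim(sl))
    }
  }
  attr(scar, "threshold") <- stats$threshold
  attr(scar, "rule") <- rule
  scar
}

#' Combine scar with the MVO core
#'
#' Whether the hypointense MVO core counts toward total infarct volume is a
#' reporting policy; `"include"` (the common convention) takes the union,
#' `"exclude"` leaves the scar set unchanged.
#'
#' @param scar,mvo Logical arrays on the same grid.
#' @param policy `"include"` (default) or `"exclude"`.
#' @return Logical array with attribute `mvo_policy`.
#' @export
include_mvo_core <- function(scar, mvo, policy = c("include", "exclude")) {
  policy <- match.arg(policy)
  out <- if (policy == "include") scar | mvo else scar
  attr(out, "mvo_policy") <- policy
  out
}
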