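# Quantitative agreement between predicted (P) and reference (G)
# segmentations: Dice, absolute volume difference (AVD, mL) and its rate
# relative to myocardial volume (AVDR, %), infarct size as % of LV mass,
# Lin's concordance, Bland-Altman limits of agreement, paired Wilcoxon.

as_mask <- function(x) {
  if (inherits(x, "label_volume")) stop("pass a logical mask or index set, not a label_volume")
  if (is.logical(x)) return(x)
  x != 0
}

#' Dice similarity coefficient
#'
#' `2|P n G| / (|P| + |G|)`. When both masks are empty the coefficient is
#' undefined and is set to 1, the convention for correctly-absent structures
#' (e.g. MVO-negative cases).
#'
#' @param P,G Logical arrays (or 0/1 arrays) of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
#' @examples
#' dice(array(c(TRUE, TRUE, FALSE), 3), array(c(TRUE, FALSE, FALSE), 3))
dice <- function(P, G) {
  P <- as_mask(P); G <- as_mask(G)
  if (!identical(dim(P), dim(G)) || length(P) != length(G))
    stop("P and G must have identical shape")
  p <- sum(P); g <- sum(G)
  if (p + g == 0) return(1)
  2 * sum(P & G) / (p + g)
}

#' Absolute volume difference
#'
#' `AVD = ||P| - |G|| x voxelvolume`, reported in mL.
#'
#' @inheritParams dice
#' @param voxel_volume_mm3 Physical volume of one voxel in mm^3.
#' @return AVD in mL.
#' @export
avd <- function(P, G, voxel_volume_mm3) {
  if (voxel_volume_mm3 <= 0) stop("voxel_volume_mm3 must be > 0")
  abs(sum(as_mask(P)) - sum(as_mask(G))) * voxel_volume_mm3 / 1000
}

#' Absolute volume difference rate
#'
#' AVD normalized by the LV myocardial volume, in percent.
#'
#' @param avd_ml AVD in mL.
#' @param v_myo_ml Myocardial volume V_MYO in mL, > 0.
#' @return AVDR in percent.
#' @export
avdr <- function(avd_ml, v_myo_ml) {
  if (!is.finite(v_myo_ml) || v_myo_ml <= 0)
    stop("AVDR undefined: v_myo_ml must be > 0")
  100 * avd_ml / v_myo_ml
}

#' Infarct size as a percentage of LV myocardial mass
#'
#' @param scar_vol_ml Scar volume in mL.
#' @param v_myo_ml Total LV myocardial volume in mL (includes scar and MVO
#'   voxels), > 0.
#' @return Infarct size in percent.
#' @export
infarct_size_percent <- function(scar_vol_ml, v_myo_ml) {
  if (!is.finite(v_myo_ml) || v_myo_ml <= 0)
    stop("infarct size undefined: v_myo_ml must be > 0")
  100 * scar_vol_ml / v_myo_ml
}

#' Per-case segmentation metrics for one tissue class
#'
#' Computes Dice, AVD and AVDR between a predicted and a reference label
#' volume for one class. V_MYO is taken from the reference as the union of
#' myocardium, scar and MVO voxels (total LV myocardial mass).
#'
#' @param pred,ref [label_volume()] objects on the same grid.
#' @param class Class code or name (see [label_codes()]).
#' @param case_id Optional identifier carried into the output.
#' @return One-row tibble: `case_id`, `class`, `dcs`, `avd_ml`,
#'   `avdr_percent`, `vol_pred_ml`, `vol_ref_ml`, `v_myo_ml`.
#' @export
seg_metrics <- function(pred, ref, class = "scar", case_id = NA_character_) {
  if (!identical(dim(pred$labels), dim(ref$labels)))
    stop("pred and ref must share the same grid")
  code <- resolve_class(class)
  vv <- voxel_volume_mm3(ref)
  P <- pred$labels == code
  G <- ref$labels == code
  v_myo <- sum(ref$labels %in% c(2L, 3L, 4L)) * vv / 1000
  a <- avd(P, G, vv)
  tibble::tibble(case_id = case_id,
                 class = names(label_codes())[match(code, label_codes())],
                 dcs = dice(P, G),
                 avd_ml = a,
                 avdr_percent = if (v_myo > 0) avdr(a, v_myo) else NA_real_,
                 vol_pred_ml = sum(P) * vv / 1000,
                 vol_ref_ml = sum(G) * vv / 1000,
                 v_myo_ml = v_myo)
}

#' Mean +/- SD summary of per-case metrics
#'
#' Aggregates a per-case metric table (one row per case) into the
#' mean +/- standard-deviation presentation used for cohort reporting.
#'
#' @param metrics Tibble from [seg_metrics()] rows.
#' @return Tibble with one row per class and `mean`/`sd` columns per metric.
#' @export
summarize_metrics <- function(metrics) {
  dplyr::summarise(
    dplyr::group_by(metrics, .data$class),
    n = dplyr::n(),
    dcs_mean = mean(.data$dcs), dcs_sd = stats::sd(.data$dcs),
    avd_ml_mean = mean(.data$avd_ml), avd_ml_sd = stats::sd(.data$avd_ml),
    avdr_percent_mean = mean(.data$avdr_percent, na.rm = TRUE),
    avdr_percent_sd = stats::sd(.data$avdr_percent, na.rm = TRUE),
    .groups = "drop")
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (xbar - ybar)^2)` with population
#' moments; penalizes both poor correlation and location/scale shift. The
#' 95% CI uses the asymptotic variance of the Fisher z-transformed
#' coefficient.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param level Confidence level (default 0.95).
#' @return Object of class `lin_ccc`: `rho_c`, `ci95`, `n`, `level`.
#' @export
lin_concordance <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need at least 3 complete pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("rho_c undefined: both variables constant with equal means")
  rho_c <- 2 * sxy / denom

  ci <- c(NA_real_, NA_real_)
  if (sx2 > 0 && sy2 > 0 && abs(rho_c) < 1) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^(1 / 4)
    # asymptotic variance of atanh(rho_c)
    v <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
            2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
            rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2)) / (n - 2)
    if (is.finite(v) && v > 0) {
      z <- atanh(rho_c)
      q <- stats::qnorm(1 - (1 - level) / 2)
      ci <- tanh(z + c(-1, 1) * q * sqrt(v))
    }
  } else if (abs(rho_c) == 1) {
    ci <- c(rho_c, rho_c)
  }
  structure(list(rho_c = rho_c, ci95 = ci, n = n, level = level),
            class = "lin_ccc")
}

#' @export
print.lin_ccc <- function(x, ...) {
  cat(sprintf("Lin's concordance rho_c = %.3f (%d%% CI %.3f-%.3f), n = %d\n",
              x$rho_c, round(100 * x$level), x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Bland-Altman analysis
#'
#' Differences are taken as `x - y`; by convention `x` is the manual and `y`
#' the automatic measurement, so a negative bias means the automatic method
#' measures larger. Limits of agreement are `bias +/- 1.96 x sample SD`.
#'
#' @param x,y Paired numeric vectors, n >= 2.
#' @return Object of class `bland_altman`: `bias`, `loa` (lo, hi),
#'   `sd_diff`, `n`, plus the per-pair `means` and `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L || length(y) != n) stop("need at least 2 complete pairs")
  diffs <- x - y
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(bias = bias, loa = bias + c(-1, 1) * 1.96 * s,
                 sd_diff = s, n = n,
                 means = (x + y) / 2, diffs = diffs),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Exact p-value for n <= 25 non-zero differences, normal approximation with
#' tie correction above; zero differences are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `statistic` (V), `p_value`, `n_nonzero`, `alternative`.
#' @export
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L) stop("no nonzero differences")
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                       exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_nonzero = length(nz), alternative = alternative)
}
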