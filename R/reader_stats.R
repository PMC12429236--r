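# Reader-study statistics: 2x2 diagnostic tables with exact binomial CIs,
# qualitative rating tabulation with parametric-bootstrap CIs, one-way
# chi-square preference test, and (weighted) Cohen's kappa.

#' Construct a 2x2 contingency table
#'
#' @param tp,fp,fn,tn Non-negative integer counts (predicted vs reference
#'   presence of a finding).
#' @return Object of class `contingency_2x2`.
#' @export
#' @examples
#' contingency_2x2(tp = 15, fp = 4, fn = 8, tn = 125)
contingency_2x2 <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) == 0) stop("table total must be > 0")
  structure(lapply(as.list(v), as.integer), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(prediction = c("present", "absent"),
                              reference = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Lower bound `qbeta(alpha/2; x, n-x+1)`, upper `qbeta(1-alpha/2; x+1, n-x)`;
#' 0% at `x = 0` and 100% at `x = n` by convention. All values in percent.
#'
#' @param x Successes, `0 <= x <= n`.
#' @param n Trials, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `estimate_pct`, `lo_pct`, `hi_pct`, `x`, `n`,
#'   `level`, `method`.
#' @export
#' @examples
#' clopper_pearson(152, 152)  # lower bound 100 * 0.025^(1/152)
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integers 0 <= x <= n with n >= 1")
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  tibble::tibble(estimate_pct = 100 * x / n, lo_pct = 100 * lo, hi_pct = 100 * hi,
                 x = as.integer(x), n = as.integer(n), level = level,
                 method = "clopper-pearson")
}

#' Sensitivity of a 2x2 table
#'
#' @param t A [contingency_2x2()].
#' @return Sensitivity in percent.
#' @export
sensitivity <- function(t) {
  if (t$tp + t$fn == 0) stop("sensitivity undefined: no reference-positive cases")
  100 * t$tp / (t$tp + t$fn)
}

#' Specificity of a 2x2 table
#'
#' @param t A [contingency_2x2()].
#' @return Specificity in percent.
#' @export
specificity <- function(t) {
  if (t$fp + t$tn == 0) stop("specificity undefined: no reference-negative cases")
  100 * t$tn / (t$fp + t$tn)
}

#' Sensitivity and specificity with exact binomial CIs
#'
#' Point estimates are reported both unrounded and rounded to the nearest
#' integer percent with CI bounds to one decimal (the usual display style);
#' a component whose denominator is zero is returned as `NA` (displayed "-").
#'
#' @param t A [contingency_2x2()].
#' @param level Confidence level (default 0.95).
#' @return Tibble with rows `sensitivity` and `specificity`: `estimate_pct`,
#'   `lo_pct`, `hi_pct` (unrounded) and `display_pct`, `display_lo`,
#'   `display_hi` (rounded).
#' @export
#' @examples
#' sens_spec(contingency_2x2(15, 4, 8, 125))
sens_spec <- function(t, level = 0.95) {
  one <- function(x, n) {
    if (n == 0)
      return(tibble::tibble(estimate_pct = NA_real_, lo_pct = NA_real_,
                            hi_pct = NA_real_))
    ci <- clopper_pearson(x, n, level)
    tibble::tibble(estimate_pct = ci$estimate_pct, lo_pct = ci$lo_pct,
                   hi_pct = ci$hi_pct)
  }
  out <- dplyr::bind_rows(one(t$tp, t$tp + t$fn), one(t$tn, t$fp + t$tn))
  out <- dplyr::mutate(out,
                       measure = c("sensitivity", "specificity"),
                       display_pct = round(.data$estimate_pct),
                       display_lo = round(.data$lo_pct, 1),
                       display_hi = round(.data$hi_pct, 1))
  dplyr::select(out, "measure", dplyr::everything())
}

#' Qualitative rating categories
#'
#' Closed per-slice rating set used in blinded expert review of scar/MVO
#' segmentations.
#'
#' @return Character vector of the seven categories.
#' @export
rating_levels <- function() {
  c("true_negative", "optimal", "too_big", "too_small",
    "wrong_tissue", "false_negative", "false_positive")
}

#' Tabulate qualitative ratings with parametric-bootstrap CIs
#'
#' Per method, category proportions in percent with percentile confidence
#' intervals from a parametric bootstrap: category counts are resampled from
#' a multinomial at the observed proportions.
#'
#' @param records Data frame with columns `method` and `rating` (values from
#'   [rating_levels()]), one row per rated slice.
#' @param B Number of bootstrap replicates (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return Tibble: `method`, `rating`, `n`, `pct`, `lo_pct`, `hi_pct`.
#' @export
tabulate_ratings <- function(records, B = 10000, level = 0.95, seed = 1L) {
  if (is.null(records) || nrow(records) == 0L) stop("no rating records supplied")
  bad <- setdiff(unique(records$rating), rating_levels())
  if (length(bad)) stop("unknown rating categories: ", paste(bad, collapse = ", "))
  a <- (1 - level) / 2
  with_seed(seed, function() {
    out <- lapply(split(records, records$method), function(df) {
      n <- nrow(df)
      counts <- table(factor(df$rating, levels = rating_levels()))
      phat <- as.numeric(counts) / n
      draws <- stats::rmultinom(B, n, phat) / n            # categories x B
      qs <- apply(draws, 1, stats::quantile, probs = c(a, 1 - a))
      tibble::tibble(method = df$method[1], rating = rating_levels(),
                     n = as.integer(counts), pct = 100 * phat,
                     lo_pct = 100 * qs[1, ], hi_pct = 100 * qs[2, ])
    })
    dplyr::bind_rows(out)
  })
}

#' One-way chi-square preference test
#'
#' Tests whether one method is preferred more often than the other under a
#' uniform null; slice pairs rated "equal" are excluded before calling.
#' `chi2 = sum (O - E)^2 / E` with `E = (n1 + n2) / 2`, df = 1.
#'
#' @param n_method1,n_method2 Preference counts for the two methods.
#' @return List: `chi2`, `p_value`, `df`.
#' @export
#' @examples
#' preference_chisq(30, 10)  # chi2 = 10
preference_chisq <- function(n_method1, n_method2) {
  n1 <- n_method1; n2 <- n_method2
  if (any(c(n1, n2) < 0)) stop("counts must be non-negative")
  if (n1 + n2 == 0) stop("no preference calls: n1 + n2 must be > 0")
  e <- (n1 + n2) / 2
  chi2 <- (n1 - e)^2 / e + (n2 - e)^2 / e
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)`; the linearly weighted variant uses
#' agreement weights `w_ij = 1 - |i - j| / (k - 1)` with categories taken in
#' the row/column order of `confusion`.
#'
#' @param confusion k x k count matrix (raters in rows/cols, same category
#'   order), k >= 2.
#' @param weighting `"none"` (default) or `"linear"`.
#' @return Object of class `kappa_result`: `kappa`, `weighting`, `n`,
#'   `p_o`, `p_e`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2))  # 0.4
cohen_kappa <- function(confusion, weighting = c("none", "linear")) {
  weighting <- match.arg(weighting)
  m <- as.matrix(confusion)
  k <- nrow(m)
  if (k < 2L || ncol(m) != k) stop("confusion must be a square matrix with k >= 2")
  if (any(m < 0)) stop("counts must be non-negative")
  n <- sum(m)
  if (n == 0) stop("table total must be > 0")
  p <- m / n
  w <- if (weighting == "linear") {
    1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  } else {
    diag(k)
  }
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (isTRUE(all.equal(pe, 1))) stop("kappa undefined: chance agreement is 1")
  structure(list(kappa = (po - pe) / (1 - pe), weighting = weighting,
                 n = as.integer(n), p_o = po, p_e = pe),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  strength <- cut(x$kappa, c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
                  labels = c("slight", "fair", "moderate", "substantial",
                             "almost perfect"))
  cat(sprintf("Cohen's kappa = %.3f (%s weighting, n = %d): %s agreement\n",
              x$kappa, x$weighting, x$n, strength))
  invisible(x)
}

#' Classify a slice prediction against its reference
#'
#' Per-slice presence/absence agreement: TP = finding in both, TN = in
#' neither, FP = prediction only, FN = reference only. Presence means a
#' nonempty mask for the class on that slice.
#'
#' @param pred_present,ref_present Logicals (or nonempty masks coerced with
#'   `any()`).
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
classify_slice <- function(pred_present, ref_present) {
  p <- isTRUE(any(pred_present)); g <- isTRUE(any(ref_present))
  if (p && g) "TP" else if (!p && !g) "TN" else if (p) "FP" else "FN"
}

#' Per-slice presence classification for a volume pair
#'
#' @param pred,ref [label_volume()] objects on the same grid.
#' @param class Class code or name.
#' @param case_id Optional identifier carried into the output.
#' @return Tibble: `case_id`, `slice`, `classification`.
#' @export
classify_slices <- function(pred, ref, class = "scar", case_id = NA_character_) {
  if (!identical(dim(pred$labels), dim(ref$labels)))
    stop("pred and ref must share the same grid")
  code <- resolve_class(class)
  n <- dim(pred$labels)[1]
  cls <- vapply(seq_len(n), function(s) {
    classify_slice(any(pred$labels[s, , ] == code),
                   any(ref$labels[s, , ] == code))
  }, character(1))
  tibble::tibble(case_id = case_id, slice = seq_len(n), classification = cls)
}

#' Build a 2x2 table from per-case presence calls
#'
#' @param pred_present,ref_present Logical vectors (one element per case).
#' @return A [contingency_2x2()].
#' @export
presence_table <- function(pred_present, ref_present) {
  if (length(pred_present) != length(ref_present)) stop("length mismatch")
  contingency_2x2(tp = sum(pred_present & ref_present),
                  fp = sum(pred_present & !ref_present),
                  fn = sum(!pred_present & ref_present),
                  tn = sum(!pred_present & !ref_present))
}
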