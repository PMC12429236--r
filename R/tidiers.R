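# broom-style tidiers for the statistics result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy Lin's concordance result
#'
#' @param x A `lin_ccc` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `n`.
#' @export
tidy.lin_ccc <- function(x, ...) {
  tibble::tibble(term = "rho_c", estimate = x$rho_c,
                 conf.low = x$ci95[1], conf.high = x$ci95[2], n = x$n)
}

#' @rdname tidy.lin_ccc
#' @export
glance.lin_ccc <- function(x, ...) tidy.lin_ccc(x)

#' Tidy a Bland-Altman result
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return One-row tibble: `bias`, `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_lower = x$loa[1], loa_upper = x$loa[2],
                 sd_diff = x$sd_diff, n = x$n)
}

#' Tidy a Cohen's kappa result
#'
#' @param x A `kappa_result` object.
#' @param ... Unused.
#' @return One-row tibble: `kappa`, `weighting`, `p_o`, `p_e`, `n`.
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, weighting = x$weighting,
                 p_o = x$p_o, p_e = x$p_e, n = x$n)
}

#' Tidy a 2x2 contingency table
#'
#' @param x A `contingency_2x2` object.
#' @param ... Passed to [sens_spec()].
#' @return The [sens_spec()] tibble.
#' @export
tidy.contingency_2x2 <- function(x, ...) sens_spec(x, ...)
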