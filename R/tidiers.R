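# broom-style tidiers for the comparison objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group comparison table
#'
#' One row per metric and cohort with median, IQR bounds and the shared
#' two-sided Mann-Whitney p-value.
#'
#' @param x \code{group_comparison}.
#' @param ... unused.
#' @return a long tibble: metric, group, median, iqr_lo, iqr_hi, p_value.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(metric = x$metric, group = "A", median = x$median_A,
                   iqr_lo = x$iqr_lo_A, iqr_hi = x$iqr_hi_A,
                   p_value = x$p_value),
    tibble::tibble(metric = x$metric, group = "B", median = x$median_B,
                   iqr_lo = x$iqr_lo_B, iqr_hi = x$iqr_hi_B,
                   p_value = x$p_value)
  )
}

#' Tidy a p-value map
#'
#' @param x \code{pvalue_map}.
#' @param ... unused.
#' @return tibble of testable locations: location, p, direction,
#'   significant.
#' @export
tidy.pvalue_map <- function(x, ...) {
  tibble::as_tibble(x[!is.na(x$p), ])
}

#' One-row summary of a p-value map
#'
#' @param x \code{pvalue_map}.
#' @param ... unused.
#' @return tibble: alpha, n_testable, percent significant per direction.
#' @export
glance.pvalue_map <- function(x, ...) {
  fr <- attr(x, "fractions")
  tibble::tibble(
    alpha = attr(x, "alpha"),
    n_testable = attr(x, "n_testable"),
    percent_b_higher = fr$percent[fr$direction == 1],
    percent_a_higher = fr$percent[fr$direction == -1]
  )
}
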