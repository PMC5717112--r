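# Rank-based two-sample comparisons: the Mann-Whitney U test (exact by the
# null permutation distribution for small tie-free samples, tie-corrected
# normal approximation otherwise), per-location p-value maps over a shared
# geometry, significance fractions, and the conventional group-summary
# table.

#' Mann-Whitney U test
#'
#' U is computed by rank summation with midranks for ties. For tie-free
#' samples with \code{length(x) + length(y) <= exact_max} the two-sided p
#' comes from the exact null permutation distribution of U; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. When all pooled values are identical the test is degenerate and
#' p = 1 is returned with \code{flagged = TRUE}.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exact_max largest pooled size for the exact path.
#' @return list: \code{U} (statistic of \code{x}), \code{p} (two-sided),
#'   \code{direction} (+1 if median(y) > median(x), -1 if smaller, 0 on
#'   tie), \code{method}, \code{flagged}.
#' @export
mann_whitney_u <- function(x, y, exact_max = 16) {
  m <- length(x)
  n <- length(y)
  if (m < 1 || n < 1) stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  dir <- sign(stats::median(y) - stats::median(x))

  if (all(pooled == pooled[1])) {
    return(list(U = U, p = 1, direction = 0, method = "degenerate",
                flagged = TRUE))
  }
  if (!has_ties && (m + n) <= exact_max) {
    p <- 2 * min(stats::pwilcox(U, m, n),
                 1 - stats::pwilcox(U - 1, m, n))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- m * n / 2
    N <- m + n
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      return(list(U = U, p = 1, direction = 0, method = "degenerate",
                  flagged = TRUE))
    }
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approx"
  }
  list(U = U, p = p, direction = dir, method = method, flagged = FALSE)
}

#' Per-location p-value map between two cohorts
#'
#' Runs \code{\link{mann_whitney_u}} at every shared location where both
#' cohorts have at least \code{min_n} non-missing values. No
#' multiple-testing correction is applied by default; set \code{fdr} to
#' adjust p-values by Benjamini-Hochberg.
#'
#' @param cohortA,cohortB \code{cohort_map} objects on one shared geometry
#'   (A is the reference cohort; direction +1 means B larger).
#' @param alpha significance level.
#' @param min_n minimum per-cohort sample size per location.
#' @param fdr apply Benjamini-Hochberg adjustment over testable locations.
#' @return tibble of class \code{pvalue_map}: location, p, direction,
#'   significant; attributes alpha, n_testable, fractions (from
#'   \code{\link{significance_fractions}}).
#' @export
pvalue_map <- function(cohortA, cohortB, alpha = 0.05, min_n = 7,
                       fdr = FALSE) {
  stopifnot(nrow(cohortA$values) == nrow(cohortB$values))
  nloc <- nrow(cohortA$values)
  nA <- rowSums(!is.na(cohortA$values))
  nB <- rowSums(!is.na(cohortB$values))
  testable <- nA >= min_n & nB >= min_n
  if (!any(testable)) stop("no testable locations", call. = FALSE)
  p <- rep(NA_real_, nloc)
  dir <- rep(NA_real_, nloc)
  for (i in which(testable)) {
    a <- cohortA$values[i, ]
    b <- cohortB$values[i, ]
    res <- mann_whitney_u(a[!is.na(a)], b[!is.na(b)])
    p[i] <- res$p
    dir[i] <- res$direction
  }
  if (fdr) p[testable] <- stats::p.adjust(p[testable], method = "BH")
  out <- tibble::tibble(
    location = seq_len(nloc),
    p = p,
    direction = dir,
    significant = !is.na(p) & p < alpha
  )
  attr(out, "alpha") <- alpha
  attr(out, "min_n") <- min_n
  attr(out, "n_testable") <- sum(testable)
  class(out) <- unique(c("pvalue_map", class(out)))
  attr(out, "fractions") <- significance_fractions(out)
  out
}

#' Significance fractions of a p-value map
#'
#' Percentage of testable locations significant in each direction:
#' direction +1 (cohort B larger) and -1 (cohort A larger). For velocity
#' and energy loss maps the locations are voxels (percent of volume); for
#' WSS they are wall points (percent of wall surface).
#'
#' @param pmap \code{pvalue_map}.
#' @return tibble: direction (+1 / -1), n_significant, percent.
#' @export
significance_fractions <- function(pmap) {
  testable <- !is.na(pmap$p)
  n_tot <- sum(testable)
  pos <- sum(pmap$significant & pmap$direction > 0, na.rm = TRUE)
  neg <- sum(pmap$significant & pmap$direction < 0, na.rm = TRUE)
  tibble::tibble(
    direction = c(1, -1),
    n_significant = c(pos, neg),
    percent = if (n_tot > 0) 100 * c(pos, neg) / n_tot else c(0, 0)
  )
}

#' Conventional group comparison of haemodynamic summaries
#'
#' Per metric: median and interquartile range per cohort and the two-sided
#' Mann-Whitney p-value, in the layout of a clinical summary table.
#'
#' @param groupA,groupB tibbles of per-subject summaries (rows = subjects)
#'   as produced by \code{\link{summarize_hemodynamics}}.
#' @param metrics columns to compare.
#' @return tibble of class \code{group_comparison}: metric, median_A,
#'   iqr_lo_A, iqr_hi_A, median_B, iqr_lo_B, iqr_hi_B, p_value.
#' @export
compare_group_summaries <- function(groupA, groupB,
                                    metrics = c("peak_velocity", "mean_velocity",
                                                "mean_wss", "energy_loss")) {
  if (nrow(groupA) < 2 || nrow(groupB) < 2) {
    stop("need at least two subjects per group", call. = FALSE)
  }
  metrics <- intersect(metrics, intersect(names(groupA), names(groupB)))
  rows <- lapply(metrics, function(mname) {
    a <- groupA[[mname]]
    b <- groupB[[mname]]
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    res <- mann_whitney_u(a, b)
    tibble::tibble(
      metric = mname,
      median_A = qa[2], iqr_lo_A = qa[1], iqr_hi_A = qa[3],
      median_B = qb[2], iqr_lo_B = qb[1], iqr_hi_B = qb[3],
      p_value = res$p
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("group_comparison", class(out)))
  out
}
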