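# Two-group statistical layer: normality-routed comparison (Student's t vs
# Mann-Whitney U), mean +/- SEM summaries, and immunoblot normalization
# arithmetic.

#' Summarize a sample as mean, SEM and n
#'
#' SEM uses the n-1 denominator sample standard deviation.  A single value
#' has an undefined SEM.
#'
#' @param values Numeric vector (NAs dropped).
#' @return A list: \code{mean}, \code{sem}, \code{n}.
#' @examples
#' summarize_sample(c(2, 4, 6))  # mean 4, sem 1.1547
#' @export
summarize_sample <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Normality-routed two-group comparison
#'
#' Assesses normality of each group (Shapiro-Wilk at \code{alpha_normality};
#' groups too small for the test, n < 3, or constant groups are treated as
#' non-normal).  When both groups pass, the comparison is a two-tailed
#' unpaired Student's t-test (pooled variance); otherwise a two-sided
#' Mann-Whitney U test, exact for small untied samples and
#' normal-approximated with tie correction otherwise.  The route taken is
#' recorded in the result.  Two identical constant groups are degenerate and
#' reported with p = 1.
#'
#' @param a,b Numeric vectors (NAs dropped).
#' @param labels Character vector of two group labels.
#' @param alpha_normality Significance level of the per-group normality
#'   screen (default 0.05).
#' @return A list of class \code{icp_comparison}: \code{test} ("t-test" or
#'   "mann-whitney"), \code{statistic}, \code{p}, \code{summary_a},
#'   \code{summary_b}, \code{normal_a}, \code{normal_b}, \code{degenerate}.
#' @export
route_and_compare <- function(a, b, labels = c("a", "b"),
                              alpha_normality = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1 || length(b) < 1)
    stop("route_and_compare: both groups need at least one value")
  sa <- summarize_sample(a); sb <- summarize_sample(b)
  is_normal <- function(x) {
    if (length(x) < 3 || length(unique(x)) == 1) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha_normality
  }
  degenerate <- length(unique(c(a, b))) == 1
  out <- list(labels = labels, summary_a = sa, summary_b = sb,
              normal_a = is_normal(a), normal_b = is_normal(b),
              degenerate = degenerate)
  if (degenerate) {
    out$test <- "degenerate"; out$statistic <- 0; out$p <- 1
    class(out) <- "icp_comparison"
    return(out)
  }
  if (out$normal_a && out$normal_b && length(a) >= 2 && length(b) >= 2) {
    tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
    out$test <- "t-test"
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided"))
    out$test <- "mann-whitney"
    out$statistic <- unname(wt$statistic)
    out$p <- wt$p.value
  }
  class(out) <- "icp_comparison"
  out
}

#' @export
print.icp_comparison <- function(x, ...) {
  fmt <- function(s) sprintf("%.3g +/- %.3g (n = %d)", s$mean, s$sem, s$n)
  cat(sprintf("%s: %s vs %s: %s | %s, statistic %.4g, p = %.4g\n",
              paste(x$labels, collapse = " vs "),
              fmt(x$summary_a), x$labels[2], fmt(x$summary_b),
              x$test, x$statistic, x$p))
  invisible(x)
}

#' Immunoblot densitometry normalization
#'
#' Each lane's integrated density is divided by its loading-control density,
#' and that ratio divided by the mean ratio over control lanes.  Control
#' outputs therefore average exactly 1.  Lanes with zero loading-control
#' density are excluded with a warning.
#'
#' @param density Per-lane integrated density of the target band.
#' @param loading_control Per-lane loading-control (e.g. tubulin) density.
#' @param is_control Logical per lane; must select a non-empty control group.
#' @return Numeric vector of normalized densities (NA for excluded lanes).
#' @export
normalize_densitometry <- function(density, loading_control, is_control) {
  stopifnot(length(density) == length(loading_control),
            length(density) == length(is_control))
  ok <- loading_control != 0
  if (!all(ok))
    warning(sum(!ok), " lane(s) with zero loading-control density excluded")
  ratio <- ifelse(ok, density / loading_control, NA_real_)
  ctrl <- ratio[is_control & ok]
  if (length(ctrl) == 0)
    stop("normalize_densitometry: no usable control lanes")
  ratio / mean(ctrl)
}
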