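#' Nonparametric two-group comparison
#'
#' Cohort comparisons of per-subject Ka values or frequencies: the
#' Mann-Whitney (Wilcoxon rank-sum) test for unpaired designs and the
#' Wilcoxon signed-rank test for paired (within-subject, across-timepoint)
#' designs. Exact p-values are used for small samples (group sizes below
#' `exact_n`) without ties; otherwise the normal approximation with tie and
#' continuity correction. Two-sided by default; no multiple-testing
#' correction is applied (comparisons are reported per test) — pass the
#' resulting p-values to [stats::p.adjust()] if a family-wise correction is
#' wanted.
#'
#' @param x,y Numeric vectors: the two groups (unpaired) or the two
#'   timepoints in subject order (paired).
#' @param paired Paired (signed-rank) or unpaired (rank-sum) design.
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @param exact_n Largest sample size for which the exact distribution is
#'   used (when there are no ties).
#' @return An object of class `comparison_result`: test name, statistic,
#'   p-value, group sizes, direction (sign of the median difference).
#' @export
#' @examples
#' compare_groups(c(5, 6, 7, 9), c(1, 2, 3, 4))$p_value
compare_groups <- function(x, y, paired = FALSE,
                           alternative = c("two.sided", "less", "greater"),
                           exact_n = 25) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), is.numeric(y))
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired design requires equal-length vectors", call. = FALSE)
    }
    if (anyNA(x) || anyNA(y)) stop("paired design has incomplete pairs", call. = FALSE)
    if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      stop("need at least 2 observations per group", call. = FALSE)
    }
  }
  exact <- max(length(x), length(y)) < exact_n
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  direction <- if (paired) sign(stats::median(x - y)) else
    sign(stats::median(x) - stats::median(y))
  structure(list(test = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = c(x = length(x), y = length(y)),
                 alternative = alternative, direction = direction,
                 method_detail = wt$method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$test, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (!is.null(x$estimate)) sprintf(", rho = %.3f", x$estimate) else ""))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(test = x$test, statistic = x$statistic, p_value = x$p_value,
             n_x = x$n[[1]], n_y = x$n[[2]],
             estimate = if (is.null(x$estimate)) NA_real_ else x$estimate,
             alternative = x$alternative,
             direction = if (is.null(x$direction)) NA_real_ else x$direction,
             stringsAsFactors = FALSE)
}

#' Tie-corrected Spearman correlation
#'
#' Nonparametric Spearman rank correlation with p-value (exact for small
#' tie-free samples, asymptotic with tie correction otherwise). A constant
#' input vector yields a flagged undefined result with a warning rather than
#' an error.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return A `comparison_result` with `estimate` = rho.
#' @export
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
spearman_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman correlation undefined", call. = FALSE)
    res <- list(test = "Spearman", statistic = NA_real_, p_value = NA_real_,
                n = c(x = length(x), y = length(y)),
                alternative = "two.sided", direction = NA_real_,
                estimate = NA_real_, defined = FALSE)
    class(res) <- "comparison_result"
    return(res)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(test = "Spearman", statistic = unname(ct$statistic),
                 p_value = ct$p.value, n = c(x = length(x), y = length(y)),
                 alternative = "two.sided", direction = sign(unname(ct$estimate)),
                 estimate = unname(ct$estimate), defined = TRUE),
            class = "comparison_result")
}
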