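#' Association constant of T cell:monocyte complex formation
#'
#' Computes the mass-action association constant
#' `Ka = f_complex / (f_T * f_M)` from three population frequencies measured
#' on a common denominator population (by convention the live non-complex
#' singlet events). Ka corrects the raw complex frequency for the abundance
#' of the two partner populations, by analogy with a chemical association
#' constant.
#'
#' A zero `f_T` or `f_M` yields a flagged undefined result (`ka = NA`,
#' `defined = FALSE`) rather than an error, so cohort runs proceed and
#' undefined values can be excluded pairwise downstream.
#'
#' @param f_complex Complex frequency (fraction of the denominator).
#' @param f_T Singlet T-cell frequency.
#' @param f_M Singlet monocyte frequency.
#' @param subset Subset label (`"all"`, `"CD4"`, `"CD8"`, `"DNEG"`, `"DPOS"`).
#' @param subject_id Optional subject identifier carried into the result.
#' @param denominator Name of the denominator population.
#' @return An object of class `ka_result`: the three input frequencies, `ka`,
#'   a `defined` flag, and the labels.
#' @export
#' @examples
#' compute_ka(0.001, 0.4, 0.1)  # Ka = 0.025
compute_ka <- function(f_complex, f_T, f_M, subset = "all",
                       subject_id = NA_character_,
                       denominator = "live_singlets") {
  for (v in list(f_complex, f_T, f_M)) {
    stopifnot(length(v) == 1L, is.numeric(v), !is.na(v), v >= 0, v <= 1)
  }
  defined <- f_T > 0 && f_M > 0
  ka <- if (defined) f_complex / (f_T * f_M) else NA_real_
  structure(list(subject_id = subject_id, subset = subset,
                 f_complex = f_complex, f_T = f_T, f_M = f_M,
                 ka = ka, defined = defined, denominator = denominator),
            class = "ka_result")
}

#' @export
print.ka_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<ka_result> subset %s: Ka = %.4g (f_complex = %.4g, f_T = %.4g, f_M = %.4g)\n",
                x$subset, x$ka, x$f_complex, x$f_T, x$f_M))
  } else {
    cat(sprintf("<ka_result> subset %s: undefined (f_T = %.4g, f_M = %.4g)\n",
                x$subset, x$f_T, x$f_M))
  }
  invisible(x)
}

#' @export
as.data.frame.ka_result <- function(x, ...) {
  data.frame(subject_id = x$subject_id, subset = x$subset,
             f_complex = x$f_complex, f_T = x$f_T, f_M = x$f_M,
             ka = x$ka, defined = x$defined, denominator = x$denominator,
             stringsAsFactors = FALSE)
}

#' Association constant from a gated acquisition
#'
#' Applies the Ka estimator to the population counts of a [tm_strategy()]
#' gating result. All frequencies share one denominator:
#' the live singlet event count with complex events excluded (the default;
#' `include_complexes = TRUE` keeps them in), so that `f_T` and `f_M` are
#' singlet-only frequencies matching the generative mass-action model.
#'
#' For the global estimate (`subset = "all"`), CD3+CD14mid (`debrisT`) events
#' are counted into `f_T` by default since they are single T cells carrying
#' monocyte debris; subset estimates use the CD3+CD14- subset quadrants,
#' where debris-bound cells are not subset-resolved.
#'
#' @param result A `gating_result` from [apply_strategy()] with the
#'   [tm_strategy()] populations.
#' @param subset `"all"` or one of `"CD4"`, `"CD8"`, `"DNEG"`, `"DPOS"`.
#' @param subject_id Optional subject identifier.
#' @param include_debris_t Count CD14mid debris-bound T cells into the global
#'   `f_T` (default `TRUE`).
#' @param include_complexes Keep complex events in the denominator (default
#'   `FALSE`).
#' @return A [compute_ka()] result.
#' @export
ka_from_gating <- function(result, subset = "all", subject_id = NA_character_,
                           include_debris_t = TRUE, include_complexes = FALSE) {
  stopifnot(inherits(result, "gating_result"))
  need <- function(p) {
    if (!p %in% result$frequencies$population) {
      stop(sprintf("required population '%s' missing from gating result", p),
           call. = FALSE)
    }
    population_count(result, p)
  }
  n_complex_all <- need("complexes")
  D <- need("singlet") - if (include_complexes) 0L else n_complex_all
  if (D <= 0) {
    return(compute_ka(0, 0, 0, subset = subset, subject_id = subject_id))
  }
  n_M <- need("M")
  if (subset == "all") {
    n_T <- need("T") + if (include_debris_t) need("debrisT") else 0L
    n_complex <- n_complex_all
  } else {
    subset <- match.arg(subset, c("CD4", "CD8", "DNEG", "DPOS"))
    n_T <- need(paste0(subset, "T"))
    n_complex <- need(paste0(subset, "complex"))
  }
  compute_ka(n_complex / D, n_T / D, n_M / D, subset = subset,
             subject_id = subject_id,
             denominator = if (include_complexes) "live_singlet_events"
             else "live_singlets")
}

#' Per-subset Ka table for one acquisition
#'
#' @param result A `gating_result` over the [tm_strategy()] populations.
#' @param subject_id Optional subject identifier.
#' @param ... Passed to [ka_from_gating()].
#' @return Data frame with one row per subset (`all`, `CD4`, `CD8`, `DNEG`,
#'   `DPOS`).
#' @export
ka_table <- function(result, subject_id = NA_character_, ...) {
  subsets <- c("all", "CD4", "CD8", "DNEG", "DPOS")
  do.call(rbind, lapply(subsets, function(s) {
    as.data.frame(ka_from_gating(result, subset = s, subject_id = subject_id, ...))
  }))
}

#' Worked percentage of a count pair
#'
#' Expresses `k` of `n` as a whole percentage, rounded half-up, retaining the
#' exact fraction (e.g. 30 of 105 doublets with polarized adhesion markers is
#' 29%).
#'
#' @param k Numerator count, `0 <= k <= n`.
#' @param n Denominator count, `> 0`.
#' @return List with `percent` (integer), `k`, `n` and the exact `fraction`.
#' @export
#' @examples
#' proportion_percent(30, 105)$percent  # 29
proportion_percent <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L, n > 0, k >= 0, k <= n,
            k == round(k), n == round(n))
  structure(list(percent = as.integer(round_half_up(100 * k / n)),
                 k = as.integer(k), n = as.integer(n), fraction = k / n),
            class = "proportion_percent")
}

#' @export
print.proportion_percent <- function(x, ...) {
  cat(sprintf("%d of %d = %d%% (exact %.4f)\n", x$k, x$n, x$percent, x$fraction))
  invisible(x)
}
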