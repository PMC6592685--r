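#' Arcsinh display transform
#'
#' The standard cytometry display transform `asinh(x / cofactor)`. Gate
#' geometry on fluorescence channels is interpreted on this scale by default
#' (cofactor 150); scatter gates use the identity transform.
#'
#' @param x Numeric vector of raw channel intensities.
#' @param cofactor Positive scale factor; values well below the cofactor are
#'   close to linear, values well above close to logarithmic.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' arcsinh_trans(c(0, 150, 1500))
arcsinh_trans <- function(x, cofactor = 150) {
  stopifnot(is.numeric(cofactor), length(cofactor) == 1L, cofactor > 0)
  asinh(x / cofactor)
}

# Resolve a transform spec into a vectorized function.
# Spec forms: NULL / "identity", "log10", "asinh" (default cofactor 150),
# or list(type =, cofactor =).
resolve_transform <- function(spec) {
  if (is.null(spec)) spec <- "identity"
  if (is.character(spec)) spec <- list(type = spec)
  type <- match.arg(spec$type, c("identity", "log10", "asinh"))
  switch(type,
    identity = identity,
    log10 = function(x) log10(x),
    asinh = {
      cof <- if (is.null(spec$cofactor)) 150 else spec$cofactor
      function(x) asinh(x / cof)
    }
  )
}

# Per-channel transform lookup for a gate: `transform` may be NULL (identity
# everywhere), a single spec applied to all channels, or a named list.
channel_transform <- function(transform, channel) {
  if (is.null(transform)) return(identity)
  if (!is.null(names(transform)) && channel %in% names(transform)) {
    return(resolve_transform(transform[[channel]]))
  }
  if (is.list(transform) && is.null(transform$type) && is.null(names(transform))) {
    stop("unnamed list transform must name its channels", call. = FALSE)
  }
  if (!is.null(names(transform)) && !is.null(transform$type)) {
    return(resolve_transform(transform))
  }
  if (is.character(transform)) return(resolve_transform(transform))
  identity
}

#' Rank-based area under the ROC curve
#'
#' AUC of a continuous score for a binary ground truth, computed from the
#' Mann-Whitney rank identity: the probability that a random positive scores
#' higher than a random negative (ties count 1/2).
#'
#' @param score Numeric score, higher = more doublet-like / positive.
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  keep <- is.finite(score) & !is.na(positive)
  score <- score[keep]; positive <- positive[keep]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# round-half-up to integer (base round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

# small helper: named list -> data.frame row-bind with consistent columns
rbind_fill <- function(lst) do.call(rbind, lst)
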