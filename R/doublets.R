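#' Imaging-flow doublet score
#'
#' Per-event brightfield doublet score `bf_area / bf_aspect_ratio`. Doublets
#' present a larger projected area and a reduced aspect ratio than single
#' cells, so their area-to-aspect-ratio ratio is greater; the score is
#' monotone increasing in area and decreasing in aspect ratio. (Some figure
#' legends phrase the quantity as "aspect ratio vs area"; the implemented
#' direction follows the stated inequality — greater for doublets.)
#'
#' @param table An [event_table()] with `bf_area` and `bf_aspect_ratio`.
#' @return Object of class `doublet_score`: numeric scores named by
#'   `event_id`.
#' @export
doublet_score <- function(table) {
  stopifnot(inherits(table, "event_table"))
  missing <- setdiff(c("bf_area", "bf_aspect_ratio"), names(table))
  if (length(missing)) {
    stop(sprintf("imaging channel '%s' missing; doublet score undefined", missing[1]),
         call. = FALSE)
  }
  s <- table$bf_area / table$bf_aspect_ratio
  structure(stats::setNames(s, table$event_id), class = "doublet_score")
}

#' @export
print.doublet_score <- function(x, ...) {
  cat(sprintf("<doublet_score> %d events, median %.3g [%.3g, %.3g]\n",
              length(x), stats::median(unclass(x)),
              min(unclass(x)), max(unclass(x))))
  invisible(x)
}

#' Calibrate the doublet-gate threshold by Youden's J
#'
#' Chooses the score cutoff maximizing sensitivity + specificity - 1 against
#' a binary truth (from simulated calibration data with truth labels).
#'
#' @param scores A [doublet_score()] (or numeric vector).
#' @param truth_doublet Logical vector, `TRUE` for true doublets.
#' @return The threshold (numeric scalar) with attributes `sensitivity` and
#'   `specificity` at the optimum.
#' @export
youden_threshold <- function(scores, truth_doublet) {
  s <- as.numeric(scores)
  stopifnot(length(s) == length(truth_doublet), is.logical(truth_doublet))
  stopifnot(any(truth_doublet), any(!truth_doublet))
  o <- order(s)
  s_sorted <- s[o]; lab <- truth_doublet[o]
  n1 <- sum(lab); n0 <- sum(!lab)
  # candidate thresholds: each observed score (classify score >= t as doublet)
  tp <- n1 - cumsum(lab) + lab          # positives with score >= s_sorted[i]
  tn <- cumsum(!lab) - !lab             # negatives with score <  s_sorted[i]
  j <- tp / n1 + tn / n0 - 1
  i <- which.max(j)
  structure(s_sorted[i], sensitivity = tp[i] / n1, specificity = tn[i] / n0)
}

#' Classify events as doublets by score threshold
#'
#' Labels an event a doublet when its score is at or above the threshold.
#' When `threshold` is omitted it is calibrated by [youden_threshold()]
#' against the supplied truth; the threshold used is recorded in the result's
#' attributes (provenance).
#'
#' @param scores A [doublet_score()].
#' @param threshold Score cutoff; `NULL` to calibrate from `truth_doublet`.
#' @param truth_doublet Logical truth, required only for calibration.
#' @return Logical vector (`TRUE` = doublet) with attribute `threshold`.
#' @export
classify_doublets <- function(scores, threshold = NULL, truth_doublet = NULL) {
  s <- as.numeric(scores)
  if (is.null(threshold)) {
    if (is.null(truth_doublet)) {
      stop("supply a threshold or truth labels to calibrate one", call. = FALSE)
    }
    threshold <- youden_threshold(s, truth_doublet)
  }
  structure(s >= as.numeric(threshold), threshold = as.numeric(threshold),
            names = names(scores))
}

#' Screen axis-aligned scatter gates for doublet discrimination
#'
#' Exhaustively scores rectangular gates over every 2D combination of the six
#' scatter pulse channels (`{FSC,SSC} x {A,H,W}`), with gate boundaries on a
#' per-channel quantile grid, as binary doublet classifiers: each gate's AUC
#' is its balanced accuracy `(sensitivity + specificity) / 2` for separating
#' a positive truth class from a reference class. Used to demonstrate that no
#' conventional pulse-geometry gate separates T cell:monocyte complexes from
#' the monocyte singlets they resemble, while the brightfield score does.
#'
#' @param table Simulated [event_table()] with `truth_label`.
#' @param positive Predicate on truth labels for the positive class (default
#'   complexes).
#' @param reference Predicate for the reference class (default monocyte
#'   singlets).
#' @param n_breaks Number of interior quantile breakpoints per channel.
#' @return List: `max_auc`, `best` (channel pair and bounds of the best
#'   gate), `by_pair` (data frame of best AUC per channel pair), `n_pos`,
#'   `n_ref`.
#' @export
scatter_gate_screen <- function(table,
                                positive = function(l) startsWith(l, "complex:"),
                                reference = function(l) l == "singlet:mono",
                                n_breaks = 6) {
  stopifnot(inherits(table, "event_table"), "truth_label" %in% names(table))
  chans <- c("FSC_A", "FSC_H", "FSC_W", "SSC_A", "SSC_H", "SSC_W")
  stopifnot(all(chans %in% names(table)))
  pos <- positive(table$truth_label)
  ref <- reference(table$truth_label)
  keep <- pos | ref
  n1 <- sum(pos); n0 <- sum(ref)
  stopifnot(n1 > 0, n0 > 0)
  pairs <- utils::combn(chans, 2)
  best <- list(auc = -Inf)
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    cx <- pairs[1, p]; cy <- pairs[2, p]
    x <- table[[cx]][keep]; y <- table[[cy]][keep]
    ispos <- pos[keep]
    bx <- c(-Inf, stats::quantile(x, probs = seq_len(n_breaks) / (n_breaks + 1),
                                  names = FALSE), Inf)
    by <- c(-Inf, stats::quantile(y, probs = seq_len(n_breaks) / (n_breaks + 1),
                                  names = FALSE), Inf)
    ix <- findInterval(x, bx, left.open = FALSE)  # bin index per event
    iy <- findInterval(y, by, left.open = FALSE)
    nb <- n_breaks + 1L
    # 2D bin counts for each class, then 2D cumulative sums => O(1) per gate
    cnt_pos <- matrix(tabulate(((iy - 1L) * nb + ix)[ispos], nbins = nb * nb), nb, nb)
    cnt_ref <- matrix(tabulate(((iy - 1L) * nb + ix)[!ispos], nbins = nb * nb), nb, nb)
    cum2 <- function(m) apply(apply(m, 2, cumsum), 1, cumsum)  # returns t(cumsum2)
    P <- cum2(cnt_pos); R <- cum2(cnt_ref)  # P[j, i] = sum over x-bins<=i, y-bins<=j
    pad <- function(m) rbind(0, cbind(0, m))
    P <- pad(P); R <- pad(R)
    rect_count <- function(M, i1, i2, j1, j2) {
      M[j2 + 1L, i2 + 1L] - M[j1, i2 + 1L] - M[j2 + 1L, i1] + M[j1, i1]
    }
    pair_best <- -Inf; pair_gate <- NULL
    for (i1 in 1:nb) for (i2 in i1:nb) for (j1 in 1:nb) for (j2 in j1:nb) {
      tp <- rect_count(P, i1, i2, j1, j2) / n1
      fp <- rect_count(R, i1, i2, j1, j2) / n0
      auc <- (tp + 1 - fp) / 2
      auc <- max(auc, 1 - auc)  # the complementary gate is also available
      if (auc > pair_best) {
        pair_best <- auc
        pair_gate <- list(channels = c(cx, cy),
                          xlim = c(bx[i1], bx[i2 + 1L]), ylim = c(by[j1], by[j2 + 1L]))
      }
    }
    rows[[p]] <- data.frame(ch_x = cx, ch_y = cy, auc = pair_best,
                            stringsAsFactors = FALSE)
    if (pair_best > best$auc) best <- c(list(auc = pair_best), pair_gate)
  }
  list(max_auc = best$auc, best = best, by_pair = do.call(rbind, rows),
       n_pos = n1, n_ref = n0)
}
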