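#' Most variable genes
#'
#' Ranks genes by expression variability across samples and returns the top
#' `n`. The default metric is the variance of `log2(TPM + 1)` (log
#' stabilization because TPM is heavy-tailed); raw variance and the
#' coefficient of variation are available. Ties are broken by gene id
#' (C-locale lexicographic), so the ranking is deterministic.
#'
#' @param expr A [gene_expression_matrix()].
#' @param n Number of genes to return (default 100).
#' @param metric `"log2var"` (default), `"var"`, or `"cv"`.
#' @return Character vector of `n` gene ids, most variable first.
#' @export
top_variable_genes <- function(expr, n = 100, metric = c("log2var", "var", "cv")) {
  stopifnot(inherits(expr, "gene_expression_matrix"))
  metric <- match.arg(metric)
  tpm <- expr$tpm
  if (nrow(tpm) < n) {
    stop(sprintf("requested %d genes but matrix has %d", n, nrow(tpm)), call. = FALSE)
  }
  if (ncol(tpm) < 3L) stop("need >= 3 samples", call. = FALSE)
  v <- switch(metric,
    log2var = apply(log2(tpm + 1), 1, stats::var),
    var = apply(tpm, 1, stats::var),
    cv = apply(tpm, 1, function(r) stats::sd(r) / mean(r))
  )
  ord <- order(-v, rownames(tpm), method = "radix")
  rownames(tpm)[ord][seq_len(n)]
}

# mean off-diagonal of a correlation submatrix
mean_offdiag <- function(m) {
  k <- nrow(m)
  if (k < 2L) return(NA_real_)
  (sum(m) - k) / (k * (k - 1))
}

#' Extract the tightly co-expressed gene module
#'
#' Reconstructs the co-expression module discovery step: average-linkage
#' hierarchical clustering of the candidate (most-variable) genes on the
#' distance `1 - Spearman rho` of their `log2(TPM + 1)` profiles; clusters
#' are the branches obtained by cutting the tree at height `1 - rho_min`
#' (so a cluster's average linkage correlation is at least `rho_min` when it
#' forms), and the module is the largest such cluster whose mean
#' intra-cluster pairwise rho is at least `rho_min` (ties broken by higher
#' mean rho). Cutting at the threshold height prevents weakly correlated
#' genes from free-riding on a strong block, which a qualification on the
#' mean alone would allow. When contaminating monocytes drive a coherent
#' block of monocyte genes, that block is the selected module; on
#' unstructured data no cluster qualifies and an empty, flagged module is
#' returned.
#'
#' @param expr A [gene_expression_matrix()].
#' @param genes Candidate gene ids (typically from [top_variable_genes()]).
#' @param rho_min Minimum mean intra-module Spearman correlation (default
#'   0.6).
#' @return Object of class `coexpression_module`: `genes`, `mean_rho`,
#'   `qualified` flag and the extraction parameters.
#' @export
extract_coexpression_module <- function(expr, genes, rho_min = 0.6) {
  stopifnot(inherits(expr, "gene_expression_matrix"), length(genes) >= 2)
  missing <- setdiff(genes, rownames(expr$tpm))
  if (length(missing)) stop(sprintf("gene '%s' not in matrix", missing[1]), call. = FALSE)
  lx <- log2(expr$tpm[genes, , drop = FALSE] + 1)
  const <- apply(lx, 1, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("excluding %d constant gene(s) before correlation", sum(const)),
            call. = FALSE)
    lx <- lx[!const, , drop = FALSE]
  }
  empty <- structure(list(genes = character(0), mean_rho = NA_real_,
                          qualified = FALSE,
                          params = list(n_candidates = length(genes),
                                        rho_min = rho_min, linkage = "average")),
                     class = "coexpression_module")
  if (nrow(lx) < 2L) return(empty)
  rho <- stats::cor(t(lx), method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  cl <- stats::cutree(hc, h = 1 - rho_min)
  best <- NULL
  for (k in unique(cl)) {
    idx <- which(cl == k)
    if (length(idx) < 2L) next
    mr <- mean_offdiag(rho[idx, idx, drop = FALSE])
    if (mr >= rho_min) {
      if (is.null(best) || length(idx) > length(best$idx) ||
          (length(idx) == length(best$idx) && mr > best$mr)) {
        best <- list(idx = idx, mr = mr)
      }
    }
  }
  if (is.null(best)) return(empty)
  structure(list(genes = sort(rownames(lx)[best$idx]), mean_rho = best$mr,
                 qualified = TRUE,
                 params = list(n_candidates = length(genes),
                               rho_min = rho_min, linkage = "average")),
            class = "coexpression_module")
}

#' @export
print.coexpression_module <- function(x, ...) {
  if (!x$qualified) {
    cat(sprintf("<coexpression_module> no qualifying module (rho_min = %.2f, %d candidates)\n",
                x$params$rho_min, x$params$n_candidates))
  } else {
    cat(sprintf("<coexpression_module> %d genes, mean pairwise rho = %.3f\n",
                length(x$genes), x$mean_rho))
  }
  invisible(x)
}

#' Module PC1 score per sample
#'
#' Scores each sample by the first principal component of the z-scored
#' `log2(TPM + 1)` expression of the module genes — the standard module
#' eigengene. Z-scoring prevents high-abundance genes from dominating; the
#' sign is fixed so the score correlates positively with the module's mean
#' expression, and scores have zero mean over samples.
#'
#' @param expr A [gene_expression_matrix()].
#' @param module A [extract_coexpression_module()] result (or character
#'   vector of gene ids), at least 2 genes.
#' @return Object of class `module_score`: per-sample scores, the explained
#'   variance fraction of PC1, loadings and the sign convention flag.
#' @export
module_score <- function(expr, module) {
  stopifnot(inherits(expr, "gene_expression_matrix"))
  genes <- if (inherits(module, "coexpression_module")) module$genes else module
  if (length(genes) < 2L) stop("module must contain >= 2 genes", call. = FALSE)
  missing <- setdiff(genes, rownames(expr$tpm))
  if (length(missing)) stop(sprintf("gene '%s' not in matrix", missing[1]), call. = FALSE)
  lx <- t(log2(expr$tpm[genes, , drop = FALSE] + 1))   # samples x genes
  sds <- apply(lx, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant gene(s) from scoring", sum(sds == 0)),
            call. = FALSE)
    lx <- lx[, sds > 0, drop = FALSE]
    if (ncol(lx) < 2L) stop("fewer than 2 non-constant module genes", call. = FALSE)
  }
  z <- scale(lx)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  flipped <- FALSE
  if (stats::cor(scores, rowMeans(z)) < 0) {
    scores <- -scores
    flipped <- TRUE
  }
  scores <- scores - mean(scores)
  structure(list(scores = stats::setNames(scores, rownames(lx)),
                 explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2),
                 loadings = pc$rotation[, 1] * (if (flipped) -1 else 1),
                 sign_flipped = flipped, genes = colnames(lx)),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("<module_score> %d samples, %d genes, PC1 explains %.1f%% of variance\n",
              length(x$scores), length(x$genes), 100 * x$explained_variance))
  invisible(x)
}

#' Correlate the module score with the gated CD14+ fraction
#'
#' Spearman correlation between per-sample module PC1 scores and the
#' measured CD14+ event fraction of the same sorted samples — the check that
#' the transcriptomic module tracks the cytometric contamination readout.
#' Samples are matched by id; unmatched ids raise an error listing them.
#'
#' @param score A [module_score()].
#' @param freq Named numeric vector (or 2-column data frame of sample id and
#'   fraction) of per-sample CD14+ fractions.
#' @return A [spearman_cor()] result.
#' @export
correlate_score_with_gate <- function(score, freq) {
  stopifnot(inherits(score, "module_score"))
  if (is.data.frame(freq)) freq <- stats::setNames(freq[[2]], as.character(freq[[1]]))
  if (is.null(names(freq))) stop("freq must be named by sample id", call. = FALSE)
  ids <- names(score$scores)
  unmatched <- c(setdiff(ids, names(freq)), setdiff(names(freq), ids))
  if (length(unmatched)) {
    stop(sprintf("unmatched sample ids: %s", paste(unmatched, collapse = ", ")),
         call. = FALSE)
  }
  spearman_cor(score$scores, freq[ids])
}
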