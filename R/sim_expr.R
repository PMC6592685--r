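#' Gene expression matrix container
#'
#' A genes x samples matrix of TPM values with unique gene and sample
#' identifiers and optional per-sample metadata (e.g. the measured CD14+
#' event fraction of each sorted sample).
#'
#' @param tpm Numeric matrix, genes as rows (rownames = gene ids, colnames =
#'   sample ids); all values must be >= 0.
#' @param metadata Optional data frame with one row per sample.
#' @return Object of class `gene_expression_matrix`.
#' @export
gene_expression_matrix <- function(tpm, metadata = NULL) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("tpm must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(tpm))) stop("gene ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(tpm))) stop("sample ids must be unique", call. = FALSE)
  if (any(tpm < 0)) stop("TPM values must be >= 0", call. = FALSE)
  if (!is.null(metadata)) {
    stopifnot(is.data.frame(metadata), nrow(metadata) == ncol(tpm))
  }
  structure(list(tpm = tpm, metadata = metadata), class = "gene_expression_matrix")
}

#' @export
print.gene_expression_matrix <- function(x, ...) {
  cat(sprintf("<gene_expression_matrix> %d genes x %d samples%s\n",
              nrow(x$tpm), ncol(x$tpm),
              if (!is.null(x$metadata)) sprintf(" (+%d metadata fields)",
                                                ncol(x$metadata)) else ""))
  invisible(x)
}

#' @export
dim.gene_expression_matrix <- function(x) dim(x$tpm)

#' Read / write a TPM expression matrix (TSV)
#'
#' Genes as rows, samples as columns, first column the gene identifier.
#'
#' @param path TSV file path.
#' @return A [gene_expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- genes
  gene_expression_matrix(m)
}

#' @rdname read_expression_matrix
#' @param expr A [gene_expression_matrix()].
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "gene_expression_matrix"))
  out <- data.frame(gene_id = rownames(expr$tpm), expr$tpm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Configure the sorted-T-cell expression simulator
#'
#' Generates TPM matrices for sorted memory T-cell samples carrying a
#' variable planted monocyte-contamination fraction. Each sample's profile is
#' the convex mixture `(1 - c) * T_profile + c * M_profile` per gene, times
#' multiplicative log-normal noise, where `c` is the sample's contamination
#' fraction. A designated gene module (monocyte-associated genes) has a
#' monocyte profile exceeding its T-cell profile by per-gene log2 fold
#' differences, so contamination drives co-expression of exactly those genes.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param module_size Number of planted monocyte-module genes.
#' @param log2_fold Per-module-gene monocyte-vs-T log2 fold differences
#'   (recycled); default draws once from `runif(module_size, 7, 11)` at
#'   simulation time, matching canonical monocyte marker genes (CD14-, LYZ-,
#'   S100A8/9-like) whose expression exceeds T cells by two to three orders
#'   of magnitude.
#' @param baseline_meanlog,baseline_sdlog Log-normal model of per-gene
#'   baseline T-cell mean TPM.
#' @param contamination_max Contamination fractions are drawn per sample from
#'   `Uniform(0, contamination_max)`.
#' @param noise_sdlog SD (natural-log scale) of the multiplicative noise.
#' @param n_sorted_events Events per sample used to report the measured CD14+
#'   event fraction in the metadata (binomial draw around `c`).
#' @param seed Optional seed stored with the config.
#' @return Object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 200, n_samples = 59, module_size = 22,
                            log2_fold = NULL,
                            baseline_meanlog = log(10), baseline_sdlog = 1,
                            contamination_max = 0.05, noise_sdlog = 0.2,
                            n_sorted_events = 20000, seed = NULL) {
  stopifnot(n_genes >= module_size, module_size >= 2, n_samples >= 3,
            contamination_max >= 0, contamination_max <= 1, noise_sdlog >= 0)
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 module_size = as.integer(module_size), log2_fold = log2_fold,
                 baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
                 contamination_max = contamination_max, noise_sdlog = noise_sdlog,
                 n_sorted_events = as.integer(n_sorted_events), seed = seed),
            class = "expr_sim_config")
}

#' Simulate a sorted-T-cell TPM matrix with planted contamination
#'
#' See [expr_sim_config()] for the generative model. The truth contamination
#' vector is returned alongside the matrix, and the measured CD14+ event
#' fraction (a binomial measurement of `c` from the accompanying sort) is
#' placed in the sample metadata, so the full discovery procedure —
#' variable genes, co-expression module, PC1 score, correlation with the
#' gated CD14+ fraction — can be validated by parameter recovery.
#'
#' @param config An [expr_sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List: `expr` (a [gene_expression_matrix()] with `cd14_fraction`
#'   metadata), `contamination` (truth vector), `module_genes` (planted gene
#'   ids).
#' @export
simulate_expression <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "expr_sim_config"))
  run <- function() {
    G <- config$n_genes; S <- config$n_samples; K <- config$module_size
    genes <- sprintf("gene%03d", seq_len(G))
    samples <- sprintf("s%02d", seq_len(S))
    module <- genes[seq_len(K)]
    t_prof <- stats::rlnorm(G, config$baseline_meanlog, config$baseline_sdlog)
    m_prof <- t_prof
    fold <- if (is.null(config$log2_fold)) stats::runif(K, 7, 11)
            else rep_len(config$log2_fold, K)
    m_prof[seq_len(K)] <- t_prof[seq_len(K)] * 2^fold
    cvec <- stats::runif(S, 0, config$contamination_max)
    mean_expr <- outer(t_prof, 1 - cvec) + outer(m_prof, cvec)
    noise <- matrix(stats::rlnorm(G * S, 0, config$noise_sdlog), G, S)
    tpm <- mean_expr * noise
    dimnames(tpm) <- list(genes, samples)
    cd14 <- stats::rbinom(S, config$n_sorted_events, cvec) / config$n_sorted_events
    meta <- data.frame(sample_id = samples, cd14_fraction = cd14,
                       stringsAsFactors = FALSE)
    list(expr = gene_expression_matrix(tpm, metadata = meta),
         contamination = stats::setNames(cvec, samples),
         module_genes = module)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
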