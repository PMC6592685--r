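make_expr <- function(tpm) {
  dimnames(tpm) <- list(sprintf("g%03d", seq_len(nrow(tpm))),
                        sprintf("s%03d", seq_len(ncol(tpm))))
  gene_expression_matrix(tpm)
}

test_that("variable-gene ranking is deterministic and matches brute force", {
  withr::local_seed(101)
  tpm <- matrix(rlnorm(50 * 20, log(10), 0.3), 50, 20)
  tpm[7, ] <- rlnorm(20, log(10), 3)  # dominant-variance gene
  e <- make_expr(tpm)
  top <- top_variable_genes(e, 10)
  expect_identical(top[1], "g007")
  # brute-force ranking oracle
  v <- apply(log2(e$tpm + 1), 1, var)
  want <- names(sort(v, decreasing = TRUE))[1:10]
  expect_setequal(top, want)
  # n = total returns all genes; larger n errors
  expect_setequal(top_variable_genes(e, 50), rownames(e$tpm))
  expect_error(top_variable_genes(e, 51), "50")
})

test_that("a perfect module of correlated copies is recovered with rho 1", {
  withr::local_seed(102)
  latent <- rnorm(30)
  tpm <- matrix(rlnorm(10 * 30, log(50), 0.5), 10, 30)
  for (i in 1:5) tpm[i, ] <- exp(latent + i)  # exact monotone copies
  e <- make_expr(tpm)
  mod <- extract_coexpression_module(e, rownames(e$tpm), rho_min = 0.6)
  expect_setequal(mod$genes, sprintf("g%03d", 1:5))
  expect_equal(mod$mean_rho, 1)
})

test_that("independent noise yields an empty flagged module", {
  withr::local_seed(103)
  tpm <- matrix(rlnorm(100 * 100, log(10), 0.3), 100, 100)
  e <- make_expr(tpm)
  mod <- extract_coexpression_module(e, rownames(e$tpm), rho_min = 0.6)
  expect_false(mod$qualified)
  expect_length(mod$genes, 0)
})

test_that("constant genes are excluded with a warning before correlation", {
  tpm <- rbind(matrix(rlnorm(4 * 10), 4, 10), matrix(5, 1, 10))
  e <- make_expr(tpm)
  expect_warning(extract_coexpression_module(e, rownames(e$tpm)), "constant")
})

test_that("module scoring has the documented algebraic properties", {
  withr::local_seed(104)
  latent <- rnorm(25)
  # scale well above the +1 offset so log2(TPM + 1) is affine in `latent`
  tpm <- rbind(1e4 * exp(latent), 2e4 * exp(latent), matrix(rlnorm(3 * 25), 3, 25))
  e <- make_expr(tpm)
  sc <- module_score(e, c("g001", "g002"))
  expect_gt(sc$explained_variance, 0.9999)
  expect_equal(mean(sc$scores), 0)
  # sign convention: score correlates positively with mean module expression
  expect_gt(cor(sc$scores, rowMeans(scale(t(log2(e$tpm[c("g001", "g002"), ] + 1))))), 0)
  # the score is the latent coordinate up to orientation
  expect_equal(abs(cor(sc$scores, latent)), 1, tolerance = 1e-4)
  expect_error(module_score(e, "g001"), ">= 2")
})

test_that("the full discovery pipeline recovers planted contamination", {
  sim <- simulate_expression(expr_sim_config(), seed = 105)
  genes <- top_variable_genes(sim$expr, 100)
  mod <- extract_coexpression_module(sim$expr, genes)
  expect_true(mod$qualified)
  jac <- length(intersect(mod$genes, sim$module_genes)) /
    length(union(mod$genes, sim$module_genes))
  expect_gte(jac, 0.9)
  sc <- module_score(sim$expr, mod)
  rho <- spearman_cor(sc$scores, sim$contamination[names(sc$scores)])$estimate
  expect_gte(rho, 0.8)
  # and the score tracks the cytometric CD14+ readout of the same samples
  corr <- correlate_score_with_gate(
    sc, stats::setNames(sim$expr$metadata$cd14_fraction,
                        sim$expr$metadata$sample_id))
  expect_gte(corr$estimate, 0.6)
})

test_that("recovery degrades monotonically with noise", {
  rho_at <- vapply(c(0.2, 1.0, 2.5), function(sig) {
    sim <- simulate_expression(expr_sim_config(noise_sdlog = sig), seed = 106)
    genes <- top_variable_genes(sim$expr, 100)
    mod <- extract_coexpression_module(sim$expr, genes)
    if (!mod$qualified) return(0)
    sc <- module_score(sim$expr, mod)
    spearman_cor(sc$scores, sim$contamination[names(sc$scores)])$estimate
  }, numeric(1))
  expect_true(all(diff(rho_at) < 0))
  expect_gte(rho_at[1], 0.8)
})

test_that("extraction and scoring are permutation-equivariant", {
  sim <- simulate_expression(expr_sim_config(n_genes = 60, n_samples = 30), seed = 107)
  e <- sim$expr
  perm_g <- withr::with_seed(1, sample(nrow(e$tpm)))
  perm_s <- withr::with_seed(2, sample(ncol(e$tpm)))
  e2 <- gene_expression_matrix(e$tpm[perm_g, perm_s])
  genes1 <- top_variable_genes(e, 30)
  genes2 <- top_variable_genes(e2, 30)
  expect_setequal(genes1, genes2)
  mod1 <- extract_coexpression_module(e, genes1)
  mod2 <- extract_coexpression_module(e2, genes2)
  expect_identical(mod1$genes, mod2$genes)
  s1 <- module_score(e, mod1)$scores
  s2 <- module_score(e2, mod2)$scores
  expect_equal(s1[names(s2)], s2, tolerance = 1e-9)
})

test_that("sample mismatches are reported by id", {
  sim <- simulate_expression(expr_sim_config(n_genes = 40, n_samples = 10), seed = 108)
  genes <- top_variable_genes(sim$expr, 30)
  mod <- extract_coexpression_module(sim$expr, genes)
  sc <- module_score(sim$expr, mod)
  bad <- stats::setNames(runif(10), c(names(sc$scores)[-1], "sXX"))
  expect_error(correlate_score_with_gate(sc, bad), "sXX")
})
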