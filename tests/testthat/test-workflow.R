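write_sim_config <- function(path, n_events = 4000, subjects) {
  yaml::write_yaml(list(version = 1, n_events = n_events, ka_true = 2,
                        subject_sd = 0.2, subjects = subjects), path)
}

test_that("run_simulate writes tables, truth sidecar and manifest deterministically", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, subjects = list(
    list(subject_id = "s1", cohort = "healthy", timepoint = 1),
    list(subject_id = "s1", cohort = "healthy", timepoint = 2),
    list(subject_id = "s2", cohort = "healthy", timepoint = 1)))
  out1 <- withr::local_tempdir()
  files <- run_simulate(cfg, out1, seed = 5)
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  expect_true(file.exists(file.path(out1, "truth.json")))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$command, "simulate")
  expect_equal(manifest$seed, 5)
  # identical seed => identical event files
  out2 <- withr::local_tempdir()
  files2 <- run_simulate(cfg, out2, seed = 5)
  expect_identical(unname(tools::md5sum(files)), unname(tools::md5sum(files2)))
  truth <- jsonlite::read_json(file.path(out1, "truth.json"))
  expect_equal(truth[[1]]$subject_id, "s1")
  expect_equal(truth[[1]]$ka_true$CD4, truth[[2]]$ka_true$CD4)  # shared subject effect
})

test_that("run_analyze produces Ka tables, a mass-action fit and designed comparisons", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  subjects <- unlist(lapply(sprintf("p%02d", 1:6), function(id) {
    list(list(subject_id = id, cohort = "healthy", timepoint = 1),
         list(subject_id = id, cohort = "healthy", timepoint = 2, ka_scale = 0.5))
  }), recursive = FALSE)
  write_sim_config(cfg, n_events = 20000, subjects = subjects)
  events <- withr::local_tempdir()
  run_simulate(cfg, events, seed = 11)
  design <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(comparisons = list(
    list(name = "pre_vs_post", type = "paired", subset = "all",
         timepoints = list(1, 2)),
    list(name = "h_vs_h", type = "unpaired", subset = "all",
         cohorts = list("healthy", "healthy")))), design)
  out <- withr::local_tempdir()
  res <- run_analyze(events, out, design_path = design)
  expect_true(file.exists(file.path(out, "ka.csv")))
  ka <- utils::read.csv(file.path(out, "ka.csv"))
  expect_equal(nrow(ka), 12 * 5)  # subject-timepoints x subsets
  expect_setequal(unique(ka$subset), c("all", "CD4", "CD8", "DNEG", "DPOS"))
  expect_s3_class(res$fit, "mass_action")
  cmp <- utils::read.csv(file.path(out, "comparisons.csv"))
  expect_equal(cmp$test[cmp$name == "pre_vs_post"], "Wilcoxon signed-rank")
  expect_equal(cmp$test[cmp$name == "h_vs_h"], "Mann-Whitney")
  # the halving design comes out significant in the paired comparison
  expect_lt(cmp$p_value[cmp$name == "pre_vs_post"], 0.05)
})

test_that("run_signature writes module, scores and correlation report", {
  sim <- simulate_expression(expr_sim_config(), seed = 12)
  expr_path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$expr, expr_path)
  freq_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sample_id = sim$expr$metadata$sample_id,
                              cd14_fraction = sim$expr$metadata$cd14_fraction),
                   freq_path, row.names = FALSE)
  out <- withr::local_tempdir()
  res <- run_signature(expr_path, freq_path, out)
  expect_true(file.exists(file.path(out, "module.tsv")))
  expect_true(file.exists(file.path(out, "scores.csv")))
  report <- jsonlite::read_json(file.path(out, "correlation.json"))
  expect_true(report$qualified)
  expect_gt(report$spearman_rho, 0.6)
  # unmatched ids abort with the ids listed
  bad_freq <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sample_id = "nope", cd14_fraction = 0.1),
                   bad_freq, row.names = FALSE)
  expect_error(run_signature(expr_path, bad_freq, withr::local_tempdir()), "nope")
})

test_that("run_signature flags the no-module case but still succeeds", {
  tpm <- withr::with_seed(13, matrix(rlnorm(120 * 50, log(10), 0.3), 120, 50,
                                     dimnames = list(sprintf("g%03d", 1:120),
                                                     sprintf("s%02d", 1:50))))
  e <- gene_expression_matrix(tpm)
  expr_path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(e, expr_path)
  freq_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sample_id = colnames(tpm),
                              cd14_fraction = runif(50, 0, 0.01)),
                   freq_path, row.names = FALSE)
  out <- withr::local_tempdir()
  expect_warning(run_signature(expr_path, freq_path, out), "no qualifying")
  report <- jsonlite::read_json(file.path(out, "correlation.json"))
  expect_false(report$qualified)
})
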