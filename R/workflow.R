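# Run manifest: every workflow run writes exactly one manifest recording the
# command, config hash, seed, inputs/outputs and package version, so a rerun
# with identical inputs and seed reproduces identical outputs.
write_manifest <- function(out_dir, command, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    package = "kassoc",
    package_version = as.character(utils::packageVersion("kassoc")),
    seed = seed,
    inputs = lapply(inputs, function(p) {
      if (is.character(p) && length(p) == 1L && file.exists(p) && !dir.exists(p)) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      } else p
    }),
    outputs = outputs,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Reads a cohort simulation config (YAML), simulates every subject
#' acquisition via [simulate_cohort()], and writes one event CSV per
#' subject/timepoint plus a cohort index (`cohort.csv`), a truth sidecar
#' (`truth.json`, per-subject true Ka) and a run manifest. Deterministic:
#' identical config + seed reproduce identical files.
#'
#' Config schema (version 1): `n_events`, `ka_true` (scalar or map over CD4/
#' CD8/DNEG/DPOS), optional `composition` map, `subject_sd`, `ka_cv`,
#' `debris_binding_rate`, `pulse_overlap`, and `subjects` — a list of
#' `{subject_id, cohort, timepoint, ka_scale}` entries.
#'
#' @param config_path YAML config path.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (mandatory; no silent clock seeding).
#' @return Invisibly, the list of written event-file paths.
#' @export
run_simulate <- function(config_path, out_dir, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$subjects)) stop("config lacks 'subjects'", call. = FALSE)
  design <- do.call(rbind, lapply(cfg$subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               cohort = if (is.null(s$cohort)) "cohort" else s$cohort,
               timepoint = if (is.null(s$timepoint)) 1L else s$timepoint,
               ka_scale = if (is.null(s$ka_scale)) 1 else s$ka_scale,
               stringsAsFactors = FALSE)
  }))
  ka_true <- cfg$ka_true
  if (is.list(ka_true)) ka_true <- unlist(ka_true)
  if (is.null(ka_true)) ka_true <- 2
  composition <- if (is.null(cfg$composition)) default_composition()
                 else unlist(cfg$composition)
  base <- flow_sim_config(
    n_events = if (is.null(cfg$n_events)) 50000 else cfg$n_events,
    composition = composition, ka_true = ka_true,
    debris_binding_rate = if (is.null(cfg$debris_binding_rate)) 0.02
                          else cfg$debris_binding_rate,
    pulse_overlap = if (is.null(cfg$pulse_overlap)) 0 else cfg$pulse_overlap)
  records <- simulate_cohort(
    design, base,
    subject_sd = if (is.null(cfg$subject_sd)) 0.2 else cfg$subject_sd,
    ka_cv = if (is.null(cfg$ka_cv)) 0 else cfg$ka_cv,
    events = "table", seed = as.integer(seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(design))
  truth <- vector("list", nrow(design))
  for (i in seq_along(records)) {
    r <- records[[i]]
    files[i] <- file.path(out_dir, sprintf("%s_t%s.csv", r$subject_id, r$timepoint))
    write_event_table(r$events, files[i])
    truth[[i]] <- list(subject_id = r$subject_id, cohort = r$cohort,
                       timepoint = r$timepoint, file = basename(files[i]),
                       ka_true = as.list(r$ka_true))
  }
  index <- data.frame(subject_id = design$subject_id, cohort = design$cohort,
                      timepoint = design$timepoint, file = basename(files),
                      stringsAsFactors = FALSE)
  utils::write.csv(index, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "simulate", seed, inputs = list(config = config_path),
                 outputs = c(basename(files), "cohort.csv", "truth.json"))
  invisible(files)
}

#' Gate a cohort and compute Ka tables, the mass-action fit and comparisons
#'
#' Reads every event CSV listed in the cohort index of `events_dir`, applies
#' the gating strategy (default [tm_strategy()]), computes the per-subject,
#' per-subset Ka table, fits the through-origin mass-action model over
#' subjects, and runs the comparisons declared in the optional design file
#' (paired Wilcoxon across timepoints, Mann-Whitney across cohorts). Writes
#' tidy CSV/JSON outputs plus a manifest.
#'
#' Design schema: `comparisons:` list of `{name, type: paired|unpaired,
#' subset, timepoints: [t1, t2]}` (paired, within subject) or `{...,
#' cohorts: [a, b]}` (unpaired).
#'
#' @param events_dir Directory produced by [run_simulate()] (or containing a
#'   compatible `cohort.csv` index).
#' @param out_dir Output directory.
#' @param strategy A [gating_strategy()], a strategy config path, or `NULL`
#'   for [tm_strategy()].
#' @param design_path Optional YAML design file of comparisons.
#' @return Invisibly, a list with the Ka data frame, the `mass_action` fit
#'   and the comparison table.
#' @export
run_analyze <- function(events_dir, out_dir, strategy = NULL, design_path = NULL) {
  index_path <- file.path(events_dir, "cohort.csv")
  if (!file.exists(index_path)) stop(sprintf("no cohort index at %s", index_path),
                                     call. = FALSE)
  index <- utils::read.csv(index_path, stringsAsFactors = FALSE)
  if (is.null(strategy)) strategy <- tm_strategy()
  if (is.character(strategy)) strategy <- parse_gating_strategy(strategy)
  rows <- vector("list", nrow(index))
  for (i in seq_len(nrow(index))) {
    tab <- read_event_table(file.path(events_dir, index$file[i]))
    gres <- apply_strategy(tab, strategy)
    kt <- ka_table(gres, subject_id = index$subject_id[i])
    kt$cohort <- index$cohort[i]
    kt$timepoint <- index$timepoint[i]
    rows[[i]] <- kt
  }
  ka <- do.call(rbind, rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ka, file.path(out_dir, "ka.csv"), row.names = FALSE)
  glob <- ka[ka$subset == "all" & ka$defined, ]
  fit <- NULL
  if (nrow(glob) >= 3) {
    fit <- mass_action(f_complex ~ f_T : f_M, glob)
    jsonlite::write_json(list(Ka = unname(coef(fit)[["Ka"]]), se = fit$se[["Ka"]],
                              spearman_rho = fit$rho, spearman_p = fit$rho_p,
                              n = fit$n),
                         file.path(out_dir, "mass_action.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  comparisons <- NULL
  if (!is.null(design_path)) {
    design <- yaml::read_yaml(design_path)
    comparisons <- do.call(rbind, lapply(design$comparisons, function(cmp) {
      sub <- ka[ka$subset == (if (is.null(cmp$subset)) "all" else cmp$subset) &
                  ka$defined, ]
      res <- if (identical(cmp$type, "paired")) {
        tp <- cmp$timepoints
        a <- sub[sub$timepoint == tp[[1]], c("subject_id", "ka")]
        b <- sub[sub$timepoint == tp[[2]], c("subject_id", "ka")]
        m <- merge(a, b, by = "subject_id")
        compare_groups(m$ka.x, m$ka.y, paired = TRUE)
      } else {
        compare_groups(sub$ka[sub$cohort == cmp$cohorts[[1]]],
                       sub$ka[sub$cohort == cmp$cohorts[[2]]])
      }
      cbind(data.frame(name = cmp$name, stringsAsFactors = FALSE),
            as.data.frame(res))
    }))
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  write_manifest(out_dir, "analyze", seed = NA,
                 inputs = list(events = events_dir, design = design_path),
                 outputs = c("ka.csv",
                             if (!is.null(fit)) "mass_action.json",
                             if (!is.null(comparisons)) "comparisons.csv"))
  invisible(list(ka = ka, fit = fit, comparisons = comparisons))
}

#' Run the monocyte-signature procedure on an expression matrix
#'
#' Reads a genes x samples TPM matrix (TSV) and a per-sample CD14+ gated
#' fraction table (CSV: `sample_id, cd14_fraction`), selects the most
#' variable genes, extracts the co-expression module, scores samples by the
#' module PC1, and correlates the score with the gated fraction. Writes the
#' module gene list (TSV), score vector (CSV), a correlation report (JSON)
#' and a manifest. When no module qualifies the report flags it and the run
#' still succeeds with a warning.
#'
#' @param expr_path TSV expression matrix path.
#' @param freq_path CSV of per-sample CD14+ fractions (matched sample ids).
#' @param out_dir Output directory.
#' @param n_top Number of variable genes to consider.
#' @param rho_min Module qualification threshold.
#' @return Invisibly, list with `module`, `score`, `correlation`.
#' @export
run_signature <- function(expr_path, freq_path, out_dir, n_top = 100,
                          rho_min = 0.6) {
  expr <- read_expression_matrix(expr_path)
  freq_df <- utils::read.csv(freq_path, stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- top_variable_genes(expr, n = min(n_top, nrow(expr$tpm)))
  module <- extract_coexpression_module(expr, genes, rho_min = rho_min)
  score <- NULL; corr <- NULL
  if (!module$qualified) {
    warning("no qualifying co-expression module found", call. = FALSE)
    report <- list(qualified = FALSE, rho_min = rho_min, n_candidates = length(genes))
  } else {
    score <- module_score(expr, module)
    corr <- correlate_score_with_gate(score,
                                      stats::setNames(freq_df[[2]],
                                                      as.character(freq_df[[1]])))
    utils::write.csv(data.frame(sample_id = names(score$scores),
                                pc1_score = unname(score$scores)),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
    report <- list(qualified = TRUE, n_genes = length(module$genes),
                   mean_intramodule_rho = module$mean_rho,
                   pc1_explained_variance = score$explained_variance,
                   spearman_rho = corr$estimate, spearman_p = corr$p_value)
  }
  utils::write.table(data.frame(gene_id = module$genes),
                     file.path(out_dir, "module.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "signature", seed = NA,
                 inputs = list(expr = expr_path, freq = freq_path),
                 outputs = c("module.tsv", "correlation.json",
                             if (module$qualified) "scores.csv"))
  invisible(list(module = module, score = score, correlation = corr))
}
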