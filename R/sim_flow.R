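# ---- population bookkeeping ---------------------------------------------

T_SUBSETS_FINE <- c("CD4_naive", "CD4_Tcm", "CD4_Tem", "CD4_Temra",
                    "CD8", "DNEG", "DPOS")
T_SUBSETS_COARSE <- c("CD4", "CD8", "DNEG", "DPOS")
SINGLET_CATEGORIES <- c(T_SUBSETS_FINE, "mono", "other")
ALL_CATEGORIES <- c(SINGLET_CATEGORIES, "debris", "dead")
MARKERS <- c("CD3", "CD14", "CD4", "CD8", "CD45RA", "CCR7", "CD45", "viability")

coarse_subset <- function(fine) {
  ifelse(startsWith(fine, "CD4_"), "CD4", fine)
}

# ---- default generative models ------------------------------------------

#' Default per-population marker intensity models
#'
#' Log-normal fluorescence models per population and marker, as
#' `list(level = <raw-unit median matrix>, sdlog = <matrix>)`. Positive
#' markers sit at 1000 arbitrary units (sdlog 0.35), negative at 10
#' (sdlog 0.6); the viability dye is low on live cells and high on dead cells
#' and debris; CD45 is high on all leukocytes and low on debris.
#'
#' @return List with `level` and `sdlog` matrices (populations x markers).
#' @export
default_marker_models <- function() {
  pos <- 1000; neg <- 10
  lv <- matrix(neg, nrow = length(ALL_CATEGORIES), ncol = length(MARKERS),
               dimnames = list(ALL_CATEGORIES, MARKERS))
  sd <- matrix(0.5, nrow = length(ALL_CATEGORIES), ncol = length(MARKERS),
               dimnames = list(ALL_CATEGORIES, MARKERS))
  tcells <- T_SUBSETS_FINE
  lv[tcells, "CD3"] <- pos
  lv["mono", "CD14"] <- pos
  lv[c("CD4_naive", "CD4_Tcm", "CD4_Tem", "CD4_Temra", "DPOS"), "CD4"] <- pos
  lv[c("CD8", "DPOS"), "CD8"] <- pos
  lv[c("CD4_naive", "CD4_Temra", "CD8", "DNEG"), "CD45RA"] <- pos
  lv[c("CD4_naive", "CD4_Tcm", "CD8"), "CCR7"] <- pos
  lv[setdiff(ALL_CATEGORIES, "debris"), "CD45"] <- 2000
  lv["debris", "CD45"] <- 10
  lv[, "viability"] <- 20
  lv[c("dead", "debris"), "viability"] <- 2000
  sd[lv == pos] <- 0.35
  sd[, "CD45"] <- 0.3
  sd[, "viability"] <- 0.5
  list(level = lv, sdlog = sd)
}

#' Default per-population scatter pulse models
#'
#' Each population draws pulse area log-normally; height is a tight
#' proportional band around area (`H = h_ratio * A * exp(noise)`, the basis of
#' the conventional singlet gate) and width is an independent log-normal.
#' Lymphocytes are small/low side scatter, monocytes larger with higher side
#' scatter, debris small and dim.
#'
#' @return Named list of per-population parameter lists.
#' @export
default_scatter_models <- function() {
  lymph <- list(fsc_a = 5e4, fsc_a_sdlog = 0.12, ssc_a = 1.5e4, ssc_a_sdlog = 0.2,
                fsc_w = 55, ssc_w = 55, w_sdlog = 0.08, h_ratio = 0.95, h_sdlog = 0.05)
  mono <- list(fsc_a = 9e4, fsc_a_sdlog = 0.12, ssc_a = 6e4, ssc_a_sdlog = 0.2,
               fsc_w = 70, ssc_w = 70, w_sdlog = 0.08, h_ratio = 0.95, h_sdlog = 0.05)
  debris <- list(fsc_a = 5e3, fsc_a_sdlog = 0.3, ssc_a = 2e3, ssc_a_sdlog = 0.3,
                 fsc_w = 40, ssc_w = 40, w_sdlog = 0.1, h_ratio = 0.95, h_sdlog = 0.08)
  dead <- list(fsc_a = 3.5e4, fsc_a_sdlog = 0.15, ssc_a = 2.5e4, ssc_a_sdlog = 0.25,
               fsc_w = 55, ssc_w = 55, w_sdlog = 0.08, h_ratio = 0.95, h_sdlog = 0.05)
  out <- c(stats::setNames(rep(list(lymph), length(T_SUBSETS_FINE)), T_SUBSETS_FINE),
           list(mono = mono, other = lymph, debris = debris, dead = dead))
  out
}

#' Default per-population brightfield imaging models
#'
#' Log-normal brightfield object area (square micrometres) and beta-distributed
#' aspect ratio. Single cells are near-circular (aspect ratio close to 1);
#' doublet complexes have roughly the summed area of their members and a
#' markedly lower aspect ratio.
#'
#' @return Named list with per-population `area`/`area_sdlog` and beta
#'   `ar_shape1`/`ar_shape2`, plus the `complex` aspect-ratio model.
#' @export
default_imaging_models <- function() {
  single <- list(ar_shape1 = 40, ar_shape2 = 3)
  area <- list(lymph = 60, mono = 120, debris = 8, dead = 55)
  pops <- stats::setNames(rep(list(c(list(area = area$lymph, area_sdlog = 0.15), single)),
                              length(T_SUBSETS_FINE)), T_SUBSETS_FINE)
  pops$other <- c(list(area = area$lymph, area_sdlog = 0.15), single)
  pops$mono <- c(list(area = area$mono, area_sdlog = 0.15), single)
  pops$dead <- c(list(area = area$dead, area_sdlog = 0.15), single)
  pops$debris <- list(area = area$debris, area_sdlog = 0.3, ar_shape1 = 4, ar_shape2 = 2)
  pops$complex <- list(ar_shape1 = 8, ar_shape2 = 6)
  pops
}

#' Default live-event composition
#'
#' Fractions of acquired events per latent population. The defaults keep the
#' T-cell and monocyte singlet fractions small enough that the mass-action
#' feasibility bound `Ka * f_T * f_M <= min(f_T, f_M)` holds with margin for
#' association constants up to 5 (the range the recovery studies exercise),
#' including under inter-subject composition variability.
#'
#' @return Named numeric vector over the simulator's population categories,
#'   summing to 1.
#' @export
default_composition <- function() {
  c(CD4_naive = 0.022, CD4_Tcm = 0.020, CD4_Tem = 0.015, CD4_Temra = 0.008,
    CD8 = 0.025, DNEG = 0.007, DPOS = 0.003,
    mono = 0.050, other = 0.670, debris = 0.080, dead = 0.100)
}

# ---- configuration -------------------------------------------------------

#' Configure the flow-cytometry event simulator
#'
#' Defines the generative model for one subject's acquisition: the latent
#' event composition, the per-T-subset association constant `Ka` under which
#' T cell:monocyte complexes form by mass action, the rate at which single T
#' cells carry CD14+ monocyte debris (producing CD3+CD14mid events), and the
#' per-population marker / scatter / imaging models.
#'
#' Complex formation: with `L` the realized live singlet pool, each fine
#' T subset `s` contributes `C_s ~ Binomial(L, Ka_s * f_s * f_M)` complex
#' events, where `f_s` and `f_M` are realized singlet fractions of `L`. The
#' config is rejected when the implied complex fraction exceeds the
#' feasibility bound `min(f_T, f_M)` for any subset (or `f_M` in total).
#'
#' `pulse_overlap` controls the scatter pulse geometry of complexes: `0`
#' (default) draws complex A/H/W from the monocyte singlet model — encoding
#' the empirical finding that conventional pulse geometry cannot separate
#' complexes from large singlets — while `1` gives a classical additive
#' doublet signature (summed areas and widths, near-max height).
#'
#' @param n_events Total events to acquire.
#' @param composition Named fractions over the population categories (see
#'   [default_composition()]); must sum to 1.
#' @param ka_true Association constant(s): a single value, or a named vector
#'   over `c("CD4", "CD8", "DNEG", "DPOS")`. Dimensionless, on the
#'   fraction-of-live-singlets scale.
#' @param debris_binding_rate Probability that a single T cell carries CD14+
#'   debris (CD3+CD14mid phenotype).
#' @param cd14_debris_level CD14 level of debris-bound T cells as a fraction
#'   of the monocyte CD14 location parameter (default 0.15).
#' @param pulse_overlap Doublet pulse-geometry knob in \[0, 1\]; see Details.
#' @param markers,scatter,imaging Generative models; see
#'   [default_marker_models()], [default_scatter_models()],
#'   [default_imaging_models()].
#' @param seed Optional integer seed stored with the config.
#' @return An object of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 50000,
                            composition = default_composition(),
                            ka_true = 2,
                            debris_binding_rate = 0.02,
                            cd14_debris_level = 0.15,
                            pulse_overlap = 0,
                            markers = default_marker_models(),
                            scatter = default_scatter_models(),
                            imaging = default_imaging_models(),
                            seed = NULL) {
  stopifnot(length(n_events) == 1L, n_events >= 1, n_events == round(n_events))
  if (!setequal(names(composition), ALL_CATEGORIES)) {
    stop(sprintf("composition must name exactly: %s",
                 paste(ALL_CATEGORIES, collapse = ", ")), call. = FALSE)
  }
  composition <- composition[ALL_CATEGORIES]
  if (any(composition < 0)) stop("composition fractions must be >= 0", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-6) {
    stop(sprintf("composition fractions must sum to 1 (got %.6f)", sum(composition)),
         call. = FALSE)
  }
  ka <- expand_ka(ka_true)
  if (any(ka < 0)) stop("ka_true must be >= 0", call. = FALSE)
  stopifnot(debris_binding_rate >= 0, debris_binding_rate <= 1,
            cd14_debris_level > 0, cd14_debris_level <= 1,
            pulse_overlap >= 0, pulse_overlap <= 1)
  cfg <- structure(list(n_events = as.integer(n_events), composition = composition,
                        ka_true = ka, debris_binding_rate = debris_binding_rate,
                        cd14_debris_level = cd14_debris_level,
                        pulse_overlap = pulse_overlap, markers = markers,
                        scatter = scatter, imaging = imaging, seed = seed),
                   class = "flow_sim_config")
  check_feasibility(cfg)
  cfg
}

expand_ka <- function(ka_true) {
  if (length(ka_true) == 1L && is.null(names(ka_true))) {
    return(stats::setNames(rep(as.numeric(ka_true), 4), T_SUBSETS_COARSE))
  }
  if (!setequal(names(ka_true), T_SUBSETS_COARSE)) {
    stop(sprintf("ka_true must be a single value or named over: %s",
                 paste(T_SUBSETS_COARSE, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(as.numeric(ka_true[T_SUBSETS_COARSE]), T_SUBSETS_COARSE)
}

# Reject configs whose implied complex fraction violates mass-action
# feasibility: Ka_s * f_s * f_M <= min(f_s, f_M) per subset and
# sum_s Ka_s * f_s * f_M <= f_M overall (complexes cannot outnumber the
# monocytes available to form them).
check_feasibility <- function(cfg) {
  comp <- cfg$composition
  L <- sum(comp[SINGLET_CATEGORIES])
  if (L <= 0) stop("composition has no live singlet mass", call. = FALSE)
  f_M <- comp[["mono"]] / L
  total <- 0
  for (s in T_SUBSETS_FINE) {
    f_s <- comp[[s]] / L
    ka_s <- cfg$ka_true[[coarse_subset(s)]]
    implied <- ka_s * f_s * f_M
    if (implied > min(f_s, f_M) + 1e-12 && implied > 0) {
      stop(sprintf(paste0("infeasible config: implied complex fraction %.4f for ",
                          "subset %s exceeds min(f_T, f_M) = %.4f"),
                   implied, s, min(f_s, f_M)), call. = FALSE)
    }
    total <- total + implied
  }
  if (total > f_M + 1e-12) {
    stop(sprintf("infeasible config: total implied complex fraction %.4f exceeds f_M = %.4f",
                 total, f_M), call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.flow_sim_config <- function(x, ...) {
  cat(sprintf("<flow_sim_config> %d events, pulse_overlap = %.2f\n",
              x$n_events, x$pulse_overlap))
  cat("  Ka_true:", paste(sprintf("%s=%.3g", names(x$ka_true), x$ka_true),
                          collapse = ", "), "\n")
  L <- sum(x$composition[SINGLET_CATEGORIES])
  cat(sprintf("  singlet pool %.3f of events (f_T = %.3f, f_M = %.3f of pool)\n",
              L, sum(x$composition[T_SUBSETS_FINE]) / L, x$composition[["mono"]] / L))
  invisible(x)
}

# ---- count layer ---------------------------------------------------------

# Draw the latent event counts for one subject: singlet counts per category,
# debris-bound T counts per subset, complex counts per fine subset.
draw_counts <- function(cfg) {
  N <- as.vector(stats::rmultinom(1, cfg$n_events, cfg$composition))
  names(N) <- names(cfg$composition)
  L <- sum(N[SINGLET_CATEGORIES])
  f_M <- N[["mono"]] / L
  C <- stats::setNames(integer(length(T_SUBSETS_FINE)), T_SUBSETS_FINE)
  for (s in T_SUBSETS_FINE) {
    p <- cfg$ka_true[[coarse_subset(s)]] * (N[[s]] / L) * f_M
    C[s] <- stats::rbinom(1, L, min(1, p))
  }
  B <- stats::setNames(integer(length(T_SUBSETS_FINE)), T_SUBSETS_FINE)
  if (cfg$debris_binding_rate > 0) {
    for (s in T_SUBSETS_FINE) B[s] <- stats::rbinom(1, N[[s]], cfg$debris_binding_rate)
  }
  list(N = N, B = B, C = C, L = L)
}

#' Simulate the latent count layer of one subject
#'
#' Draws only the event counts of the generative model (singlets per
#' population, debris-bound T cells, complexes per T subset), without
#' materializing per-event channel data. Useful for frequency-level studies
#' (e.g. cohort power simulations) where the full event table is not needed.
#'
#' @param config A [flow_sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `N` (category counts), `B` (debris-bound T counts per
#'   fine subset), `C` (complex counts per fine subset) and `L` (live singlet
#'   pool size).
#' @export
simulate_subject_counts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "flow_sim_config"))
  if (is.null(seed)) draw_counts(config) else withr::with_seed(seed, draw_counts(config))
}

#' Association constant from latent counts
#'
#' Applies the Ka estimator directly to the simulator's latent count layer
#' (complex, singlet T and singlet monocyte counts over the live singlet
#' pool), i.e. with perfect gating.
#'
#' @param counts Output of [simulate_subject_counts()].
#' @param subset `"all"` or one of `"CD4"`, `"CD8"`, `"DNEG"`, `"DPOS"`.
#' @return A [compute_ka()] result.
#' @export
ka_from_counts <- function(counts, subset = "all") {
  L <- counts$L
  if (subset == "all") {
    fine <- T_SUBSETS_FINE
  } else {
    subset <- match.arg(subset, T_SUBSETS_COARSE)
    fine <- T_SUBSETS_FINE[coarse_subset(T_SUBSETS_FINE) == subset]
  }
  f_complex <- sum(counts$C[fine]) / L
  f_T <- sum(counts$N[fine]) / L
  f_M <- counts$N[["mono"]] / L
  compute_ka(f_complex, f_T, f_M, subset = subset, denominator = "live_singlets")
}

# ---- event materialization ----------------------------------------------

draw_scatter <- function(sc, n) {
  fsc_a <- stats::rlnorm(n, log(sc$fsc_a), sc$fsc_a_sdlog)
  ssc_a <- stats::rlnorm(n, log(sc$ssc_a), sc$ssc_a_sdlog)
  data.frame(
    FSC_A = fsc_a,
    FSC_H = fsc_a * sc$h_ratio * exp(stats::rnorm(n, 0, sc$h_sdlog)),
    FSC_W = stats::rlnorm(n, log(sc$fsc_w), sc$w_sdlog),
    SSC_A = ssc_a,
    SSC_H = ssc_a * sc$h_ratio * exp(stats::rnorm(n, 0, sc$h_sdlog)),
    SSC_W = stats::rlnorm(n, log(sc$ssc_w), sc$w_sdlog)
  )
}

draw_markers <- function(mk, pop, n) {
  out <- lapply(MARKERS, function(m) {
    stats::rlnorm(n, log(mk$level[pop, m]), mk$sdlog[pop, m])
  })
  names(out) <- MARKERS
  as.data.frame(out)
}

draw_imaging <- function(im, pop, n) {
  p <- im[[pop]]
  data.frame(bf_area = stats::rlnorm(n, log(p$area), p$area_sdlog),
             bf_aspect_ratio = stats::rbeta(n, p$ar_shape1, p$ar_shape2))
}

# additive doublet pulse from two member scatter draws
additive_pulse <- function(t_sc, m_sc) {
  data.frame(
    FSC_A = t_sc$FSC_A + m_sc$FSC_A,
    FSC_H = 1.05 * pmax(t_sc$FSC_H, m_sc$FSC_H),
    FSC_W = t_sc$FSC_W + m_sc$FSC_W,
    SSC_A = t_sc$SSC_A + m_sc$SSC_A,
    SSC_H = 1.05 * pmax(t_sc$SSC_H, m_sc$SSC_H),
    SSC_W = t_sc$SSC_W + m_sc$SSC_W
  )
}

gen_block <- function(cfg, pop, n, role = c("singlet", "debrisT", "complex")) {
  role <- match.arg(role)
  if (n == 0L) return(NULL)
  mk <- cfg$markers
  if (role == "singlet") {
    df <- cbind(draw_scatter(cfg$scatter[[pop]], n),
                draw_markers(mk, pop, n),
                draw_imaging(cfg$imaging, pop, n))
    lab <- if (pop %in% c("debris", "dead")) pop else paste0("singlet:", pop)
    df$truth_label <- lab
    return(df)
  }
  if (role == "debrisT") {
    df <- cbind(draw_scatter(cfg$scatter[[pop]], n),
                draw_markers(mk, pop, n),
                draw_imaging(cfg$imaging, pop, n))
    # attached CD14+ debris: CD14 at a fraction of the monocyte level
    df$CD14 <- stats::rlnorm(n, log(cfg$cd14_debris_level * mk$level["mono", "CD14"]),
                             mk$sdlog["mono", "CD14"])
    df$truth_label <- paste0("debrisT:", pop)
    return(df)
  }
  # complex: one T member of subset `pop` + one monocyte member
  t_sc <- draw_scatter(cfg$scatter[[pop]], n)
  m_sc <- draw_scatter(cfg$scatter[["mono"]], n)
  mono_like <- draw_scatter(cfg$scatter[["mono"]], n)
  lam <- cfg$pulse_overlap
  sc <- as.data.frame(Map(function(a, b) (1 - lam) * a + lam * b,
                          mono_like, additive_pulse(t_sc, m_sc)))
  mkdf <- draw_markers(mk, pop, n)     # T-member markers incl. CD3 subset profile
  mkdf$CD14 <- stats::rlnorm(n, log(mk$level["mono", "CD14"]), mk$sdlog["mono", "CD14"])
  mkdf$CD45 <- mkdf$CD45 + stats::rlnorm(n, log(mk$level["mono", "CD45"]),
                                         mk$sdlog["mono", "CD45"])
  t_im <- draw_imaging(cfg$imaging, pop, n)
  m_im <- draw_imaging(cfg$imaging, "mono", n)
  imdf <- data.frame(
    bf_area = t_im$bf_area + m_im$bf_area,
    bf_aspect_ratio = stats::rbeta(n, cfg$imaging$complex$ar_shape1,
                                   cfg$imaging$complex$ar_shape2))
  df <- cbind(sc, mkdf, imdf)
  df$truth_label <- paste0("complex:", pop)
  df
}

build_event_table <- function(cfg) {
  cnt <- draw_counts(cfg)
  blocks <- list()
  for (pop in ALL_CATEGORIES) {
    n_here <- cnt$N[[pop]]
    if (pop %in% T_SUBSETS_FINE) n_here <- n_here - cnt$B[[pop]]
    blocks[[length(blocks) + 1L]] <- gen_block(cfg, pop, n_here, "singlet")
  }
  for (s in T_SUBSETS_FINE) {
    blocks[[length(blocks) + 1L]] <- gen_block(cfg, s, cnt$B[[s]], "debrisT")
    blocks[[length(blocks) + 1L]] <- gen_block(cfg, s, cnt$C[[s]], "complex")
  }
  df <- do.call(rbind, blocks)
  # complexes are acquired on top of the singlet stream; subsample back to the
  # configured acquisition size so category counts sum to n_events exactly
  # (uniform subsampling preserves all fractions in expectation)
  keep <- sample.int(nrow(df), cfg$n_events)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df$event_id <- seq_len(nrow(df))
  out <- event_table(df)
  attr(out, "truth") <- list(counts = cnt, ka_true = cfg$ka_true,
                             pulse_overlap = cfg$pulse_overlap)
  out
}

#' Simulate one subject's flow-cytometry event table
#'
#' Generates a per-event acquisition containing live singlets of each
#' configured population, dead cells and debris, debris-bound CD3+CD14mid T
#' cells, and T cell:monocyte complexes formed by mass action at the
#' configured `Ka` (see [flow_sim_config()] for the generative model).
#' Complex events carry CD3 (and CD4/CD8/CD45RA/CCR7) from their T member and
#' CD14 at the full monocyte level; their brightfield area is the sum of the
#' member areas with a lower aspect ratio than single cells; their scatter
#' pulse geometry interpolates between monocyte-like (`pulse_overlap = 0`) and
#' classical additive doublet (`pulse_overlap = 1`).
#'
#' The returned table carries a `truth_label` column and a `truth` attribute
#' recording the latent counts, so downstream estimators can be validated by
#' parameter recovery. Identical config + seed yields an identical table.
#'
#' @param config A [flow_sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An [event_table()] with `truth_label`.
#' @export
simulate_subject_events <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "flow_sim_config"))
  check_feasibility(config)
  if (is.null(seed)) build_event_table(config)
  else withr::with_seed(seed, build_event_table(config))
}

#' Truth-label category counts
#'
#' Tabulates a simulated table's `truth_label` column into the latent
#' categories (singlets per population, complexes and debris-bound T cells
#' per subset, debris, dead).
#'
#' @param table A simulated [event_table()].
#' @return Named integer vector of counts.
#' @export
truth_counts <- function(table) {
  stopifnot(inherits(table, "event_table"))
  if (!"truth_label" %in% names(table)) stop("table has no truth_label", call. = FALSE)
  table(factor(table$truth_label))
}

#' Truth predicates on simulated labels
#'
#' @param labels Character vector of `truth_label` values.
#' @return Logical vector.
#' @export
is_complex_truth <- function(labels) startsWith(labels, "complex:")

#' @rdname is_complex_truth
#' @export
is_singlet_truth <- function(labels) startsWith(labels, "singlet:")

# ---- cohorts -------------------------------------------------------------

# logistic-normal perturbation of a composition vector
perturb_composition <- function(comp, sd) {
  z <- log(comp) + stats::rnorm(length(comp), 0, sd)
  p <- exp(z - max(z))
  stats::setNames(p / sum(p), names(comp))
}

#' Simulate a cohort of subjects
#'
#' Generates one acquisition per design row. Subject-level random effects —
#' a logistic-normal perturbation of the composition and (optionally) a
#' log-normal multiplier on `Ka` — are drawn once per subject and reused
#' across that subject's timepoints, so paired designs share subject effects
#' (the within-subject stability the association constant is meant to
#' capture). The design's `ka_scale` column applies condition effects (e.g.
#' halving Ka post-treatment).
#'
#' @param design Data frame with columns `subject_id`, optional `cohort`,
#'   `timepoint` (default 1) and `ka_scale` (default 1). `(subject_id,
#'   timepoint)` pairs must be unique.
#' @param config Base [flow_sim_config()] shared by all subjects.
#' @param subject_sd Logistic-normal SD of inter-subject composition
#'   variation (0 disables).
#' @param ka_cv Coefficient of variation of the subject-level log-normal Ka
#'   multiplier (mean 1; 0 disables).
#' @param events `"table"` materializes full event tables; `"counts"` keeps
#'   only the latent count layer (fast, for frequency-level studies).
#' @param seed Integer seed for the whole cohort; `NULL` uses the current RNG
#'   stream.
#' @return List of `subject_record` objects: `subject_id`, `cohort`,
#'   `timepoint`, `ka_true` (the subject's scaled true constants), and
#'   `events` (event table) or `counts`.
#' @export
simulate_cohort <- function(design, config, subject_sd = 0.2, ka_cv = 0,
                            events = c("table", "counts"), seed = 1L) {
  events <- match.arg(events)
  stopifnot(is.data.frame(design), "subject_id" %in% names(design))
  if (!"timepoint" %in% names(design)) design$timepoint <- 1L
  if (!"ka_scale" %in% names(design)) design$ka_scale <- 1
  if (!"cohort" %in% names(design)) design$cohort <- "cohort"
  key <- paste(design$subject_id, design$timepoint)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (subject, timepoint): %s", key[duplicated(key)][1]),
         call. = FALSE)
  }
  run <- function() {
    ids <- unique(design$subject_id)
    sdlog <- sqrt(log(1 + ka_cv^2))
    effects <- lapply(ids, function(i) {
      list(comp = if (subject_sd > 0) perturb_composition(config$composition, subject_sd)
           else config$composition,
           ka_mult = if (ka_cv > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1)
    })
    names(effects) <- as.character(ids)
    out <- vector("list", nrow(design))
    for (r in seq_len(nrow(design))) {
      eff <- effects[[as.character(design$subject_id[r])]]
      cfg_r <- config
      cfg_r$composition <- eff$comp
      cfg_r$ka_true <- config$ka_true * eff$ka_mult * design$ka_scale[r]
      check_feasibility(cfg_r)
      rec <- list(subject_id = design$subject_id[r], cohort = design$cohort[r],
                  timepoint = design$timepoint[r], ka_true = cfg_r$ka_true)
      if (events == "table") {
        rec$events <- simulate_subject_events(cfg_r, seed = NULL)
      } else {
        rec$counts <- simulate_subject_counts(cfg_r, seed = NULL)
      }
      out[[r]] <- structure(rec, class = "subject_record")
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s / %s / t=%s\n", x$subject_id, x$cohort, x$timepoint))
  invisible(x)
}
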