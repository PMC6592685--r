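test_that("config validation enforces composition, Ka and feasibility invariants", {
  expect_error(flow_sim_config(composition = c(mono = 1)), "composition must name")
  bad <- default_composition(); bad["mono"] <- bad["mono"] + 0.1
  expect_error(flow_sim_config(composition = bad), "sum to 1")
  expect_error(flow_sim_config(ka_true = -1), ">= 0")
  expect_error(flow_sim_config(ka_true = c(CD4 = 1, CD8 = 1)), "named over")
  # implied complex fraction above min(f_T, f_M) is rejected with a message
  expect_error(flow_sim_config(composition = simple_composition(0.4, 0.1), ka_true = 5),
               "infeasible")
  expect_error(flow_sim_config(pulse_overlap = 2))
})

test_that("Ka = 0 produces no complexes; composition is conserved exactly", {
  tab <- simulate_subject_events(flow_sim_config(n_events = 20000, ka_true = 0), seed = 1)
  expect_equal(sum(is_complex_truth(tab$truth_label)), 0L)
  expect_equal(nrow(tab), 20000L)
  # singlets + complexes + debris-bound + dead (+ debris) account for every event
  cnt <- truth_counts(tab)
  expect_equal(sum(cnt), 20000L)
})

test_that("realized complex fraction obeys the mass-action binomial law", {
  # f_T = 0.4, f_M = 0.1, Ka = 1: complex fraction 0.04 of the singlet pool
  cfg <- flow_sim_config(n_events = 200000,
                         composition = simple_composition(0.4, 0.1),
                         ka_true = 1, debris_binding_rate = 0)
  tab <- simulate_subject_events(cfg, seed = 21)
  lab <- tab$truth_label
  n_singlet <- sum(is_singlet_truth(lab))
  f_complex <- sum(is_complex_truth(lab)) / n_singlet
  f_T <- sum(lab %in% paste0("singlet:", c("CD4_naive", "CD4_Tcm", "CD4_Tem", "CD4_Temra"))) /
    n_singlet
  f_M <- sum(lab == "singlet:mono") / n_singlet
  expected <- 1 * f_T * f_M
  se <- sqrt(expected * (1 - expected) / n_singlet)
  expect_lt(abs(f_complex - expected), 3 * se)
})

test_that("mean realized complex fraction is unbiased over repeated count draws", {
  cfg <- flow_sim_config(n_events = 50000)
  reps <- withr::with_seed(77, replicate(100, {
    cnt <- simulate_subject_counts(cfg, seed = NULL)
    c(sum(cnt$C) / cnt$L,
      sum(cfg$ka_true[c("CD4", "CD4", "CD4", "CD4", "CD8", "DNEG", "DPOS")] *
            cnt$N[kassoc:::T_SUBSETS_FINE] / cnt$L) * cnt$N[["mono"]] / cnt$L)
  }))
  dev <- mean(reps[1, ] - reps[2, ])
  se <- stats::sd(reps[1, ] - reps[2, ]) / sqrt(ncol(reps))
  expect_lt(abs(dev), 3 * se)
})

test_that("pulse_overlap = 1 gives complexes stochastically larger FSC_A than monocytes", {
  tab <- simulate_subject_events(
    flow_sim_config(n_events = 120000, ka_true = 3, pulse_overlap = 1), seed = 31)
  lab <- tab$truth_label
  x <- tab$FSC_A[is_complex_truth(lab)]
  y <- tab$FSC_A[lab == "singlet:mono"]
  expect_gte(length(x), 1000)
  p <- stats::wilcox.test(x[1:1000], y[1:1000], alternative = "greater")$p.value
  expect_lt(p, 1e-6)
})

test_that("pulse_overlap = 0 makes complex and monocyte scatter indistinguishable", {
  # encodes the central negative result as a simulator contract
  pvals <- withr::with_seed(41, replicate(30, {
    cfg <- flow_sim_config(n_events = 60000, ka_true = 3)
    tab <- simulate_subject_events(cfg, seed = NULL)
    lab <- tab$truth_label
    x <- tab$FSC_A[is_complex_truth(lab)]
    y <- tab$FSC_A[lab == "singlet:mono"]
    stats::wilcox.test(sample(x, 500), sample(y, 500))$p.value
  }))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("identical config and seed reproduce the identical table", {
  cfg <- flow_sim_config(n_events = 5000)
  t1 <- simulate_subject_events(cfg, seed = 99)
  t2 <- simulate_subject_events(cfg, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_subject_events(cfg, seed = 100)
  expect_false(identical(t1$FSC_A, t3$FSC_A))
})

test_that("complex events carry T-member markers and monocyte-level CD14", {
  tab <- simulate_subject_events(flow_sim_config(n_events = 100000, ka_true = 3), seed = 55)
  lab <- tab$truth_label
  cd14_complex <- median(tab$CD14[is_complex_truth(lab)])
  cd14_mono <- median(tab$CD14[lab == "singlet:mono"])
  cd14_debris_t <- median(tab$CD14[startsWith(lab, "debrisT:")])
  expect_lt(abs(log(cd14_complex / cd14_mono)), 0.2)           # full monocyte level
  expect_lt(abs(cd14_debris_t / cd14_mono - 0.15), 0.05)        # CD14mid at ~15%
  cd3_complex <- median(tab$CD3[is_complex_truth(lab)])
  cd3_t <- median(tab$CD3[lab == "singlet:CD8"])
  expect_lt(abs(log(cd3_complex / cd3_t)), 0.2)
  # brightfield area approximately sums the members; aspect ratio is lower
  expect_gt(median(tab$bf_area[is_complex_truth(lab)]),
            median(tab$bf_area[lab == "singlet:mono"]))
  expect_lt(median(tab$bf_aspect_ratio[is_complex_truth(lab)]),
            median(tab$bf_aspect_ratio[lab == "singlet:mono"]))
})

test_that("cohorts link subject records and share subject effects across timepoints", {
  design <- data.frame(subject_id = rep(c("s1", "s2"), each = 2),
                       timepoint = rep(1:2, 2))
  recs <- simulate_cohort(design, flow_sim_config(n_events = 2000),
                          ka_cv = 0.5, events = "counts", seed = 7)
  expect_length(recs, 4)
  expect_identical(recs[[1]]$subject_id, recs[[2]]$subject_id)
  # subject Ka effect identical across timepoints, different across subjects
  expect_identical(recs[[1]]$ka_true, recs[[2]]$ka_true)
  expect_false(identical(recs[[1]]$ka_true, recs[[3]]$ka_true))
  # determinism
  recs2 <- simulate_cohort(design, flow_sim_config(n_events = 2000),
                           ka_cv = 0.5, events = "counts", seed = 7)
  expect_identical(recs, recs2)
  expect_error(
    simulate_cohort(data.frame(subject_id = c("a", "a"), timepoint = c(1, 1)),
                    flow_sim_config(n_events = 1000)),
    "duplicate")
})

test_that("ka_scale applies condition effects on top of subject effects", {
  design <- data.frame(subject_id = rep("s1", 2), timepoint = 1:2,
                       ka_scale = c(1, 0.5))
  recs <- simulate_cohort(design, flow_sim_config(n_events = 1000),
                          events = "counts", seed = 3)
  expect_equal(unname(recs[[2]]$ka_true / recs[[1]]$ka_true), rep(0.5, 4))
})
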