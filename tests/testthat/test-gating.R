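test_that("rectangle boundaries are lower-inclusive, upper-exclusive", {
  tab <- event_table(data.frame(x = c(5, 10), y = c(5, 5)))
  g <- gate("box", "rectangle", c("x", "y"), xlim = c(0, 10), ylim = c(0, 10))
  expect_identical(apply_gate(tab, g), 1L)
  # full-range gate keeps the whole parent
  g_all <- gate("all", "rectangle", c("x", "y"), xlim = c(-Inf, Inf), ylim = c(-Inf, Inf))
  expect_identical(apply_gate(tab, g_all), tab$event_id)
})

test_that("interval and threshold conventions match their definitions", {
  tab <- event_table(data.frame(x = c(0, 1, 2, 3)))
  expect_identical(apply_gate(tab, gate("i", "interval", "x", lo = 1, hi = 3)),
                   c(2L, 3L))
  expect_identical(apply_gate(tab, gate("t", "threshold", "x", at = 2)),
                   c(3L, 4L))
  expect_identical(apply_gate(tab, gate("t", "threshold", "x", at = 2, side = "below")),
                   c(1L, 2L))
})

test_that("gate geometry is interpreted on the declared transform", {
  tab <- event_table(data.frame(CD3 = c(10, 1000)))
  g <- gate("t", "threshold", "CD3", at = asinh(100 / 150),
            transform = list(type = "asinh", cofactor = 150))
  expect_identical(apply_gate(tab, g), 2L)
  g10 <- gate("t", "threshold", "CD3", at = 2, transform = "log10")
  expect_identical(apply_gate(tab, g10), 2L)
})

test_that("gating engine equals brute-force evaluation on random geometry", {
  withr::local_seed(301)
  for (rep in 1:25) {
    tab <- random_event_table(500)
    g <- random_gate(tab)
    got <- apply_gate(tab, g)
    want <- oracle_apply_gate(tab, g)
    if (g$kind == "quadrant") {
      for (q in names(want)) expect_identical(got[[q]], want[[q]])
    } else {
      expect_identical(got, want)
    }
  }
})

test_that("on-edge polygon points are members", {
  tab <- event_table(data.frame(x = c(0.5, 0, 2), y = c(0, 0, 2)))
  tri <- gate("tri", "polygon", c("x", "y"),
              vertices = rbind(c(0, 0), c(1, 0), c(0.5, 1)))
  expect_identical(apply_gate(tab, tri), c(1L, 2L))
})

test_that("quadrant children partition the parent exactly", {
  withr::local_seed(302)
  tab <- random_event_table(2000)
  g <- gate("q", "quadrant", c("CD3", "CD14"), x_at = 100, y_at = 100)
  parts <- apply_gate(tab, g)
  all_ids <- sort(unlist(parts, use.names = FALSE))
  expect_identical(all_ids, sort(tab$event_id))
  expect_equal(sum(lengths(parts)), nrow(tab))  # disjoint by the count identity
})

test_that("apply_strategy reports fractions against the declared denominator", {
  tab <- random_event_table(100, seed = 5)
  root_only <- gating_strategy(root = "all")
  res <- apply_strategy(tab, root_only)
  expect_equal(population_fraction(res, "all"), 1.0)
  # empty denominator: warn, fractions undefined (never silently zero)
  s <- gating_strategy(root = "all", entries = list(
    list(parent = "all", child = "none",
         gate = gate("none", "threshold", "CD3", at = Inf))),
    denominator = "none")
  expect_warning(res2 <- apply_strategy(tab, s), "empty")
  expect_true(is.na(population_fraction(res2, "all")))
})

test_that("missing channels are reported by name", {
  tab <- event_table(data.frame(x = 1))
  expect_error(apply_gate(tab, gate("g", "threshold", "CD3", at = 1)), "CD3")
})

test_that("hierarchy is monotone: every population within its parent", {
  tab <- simulate_subject_events(flow_sim_config(n_events = 20000), seed = 17)
  strat <- tm_strategy()
  res <- apply_strategy(tab, strat)
  for (p in setdiff(strat$populations, strat$root)) {
    parent <- strat$parents[[p]]
    expect_true(all(res$membership[[p]] %in% res$membership[[parent]]),
                label = sprintf("%s within %s", p, parent))
  }
})

test_that("canonical strategy resolves truth populations correctly", {
  tab <- simulate_subject_events(flow_sim_config(n_events = 100000), seed = 11)
  res <- apply_strategy(tab, tm_strategy())
  lab <- tab$truth_label
  id_complex <- tab$event_id[is_complex_truth(lab)]
  id_debris_t <- tab$event_id[startsWith(lab, "debrisT:")]
  expect_gt(mean(id_complex %in% res$membership$complexes), 0.95)
  expect_gt(mean(id_debris_t %in% res$membership$debrisT), 0.90)
  expect_gt(mean(id_complex %in% res$membership$singlet), 0.99)
  # gated complex fraction tracks the truth fraction within binomial noise
  n_singlet_truth <- sum(is_singlet_truth(lab) | startsWith(lab, "debrisT:"))
  f_truth <- length(id_complex) / n_singlet_truth
  f_gated <- population_count(res, "complexes") /
    (population_count(res, "singlet") - population_count(res, "complexes"))
  se <- sqrt(f_truth * (1 - f_truth) / n_singlet_truth)
  expect_lt(abs(f_gated - f_truth), 3 * se)
})

test_that("a table without monocytes yields an essentially empty complex gate", {
  comp <- default_composition()
  comp["other"] <- comp["other"] + comp["mono"]
  comp["mono"] <- 0
  tab <- simulate_subject_events(
    flow_sim_config(n_events = 50000, composition = comp, ka_true = 0), seed = 3)
  res <- apply_strategy(tab, tm_strategy())
  expect_lt(population_count(res, "complexes"),
            0.001 * population_count(res, "live"))
})

test_that("a CD45-SSC pre-gate leaves the complex frequency essentially unchanged", {
  tab <- simulate_subject_events(flow_sim_config(n_events = 100000), seed = 12)
  f_plain <- population_fraction(apply_strategy(tab, tm_strategy()), "complexes")
  f_pre <- population_fraction(apply_strategy(tab, tm_strategy(cd45_pregate = TRUE)),
                               "complexes")
  expect_lt(abs(f_pre / f_plain - 1), 0.05)
})
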