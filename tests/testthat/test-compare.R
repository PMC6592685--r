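test_that("identical groups give p = 1 and paired monotone shifts the exact tail", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)
  # all pairs decreasing (distinct differences): one-sided signed-rank p = 2^-n
  for (n in c(5, 8, 12)) {
    y <- seq_len(n)
    x <- y + seq_len(n)  # differences 1..n, no ties
    res <- compare_groups(x, y, paired = TRUE, alternative = "greater")
    expect_equal(res$p_value, 2^-n)
    expect_equal(res$direction, 1)
  }
})

test_that("design validation rejects incomplete or undersized inputs", {
  expect_error(compare_groups(c(1, 2, 3), c(1, 2), paired = TRUE), "equal-length")
  expect_error(compare_groups(c(1, NA, 3), c(1, 2, 3), paired = TRUE), "incomplete")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("rank-sum test matches exhaustive enumeration for all n <= 8", {
  withr::local_seed(91)
  for (n in 2:8) {
    for (m in unique(c(2, n, 8))) {
      x <- sample(seq_len(100), n)
      y <- sample(setdiff(seq_len(100), x), m)
      for (alt in c("two.sided", "greater", "less")) {
        got <- compare_groups(x, y, alternative = alt)
        want <- oracle_rank_sum(x, y, alternative = alt)
        expect_equal(got$statistic, want$statistic,
                     label = sprintf("W n=%d m=%d %s", n, m, alt))
        expect_equal(got$p_value, want$p_value, tolerance = 1e-12,
                     label = sprintf("p n=%d m=%d %s", n, m, alt))
      }
    }
  }
})

test_that("signed-rank test matches exhaustive enumeration for all n <= 8", {
  withr::local_seed(92)
  for (n in 2:8) {
    repeat {
      x <- sample(seq_len(50), n) + runif(n)
      y <- sample(seq_len(50), n) + runif(n)
      d <- x - y
      if (all(d != 0) && !anyDuplicated(abs(d))) break
    }
    for (alt in c("two.sided", "greater", "less")) {
      got <- compare_groups(x, y, paired = TRUE, alternative = alt)
      want <- oracle_signed_rank(x, y, alternative = alt)
      expect_equal(got$statistic, want$statistic,
                   label = sprintf("V n=%d %s", n, alt))
      expect_equal(got$p_value, want$p_value, tolerance = 1e-12,
                   label = sprintf("p n=%d %s", n, alt))
    }
  }
})

test_that("tied data falls back to the corrected normal approximation", {
  x <- c(1, 1, 2, 3, 3, 4)
  y <- c(2, 2, 3, 4, 4, 5)
  res <- compare_groups(x, y)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_match(res$method_detail, "correction")
})

test_that("spearman correlation matches the textbook rank formula", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$estimate, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$estimate, -1)
  withr::local_seed(93)
  for (i in 1:10) {
    x <- sample(100, 6)
    y <- sample(100, 6)
    expect_equal(spearman_cor(x, y)$estimate, oracle_spearman_rho(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(res <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$estimate))
  expect_error(spearman_cor(1:2, 1:2), ">= 3")
})

test_that("paired halving of Ka is detectable at realistic cohort power", {
  # reduced-scale rehearsal of the treatment design (full version in the
  # acceptance suite): 15 pairs, Ka halves, inter-subject CV 50%
  hits <- withr::with_seed(94, replicate(25, {
    design <- data.frame(subject_id = rep(sprintf("p%02d", 1:15), each = 2),
                         timepoint = rep(1:2, 15),
                         ka_scale = rep(c(1, 0.5), 15))
    recs <- simulate_cohort(design, flow_sim_config(n_events = 50000, ka_true = 0.5),
                            subject_sd = 0.1, ka_cv = 0.5, events = "counts",
                            seed = NULL)
    ka <- vapply(recs, function(r) ka_from_counts(r$counts)$ka, numeric(1))
    pre <- ka[seq(1, 30, 2)]; post <- ka[seq(2, 30, 2)]
    compare_groups(pre, post, paired = TRUE)$p_value < 0.05
  }))
  expect_gte(mean(hits), 0.8)
})
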