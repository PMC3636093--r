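test_that("walking t-test equals junction-by-junction t.test", {
  set.seed(101)
  for (rep in 1:60) {
    m <- sample(4:25, 1)
    v <- rnorm(m, mean = runif(1, -3, 3), sd = sample(c(0.05, 0.5, 2), 1))
    res <- walking_ttest(v)
    expect_equal(nrow(res), m - 3)
    for (k in seq_len(nrow(res))) {
      j <- res$junction[k]
      tt <- t.test(v[(j + 1):m], v[1:j], var.equal = TRUE)
      expect_equal(res$t_stat[k], unname(tt$statistic), tolerance = 1e-12)
      expect_equal(res$p_value[k], tt$p.value, tolerance = 1e-12)
    }
  }
})

test_that("degenerate and boundary profiles behave as documented", {
  res <- walking_ttest(rep(1.3, 8))
  expect_true(all(res$t_stat == 0))
  expect_true(all(res$p_value == 1))
  # zero pooled variance with unequal means: flagged, minimal p
  res <- walking_ttest(c(1, 1, 2, 2), min_group = 2)
  expect_true(res$flagged)
  expect_equal(res$p_value, .Machine$double.xmin)
  # length 3 with min_group 2: no testable junction
  expect_equal(nrow(walking_ttest(c(1, 2, 3), min_group = 2)), 0)
  # missing values are dropped but junction keeps original exon numbering
  v <- c(0, 0, NA, 0, 2, 2, 2)
  res <- walking_ttest(v)
  expect_true(all(res$junction %in% c(2, 4, 5)))
})

test_that("the minimum-P junction localises a planted step", {
  set.seed(1)
  v <- c(rep(0, 4), rep(2, 4)) + rnorm(8, sd = 0.01)
  res <- walking_ttest(v)
  expect_equal(res$junction[which.min(res$p_value)], 4)
  expect_gt(res$t_stat[res$junction == 4], 0)
})

test_that("reversing a profile mirrors junctions and negates t", {
  set.seed(7)
  v <- rnorm(12)
  a <- walking_ttest(v)
  b <- walking_ttest(rev(v))
  b <- b[order(-b$junction), ]
  expect_equal(a$junction, 12 - b$junction)
  expect_equal(a$t_stat, -b$t_stat, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("bonferroni_threshold divides alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 3218), 3), 1.55e-5)
  expect_equal(signif(bonferroni_threshold(0.05, 1807), 3), 2.77e-5)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("planted 3' elevation is recovered and census-restricted", {
  sim <- make_exon_matrix(n_genes = 40, n_samples = 3, noise_sd = 0.3,
                          breaks = data.frame(gene = "G0005", sample = "S002",
                                              junction = 6, step = 2),
                          seed = 21)
  cen <- census_list(names(sim$profiles), "either")
  calls <- call_expression_breakpoints(sim$profiles, cen)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$gene_id, "G0005")
  expect_equal(calls$sample_id, "S002")
  expect_equal(calls$junction_index, 6)
  expect_equal(calls$direction, "distal_elevated")
  expect_true(all(calls$p_value <= calls$p_threshold))
  # the same planted gene absent from the census is not emitted
  cen2 <- census_list(setdiff(names(sim$profiles), "G0005"), "either")
  expect_false("G0005" %in%
                 call_expression_breakpoints(sim$profiles, cen2)$gene_id)
})

test_that("increasing the planted step never weakens the minimum P", {
  set.seed(5)
  noise <- rnorm(10, sd = 0.3)
  last_p <- Inf
  for (step in c(0.5, 1, 1.5, 2, 3)) {
    v <- noise + c(rep(0, 5), rep(step, 5))
    p <- min(walking_ttest(v)$p_value)
    expect_lte(p, last_p)
    last_p <- p
  }
})

test_that("direction filter honours fusion roles", {
  calls <- data.frame(
    gene_id = c("A3", "A3", "B5", "E"), sample_id = "s",
    junction_index = 2L, t_stat = c(5, -5, 5, -5),
    p_value = 1e-9, p_threshold = 1e-5,
    direction = c("distal_elevated", "proximal_elevated",
                  "distal_elevated", "proximal_elevated"),
    n_tests_in_family = 100L, stringsAsFactors = FALSE)
  class(calls) <- c("rba_calls", "data.frame")
  cen <- census_list(c("A3", "B5", "E"),
                     c("three_prime", "five_prime", "either"))
  kept <- direction_filter(calls, cen)
  # 3' partner keeps distal elevation only; 5'-only gene loses it; either keeps all
  expect_equal(paste(kept$gene_id, kept$direction),
               c("A3 distal_elevated", "E proximal_elevated"))
  # empty census disables the filter
  expect_equal(nrow(direction_filter(calls, census_list(character(0)))), 4)
  # unknown gene in a non-empty census is an error
  expect_error(direction_filter(calls, census_list("A3", "three_prime")),
               "absent")
})
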