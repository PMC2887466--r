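test_that("off-target exclusion removes flagged amplicons with conservation", {
  zt <- data.frame(amplicon_id = c("A1", "A2", "A3"),
                   z = c(-5, 1, 3),
                   off_target = c(TRUE, FALSE, FALSE))
  out <- exclude_off_targets(zt)
  expect_equal(out$kept$amplicon_id, c("A2", "A3"))
  expect_equal(out$excluded$amplicon_id, "A1")
  expect_match(out$excluded$reason, "19 bp")
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(zt))
  # a -5 scorer that is flagged is not a hit anywhere downstream
  calls <- call_insulin_hits(data.frame(amplicon_id = out$kept$amplicon_id,
                                        avg_z = out$kept$z))
  expect_false("A1" %in% calls$amplicon_id)
  # no flags: unchanged
  zt$off_target <- FALSE
  expect_equal(exclude_off_targets(zt)$kept, zt)
  # flags joined from annotation when the table lacks them
  ann <- data.frame(amplicon_id = c("A1", "A2", "A3"),
                    off_target = c(FALSE, TRUE, FALSE))
  out2 <- exclude_off_targets(zt[, c("amplicon_id", "z")], ann)
  expect_equal(out2$excluded$amplicon_id, "A2")
})

test_that("replicate averaging is the arithmetic mean with n recorded", {
  zt <- data.frame(amplicon_id = c("A1", "A1", "A2"),
                   replicate = c(1, 2, 1),
                   z = c(2, 3, -2.6))
  avg <- average_replicates(zt)
  expect_equal(avg$avg_z[avg$amplicon_id == "A1"], 2.5)
  expect_equal(avg$n_replicates[avg$amplicon_id == "A1"], 2L)
  expect_equal(avg$avg_z[avg$amplicon_id == "A2"], -2.6)
  expect_equal(avg$n_replicates[avg$amplicon_id == "A2"], 1L)
  # averaging an already averaged table is the identity
  avg$replicate <- 1L
  avg2 <- average_replicates(avg, z_col = "avg_z")
  expect_equal(avg2$avg_z, avg$avg_z)
})

test_that("insulin calls use the inclusive +/- 2.5 boundary", {
  avg <- data.frame(amplicon_id = sprintf("A%d", 1:5),
                    avg_z = c(-2.6, -2.5, 0, 2.5, 2.49))
  out <- call_insulin_hits(avg)
  expect_equal(out$call, c("suppressor", "suppressor", "none",
                           "enhancer", "none"))
  out2 <- call_insulin_hits(avg, cutoff = 3)
  expect_equal(out2$call, rep("none", 5))
})

test_that("reference-panel recall is per class with misses listed", {
  calls <- data.frame(amplicon_id = sprintf("A%d", 1:10),
                      call = c(rep("suppressor", 5), rep("none", 5)))
  ann <- data.frame(amplicon_id = sprintf("A%d", 1:10),
                    known_component_class = c(rep("upstream_InR_branch", 8),
                                              "none", "none"))
  out <- evaluate_reference_panel(calls, ann)
  expect_equal(out$recall$n, 8)
  expect_equal(out$recall$n_called, 5)
  expect_equal(out$recall$recall, 5 / 8)
  expect_setequal(out$misses$upstream_InR_branch, sprintf("A%d", 6:8))
  # fully recovered panel
  calls$call <- "suppressor"
  expect_equal(evaluate_reference_panel(calls, ann)$recall$recall, 1)
})

test_that("the pooled t-test matches its closed form and symmetries", {
  a <- c(1, 2, 3)
  expect_equal(two_sample_ttest(a, a)$t, 0)
  expect_equal(two_sample_ttest(a, a)$p, 1)
  set.seed(61)
  b <- rnorm(8, 1)
  g <- rnorm(6)
  got <- two_sample_ttest(g, b)
  # independent closed-form computation
  sp2 <- (sum((g - mean(g))^2) + sum((b - mean(b))^2)) / (6 + 8 - 2)
  t_oracle <- (mean(g) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 8))
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_oracle), 12), tolerance = 1e-12)
  # swapping groups flips t, keeps p
  swapped <- two_sample_ttest(b, g)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  # a well-separated contrast is highly significant
  expect_lt(two_sample_ttest(c(0, 0, 0, 0),
                             c(1, 1, 1, 1) + rnorm(4, 0, 1e-4))$p, 1e-4)
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("ranked reports are stably ordered with conservation", {
  avg <- data.frame(amplicon_id = c("B", "A", "C", "D"),
                    avg_z = c(0, -3, 2, 0))
  out <- ranked_z_report(avg)
  expect_equal(out$rank, 1:4)
  expect_equal(out$amplicon_id, c("A", "B", "D", "C"))  # tie broken by id
  expect_equal(nrow(out), nrow(avg))
  ann <- data.frame(amplicon_id = "A", known_component_class = "tsc_tor_branch")
  out2 <- ranked_z_report(avg, ann)
  expect_equal(out2$known_component_class,
               c("tsc_tor_branch", "none", "none", "none"))
})
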