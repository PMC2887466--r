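test_that("plate decomposition partitions wells into four 96-well groups", {
  df <- make_plate_df(seed = 51, condition = "baseline")
  groups <- decompose_plate(df)
  expect_equal(vapply(groups, nrow, integer(1)), rep(96L, 4))
  expect_setequal(do.call(rbind, groups)$well, df$well)
  # a missing corner well shrinks exactly its own group
  groups2 <- decompose_plate(df[df$well != "A1", ])
  expect_equal(vapply(groups2, nrow, integer(1)), c(95L, 96L, 96L, 96L))
})

test_that("group standardization sets mean 0 / SD 1 and is affine-invariant", {
  expect_equal(standardize_group(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(52)
  v <- rlnorm(96, 0, 0.4)
  s <- standardize_group(v)
  expect_lt(abs(mean(s)), 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  # any affine transform of the input yields identical output
  expect_equal(standardize_group(3.7 * v + 11), s, tolerance = 1e-10)
  expect_error(standardize_group(rep(2, 96), "P01 quadrant 2"), "P01 quadrant 2")
  expect_error(standardize_group(c(1)), "2 distinct")
})

test_that("recombined plate Z stays close to the standardized values", {
  set.seed(53)
  df <- make_plate_df(seed = 53, condition = "baseline")
  df$ratio <- df$pdakt / df$nucfl
  z <- recombine_and_zscore(df)
  # each group is mean-0/SD-1, so plate mean ~ 0, SD ~ 1, z ~ standardized v
  qd <- well_quadrant(df$row, df$col)
  std <- rep(NA_real_, 384)
  for (g in 1:4) std[qd == g] <- standardize_group(df$ratio[qd == g])
  expect_equal(z, std, tolerance = 0.02)
  # identical groups: z = v' / sqrt(4*95/383) exactly (pooling factor)
  df4 <- df
  for (g in 1:4) df4$ratio[qd == g] <- df$ratio[qd == 1]
  z4 <- recombine_and_zscore(df4)
  v1 <- standardize_group(df4$ratio[qd == 1])
  expect_equal(z4[qd == 2], v1 / sqrt(4 * 95 / 383), tolerance = 1e-10)
})

test_that("per-(plate, quadrant) batch offsets are removed exactly", {
  df <- make_plate_df(seed = 54, condition = "baseline")
  df$ratio <- df$pdakt / df$nucfl
  z0 <- recombine_and_zscore(df)
  qd <- well_quadrant(df$row, df$col)
  df2 <- df
  # multiplicative offsets, as produced by per-quadrant log2 shifts
  for (g in 1:4) df2$ratio[qd == g] <- df2$ratio[qd == g] * 2^c(0.5, -0.7, 1.2, 0)[g]
  z2 <- recombine_and_zscore(df2)
  expect_equal(z2, z0, tolerance = 1e-10)
})

test_that("the baseline pipeline calls planted enhancers and conserves wells", {
  cfg <- screen_config(n_plates = 6, n_suppressors = 0, n_enhancers = 10,
                       hit_strength_sd = 5, off_target_fraction = 0.05,
                       panel_upstream_mult = numeric(0),
                       panel_tsc_tor_mult = numeric(0),
                       conditions = "baseline", seed = 55)
  sim <- simulate_screen(cfg)
  res <- run_baseline_screen(sim$dataset)
  enh <- sim$truth$amplicon_id[sim$truth$class == "enhancer"]
  calls <- res$amplicons$call[match(enh, res$amplicons$amplicon_id)]
  expect_true(mean(calls == "enhancer") >= 0.9)
  # conservation: scored + excluded = all sample wells
  n_sample <- sum(sim$dataset$control_class == "sample")
  expect_equal(nrow(res$wells), n_sample)
  expect_equal(nrow(res$amplicons) + length(unique(res$excluded$amplicon_id)),
               cfg$n_plates * 384)
  # boundary: calls match the stated inclusive cutoff
  expect_true(all(abs(res$amplicons$avg_z_baseline[res$amplicons$call != "none"]) >= 3))
})
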