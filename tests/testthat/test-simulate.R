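small_cfg <- function(...) {
  screen_config(n_plates = 4, n_suppressors = 10, n_enhancers = 10,
                panel_upstream_mult = c(-6, -1), panel_tsc_tor_mult = c(6, 1),
                off_target_fraction = 0.05, ...)
}

test_that("a fixed seed reproduces the dataset byte for byte", {
  s1 <- simulate_screen(small_cfg(seed = 81))
  s2 <- simulate_screen(small_cfg(seed = 81))
  expect_identical(as.data.frame(s1$dataset), as.data.frame(s2$dataset))
  expect_identical(s1$truth, s2$truth)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(s1$dataset, p1)
  write_screen_csv(s2$dataset, p2)
  expect_identical(readLines(p1), readLines(p2))
  s3 <- simulate_screen(small_cfg(seed = 82))
  expect_false(identical(s1$dataset$pdakt, s3$dataset$pdakt))
})

test_that("a noise-free screen yields zero residuals and zero Z", {
  cfg <- screen_config(n_plates = 3, sigma0 = 0, sigma1 = 0, edge_amp = 0,
                       tau_baseline = 0, tau_insulin = 0,
                       n_suppressors = 0, n_enhancers = 0,
                       panel_upstream_mult = numeric(0),
                       panel_tsc_tor_mult = numeric(0),
                       off_target_fraction = 0, seed = 83)
  sim <- simulate_screen(cfg)
  ins <- run_insulin_screen(sim$dataset)
  expect_lt(max(abs(ins$wells$residual), na.rm = TRUE), 1e-9)
  # Z inherits only float rounding amplified by the SD floor
  expect_lt(max(abs(ins$wells$z), na.rm = TRUE), 1e-3)
  expect_equal(sum(ins$amplicons$call != "none"), 0)
})

test_that("low cell-count wells are noisier than high ones by design", {
  cfg <- screen_config(n_plates = 8, conditions = "insulin",
                       n_suppressors = 0, n_enhancers = 0,
                       panel_upstream_mult = numeric(0),
                       panel_tsc_tor_mult = numeric(0),
                       off_target_fraction = 0, seed = 84)
  sim <- simulate_screen(cfg)
  norm <- normalize_screen(sim$dataset)
  w <- norm$wells[norm$wells$status == "ok" & norm$wells$control_class == "sample", ]
  dec <- quantile(w$nucfl, c(0.1, 0.9))
  sd_low <- sd(w$residual[w$nucfl <= dec[1]])
  sd_high <- sd(w$residual[w$nucfl >= dec[2]])
  expect_gt(sd_low, sd_high)
})

test_that("invalid configurations fail before any generation", {
  expect_error(screen_config(sigma0 = -0.1), "sigma0")
  expect_error(screen_config(off_target_fraction = 1.5), "off_target_fraction")
  expect_error(screen_config(hit_strength_sd = 0), "hit_strength_sd")
  expect_error(screen_config(n_plates = 2, n_suppressors = 200),
               "source-plate groups")
  expect_error(screen_config(conditions = "starved"))
})

test_that("ground truth is consistent with the emitted dataset", {
  sim <- simulate_screen(small_cfg(seed = 85))
  tr <- sim$truth
  expect_equal(as.vector(table(tr$class)[c("suppressor", "enhancer")]),
               c(10L, 10L))
  # off-target flags never touch planted hits or panel members
  expect_false(any(tr$off_target & tr$class != "null"))
  # flags in the dataset match the truth table
  d <- as.data.frame(sim$dataset)
  m <- match(d$amplicon_id[d$control_class == "sample"], tr$amplicon_id)
  expect_identical(d$off_target[d$control_class == "sample"], tr$off_target[m])
  # spike-in placement: at most one planted hit per source-plate group
  lay <- d[d$condition == d$condition[1] & d$replicate == 1 &
             d$control_class == "sample", ]
  lay$group <- paste(lay$plate, lay$quadrant)
  sup_groups <- lay$group[lay$amplicon_id %in% tr$amplicon_id[tr$class == "suppressor"]]
  expect_equal(anyDuplicated(sup_groups), 0L)
  # effect directions: suppressors act under insulin, enhancers at baseline
  expect_true(all(tr$delta_insulin[tr$class == "suppressor"] < 0))
  expect_true(all(tr$delta_baseline[tr$class == "enhancer"] > 0))
  expect_true(all(tr$delta_baseline[tr$class == "suppressor"] == 0))
  # annotation carries the panel classes
  expect_equal(sum(sim$annotation$known_component_class == "upstream_InR_branch"), 2)
  expect_equal(sum(sim$annotation$known_component_class == "tsc_tor_branch"), 2)
})

test_that("quadrant-offset amplitude changes nothing but the offsets", {
  cfg0 <- small_cfg(seed = 86, tau_baseline = 0)
  cfg1 <- small_cfg(seed = 86, tau_baseline = 0.6)
  s0 <- simulate_screen(cfg0)
  s1 <- simulate_screen(cfg1)
  d0 <- as.data.frame(s0$dataset)
  d1 <- as.data.frame(s1$dataset)
  expect_identical(d0$nucfl, d1$nucfl)  # identical underlying draws
  ins <- d0$condition == "insulin"
  expect_identical(d0$pdakt[ins], d1$pdakt[ins])  # insulin untouched
  bas <- d0$condition == "baseline" & d0$control_class == "sample"
  # baseline signals differ only by a per-(plate, quadrant) factor
  ratio <- log2(d1$pdakt[bas] / d0$pdakt[bas])
  grp <- paste(d0$plate[bas], d0$replicate[bas], d0$quadrant[bas])
  spread <- tapply(ratio, grp, function(x) max(x) - min(x))
  expect_lt(max(spread), 1e-9)
})

test_that("follow-up simulations emit standards plus treated replicates", {
  trt <- data.frame(treatment = c("a", "b", "c"),
                    delta_baseline = c(0, 0.5, -0.5),
                    delta_insulin = 0)
  cfg <- screen_config(seed = 87)
  sim <- simulate_followup(cfg, trt, n_replicates = 7, seed = 87)
  d <- as.data.frame(sim$dataset)
  for (cond in c("baseline", "insulin")) {
    expect_equal(sum(d$control_class == "untreated" & d$condition == cond), 768)
    expect_equal(sum(d$control_class == "sample" & d$condition == cond), 21)
  }
  sim2 <- simulate_followup(cfg, trt, n_replicates = 7, seed = 87)
  expect_identical(as.data.frame(sim2$dataset), d)
})
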