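test_that("degenerate windows fall back to the SD floor", {
  cv <- seq_len(50)
  m <- fit_local_error_model(cv, cv, k = 11, weighting = "uniform",
                             sd_floor = 1e-8)
  # values equal to the covariate: interior local mean is the query itself
  expect_equal(predict(m, 25)$mean, 25, tolerance = 1e-12)
  mc <- fit_local_error_model(cv, rep(7, 50), k = 10)
  pc <- predict(mc, 25)
  expect_equal(pc$mean, 7)
  expect_equal(pc$sd, 1e-8)
})

test_that("a whole-data uniform window reproduces global mean and sample SD", {
  set.seed(5)
  v <- rnorm(200, 3, 2)
  cv <- runif(200)
  m <- fit_local_error_model(cv, v, k = 200, weighting = "uniform")
  p <- predict(m, c(0.2, 0.9))
  expect_equal(p$mean, rep(mean(v), 2), tolerance = 1e-12)
  expect_equal(p$sd, rep(sd(v), 2), tolerance = 1e-12)
})

test_that("evaluation equals the brute-force oracle, including ties", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(30:400, 1)
    k <- sample(8:min(n, 60), 1)
    weighting <- sample(c("tricube", "uniform"), 1)
    cv <- round(rnorm(n), sample(c(1, 2, 8), 1))  # coarse rounding forces ties
    v <- rnorm(n)
    m <- fit_local_error_model(cv, v, k = k, weighting = weighting)
    q <- c(rnorm(30), min(cv) - 1, max(cv) + 1, sample(cv, 5))
    got <- predict(m, q)
    want <- brute_force_local(cv, v, k, weighting, 1e-8, q)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
  }
})

test_that("out-of-range queries clamp to the edge neighborhood", {
  set.seed(7)
  m <- fit_local_error_model(runif(100, 0, 10), rnorm(100), k = 20)
  lo <- predict(m, c(-5, m$c[1]))
  expect_equal(lo$mean[1], lo$mean[2])
  expect_equal(lo$sd[1], lo$sd[2])
  hi <- predict(m, c(99, m$c[100]))
  expect_equal(hi$mean[1], hi$mean[2])
  # determinism on repeated queries
  p1 <- predict(m, rep(3.3, 2))
  expect_identical(p1$mean[1], p1$mean[2])
})

test_that("fit preconditions are enforced", {
  expect_error(fit_local_error_model(1:10, 1:10, k = 7), "k must be >= 8")
  expect_error(fit_local_error_model(1:6, 1:6, k = 8), "at least k")
  expect_error(fit_local_error_model(c(1:9, NA), 1:10, k = 8), "non-finite")
  expect_error(fit_local_error_model(1:10, 1:10, k = 8, sd_floor = 0),
               "sd_floor")
})

test_that("Z-scores express deviation in local SDs", {
  set.seed(9)
  cv <- runif(500, 0, 1)
  v <- rnorm(500)
  m <- fit_local_error_model(cv, v, k = 100)
  p <- predict(m, 0.5)
  expect_equal(local_zscore(p$mean, 0.5, m), 0)
  expect_equal(local_zscore(p$mean + 2 * p$sd, 0.5, m), 2)
})

test_that("interior local SD concentrates near truth on a flat null", {
  set.seed(123)
  n <- 10000
  cv <- runif(n)
  v <- rnorm(n)  # values independent of covariate, SD 1
  m <- fit_local_error_model(cv, v, k = 500, weighting = "tricube")
  q <- seq(0.1, 0.9, length.out = 25)  # interior queries
  p <- predict(m, q)
  expect_true(all(p$sd > 0.9 & p$sd < 1.1))
  expect_true(all(abs(p$mean) < 0.2))
  # Z-scores over all wells are approximately standard normal
  z <- local_zscore(v, cv, m)
  expect_gt(sd(z), 0.97)
  expect_lt(sd(z), 1.03)
})

test_that("the exported curve covers the training range on a grid", {
  set.seed(2)
  m <- fit_local_error_model(runif(300, 2, 9), rnorm(300), k = 50)
  crv <- error_model_curve(m, n_grid = 40)
  expect_equal(nrow(crv), 40)
  expect_equal(crv$covariate[1], m$c[1])
  expect_equal(crv$covariate[40], m$c[300])
  expect_true(all(is.finite(crv$local_mean) & crv$local_sd > 0))
})
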