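# Independent brute-force oracle for the local error model: sorts the
# training data, ranks every training point by (distance, sorted index)
# for each query, and recomputes the weighted statistics directly. Shares
# no code with the package's windowed implementation.
brute_force_local <- function(covariate, value, k, weighting, sd_floor, queries) {
  ord <- order(covariate)
  cs <- covariate[ord]
  vs <- value[ord]
  n <- length(cs)
  m_out <- s_out <- numeric(length(queries))
  for (i in seq_along(queries)) {
    q <- min(max(queries[i], cs[1]), cs[n])  # clamp
    d <- abs(cs - q)
    nb <- order(d, seq_len(n))[seq_len(k)]
    dn <- d[nb]
    if (weighting == "tricube") {
      dmax <- max(dn)
      w <- if (dmax > 0) (1 - (dn / dmax)^3)^3 else rep(1, k)
      if (sum(w) == 0) w <- rep(1, k)
    } else {
      w <- rep(1, k)
    }
    W <- sum(w)
    W2 <- sum(w^2)
    m <- sum(w * vs[nb]) / W
    denom <- W - W2 / W
    s <- sqrt(max(sum(w * (vs[nb] - m)^2), 0) / denom)
    if (!is.finite(s)) s <- 0
    m_out[i] <- m
    s_out[i] <- max(s, sd_floor)
  }
  list(mean = m_out, sd = s_out)
}

# One full synthetic plate as a raw measurement data.frame.
make_plate_df <- function(plate = "P01", replicate = 1, condition = "insulin",
                          seed = 1, n = 384) {
  set.seed(seed)
  addr <- plate_addresses()[seq_len(n), ]
  nucfl <- rlnorm(n, log(1e4), 0.5)
  data.frame(plate = plate, replicate = replicate, condition = condition,
             well = addr$well, row = addr$row, col = addr$col,
             amplicon_id = sprintf("AMP%03d", seq_len(n)),
             control_class = "sample", off_target = FALSE,
             pdakt = 2^(8 + 0.9 * log2(nucfl) + rnorm(n, 0, 0.2)),
             nucfl = nucfl, stringsAsFactors = FALSE)
}

# Closed-form OLS via the normal equations (independent of lm.fit).
ols_normal_equations <- function(x, y) {
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  n <- length(x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}
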