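#' Locally weighted, cell-number-dependent error model
#'
#' The screen's measurement noise depends strongly on the number of cells
#' in a well, so deviations are scored against a local mean and local
#' standard deviation estimated as a function of the cell-number covariate
#' rather than against global statistics. The model is a k-nearest-neighbor
#' smoother: for a query covariate `c`, the `k` training points closest in
#' covariate (ties broken toward the lower index in the sorted training
#' data) form the neighborhood; tricube weights
#' `w_i = (1 - (d_i/d_max)^3)^3` (or uniform weights) give the local
#' weighted mean and the reliability-weighted sample standard deviation
#' `s^2 = sum(w (v - m)^2) / (W - W2/W)` with `W = sum(w)`,
#' `W2 = sum(w^2)`. With uniform weights this reduces to the ordinary
#' n-1 sample SD of the window. The returned SD is floored at `sd_floor`
#' so Z-scores are always finite. Queries outside the training covariate
#' range are clamped to the nearest edge: the model never extrapolates,
#' because covariate extremes are exactly where the assay is least
#' reliable.
#'
#' @param covariate,value numeric training vectors (finite, equal length).
#' @param k neighborhood size, at least 8 and at most `length(covariate)`.
#'   Default `max(200, ceiling(0.05 * n))`, capped at `n`.
#' @param weighting `"tricube"` (default) or `"uniform"`.
#' @param sd_floor minimum SD returned (default `1e-8`).
#' @return object of class `local_error_model`.
#' @seealso [predict.local_error_model()], [local_zscore()]
#' @export
fit_local_error_model <- function(covariate, value, k = NULL,
                                  weighting = c("tricube", "uniform"),
                                  sd_floor = 1e-8) {
  weighting <- match.arg(weighting)
  if (length(covariate) != length(value)) {
    stop("covariate and value must have equal length", call. = FALSE)
  }
  if (!all(is.finite(covariate)) || !all(is.finite(value))) {
    stop("non-finite training values in error model", call. = FALSE)
  }
  n <- length(covariate)
  if (is.null(k)) k <- min(n, max(200L, as.integer(ceiling(0.05 * n))))
  k <- as.integer(k)
  if (k < 8L) stop("window size k must be >= 8", call. = FALSE)
  if (n < k) stop("need at least k = ", k, " training pairs, got ", n,
                  call. = FALSE)
  if (!(sd_floor > 0)) stop("sd_floor must be positive", call. = FALSE)
  ord <- order(covariate)  # stable; ties keep input order
  structure(
    list(c = covariate[ord], v = value[ord], k = k,
         weighting = weighting, sd_floor = sd_floor, n = n),
    class = "local_error_model")
}

#' @export
print.local_error_model <- function(x, ...) {
  cat(sprintf(
    "local_error_model: n = %d, k = %d, %s weights, covariate range [%.4g, %.4g]\n",
    x$n, x$k, x$weighting, x$c[1], x$c[x$n]))
  invisible(x)
}

# Window start (1-based, into the sorted training data) of the k-nearest
# neighborhood of each query. The neighborhood is contiguous in sorted
# order; starting from j = 1 the window advances while the candidate just
# right of it is strictly closer than the window's left end
# ((c - cs[j]) > (cs[j+k] - c)); a distance tie keeps the left (lower
# index) point. The advance condition is monotone in j, found by binary
# search, vectorized over queries.
.window_start <- function(cs, k, q) {
  n <- length(cs)
  if (n == k) return(rep(1L, length(q)))
  lo <- rep(1L, length(q))
  hi <- rep(n - k + 1L, length(q))
  act <- which(lo < hi)
  while (length(act) > 0) {
    mid <- (lo[act] + hi[act]) %/% 2L   # mid <= n - k, so cs[mid + k] exists
    adv <- (q[act] - cs[mid]) > (cs[mid + k] - q[act])
    lo[act] <- ifelse(adv, mid + 1L, lo[act])
    hi[act] <- ifelse(adv, hi[act], mid)
    act <- act[lo[act] < hi[act]]
  }
  lo
}

# Exact (distance, index)-ordered neighborhood statistics for one query;
# used when tied covariate values make the k-nearest set non-contiguous
# (a run of equal covariates crossing the window's left edge, where the
# lower-index tie rule prefers the run's first elements).
.exact_local <- function(cs, vs, k, weighting, q) {
  d <- abs(cs - q)
  nb <- order(d, seq_along(cs))[seq_len(k)]
  dn <- d[nb]
  if (weighting == "tricube") {
    dmax <- max(dn)
    w <- if (dmax > 0) (1 - (dn / dmax)^3)^3 else rep(1, k)
    if (sum(w) == 0) w <- rep(1, k)
  } else {
    w <- rep(1, k)
  }
  W <- sum(w)
  W2 <- sum(w * w)
  m <- sum(w * vs[nb]) / W
  denom <- W - W2 / W
  s <- sqrt(max(sum(w * (vs[nb] - m)^2), 0) / denom)
  c(m, if (is.finite(s)) s else 0)
}

#' Evaluate the local mean and SD at query covariates
#'
#' Deterministic: identical queries give identical results. Queries beyond
#' the training range are clamped to the nearest edge neighborhood.
#'
#' @param object a fitted [fit_local_error_model()] model.
#' @param newdata numeric vector of query covariates.
#' @param ... unused.
#' @return list with numeric vectors `mean` and `sd`.
#' @export
predict.local_error_model <- function(object, newdata, ...) {
  q <- pmin(pmax(newdata, object$c[1]), object$c[object$n])  # clamp
  k <- object$k
  cs <- object$c
  vs <- object$v
  m_out <- numeric(length(q))
  s_out <- numeric(length(q))
  chunk <- 1024L
  for (i0 in seq(1L, length(q), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(q))
    j <- .window_start(cs, k, q[idx])
    cols <- outer(j, 0:(k - 1L), "+")
    cw <- matrix(cs[cols], nrow = length(idx))
    vw <- matrix(vs[cols], nrow = length(idx))
    if (object$weighting == "tricube") {
      d <- abs(cw - q[idx])
      dmax <- pmax(d[, 1L], d[, k])  # max distance is at a window end
      w <- (1 - (d / ifelse(dmax > 0, dmax, 1))^3)^3
      w[dmax == 0, ] <- 1          # all-equal covariates: uniform fallback
      degen <- rowSums(w) == 0     # all points at d == dmax
      w[degen, ] <- 1
    } else {
      w <- matrix(1, nrow = length(idx), ncol = k)
    }
    W <- rowSums(w)
    W2 <- rowSums(w * w)
    m <- rowSums(w * vw) / W
    denom <- W - W2 / W
    ss <- rowSums(w * (vw - m)^2)
    s <- sqrt(pmax(ss, 0) / denom)
    s[!is.finite(s)] <- 0
    # tied covariates crossing the left window edge: the lower-index tie
    # rule wants the first elements of the run, so the set is not the
    # contiguous window; recompute those queries exactly
    fix <- which(j > 1L & cs[pmax(j - 1L, 1L)] == cs[j] &
                   (q[idx] - cs[j]) >= (cs[j + k - 1L] - q[idx]))
    for (f in fix) {
      ms <- .exact_local(cs, vs, k, object$weighting, q[idx[f]])
      m[f] <- ms[1]
      s[f] <- ms[2]
    }
    m_out[idx] <- m
    s_out[idx] <- pmax(s, object$sd_floor)
  }
  list(mean = m_out, sd = s_out)
}

#' Z-scores against a local error model
#'
#' `z = (value - m(c)) / s(c)`: the deviation of a well's value from the
#' local average at its covariate, expressed in multiples of the local
#' standard deviation. Finiteness is guaranteed by the model's SD floor.
#'
#' @param value numeric vector of observed values.
#' @param covariate matching covariate vector.
#' @param model a fitted [fit_local_error_model()] model.
#' @return numeric vector of Z-scores.
#' @export
local_zscore <- function(value, covariate, model) {
  stopifnot(inherits(model, "local_error_model"),
            length(value) == length(covariate))
  p <- predict(model, covariate)
  (value - p$mean) / p$sd
}

#' Export the fitted local mean/SD curve on a covariate grid
#'
#' @param model a fitted [fit_local_error_model()] model.
#' @param n_grid number of equally spaced grid points over the training
#'   covariate range.
#' @return data.frame with columns `covariate`, `local_mean`, `local_sd`.
#' @export
error_model_curve <- function(model, n_grid = 200) {
  g <- seq(model$c[1], model$c[model$n], length.out = n_grid)
  p <- predict(model, g)
  data.frame(covariate = g, local_mean = p$mean, local_sd = p$sd)
}
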