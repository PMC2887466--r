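#' Cell-number normalization of the phospho-signal
#'
#' Each well's phospho-signal is divided by its nuclear-fluorescence
#' cell-number proxy, and the ratio is log2-transformed. Wells where either
#' signal is zero cannot be normalized and are flagged
#' `excluded_zero_signal` rather than producing non-finite values; negative
#' inputs indicate corrupt data and are a hard error.
#'
#' @param pdakt,nucfl non-negative numeric vectors (arbitrary units).
#' @return data.frame with columns `ratio`, `log2_ratio`, `status`
#'   (`"ok"` or `"excluded_zero_signal"`); `ratio`/`log2_ratio` are `NA`
#'   for excluded wells.
#' @export
compute_log_ratio <- function(pdakt, nucfl) {
  if (any(pdakt < 0, na.rm = TRUE) || any(nucfl < 0, na.rm = TRUE)) {
    stop("negative signal values (corrupt data)", call. = FALSE)
  }
  ok <- !is.na(pdakt) & !is.na(nucfl) & pdakt > 0 & nucfl > 0
  ratio <- ifelse(ok, pdakt / nucfl, NA_real_)
  data.frame(
    ratio = ratio,
    log2_ratio = ifelse(ok, log2(ratio), NA_real_),
    status = ifelse(ok, "ok",
                    ifelse(is.na(pdakt) | is.na(nucfl), "excluded_missing",
                           "excluded_zero_signal")),
    stringsAsFactors = FALSE)
}

#' Per-plate regression of the log ratio on the cell-number covariate
#'
#' Ordinary least squares of `log2(pdakt/nucfl)` on the covariate
#' (by default `log2(nucfl)`), fitted separately for each screening plate.
#' Residuals inherit the OLS orthogonality identities: they sum to zero and
#' are uncorrelated with the covariate.
#'
#' @param x covariate values of the plate's usable wells.
#' @param y log2 ratio values, same length.
#' @param plate_label label used in error messages.
#' @return list with `slope`, `intercept`, `n_used`, `residuals` (aligned
#'   with `x`).
#' @export
fit_plate_regression <- function(x, y, plate_label = "<plate>") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop("plate ", plate_label, ": fewer than 3 usable wells for regression",
         call. = FALSE)
  }
  if (max(x) - min(x) <= 0) {
    stop("plate ", plate_label, ": constant covariate, regression undefined",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(intercept = 1, slope = x), y)
  list(slope = unname(fit$coefficients["slope"]),
       intercept = unname(fit$coefficients["intercept"]),
       n_used = length(x),
       residuals = unname(fit$residuals),
       keep = keep)
}

#' Normalize an insulin-condition screen replicate and pool residuals
#'
#' Stage 1 of the insulin-screen pipeline. For every plate of each
#' replicate of the requested condition: compute per-well
#' `log2(pdakt/nucfl)`, regress it on the covariate by OLS, and keep the
#' residuals. Residuals of all plates of one genome-wide screen replicate
#' are then pooled (replicates are never mixed at this stage). Every input
#' well lands either in the pooled table (`status == "ok"`) or in the
#' returned table with its exclusion status.
#'
#' @param dataset a [screen_dataset].
#' @param condition condition to process (default `"insulin"`).
#' @param covariate `"log2_nucfl"` (default) or `"nucfl"`: the regressor
#'   and, downstream, the error-model covariate.
#' @param include_controls logical; include control wells in the per-plate
#'   fit (default `TRUE`). Empty wells never enter fits.
#' @return list with elements
#'   `wells` (per-well table: identifiers, ratio, log2 ratio, covariate,
#'   residual, status), `fits` (per-plate slope/intercept/n_used), and
#'   `condition`/`covariate` metadata. Class `pooled_residuals`.
#' @export
normalize_screen <- function(dataset, condition = "insulin",
                             covariate = c("log2_nucfl", "nucfl"),
                             include_controls = TRUE) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(dataset, "screen_dataset"))
  d <- as.data.frame(dataset)
  d <- d[d$condition == condition, , drop = FALSE]
  if (nrow(d) == 0) stop("no wells with condition '", condition, "'", call. = FALSE)
  d <- d[d$control_class != "empty", , drop = FALSE]
  if (!include_controls) {
    fit_eligible <- d$control_class == "sample"
  } else {
    fit_eligible <- rep(TRUE, nrow(d))
  }

  lr <- compute_log_ratio(d$pdakt, d$nucfl)
  d$ratio <- lr$ratio
  d$log2_ratio <- lr$log2_ratio
  d$status <- lr$status
  d$covariate <- if (covariate == "log2_nucfl") {
    ifelse(d$nucfl > 0, log2(d$nucfl), NA_real_)
  } else {
    d$nucfl
  }
  d$residual <- NA_real_

  fits <- NULL
  for (rep_i in sort(unique(d$replicate))) {
    for (plate_i in unique(d$plate[d$replicate == rep_i])) {
      sel <- which(d$replicate == rep_i & d$plate == plate_i)
      use <- sel[d$status[sel] == "ok" & fit_eligible[sel] &
                   is.finite(d$covariate[sel])]
      fit <- fit_plate_regression(d$covariate[use], d$log2_ratio[use],
                                  plate_label = sprintf("%s/rep%d", plate_i, rep_i))
      d$residual[use] <- fit$residuals
      # score wells excluded from the fit (e.g. controls when
      # include_controls = FALSE) against the same line
      rest <- setdiff(sel[d$status[sel] == "ok" & is.finite(d$covariate[sel])], use)
      if (length(rest) > 0) {
        d$residual[rest] <- d$log2_ratio[rest] -
          (fit$intercept + fit$slope * d$covariate[rest])
      }
      fits <- rbind(fits, data.frame(
        plate = plate_i, replicate = rep_i, condition = condition,
        slope = fit$slope, intercept = fit$intercept, n_used = fit$n_used,
        stringsAsFactors = FALSE))
    }
  }
  cols <- c("plate", "replicate", "condition", "well", "row", "col", "quadrant",
            "amplicon_id", "control_class", "off_target", "pdakt", "nucfl",
            "ratio", "log2_ratio", "covariate", "residual", "status")
  out <- list(wells = d[, cols], fits = fits, condition = condition,
              covariate = covariate)
  class(out) <- "pooled_residuals"
  out
}

#' Pooled residual table of one screen replicate
#'
#' @param norm result of [normalize_screen()].
#' @param replicate replicate number.
#' @return data.frame of the replicate's `status == "ok"` wells with their
#'   covariate and residual (one row per usable well).
#' @export
pool_residuals <- function(norm, replicate) {
  stopifnot(inherits(norm, "pooled_residuals"))
  w <- norm$wells
  fitted_plates <- norm$fits$plate[norm$fits$replicate == replicate]
  plates <- unique(w$plate[w$replicate == replicate])
  if (length(setdiff(plates, fitted_plates)) > 0) {
    stop("unfitted plate(s) present: ",
         paste(setdiff(plates, fitted_plates), collapse = ", "), call. = FALSE)
  }
  w[w$replicate == replicate & w$status == "ok" & is.finite(w$residual), ,
    drop = FALSE]
}
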