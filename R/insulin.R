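#' Run the insulin-stimulated screen pipeline end to end
#'
#' The full pipeline for the stimulated screen: per-well
#' `log2(pdakt/nucfl)` ratios, per-plate OLS regression on the cell-number
#' covariate, pooling of residuals per genome-wide replicate, a locally
#' weighted cell-number-dependent error model fitted on each replicate's
#' pooled residuals, per-well Z-scores from the local mean/SD, plate
#' position-effect correction across each replicate, off-target exclusion,
#' replicate averaging, and the fixed cutoff (default +/- 2.5 SD;
#' suppressors below, enhancers above, boundary inclusive).
#'
#' @param dataset a [screen_dataset].
#' @param cutoff hit cutoff in SDs (default 2.5).
#' @param k error-model neighborhood size; `NULL` (default) uses
#'   `max(200, 0.05 n)` of the pooled residuals.
#' @param weighting error-model weighting, `"tricube"` (default) or
#'   `"uniform"`.
#' @param covariate `"log2_nucfl"` (default) or `"nucfl"`.
#' @param position_correct apply position-effect correction (default
#'   `TRUE`).
#' @param include_controls include control wells in the per-plate fits
#'   (default `TRUE`).
#' @return list of class `insulin_result`: `wells` (per-well table with
#'   `z_raw` and `z` columns), `fits` (per-plate regressions), `models`
#'   (per-replicate error models), `amplicons` (averaged Z + call),
#'   `excluded` (off-target report), `cutoff`.
#' @export
run_insulin_screen <- function(dataset, cutoff = 2.5, k = NULL,
                               weighting = "tricube",
                               covariate = "log2_nucfl",
                               position_correct = TRUE,
                               include_controls = TRUE) {
  norm <- normalize_screen(dataset, condition = "insulin",
                           covariate = covariate,
                           include_controls = include_controls)
  w <- norm$wells
  w <- w[w$control_class == "sample" | include_controls, , drop = FALSE]
  w$z_raw <- NA_real_
  models <- list()
  for (rep_i in sort(unique(w$replicate))) {
    pooled <- pool_residuals(norm, rep_i)
    model <- fit_local_error_model(pooled$covariate, pooled$residual,
                                   k = k, weighting = weighting)
    models[[as.character(rep_i)]] <- model
    sel <- which(w$replicate == rep_i & w$status == "ok" &
                   is.finite(w$residual))
    w$z_raw[sel] <- local_zscore(w$residual[sel], w$covariate[sel], model)
  }
  if (position_correct) {
    w <- correct_position_effects(w, z_col = "z_raw", out_col = "z")
  } else {
    w$z <- w$z_raw
  }

  scored <- w[w$control_class == "sample", , drop = FALSE]
  filt <- exclude_off_targets(scored)
  avg <- average_replicates(filt$kept, z_col = "z")
  avg <- call_insulin_hits(avg, cutoff = cutoff)
  names(avg)[names(avg) == "avg_z"] <- "avg_z_insulin"

  out <- list(wells = w, fits = norm$fits, models = models,
              amplicons = avg, excluded = filt$excluded, cutoff = cutoff)
  class(out) <- "insulin_result"
  out
}

#' @export
print.insulin_result <- function(x, ...) {
  cat(sprintf(
    "insulin screen: %d amplicons scored, %d suppressors, %d enhancers (|avg Z| >= %g), %d off-target excluded\n",
    nrow(x$amplicons), sum(x$amplicons$call == "suppressor"),
    sum(x$amplicons$call == "enhancer"), x$cutoff, nrow(x$excluded)))
  invisible(x)
}

#' Combine screen results into a hit table
#'
#' Joins the averaged Z of the baseline and insulin pipelines per
#' amplicon, attaches gene ids, and sets the combined call: the insulin
#' call where present, otherwise the baseline call.
#'
#' @param baseline a `baseline_result` (or `NULL`).
#' @param insulin an `insulin_result` (or `NULL`).
#' @param annotation optional annotation data.frame (`amplicon_id`,
#'   `gene_id`).
#' @return data.frame with `amplicon_id`, `gene_id`, `avg_z_baseline`,
#'   `avg_z_insulin`, `call`.
#' @export
combine_hit_table <- function(baseline = NULL, insulin = NULL,
                              annotation = NULL) {
  if (is.null(baseline) && is.null(insulin)) {
    stop("at least one screen result required", call. = FALSE)
  }
  b <- if (!is.null(baseline)) baseline$amplicons else NULL
  i <- if (!is.null(insulin)) insulin$amplicons else NULL
  ids <- union(if (is.null(b)) character() else b$amplicon_id,
               if (is.null(i)) character() else i$amplicon_id)
  out <- data.frame(amplicon_id = sort(ids), stringsAsFactors = FALSE)
  out$avg_z_baseline <- if (is.null(b)) NA_real_ else
    b$avg_z_baseline[match(out$amplicon_id, b$amplicon_id)]
  out$avg_z_insulin <- if (is.null(i)) NA_real_ else
    i$avg_z_insulin[match(out$amplicon_id, i$amplicon_id)]
  call_b <- if (is.null(b)) rep(NA_character_, nrow(out)) else
    b$call[match(out$amplicon_id, b$amplicon_id)]
  call_i <- if (is.null(i)) rep(NA_character_, nrow(out)) else
    i$call[match(out$amplicon_id, i$amplicon_id)]
  out$call <- ifelse(!is.na(call_i) & call_i != "none", call_i,
                     ifelse(!is.na(call_b), call_b, "none"))
  out$gene_id <- NA_character_
  if (!is.null(annotation)) {
    out$gene_id <- annotation$gene_id[match(out$amplicon_id,
                                            annotation$amplicon_id)]
  }
  out[, c("amplicon_id", "gene_id", "avg_z_baseline", "avg_z_insulin", "call")]
}
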