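#' Decompose a plate's values into its four source-plate quadrant groups
#'
#' Each 384-well screening plate is stamped from four 96-well source
#' plates; the four groups are the parity classes returned by
#' [well_quadrant()]. The groups partition the plate's usable wells.
#'
#' @param plate_df data.frame of one plate's wells with columns `row`,
#'   `col` (a `quadrant` column is recomputed if absent).
#' @return list of four data.frames, one per quadrant 1..4.
#' @export
decompose_plate <- function(plate_df) {
  plate_df$quadrant <- well_quadrant(plate_df$row, plate_df$col)
  lapply(1:4, function(qd) plate_df[plate_df$quadrant == qd, , drop = FALSE])
}

#' Standardize one quadrant group to mean 0, SD 1
#'
#' `v' = (v - mean(v)) / sd(v)` with the n-1 sample SD. Because the
#' transform is affine-invariant, any per-(plate, quadrant) batch offset
#' or gain common to the group's wells is removed exactly.
#'
#' @param values numeric vector (at least 2 distinct finite values).
#' @param label label for error messages (plate/quadrant).
#' @return standardized numeric vector.
#' @export
standardize_group <- function(values, label = "<group>") {
  v <- values[is.finite(values)]
  if (length(v) < 2 || max(v) - min(v) <= 0) {
    stop("group ", label,
         ": needs >= 2 distinct finite values for standardization",
         call. = FALSE)
  }
  (values - mean(v)) / stats::sd(v)
}

#' Quadrant-standardize and Z-score one baseline screening plate
#'
#' The plate's (pdakt/nucfl) ratios are decomposed into the four 96-well
#' source-plate groups; each group is standardized to mean 0 / SD 1
#' (absorbing source-plate batch differences); the groups are recombined
#' to a 384-well data set; and the recombined values are Z-scored against
#' the full plate's mean and n-1 sample SD. Because every group is already
#' mean-0/SD-1, the plate mean is 0 and the plate SD is 1 up to the finite
#' group-size pooling factor, so the final Z is close to the standardized
#' value itself.
#'
#' @param plate_df one plate's wells (columns `row`, `col` and the value
#'   column named by `value_col`). `NA` values pass through as `NA`.
#' @param value_col name of the value column (default `"ratio"`).
#' @param plate_label label for error messages.
#' @return numeric vector of per-well Z, aligned with `plate_df` rows.
#' @export
recombine_and_zscore <- function(plate_df, value_col = "ratio",
                                 plate_label = "<plate>") {
  v <- plate_df[[value_col]]
  qd <- well_quadrant(plate_df$row, plate_df$col)
  std <- rep(NA_real_, length(v))
  for (g in 1:4) {
    sel <- which(qd == g & is.finite(v))
    if (length(sel) == 0) next
    std[sel] <- standardize_group(v[sel],
                                  label = sprintf("%s quadrant %d", plate_label, g))
  }
  ok <- is.finite(std)
  m <- mean(std[ok])
  s <- stats::sd(std[ok])
  (std - m) / s
}

#' Run the baseline (no-stimulation) screen pipeline
#'
#' For each plate of each replicate of the baseline condition: per-well
#' (pdakt/nucfl) ratios, quadrant decomposition, per-group mean-0/SD-1
#' standardization, recombination, and per-plate Z-scoring
#' ([recombine_and_zscore()]). Per-amplicon Z is then averaged across the
#' screen replicates, off-target amplicons are excluded, and the SD cutoff
#' is applied: `avg z >= cutoff` is called an enhancer (increased
#' phospho-signal without stimulation), `avg z <= -cutoff` a suppressor;
#' the boundary is inclusive.
#'
#' @param dataset a [screen_dataset].
#' @param cutoff hit-calling cutoff in SDs (default 3).
#' @param use_log_ratio standardize `log2(pdakt/nucfl)` instead of the raw
#'   ratio (default `FALSE`, matching the raw-ratio definition of the
#'   pipeline).
#' @param position_correct also apply [correct_position_effects()] to the
#'   per-well Z before averaging (default `FALSE`; the baseline pipeline
#'   is defined without it).
#' @return list of class `baseline_result` with `wells` (per-well Z),
#'   `amplicons` (averaged Z + call per scored amplicon), `excluded`
#'   (off-target exclusion report), `cutoff`.
#' @export
run_baseline_screen <- function(dataset, cutoff = 3.0, use_log_ratio = FALSE,
                                position_correct = FALSE) {
  stopifnot(inherits(dataset, "screen_dataset"))
  d <- as.data.frame(dataset)
  d <- d[d$condition == "baseline" & d$control_class != "empty", , drop = FALSE]
  if (nrow(d) == 0) stop("no baseline-condition wells in dataset", call. = FALSE)
  d <- d[d$control_class == "sample", , drop = FALSE]

  lr <- compute_log_ratio(d$pdakt, d$nucfl)
  d$ratio <- lr$ratio
  d$status <- lr$status
  val_col <- "ratio"
  if (use_log_ratio) {
    d$log2_ratio <- lr$log2_ratio
    val_col <- "log2_ratio"
  }
  d$z <- NA_real_
  for (rep_i in sort(unique(d$replicate))) {
    for (plate_i in unique(d$plate[d$replicate == rep_i])) {
      sel <- which(d$replicate == rep_i & d$plate == plate_i)
      d$z[sel] <- recombine_and_zscore(
        d[sel, , drop = FALSE], value_col = val_col,
        plate_label = sprintf("%s/rep%d", plate_i, rep_i))
    }
  }
  if (position_correct) {
    d <- correct_position_effects(d, z_col = "z", out_col = "z")
  }

  filt <- exclude_off_targets(d)
  avg <- average_replicates(filt$kept, z_col = "z")
  avg$call <- ifelse(avg$avg_z >= cutoff, "enhancer",
                     ifelse(avg$avg_z <= -cutoff, "suppressor", "none"))
  names(avg)[names(avg) == "avg_z"] <- "avg_z_baseline"
  out <- list(wells = d, amplicons = avg, excluded = filt$excluded,
              cutoff = cutoff)
  class(out) <- "baseline_result"
  out
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf(
    "baseline screen: %d amplicons scored, %d enhancers, %d suppressors (|avg Z| >= %g), %d off-target excluded\n",
    nrow(x$amplicons), sum(x$amplicons$call == "enhancer"),
    sum(x$amplicons$call == "suppressor"), x$cutoff, nrow(x$excluded)))
  invisible(x)
}
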