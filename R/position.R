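#' Plate position-effect correction of Z-scores
#'
#' Systematic biases tied to a well's physical position on the plate
#' (edge evaporation, dispensing gradients) show up as a nonzero mean
#' Z-score of that position across the plates of a genome-wide screen
#' replicate. The correction subtracts, from every well, the mean Z of its
#' well position taken across all plates of the same replicate and
#' condition, setting every per-position mean to zero. It subtracts only
#' (no rescaling) and is idempotent. With a single plate per replicate all
#' corrected values are exactly zero, a documented degenerate case.
#'
#' @param z_table data.frame with columns `well`, `replicate`,
#'   `condition`, and the Z column named by `z_col`. Rows with `NA` Z do
#'   not contribute to position means and stay `NA`.
#' @param z_col name of the Z-score column to correct (default `"z"`).
#' @param out_col name of the corrected column added (default
#'   `"z_corrected"`).
#' @return `z_table` with `out_col` added.
#' @export
correct_position_effects <- function(z_table, z_col = "z",
                                     out_col = "z_corrected") {
  stopifnot(all(c("well", "replicate", "condition", z_col) %in% names(z_table)))
  z <- z_table[[z_col]]
  grp <- interaction(z_table$well, z_table$replicate, z_table$condition,
                     drop = TRUE)
  means <- tapply(z, grp, mean, na.rm = TRUE)
  pos_mean <- as.numeric(means[as.character(grp)])
  pos_mean[is.nan(pos_mean)] <- NA_real_
  z_table[[out_col]] <- z - pos_mean
  z_table
}

#' Per-position effect estimates of one replicate
#'
#' QC view of what [correct_position_effects()] removes: the mean raw Z of
#' each well position across the plates of each replicate and condition.
#'
#' @inheritParams correct_position_effects
#' @return data.frame with `replicate`, `condition`, `well`, `n_plates`,
#'   `mean_z`.
#' @export
position_effects <- function(z_table, z_col = "z") {
  stopifnot(all(c("well", "replicate", "condition", z_col) %in% names(z_table)))
  ok <- !is.na(z_table[[z_col]])
  agg <- stats::aggregate(
    z_table[[z_col]][ok],
    by = list(replicate = z_table$replicate[ok],
              condition = z_table$condition[ok],
              well = z_table$well[ok]),
    FUN = mean)
  cnt <- stats::aggregate(
    rep(1L, sum(ok)),
    by = list(replicate = z_table$replicate[ok],
              condition = z_table$condition[ok],
              well = z_table$well[ok]),
    FUN = sum)
  names(agg)[4] <- "mean_z"
  agg$n_plates <- cnt$x
  agg[, c("replicate", "condition", "well", "n_plates", "mean_z")]
}
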