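#' Fit an external standard curve from untreated control wells
#'
#' Follow-up (non-genome-wide) experiments are scored against an external
#' standard: a set of non-RNAi-treated control wells spanning the whole
#' spectrum of cell densities, one standard per stimulation condition. A
#' locally weighted error model over the cell-number proxy gives the
#' density-matched control mean and SD, so by construction the average
#' untreated experiment of that condition scores zero.
#'
#' @param controls data.frame of control wells (columns `condition`,
#'   `control_class`, `pdakt`, `nucfl`); all must be `untreated` and of a
#'   single condition with positive signals.
#' @param condition the condition the standard represents (checked against
#'   the control wells).
#' @param value `"pdakt"` (default): model the raw phospho-signal against
#'   raw `nucfl`; `"ratio"`: model `pdakt/nucfl` instead.
#' @param k error-model neighborhood size (default 64); at least
#'   `2 * k` control wells are required.
#' @param weighting passed to [fit_local_error_model()].
#' @return object of class `external_standard`.
#' @export
fit_external_standard <- function(controls, condition = c("baseline", "insulin"),
                                  value = c("pdakt", "ratio"), k = 64,
                                  weighting = "tricube") {
  condition <- match.arg(condition)
  value <- match.arg(value)
  stopifnot(all(c("condition", "control_class", "pdakt", "nucfl") %in%
                  names(controls)))
  if (any(controls$control_class != "untreated")) {
    stop("standard controls must all be untreated (non-RNAi) wells",
         call. = FALSE)
  }
  conds <- unique(controls$condition)
  if (length(conds) != 1 || conds != condition) {
    stop("mixed or mismatched conditions in standard controls: ",
         paste(conds, collapse = ", "), " (expected ", condition, ")",
         call. = FALSE)
  }
  ok <- controls$pdakt > 0 & controls$nucfl > 0
  controls <- controls[ok, , drop = FALSE]
  if (nrow(controls) < 2 * k) {
    stop("need at least ", 2 * k, " usable control wells, got ",
         nrow(controls), call. = FALSE)
  }
  v <- if (value == "pdakt") controls$pdakt else controls$pdakt / controls$nucfl
  model <- fit_local_error_model(controls$nucfl, v, k = k,
                                 weighting = weighting)
  structure(list(condition = condition, value = value, model = model,
                 n_controls = nrow(controls)),
            class = "external_standard")
}

#' @export
print.external_standard <- function(x, ...) {
  cat(sprintf(
    "external_standard (%s, %s): %d control wells, k = %d\n",
    x$condition, x$value, x$n_controls, x$model$k))
  invisible(x)
}

#' Z-score follow-up wells against an external standard
#'
#' Each treated well is scored against the density-matched control mean
#' and SD at its `nucfl` value. Queries outside the standard's density
#' range are clamped to the nearest edge (with a warning). Per-treatment
#' summaries report the mean and SD of the replicate wells' Z.
#'
#' @param treated data.frame of treated wells (columns `condition`,
#'   `pdakt`, `nucfl`, and `amplicon_id` naming the treatment).
#' @param standard an [fit_external_standard()] object; its condition must
#'   match the treated wells'.
#' @return list with `wells` (per-well `z` added) and `summary`
#'   (per-treatment `n`, `mean_z`, `sd_z`).
#' @export
zscore_experiment <- function(treated, standard) {
  stopifnot(inherits(standard, "external_standard"))
  conds <- unique(treated$condition)
  if (length(conds) != 1 || conds != standard$condition) {
    stop("condition mismatch: treated wells are ",
         paste(conds, collapse = ", "), ", standard is ",
         standard$condition, call. = FALSE)
  }
  rng <- c(standard$model$c[1], standard$model$c[standard$model$n])
  outside <- treated$nucfl < rng[1] | treated$nucfl > rng[2]
  if (any(outside)) {
    warning(sum(outside),
            " well(s) outside the standard's density range; clamped to edge")
  }
  v <- if (standard$value == "pdakt") treated$pdakt else
    treated$pdakt / treated$nucfl
  treated$z <- local_zscore(v, treated$nucfl, standard$model)
  f <- factor(treated$amplicon_id)
  summary <- data.frame(
    treatment = levels(f),
    condition = standard$condition,
    n = as.integer(tapply(treated$z, f, length)),
    mean_z = as.numeric(tapply(treated$z, f, mean)),
    sd_z = as.numeric(tapply(treated$z, f, stats::sd)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(wells = treated, summary = summary)
}

#' Run a follow-up experiment end to end
#'
#' Fits one external standard per condition present (from the dataset's
#' `untreated` wells), Z-scores the treated (`sample`) wells against the
#' standard of their condition, summarizes per treatment, and reports
#' two-tailed pooled-variance t-tests of every treatment against a
#' reference treatment within each condition.
#'
#' @param dataset a [screen_dataset] containing `untreated` standard wells
#'   and treated `sample` wells.
#' @param reference treatment (amplicon id) used as the t-test reference;
#'   `NULL` skips the tests.
#' @param value,k,weighting passed to [fit_external_standard()].
#' @return list with `standards` (per condition), `wells`, `summary`
#'   (per treatment x condition, with `t` and `p` columns when a reference
#'   is given).
#' @export
run_followup <- function(dataset, reference = NULL, value = "pdakt", k = 64,
                         weighting = "tricube") {
  stopifnot(inherits(dataset, "screen_dataset"))
  d <- as.data.frame(dataset)
  standards <- list()
  all_wells <- NULL
  summaries <- NULL
  for (cond in sort(unique(d$condition[d$control_class == "sample"]))) {
    ctl <- d[d$condition == cond & d$control_class == "untreated", , drop = FALSE]
    if (nrow(ctl) == 0) {
      stop("no untreated standard wells for condition '", cond, "'",
           call. = FALSE)
    }
    std <- fit_external_standard(ctl, condition = cond, value = value, k = k,
                                 weighting = weighting)
    standards[[cond]] <- std
    trt <- d[d$condition == cond & d$control_class == "sample", , drop = FALSE]
    zs <- zscore_experiment(trt, std)
    sm <- zs$summary
    if (!is.null(reference)) {
      ref_z <- zs$wells$z[zs$wells$amplicon_id == reference]
      sm$t <- NA_real_
      sm$p <- NA_real_
      for (i in seq_len(nrow(sm))) {
        if (sm$treatment[i] == reference) next
        g <- zs$wells$z[zs$wells$amplicon_id == sm$treatment[i]]
        if (length(g) >= 2 && length(ref_z) >= 2) {
          tt <- two_sample_ttest(g, ref_z)
          sm$t[i] <- tt$t
          sm$p[i] <- tt$p
        }
      }
    }
    all_wells <- rbind(all_wells, zs$wells)
    summaries <- rbind(summaries, sm)
  }
  list(standards = standards, wells = all_wells, summary = summaries)
}
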