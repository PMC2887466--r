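#' Exclude amplicons with predicted off-target effects
#'
#' dsRNAs sharing 19 bp or more with a non-target gene are flagged
#' upstream (the flag is an input, not computed here) and removed from
#' scoring and from all result files. Conservation holds: every input row
#' lands in exactly one of the kept table or the exclusion report.
#'
#' @param z_table data.frame with an `off_target` logical column (or, if
#'   absent, joined from `annotation` by `amplicon_id`).
#' @param annotation optional data.frame with `amplicon_id` and
#'   `off_target`.
#' @return list with `kept` and `excluded` (the latter with a `reason`
#'   column).
#' @export
exclude_off_targets <- function(z_table, annotation = NULL) {
  if (!("off_target" %in% names(z_table))) {
    if (is.null(annotation) || !all(c("amplicon_id", "off_target") %in% names(annotation))) {
      stop("off_target flags absent from table and annotation", call. = FALSE)
    }
    z_table$off_target <- annotation$off_target[
      match(z_table$amplicon_id, annotation$amplicon_id)]
  }
  flag <- !is.na(z_table$off_target) & z_table$off_target
  excluded <- z_table[flag, , drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- "predicted off-target (>= 19 bp homology to non-target gene)"
  } else {
    excluded$reason <- character(0)
  }
  list(kept = z_table[!flag, , drop = FALSE], excluded = excluded)
}

#' Average per-amplicon Z-scores across screen replicates
#'
#' Arithmetic mean of the available replicate values for each amplicon;
#' the number of contributing replicates is recorded so amplicons scored
#' in a single replicate are identifiable.
#'
#' @param z_table data.frame with `amplicon_id`, `replicate`, and the Z
#'   column named by `z_col`; `NA` Z values are dropped.
#' @param z_col name of the Z column to average (default `"z"`).
#' @return data.frame with `amplicon_id`, `avg_z`, `n_replicates`.
#' @export
average_replicates <- function(z_table, z_col = "z") {
  stopifnot(all(c("amplicon_id", "replicate", z_col) %in% names(z_table)))
  ok <- !is.na(z_table[[z_col]])
  f <- factor(z_table$amplicon_id[ok])
  avg <- tapply(z_table[[z_col]][ok], f, mean)
  n <- tapply(z_table[[z_col]][ok], f, length)
  data.frame(amplicon_id = levels(f),
             avg_z = as.numeric(avg),
             n_replicates = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Call insulin-screen hits at a fixed Z cutoff
#'
#' Replicate-averaged Z at or below `-cutoff` is a suppressor of the
#' insulin-stimulated phospho-signal; at or above `+cutoff` an enhancer;
#' the boundary is inclusive on both sides.
#'
#' @param avg data.frame with `amplicon_id` and `avg_z` (e.g. from
#'   [average_replicates()]).
#' @param cutoff cutoff in SDs (default 2.5).
#' @return `avg` with a `call` column (`suppressor`/`enhancer`/`none`).
#' @export
call_insulin_hits <- function(avg, cutoff = 2.5) {
  stopifnot(all(c("amplicon_id", "avg_z") %in% names(avg)))
  avg$call <- ifelse(avg$avg_z <= -cutoff, "suppressor",
                     ifelse(avg$avg_z >= cutoff, "enhancer", "none"))
  avg$call[is.na(avg$avg_z)] <- "none"
  avg
}

#' Recall of known-component reference panels
#'
#' For each annotated known-component class, the fraction of its members
#' that the screen called (any non-`none` call), plus the list of misses.
#' An empty class has undefined recall, reported as `NA`.
#'
#' @param calls data.frame with `amplicon_id` and `call`.
#' @param annotation data.frame with `amplicon_id` and
#'   `known_component_class`.
#' @return list with `recall` (data.frame: class, n, n_called, recall) and
#'   `misses` (named list of missed amplicon ids per class).
#' @export
evaluate_reference_panel <- function(calls, annotation) {
  stopifnot(all(c("amplicon_id", "call") %in% names(calls)),
            all(c("amplicon_id", "known_component_class") %in% names(annotation)))
  ann <- annotation[!is.na(annotation$known_component_class) &
                      annotation$known_component_class != "none", , drop = FALSE]
  classes <- sort(unique(ann$known_component_class))
  misses <- list()
  rows <- lapply(classes, function(cl) {
    members <- ann$amplicon_id[ann$known_component_class == cl]
    called <- calls$amplicon_id[calls$call != "none"]
    hit <- members %in% called
    misses[[cl]] <<- members[!hit]
    data.frame(class = cl, n = length(members), n_called = sum(hit),
               recall = if (length(members) > 0) mean(hit) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(recall = do.call(rbind, rows), misses = misses)
}

#' Two-sample Student t-test (pooled variance, two-tailed)
#'
#' Classical equal-variance two-sample t statistic with the two-tailed
#' p-value from the t distribution, as used to compare treatment groups of
#' follow-up Z-scores.
#'
#' @param group_a,group_b numeric vectors, each of length at least 2.
#' @return list with `t`, `p`, `df`, and the group means.
#' @export
two_sample_ttest <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  pooled_ss <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
  if (pooled_ss <= 0) {
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Ranked Z-score report
#'
#' Amplicons sorted by averaged Z (ascending), with rank and the
#' known-component flag, suitable for a rank-versus-Z plot of where known
#' pathway components fall in the genome-wide distribution. Ties share
#' their order by a stable sort on amplicon id.
#'
#' @param avg data.frame with `amplicon_id` and `avg_z`.
#' @param annotation optional data.frame with `amplicon_id`,
#'   `known_component_class`.
#' @return data.frame with `rank`, `amplicon_id`, `avg_z`,
#'   `known_component_class`.
#' @export
ranked_z_report <- function(avg, annotation = NULL) {
  stopifnot(all(c("amplicon_id", "avg_z") %in% names(avg)))
  out <- avg[order(avg$avg_z, avg$amplicon_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$known_component_class <- "none"
  if (!is.null(annotation) && "known_component_class" %in% names(annotation)) {
    m <- match(out$amplicon_id, annotation$amplicon_id)
    kc <- annotation$known_component_class[m]
    out$known_component_class <- ifelse(is.na(kc), "none", kc)
  }
  rownames(out) <- NULL
  out[, c("rank", "amplicon_id", "avg_z", "known_component_class")]
}
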