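#' @keywords internal
.conditions <- c("baseline", "insulin")
.control_classes <- c("sample", "untreated", "negative_ctrl", "positive_ctrl", "empty")
.screen_columns <- c("plate", "replicate", "condition", "well", "amplicon_id",
                     "control_class", "off_target", "pdakt", "nucfl")

#' Construct and validate a screen dataset
#'
#' A screen dataset is a long-format table with one row per measured well:
#' plate id, replicate, condition (`baseline` or `insulin`), well label,
#' amplicon id, control class, off-target flag, the phospho-signal
#' (`pdakt`) and the nuclear-fluorescence cell-number proxy (`nucfl`), both
#' in arbitrary non-negative units. Validation enforces uniqueness of
#' (plate, replicate, condition, well), legal well addresses, legal
#' condition and control-class levels, and non-negative signals; plate
#' completeness (which of the 384 addresses are absent from each indexed
#' plate) is recorded in the `completeness` attribute, never silently
#' repaired.
#'
#' @param df data.frame with the columns listed above.
#' @return object of class `screen_dataset` (a data.frame with added
#'   `row`, `col`, `quadrant` columns and a `completeness` attribute).
#' @export
screen_dataset <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.screen_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$plate <- as.character(df$plate)
  df$replicate <- as.integer(df$replicate)
  df$condition <- as.character(df$condition)
  df$amplicon_id <- as.character(df$amplicon_id)
  df$control_class <- as.character(df$control_class)
  df$off_target <- .parse_logical(df$off_target, "off_target")
  df$pdakt <- .parse_numeric(df$pdakt, "pdakt")
  df$nucfl <- .parse_numeric(df$nucfl, "nucfl")

  bad <- which(!(df$condition %in% .conditions))
  if (length(bad) > 0) {
    stop(sprintf("row %d: unknown condition '%s' (expected %s)",
                 bad[1], df$condition[bad[1]],
                 paste(.conditions, collapse = "/")), call. = FALSE)
  }
  bad <- which(!(df$control_class %in% .control_classes))
  if (length(bad) > 0) {
    stop(sprintf("row %d: unknown control_class '%s'", bad[1],
                 df$control_class[bad[1]]), call. = FALSE)
  }
  bad <- which(df$pdakt < 0 | df$nucfl < 0)
  if (length(bad) > 0) {
    stop(sprintf("row %d: negative signal value (corrupt data)", bad[1]),
         call. = FALSE)
  }
  bad <- which(df$amplicon_id == "" & df$control_class != "empty")
  if (length(bad) > 0) {
    stop(sprintf("row %d: empty amplicon_id on non-empty well", bad[1]),
         call. = FALSE)
  }

  addr <- parse_well_label(df$well)
  df$well <- format_well_label(addr$row, addr$col)  # canonical form
  df$row <- addr$row
  df$col <- addr$col
  df$quadrant <- well_quadrant(addr$row, addr$col)
  extra <- setdiff(names(df), c(.screen_columns, "row", "col", "quadrant"))
  df <- df[, c(.screen_columns, "row", "col", "quadrant", extra)]

  key <- paste(df$plate, df$replicate, df$condition, df$well, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf(
      "duplicate well: plate '%s' replicate %d condition '%s' well %s (row %d)",
      df$plate[dup[1]], df$replicate[dup[1]], df$condition[dup[1]],
      df$well[dup[1]], dup[1]), call. = FALSE)
  }

  attr(df, "completeness") <- .plate_completeness(df)
  class(df) <- c("screen_dataset", "data.frame")
  df
}

.parse_numeric <- function(x, name) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("row %d: non-numeric %s value '%s'", bad[1], name, x[bad[1]]),
         call. = FALSE)
  }
  out
}

.parse_logical <- function(x, name) {
  if (is.logical(x)) return(x)
  out <- as.logical(x)
  out[x %in% c("0", 0)] <- FALSE
  out[x %in% c("1", 1)] <- TRUE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("row %d: non-logical %s value '%s'", bad[1], name, x[bad[1]]),
         call. = FALSE)
  }
  out
}

# Missing addresses per indexed plate (plate x replicate x condition).
.plate_completeness <- function(df) {
  all_wells <- plate_addresses()$well
  keys <- unique(df[, c("plate", "replicate", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$plate == keys$plate[i] & df$replicate == keys$replicate[i] &
      df$condition == keys$condition[i]
    miss <- setdiff(all_wells, df$well[sel])
    if (length(miss) == 0) return(NULL)
    data.frame(plate = keys$plate[i], replicate = keys$replicate[i],
               condition = keys$condition[i], missing_well = miss)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(plate = character(), replicate = integer(),
                      condition = character(), missing_well = character())
  }
  out
}

#' @export
print.screen_dataset <- function(x, ...) {
  keys <- unique(x[, c("plate", "replicate", "condition")])
  comp <- attr(x, "completeness")
  cat(sprintf("screen_dataset: %d wells, %d indexed plates (%d missing wells)\n",
              nrow(x), nrow(keys), nrow(comp)))
  cat(sprintf("  conditions: %s; replicates: %s\n",
              paste(sort(unique(x$condition)), collapse = ", "),
              paste(sort(unique(x$replicate)), collapse = ", ")))
  invisible(x)
}

#' Read a screen measurement CSV
#'
#' Reads a long-format per-well measurement table (RFC-4180 CSV, header
#' required, "." decimal separator) and validates it into a
#' [screen_dataset]. Parsing problems are reported with the offending data
#' row number; duplicate wells and non-numeric signals are hard errors.
#'
#' @param path path to a CSV file with columns
#'   `plate,replicate,condition,well,amplicon_id,control_class,off_target,pdakt,nucfl`.
#' @param schema optional named character vector mapping required column
#'   names to the names used in the file, e.g. `c(pdakt = "signal")`.
#' @return a [screen_dataset].
#' @export
read_screen_csv <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!(schema[[std]] %in% names(raw))) {
        stop("schema maps '", std, "' to absent column '", schema[[std]], "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  screen_dataset(raw)
}

#' Write a screen dataset to CSV
#'
#' Inverse of [read_screen_csv()]; writes only the canonical measurement
#' columns so that read -> write -> read is idempotent.
#'
#' @param dataset a [screen_dataset].
#' @param path output file path.
#' @export
write_screen_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, .screen_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an amplicon annotation CSV
#'
#' @param path CSV with columns `amplicon_id,gene_id` and optionally
#'   `known_component_class` (one of `upstream_InR_branch`,
#'   `tsc_tor_branch`, `none`).
#' @return data.frame keyed by unique `amplicon_id`.
#' @export
read_amplicon_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("amplicon_id", "gene_id")) {
    if (!(col %in% names(ann))) {
      stop("annotation file lacks column '", col, "'", call. = FALSE)
    }
  }
  if (!("known_component_class" %in% names(ann))) {
    ann$known_component_class <- "none"
  }
  dup <- which(duplicated(ann$amplicon_id))
  if (length(dup) > 0) {
    stop("duplicate amplicon_id in annotation: ", ann$amplicon_id[dup[1]],
         call. = FALSE)
  }
  ann
}

#' Write the final hit table
#'
#' Emits the per-amplicon result file: averaged Z-scores of the baseline
#' and insulin screens plus the call, ordered by descending absolute
#' averaged Z (the larger of the two conditions' magnitudes), ties broken
#' by amplicon id. Numbers are written at full double precision, so a
#' write/read round trip preserves values to better than 12 significant
#' digits.
#'
#' @param hits data.frame with columns `amplicon_id`, `gene_id`,
#'   `avg_z_baseline`, `avg_z_insulin`, `call` (absent Z columns are
#'   written as empty fields).
#' @param path output CSV path.
#' @export
write_hit_table <- function(hits, path) {
  hits <- as.data.frame(hits)
  for (col in c("gene_id", "avg_z_baseline", "avg_z_insulin", "call")) {
    if (!(col %in% names(hits))) hits[[col]] <- NA
  }
  hits <- hits[, c("amplicon_id", "gene_id", "avg_z_baseline",
                   "avg_z_insulin", "call")]
  mag <- suppressWarnings(
    pmax(abs(as.numeric(hits$avg_z_baseline)),
         abs(as.numeric(hits$avg_z_insulin)), na.rm = TRUE))
  mag[!is.finite(mag)] <- 0
  hits <- hits[order(-mag, hits$amplicon_id), , drop = FALSE]
  out <- data.frame(
    amplicon_id = hits$amplicon_id,
    gene_id = hits$gene_id,
    avg_z_baseline = .fmt_num(hits$avg_z_baseline),
    avg_z_insulin = .fmt_num(hits$avg_z_insulin),
    call = hits$call,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.15g", as.numeric(x)))
  out
}

#' Read back a hit table written by [write_hit_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric Z columns (`NA` where empty).
#' @export
read_hit_table <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(amplicon_id = "character",
                                      gene_id = "character",
                                      avg_z_baseline = "numeric",
                                      avg_z_insulin = "numeric",
                                      call = "character"))
  h
}
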