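#' Well-address handling for 384-well screening plates
#'
#' Screening plates are 16 rows (letters A--P) by 24 columns. Internally a
#' well address is the pair (row, col), both 1-based; `parse_well_label()`
#' and `format_well_label()` convert between the vendor-style label ("A1",
#' "P24") and the numeric pair, and are exact inverses over the full grid.
#'
#' @param label character vector of well labels such as `"A1"` or `"P24"`.
#' @return `parse_well_label()` returns a data.frame with integer columns
#'   `row` and `col`; `format_well_label()` returns a character vector.
#' @examples
#' parse_well_label(c("A1", "P24"))
#' format_well_label(16, 24)
#' @export
parse_well_label <- function(label) {
  label <- as.character(label)
  m <- regmatches(label, regexec("^([A-Pa-p])([0-9]{1,2})$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well label(s): ",
         paste(sprintf("'%s'", label[bad][seq_len(min(5, sum(bad)))]),
               collapse = ", "),
         call. = FALSE)
  }
  row <- match(toupper(vapply(m, `[`, character(1), 2L)), LETTERS[1:16])
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  oob <- col < 1L | col > 24L
  if (any(oob)) {
    stop("well label column out of range 1..24: ",
         paste(sprintf("'%s'", label[oob][seq_len(min(5, sum(oob)))]),
               collapse = ", "),
         call. = FALSE)
  }
  data.frame(row = row, col = col)
}

#' @param row,col integer vectors, row in 1..16 and col in 1..24.
#' @rdname parse_well_label
#' @export
format_well_label <- function(row, col) {
  stopifnot(all(row >= 1 & row <= 16), all(col >= 1 & col <= 24))
  paste0(LETTERS[row], col)
}

#' Source-plate quadrant of a 384-well address
#'
#' A 384-well screening plate is assembled from four 96-well source plates
#' stamped in an interleaved 2x2 pattern, so each source plate occupies one
#' parity class of (row, col): odd/odd -> 1, odd/even -> 2, even/odd -> 3,
#' even/even -> 4. Each quadrant has exactly 96 wells. The mapping of
#' quadrant number to physical source plate is a convention; the baseline
#' pipeline's per-quadrant standardization is invariant to the labeling as
#' long as it matches the true stamping pattern.
#'
#' @param row,col integer vectors, row in 1..16 and col in 1..24.
#' @return integer vector of quadrant indices in 1..4.
#' @examples
#' well_quadrant(1, 1)   # 1
#' well_quadrant(16, 24) # 4
#' @export
well_quadrant <- function(row, col) {
  stopifnot(all(row >= 1 & row <= 16), all(col >= 1 & col <= 24))
  as.integer(1 + (col - 1) %% 2 + 2 * ((row - 1) %% 2))
}

#' All 384 well addresses of a plate in row-major order
#'
#' @return data.frame with columns `row`, `col`, `well` (label), `quadrant`.
#' @export
plate_addresses <- function() {
  g <- expand.grid(col = 1:24, row = 1:16)[, c("row", "col")]
  g$well <- format_well_label(g$row, g$col)
  g$quadrant <- well_quadrant(g$row, g$col)
  rownames(g) <- NULL
  g
}
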