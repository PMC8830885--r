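#' Binarize per-read modified-base probabilities
#'
#' An adenine is called m6A iff its emitted probability strictly exceeds
#' the threshold (default 0.8); all other calls, including exactly at the
#' threshold, are called unmethylated A. Record count is unchanged and the
#' operation is idempotent.
#'
#' @param calls a `perread_calls` data.frame with a `prob` column.
#' @param threshold probability threshold in (0, 1).
#' @return the call set with a logical `methylated` column and the
#'   threshold recorded as an attribute.
#' @export
binarize_calls <- function(calls, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (any(calls$prob < 0 | calls$prob > 1)) stop("probabilities must be in [0, 1]")
  calls$methylated <- calls$prob > threshold
  attr(calls, "threshold") <- threshold
  calls
}

is_binarized <- function(calls) !is.null(calls$methylated)

#' Single-read methylation matrix for a query window
#'
#' Rows are reads, columns are adenine positions inside the window. By
#' default only reads spanning the entire window are retained, as in the
#' assay's single-read plots; a read's span is taken as the interval from
#' its first to its last call on the contig. Cells are 1 (methylated),
#' 0 (unmethylated) or NA (no call emitted at that adenine under that
#' read).
#'
#' @param calls binarized `perread_calls`.
#' @param window list or vector `(contig, start, end)`; 0-based half-open.
#' @param require_full_span drop reads not covering the whole window?
#' @return object of class `methylation_matrix`: list with `window`,
#'   `positions`, `read_ids`, `mat`, `row_order`.
#' @export
build_matrix <- function(calls, window, require_full_span = TRUE) {
  if (!is_binarized(calls)) stop("calls must be binarized first")
  w <- as.list(window)
  contig <- as.character(w[[1]]); start <- as.numeric(w[[2]]); end <- as.numeric(w[[3]])
  cc <- calls[calls$contig == contig, , drop = FALSE]
  if (nrow(cc) == 0) stop("no calls on contig ", contig)
  span_lo <- tapply(cc$pos, cc$read_id, min)
  span_hi <- tapply(cc$pos, cc$read_id, max)
  anywin <- cc[cc$pos >= start & cc$pos < end, , drop = FALSE]
  if (nrow(anywin) == 0)
    stop("window contains no adenine positions with calls")
  inwin <- anywin
  if (require_full_span) {
    keep <- names(span_lo)[span_lo <= start & (span_hi + 1) >= end]
    inwin <- inwin[inwin$read_id %in% keep, , drop = FALSE]
  }
  positions <- sort(unique(inwin$pos))
  read_ids <- sort(unique(inwin$read_id))
  if (length(read_ids) == 0) {
    warning("no reads retained for window")
    mat <- matrix(NA, 0, length(positions),
                  dimnames = list(NULL, positions))
  } else {
    mat <- matrix(NA_integer_, length(read_ids), length(positions),
                  dimnames = list(read_ids, positions))
    mat[cbind(match(inwin$read_id, read_ids), match(inwin$pos, positions))] <-
      as.integer(inwin$methylated)
  }
  structure(list(window = list(contig = contig, start = start, end = end),
                 positions = positions, read_ids = read_ids, mat = mat,
                 row_order = seq_along(read_ids)),
            class = "methylation_matrix")
}

#' Order matrix rows for display
#'
#' Rows are sorted by mean methylated fraction, lowest at the top and
#' highest at the bottom, matching the assay's single-read figures. Ties
#' break by read id (stable, so figures are reproducible).
#'
#' @param matrix a `methylation_matrix`.
#' @return the matrix with `row_order` set.
#' @export
order_reads <- function(matrix) {
  if (length(matrix$read_ids) == 0) stop("empty matrix")
  m <- rowMeans(matrix$mat, na.rm = TRUE)
  matrix$row_order <- order(m, matrix$read_ids)
  matrix
}

#' Per-read methylation summary
#'
#' @param matrix a `methylation_matrix`.
#' @return data.frame with one row per read: `read_id`, `n_methylated`,
#'   `n_total` (emitted calls in the window) and `mean` methylation.
#' @export
read_summary <- function(matrix) {
  n_meth <- rowSums(matrix$mat == 1L, na.rm = TRUE)
  n_tot <- rowSums(!is.na(matrix$mat))
  data.frame(read_id = matrix$read_ids, n_methylated = as.integer(n_meth),
             n_total = as.integer(n_tot),
             mean = ifelse(n_tot > 0, n_meth / n_tot, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix: ", length(x$read_ids), " reads x ",
      length(x$positions), " adenines in ", x$window$contig, ":",
      x$window$start, "-", x$window$end, "\n", sep = "")
  invisible(x)
}

#' Export a methylation matrix as tab-separated text
#'
#' Writes the binary matrix (rows in display order) plus a sidecar file
#' with the row order and per-read means.
#'
#' @param matrix a `methylation_matrix` (ideally after [order_reads()]).
#' @param path output path; the sidecar gets extension `.rows.tsv`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  m <- matrix$mat[matrix$row_order, , drop = FALSE]
  df <- data.frame(read_id = matrix$read_ids[matrix$row_order], m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- read_summary(matrix)[matrix$row_order, , drop = FALSE]
  utils::write.table(side, paste0(sub("\\.tsv$", "", path), ".rows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
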