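#' Read a Megalodon-style per-read modified-base text file
#'
#' The per-read text dialect is tab-separated with a header and columns
#' `read_id`, `chrm`, `strand`, `pos` (0-based reference coordinate),
#' `mod_log_prob`, `can_log_prob` (natural-log probabilities, <= 0) and
#' `mod_base` (single-letter modified-base code, `Y` for all-context m6A).
#' Extra columns are ignored with a warning; unknown mod codes warn but
#' rows are kept. Probabilities are recovered as `exp(mod_log_prob)`.
#'
#' @param path file path.
#' @return a `perread_calls` data.frame (`read_id`, `contig`, `strand`,
#'   `pos`, `prob`, `mod_code`).
#' @export
read_perread_text <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("read_id", "chrm", "strand", "pos",
            "mod_log_prob", "can_log_prob", "mod_base")
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- identical(hdr[seq_len(min(4, length(hdr)))], cols[1:4]) ||
    "mod_log_prob" %in% hdr
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(new_perread_calls(data.frame(
      read_id = character(0), contig = character(0), strand = character(0),
      pos = integer(0), prob = numeric(0), mod_code = character(0))))
  }
  if (!has_header) {
    if (ncol(df) < length(cols)) stop("expected at least ", length(cols),
                                      " tab-separated columns in ", path)
    names(df)[seq_along(cols)] <- cols
  } else if (ncol(df) > length(cols)) {
    extra <- setdiff(names(df), cols)
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(df$pos))
  mlp <- suppressWarnings(as.numeric(df$mod_log_prob))
  bad <- which(is.na(pos) | is.na(mlp) | pos < 0 | mlp > 1e-12 |
                 !(df$strand %in% c("+", "-")))
  if (length(bad))
    stop("malformed per-read record at line ",
         bad[1] + as.integer(has_header), " of ", path)
  if (any(df$mod_base != "Y"))
    warning("unknown mod code(s): ",
            paste(unique(df$mod_base[df$mod_base != "Y"]), collapse = ", "),
            " (rows kept)")
  new_perread_calls(data.frame(
    read_id = df$read_id, contig = df$chrm, strand = df$strand,
    pos = pos, prob = exp(pmin(mlp, 0)), mod_code = df$mod_base,
    stringsAsFactors = FALSE))
}

#' Write a per-read call set in the per-read text dialect
#'
#' Records are sorted by (contig, pos, read_id) and log-probabilities are
#' serialized with 12 significant digits so the read/write round trip
#' recovers probabilities to better than 1e-9. Simulation-only columns
#' (`truth`) are not serialized.
#'
#' @param calls a `perread_calls` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_perread_text <- function(calls, path) {
  stopifnot(inherits(calls, "perread_calls") || is.data.frame(calls))
  ord <- order(calls$contig, calls$pos, calls$read_id)
  calls <- calls[ord, , drop = FALSE]
  p <- pmin(pmax(calls$prob, 1e-300), 1)
  mod_code <- calls$mod_code %||% rep("Y", nrow(calls))
  lines <- c(paste(c("read_id", "chrm", "strand", "pos",
                     "mod_log_prob", "can_log_prob", "mod_base"),
                   collapse = "\t"),
             if (nrow(calls)) paste(calls$read_id, calls$contig, calls$strand,
                                    calls$pos,
                                    sprintf("%.12g", log(p)),
                                    sprintf("%.12g", log1p(-pmin(p, 1 - 1e-16))),
                                    mod_code, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write single-base aggregate methylation BED
#'
#' One record per (adenine position, strand): columns chrom, start,
#' end = start + 1, name (mod code), score = coverage, strand,
#' methylated-call count, percent methylated. Coverage-0 records are
#' written with percent 0 and flagged missing (NA percent) on read.
#'
#' @param path file path.
#' @return an `aggregate_track` data.frame with columns `contig`, `pos`,
#'   `strand`, `coverage`, `n_meth`, `percent`.
#' @export
read_aggregate_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character",
                                         "integer", "numeric"),
                          quote = "", comment.char = "")
  names(df) <- c("contig", "start", "end", "name", "coverage", "strand",
                 "n_meth", "percent")
  if (any(df$end != df$start + 1L))
    stop("aggregate BED requires single-base records (end = start + 1)")
  out <- data.frame(contig = df$contig, pos = df$start, strand = df$strand,
                    coverage = df$coverage, n_meth = df$n_meth,
                    percent = ifelse(df$coverage > 0,
                                     100 * df$n_meth / df$coverage, NA_real_),
                    stringsAsFactors = FALSE)
  new_aggregate_track(out)
}

#' @rdname read_aggregate_bed
#' @param track an `aggregate_track`.
#' @export
write_aggregate_bed <- function(track, path) {
  ord <- order(track$contig, track$pos, track$strand)
  t2 <- track[ord, , drop = FALSE]
  pct <- ifelse(t2$coverage > 0, 100 * t2$n_meth / t2$coverage, 0)
  lines <- paste(t2$contig, t2$pos, t2$pos + 1L, "m6A", t2$coverage,
                 t2$strand, t2$n_meth, sprintf("%.6g", pct), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read BED6 feature annotations
#'
#' Feature kind is derived from the longest recognised kind prefix of the
#' BED name field (e.g. `silencer_E` -> `silencer`, `x_element_6R` ->
#' `x_element`). Unsorted input is sorted (stable) on load.
#'
#' @param path BED6 file path.
#' @return data.frame of features (`contig`, `start`, `end`, `strand`,
#'   `kind`, `name`) usable in [genome_annotation()].
#' @export
read_bed_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED6 annotation requires at least 4 columns")
  if (ncol(df) < 6) df[[6]] <- "."
  names(df)[c(1:4, 6)] <- c("contig", "start", "end", "name", "strand")
  kinds <- feature_kinds()[order(-nchar(feature_kinds()))]
  kind <- rep(NA_character_, nrow(df))
  for (k in kinds) kind[is.na(kind) & startsWith(df$name, k)] <- k
  if (anyNA(kind))
    stop("cannot map feature name(s) to a kind: ",
         paste(utils::head(unique(df$name[is.na(kind)])), collapse = ", "))
  out <- data.frame(contig = df$contig, start = as.integer(df$start),
                    end = as.integer(df$end), strand = df$strand,
                    kind = kind, name = df$name, stringsAsFactors = FALSE)
  out[order(out$contig, out$start, out$end), , drop = FALSE]
}

#' Write features as BED6
#' @param features feature data.frame (as in a [genome_annotation()]).
#' @param path output path.
#' @export
write_bed_annotation <- function(features, path) {
  f <- features[order(features$contig, features$start, features$end), , drop = FALSE]
  writeLines(paste(f$contig, f$start, f$end, f$name, 0L,
                   ifelse(f$strand %in% c("+", "-"), f$strand, "."),
                   sep = "\t"), path)
  invisible(path)
}

#' Read / write bedGraph coverage tracks
#'
#' Intervals are 0-based half-open and must not overlap; values attach
#' per-interval and can be expanded per-base on demand.
#'
#' @param path bedGraph path.
#' @return `coverage_track` data.frame (`contig`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "numeric"),
                          quote = "", comment.char = "#")
  names(df) <- c("contig", "start", "end", "value")
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ct in unique(df$contig)) {
    d <- df[df$contig == ct, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping bedGraph intervals on ", ct)
  }
  class(df) <- c("coverage_track", "data.frame")
  df
}

#' @rdname read_bedgraph
#' @param track a `coverage_track` data.frame.
#' @export
write_bedgraph <- function(track, path) {
  t2 <- track[order(track$contig, track$start), , drop = FALSE]
  writeLines(paste(t2$contig, t2$start, t2$end,
                   sprintf("%.10g", t2$value), sep = "\t"), path)
  invisible(path)
}

# expand a coverage_track to per-base values over one contig
expand_coverage <- function(track, contig, length) {
  d <- track[track$contig == contig, , drop = FALSE]
  v <- rep(0, length)
  for (i in seq_len(nrow(d))) {
    lo <- max(0L, d$start[i]); hi <- min(length, d$end[i])
    if (hi > lo) v[(lo + 1):hi] <- d$value[i]
  }
  v
}
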