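new_aggregate_track <- function(df, provenance = list()) {
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("aggregate_track", "data.frame")
  df
}

#' @export
print.aggregate_track <- function(x, ...) {
  cat("aggregate_track:", nrow(x), "positions on",
      paste(unique(x$contig), collapse = ","),
      if (!is.null(x$smoothed)) "(smoothed)" else "", "\n")
  invisible(x)
}

#' Aggregate binary per-read calls into a percent-methylated track
#'
#' For each (position, strand) — or each position if strands are merged —
#' coverage is the number of emitted calls and percent is
#' 100 x methylated / coverage, the "percentage of reads in each position
#' called as methylated" plotted in aggregate figures. Positions with zero
#' calls are simply absent.
#'
#' @param calls binarized `perread_calls`.
#' @param region optional `(contig, start, end)` restriction.
#' @param merge_strands pool calls from both strands at the same
#'   reference position? Adenine positions on opposite strands are
#'   distinct sites, so merging is a pooling convenience, off by default.
#' @return an `aggregate_track` data.frame (`contig`, `pos`, `strand`,
#'   `coverage`, `n_meth`, `percent`).
#' @export
aggregate_fraction <- function(calls, region = NULL, merge_strands = FALSE) {
  if (!is_binarized(calls)) stop("calls must be binarized first")
  cc <- calls
  if (!is.null(region)) {
    r <- as.list(region)
    cc <- cc[cc$contig == r[[1]] & cc$pos >= as.numeric(r[[2]]) &
               cc$pos < as.numeric(r[[3]]), , drop = FALSE]
  }
  pieces <- lapply(unique(cc$contig), function(ct) {
    d <- cc[cc$contig == ct, , drop = FALSE]
    key <- if (merge_strands) d$pos * 2 else d$pos * 2 + (d$strand == "-")
    agg <- rowsum(cbind(cov = 1, meth = as.integer(d$methylated)), key)
    k <- as.numeric(rownames(agg))
    data.frame(contig = ct, pos = as.integer(k %/% 2),
               strand = if (merge_strands) "." else ifelse(k %% 2 == 1, "-", "+"),
               coverage = as.integer(agg[, "cov"]),
               n_meth = as.integer(agg[, "meth"]),
               percent = 100 * agg[, "meth"] / agg[, "cov"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), coverage = integer(0),
                      n_meth = integer(0), percent = numeric(0))
  new_aggregate_track(out[order(out$contig, out$pos, out$strand), , drop = FALSE],
                      provenance = list(threshold = attr(calls, "threshold"),
                                        merge_strands = merge_strands))
}

#' Coverage-filter an aggregate track
#'
#' Keeps only positions with at least `min_coverage` emitted calls
#' (inclusive: coverage 10 is retained at the default 10x floor);
#' retained records are untouched.
#'
#' @param track an `aggregate_track`.
#' @param min_coverage integer >= 1.
#' @return the filtered track.
#' @export
filter_coverage <- function(track, min_coverage = 10) {
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  prov <- attr(track, "provenance") %||% list()
  prov$min_coverage <- min_coverage
  new_aggregate_track(track[track$coverage >= min_coverage, , drop = FALSE],
                      provenance = prov)
}

#' Smooth an aggregate track by coverage-weighted local regression
#'
#' Local-linear (degree 1, tricube kernel) regression of percent
#' methylated against position, with observation weights equal to the
#' coverage at each position, exactly the `loess(..., enp.target = 100,
#' weights = coverage)` smoothing applied to the assay's aggregate plots.
#' The span is calibrated so the smoother's effective number of
#' parameters matches `enp_target`, or may be pinned directly with
#' `span`. Smoothing is applied per contig and, for stranded tracks,
#' per strand.
#'
#' @param track an `aggregate_track` (>= 3 positions per group).
#' @param enp_target effective number of parameters of the smoother.
#' @param span optional span in (0, 1\]; when given, `enp_target` is
#'   ignored.
#' @param weight_by_coverage use coverage as observation weights?
#' @param surface `"interpolate"` (fast, default) or `"direct"` (exact
#'   local regression at every position).
#' @return the track with a `smoothed` column added.
#' @export
smooth_track <- function(track, enp_target = 100, span = NULL,
                         weight_by_coverage = TRUE,
                         surface = c("interpolate", "direct")) {
  surface <- match.arg(surface)
  if (nrow(track) < 3)
    stop("need >= 3 retained positions to smooth, got ", nrow(track))
  track$smoothed <- NA_real_
  grp <- interaction(track$contig, track$strand, drop = TRUE)
  for (g in levels(grp)) {
    i <- which(grp == g)
    n <- length(i)
    if (n < 3) stop("need >= 3 retained positions to smooth (group ", g, ")")
    if (is.null(span) && enp_target >= n)
      stop("enp_target (", enp_target, ") must be below the number of ",
           "positions (", n, "); pin a span instead")
    w <- if (weight_by_coverage) track$coverage[i] else rep(1, n)
    args <- list(formula = percent ~ pos,
                 data = data.frame(pos = track$pos[i], percent = track$percent[i]),
                 weights = w, degree = 1, family = "gaussian",
                 surface = surface)
    if (is.null(span)) args$enp.target <- enp_target else args$span <- span
    fit <- do.call(stats::loess, args)
    track$smoothed[i] <- stats::fitted(fit)
  }
  prov <- attr(track, "provenance") %||% list()
  prov$smoothing <- list(enp_target = if (is.null(span)) enp_target else NA,
                         span = span, weight_by_coverage = weight_by_coverage)
  new_aggregate_track(track, provenance = prov)
}

#' Normalize a coverage track to its genome-wide median
#'
#' Every value is divided by the median per-base depth over non-excluded
#' positions, the normalization applied to occupancy (ChIP) tracks:
#' exclusions are the regions whose copy number or mappability would bias
#' the genome-wide median (rDNA, the silent-locus chromosome, the first
#' and last 10 kb of each chromosome). After normalization the included
#' median is exactly 1; the operation is idempotent.
#'
#' @param coverage a `coverage_track` data.frame (`contig`, `start`,
#'   `end`, `value`).
#' @param exclusions data.frame of intervals (`contig`, `start`, `end`)
#'   excluded from the median (values there are still divided).
#' @return the normalized `coverage_track`.
#' @export
normalize_chip <- function(coverage, exclusions = NULL) {
  if (any(coverage$value < 0)) stop("depths must be non-negative")
  w <- as.numeric(coverage$end - coverage$start)
  keep <- rep(TRUE, nrow(coverage))
  if (!is.null(exclusions) && nrow(exclusions)) {
    # per-base weights with excluded bases removed, interval-wise
    for (i in seq_len(nrow(coverage))) {
      ex <- exclusions[exclusions$contig == coverage$contig[i], , drop = FALSE]
      if (nrow(ex)) {
        ov <- pmin(coverage$end[i], ex$end) - pmax(coverage$start[i], ex$start)
        w[i] <- w[i] - sum(pmax(0, ov))
      }
    }
    keep <- w > 0
  }
  if (!any(keep)) stop("no non-excluded positions")
  med <- weighted_median(coverage$value[keep], w[keep])
  if (med == 0) stop("median depth over non-excluded positions is zero")
  coverage$value <- coverage$value / med
  coverage
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Align aggregate tracks of several genotypes for comparison
#'
#' Positions are union-aligned; values missing in a track are NA, with no
#' interpolation.
#'
#' @param tracks named list of `aggregate_track`s sharing a contig.
#' @param region optional `(contig, start, end)` restriction.
#' @param value column to align (`"percent"` or `"smoothed"`).
#' @return data.frame with `contig`, `pos`, `strand` and one value column
#'   per track.
#' @export
genotype_overlay <- function(tracks, region = NULL, value = "percent") {
  stopifnot(length(tracks) >= 1)
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    names(tracks) <- paste0("track", seq_along(tracks))
  cts <- unique(unlist(lapply(tracks, function(t) unique(t$contig))))
  if (length(cts) != 1) stop("tracks must share one contig")
  if (!is.null(region)) {
    r <- as.list(region)
    if (r[[1]] != cts) stop("region contig does not match tracks")
    tracks <- lapply(tracks, function(t)
      t[t$pos >= as.numeric(r[[2]]) & t$pos < as.numeric(r[[3]]), , drop = FALSE])
  }
  keys <- unique(do.call(rbind, lapply(tracks, function(t)
    data.frame(pos = t$pos, strand = t$strand, stringsAsFactors = FALSE))))
  keys <- keys[order(keys$pos, keys$strand), , drop = FALSE]
  out <- data.frame(contig = cts, pos = keys$pos, strand = keys$strand,
                    stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    t <- tracks[[nm]]
    m <- match(paste(keys$pos, keys$strand), paste(t$pos, t$strand))
    out[[nm]] <- t[[value]][m]
  }
  rownames(out) <- NULL
  out
}
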