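#' Estimate the background methylation level
#'
#' Background is measured from a control — a sample whose methyltransferase
#' fusion partner is deleted (no targeted occupancy), or control regions of
#' the test sample — as mean + k standard deviations of the percent
#' methylated over control positions. Smoothed values are used when
#' present; on a raw track the per-position binomial noise would inflate
#' the SD far beyond the level the control actually supports.
#'
#' @param control_track an `aggregate_track` from a control sample/region.
#' @param regions optional data.frame of intervals (`contig`, `start`,
#'   `end`) restricting which positions count as control.
#' @param k number of SDs above the mean (default 2).
#' @return object of class `background_level`: list with `background`
#'   (percent), `mean`, `sd`, `n`, `k`.
#' @export
estimate_background <- function(control_track, regions = NULL, k = 2) {
  t <- control_track
  if (!is.null(regions)) {
    sel <- rep(FALSE, nrow(t))
    for (i in seq_len(nrow(regions)))
      sel <- sel | (t$contig == regions$contig[i] &
                      t$pos >= regions$start[i] & t$pos < regions$end[i])
    t <- t[sel, , drop = FALSE]
  }
  v <- if (!is.null(t$smoothed)) t$smoothed else t$percent
  v <- v[!is.na(v)]
  if (length(v) < 20) stop("need >= 20 control positions, got ", length(v))
  m <- mean(v); s <- stats::sd(v)
  structure(list(background = m + k * s, mean = m, sd = s,
                 n = length(v), k = k),
            class = "background_level")
}

#' @export
print.background_level <- function(x, ...) {
  cat(sprintf("background: %.3f%% (mean %.3f + %g sd %.3f over %d positions)\n",
              x$background, x$mean, x$k, x$sd, x$n))
  invisible(x)
}

bg_value <- function(background) {
  if (inherits(background, "background_level")) background$background
  else as.numeric(background)
}

anchor_interval <- function(anchor) {
  if (is.data.frame(anchor)) c(anchor$start[1], anchor$end[1])
  else as.numeric(anchor)[1:2]
}

dir_sign <- function(direction) {
  if (is.character(direction))
    switch(direction, "+" = 1, "-" = -1,
           stop("direction must be '+', '-', 1 or -1"))
  else sign(as.numeric(direction))
}

#' Call the spread boundary relative to a recruitment anchor
#'
#' Moving away from the anchor edge in the given direction, the boundary
#' is the first position at which the smoothed percent methylated stays at
#' or below the background level for at least `run_length` consecutive bp.
#' The sustained-run criterion (default 300 bp, about two nucleosomes)
#' makes the call robust to local dips from nucleosome-core occlusion and
#' smoothing ripple. If the signal never returns to background before the
#' track runs out, the call is `unbounded` at the window edge; if it never
#' rises above background at all, the call is `at_anchor` with extent 0.
#'
#' @param track a smoothed `aggregate_track` on one contig.
#' @param anchor recruitment feature row or `(start, end)` vector.
#' @param direction `"+"`/`1` to scan right, `"-"`/`-1` to scan left.
#' @param background a [estimate_background()] result or percent value.
#' @param run_length sustained-run length W in bp.
#' @return object of class `boundary_call`: list with `contig`, `anchor`,
#'   `direction`, `boundary_position`, `spread_extent`,
#'   `background_level`, `status`.
#' @export
call_boundary <- function(track, anchor, direction, background,
                          run_length = 300) {
  if (is.null(track$smoothed)) stop("track must be smoothed first")
  ct <- unique(track$contig)
  if (length(ct) != 1) stop("track must cover one contig")
  bg <- bg_value(background)
  ai <- anchor_interval(anchor)
  dir <- dir_sign(direction)
  edge <- if (dir > 0) ai[2] else ai[1] - 1
  sel <- if (dir > 0) track$pos >= edge else track$pos <= edge
  d <- track[sel, , drop = FALSE]
  if (nrow(d) == 0) stop("anchor outside the analyzed window")
  # orient so positions run outward from the anchor
  o <- order(if (dir > 0) d$pos else -d$pos)
  pos <- d$pos[o]; val <- d$smoothed[o]
  below <- val <= bg
  dist <- abs(pos - edge)
  # first index i such that every position within run_length bp outward of
  # pos[i] is below background
  n <- length(pos)
  cum_above <- cumsum(!below)
  win_end <- findInterval(dist + run_length - 1e-9, dist)  # last index in window
  ok <- below & (cum_above[win_end] - cum_above + as.integer(!below)) == 0
  # a run at the track tail shorter than run_length still counts only if it
  # reaches the window edge; accept it (censoring at the edge)
  hit <- which(ok)
  if (length(hit) == 0) {
    status <- "unbounded"
    boundary <- pos[n]
    extent <- dist[n]
  } else {
    i <- hit[1]
    boundary <- pos[i]
    extent <- dist[i]
    if (!any(!below[seq_len(i)])) {   # never above background before boundary
      status <- "at_anchor"; boundary <- edge; extent <- 0
    } else status <- "bounded"
  }
  structure(list(contig = ct, anchor = ai, direction = dir,
                 boundary_position = boundary, spread_extent = extent,
                 background_level = bg, run_length = run_length,
                 status = status),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat(sprintf("boundary_call [%s]: %s at %d (extent %d bp, bg %.2f%%)\n",
              x$status, x$contig, round(x$boundary_position),
              round(x$spread_extent), x$background_level))
  invisible(x)
}

#' Classify the response of a locus to a perturbation
#'
#' Compares condition b (e.g. overexpression) against condition a at one
#' anchor: `boundary_shift` is the change in spread extent and
#' `level_ratio` the ratio of mean smoothed methylation over the shared
#' above-background domain. Categories mirror the three telomere response
#' classes seen under overexpression: `extended` (boundary moved out and
#' level up), `increased_only` (level up, boundary fixed) and `unchanged`.
#' Thresholds are explicit configuration, calibrated on the simulator.
#'
#' @param track_a,track_b smoothed `aggregate_track`s for the two
#'   conditions.
#' @param anchor,direction,background,run_length as in [call_boundary()].
#' @param thresholds list with `shift` (bp) and `ratio`.
#' @return object of class `response_call`: list with `category`,
#'   `boundary_shift`, `level_ratio` and the two boundary calls.
#' @export
classify_response <- function(track_a, track_b, anchor, direction, background,
                              thresholds = list(shift = 500, ratio = 1.25),
                              run_length = 300) {
  ba <- call_boundary(track_a, anchor, direction, background, run_length)
  bb <- call_boundary(track_b, anchor, direction, background, run_length)
  shift <- bb$spread_extent - ba$spread_extent
  if (ba$status == "at_anchor" && bb$status == "at_anchor") {
    warning("both tracks at background; response is unchanged")
    return(structure(list(category = "unchanged", boundary_shift = 0,
                          level_ratio = 1, boundary_a = ba, boundary_b = bb),
                     class = "response_call"))
  }
  dir <- dir_sign(direction)
  ai <- anchor_interval(anchor)
  edge <- if (dir > 0) ai[2] else ai[1] - 1
  shared <- min(ba$spread_extent, bb$spread_extent)
  dom <- function(t) {
    d <- abs(t$pos - edge)
    onside <- if (dir > 0) t$pos >= edge else t$pos <= edge
    t$smoothed[onside & d <= max(shared, 1)]
  }
  ma <- mean(dom(track_a)); mb <- mean(dom(track_b))
  ratio <- if (isTRUE(ma > 0)) mb / ma else NA_real_
  category <-
    if (!is.na(ratio) && ratio > thresholds$ratio)
      (if (shift > thresholds$shift) "extended" else "increased_only")
    else "unchanged"
  structure(list(category = category, boundary_shift = shift,
                 level_ratio = ratio, boundary_a = ba, boundary_b = bb),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("response_call: %s (shift %+d bp, level ratio %.2f)\n",
              x$category, round(x$boundary_shift), x$level_ratio))
  invisible(x)
}

#' Per-position differential methylation between two samples
#'
#' Exact two-proportion (Fisher) test on the (methylated, coverage) counts
#' at every position shared between the two tracks and passing the
#' coverage floor in both, with Benjamini-Hochberg correction across
#' tested positions. The exact test is used because per-position coverage
#' can be small at the 10x floor.
#'
#' @param track_a,track_b `aggregate_track`s carrying integer counts.
#' @param min_coverage coverage floor applied to both samples.
#' @param fdr BH false-discovery-rate threshold for the `significant` flag.
#' @return data.frame with `contig`, `pos`, `strand`, counts for both
#'   samples, `effect` (percent_b - percent_a), `p`, `q`, `significant`.
#' @export
differential_positions <- function(track_a, track_b, min_coverage = 10,
                                   fdr = 0.05) {
  key_a <- paste(track_a$contig, track_a$pos, track_a$strand)
  key_b <- paste(track_b$contig, track_b$pos, track_b$strand)
  m <- match(key_a, key_b)
  sel <- !is.na(m)
  a <- track_a[sel, , drop = FALSE]
  b <- track_b[m[sel], , drop = FALSE]
  ok <- a$coverage >= min_coverage & b$coverage >= min_coverage
  a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  if (nrow(a) == 0) stop("no shared positions passing the coverage floor")
  p <- vapply(seq_len(nrow(a)), function(i) {
    stats::fisher.test(matrix(c(a$n_meth[i], a$coverage[i] - a$n_meth[i],
                                b$n_meth[i], b$coverage[i] - b$n_meth[i]),
                              nrow = 2))$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(contig = a$contig, pos = a$pos, strand = a$strand,
             n_meth_a = a$n_meth, coverage_a = a$coverage,
             n_meth_b = b$n_meth, coverage_b = b$coverage,
             effect = 100 * (b$n_meth / b$coverage - a$n_meth / a$coverage),
             p = p, q = q, significant = q <= fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate the methylation periodicity (nucleosome repeat length)
#'
#' Detrends the percent-methylated signal (raw minus smoothed trend),
#' expands it from the irregular adenine grid to a 1 bp grid by
#' nearest-neighbour assignment, and takes the positional autocorrelation.
#' The repeat length is the lag of the first local maximum at lags >=
#' `min_lag`; its significance is assessed against a permutation null in
#' which detrended values are shuffled across positions. Periodic
#' methylation arises because linker DNA between nucleosomes is
#' preferentially accessible, so the expected repeat is the ~165 bp
#' nucleosome repeat length.
#'
#' @param x a smoothed `aggregate_track`, or a `methylation_matrix`.
#' @param window optional `(contig, start, end)` restriction; the window
#'   must span at least `5 * max_lag` bp.
#' @param max_lag maximum lag in bp.
#' @param min_lag smallest lag searched (skips the short-range shoulder
#'   that nearest-neighbour gridding induces).
#' @param n_perm permutations for the null band.
#' @param conf confidence level of the permutation band.
#' @return object of class `periodicity_estimate`: list with
#'   `repeat_length`, `peak_strength`, `significant`, `band`, `acf`.
#' @export
estimate_periodicity <- function(x, window = NULL, max_lag = 400,
                                 min_lag = 30, n_perm = 200, conf = 0.95) {
  UseMethod("estimate_periodicity")
}

#' @export
estimate_periodicity.methylation_matrix <- function(x, window = NULL,
                                                    max_lag = 400,
                                                    min_lag = 30,
                                                    n_perm = 200,
                                                    conf = 0.95) {
  cm <- colMeans(x$mat == 1L, na.rm = TRUE)
  cov <- colSums(!is.na(x$mat))
  track <- new_aggregate_track(data.frame(
    contig = x$window$contig, pos = x$positions, strand = ".",
    coverage = cov, n_meth = as.integer(round(cm * cov)),
    percent = 100 * cm, stringsAsFactors = FALSE))
  estimate_periodicity(track, window = window, max_lag = max_lag,
                       min_lag = min_lag, n_perm = n_perm, conf = conf)
}

#' @export
estimate_periodicity.aggregate_track <- function(x, window = NULL,
                                                 max_lag = 400, min_lag = 30,
                                                 n_perm = 200, conf = 0.95) {
  t <- x
  if (!is.null(window)) {
    r <- as.list(window)
    t <- t[t$contig == r[[1]] & t$pos >= as.numeric(r[[2]]) &
             t$pos < as.numeric(r[[3]]), , drop = FALSE]
  }
  if (nrow(t) < 10) stop("insufficient positions for periodicity")
  span_bp <- max(t$pos) - min(t$pos)
  if (span_bp < 5 * max_lag)
    stop("window must span at least 5 * max_lag bp")
  if (is.null(t$smoothed)) {
    # detrend at ~800 bp resolution: broad enough not to absorb the
    # nucleosome-repeat oscillation itself
    enp <- min(max(4, round(span_bp / 800)), nrow(t) - 1)
    t <- smooth_track(t, enp_target = enp)
  }
  resid <- t$percent - t$smoothed
  peak_of <- function(r) {
    grid <- grid_nearest(t$pos, r)
    a <- as.numeric(stats::acf(grid, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1]
    a_s <- smooth_runmean(a, 11L)
    lags <- seq_along(a_s)
    cand <- which(lags >= min_lag & lags <= max_lag - 1)
    locmax <- cand[a_s[cand] > c(-Inf, a_s)[cand] &
                     a_s[cand] >= c(a_s, -Inf)[cand + 1] &
                     a_s[cand] > 0]     # a peak, not a ripple in a trough
    if (length(locmax) == 0) return(c(NA_real_, NA_real_))
    l <- locmax[1]
    c(l, a_s[l])
  }
  obs <- peak_of(resid)
  perm_max <- with_seed(derive_seed(1L, "periodicity-perm"), {
    vapply(seq_len(n_perm), function(i) {
      r <- sample(resid)
      grid <- grid_nearest(t$pos, r)
      a <- as.numeric(stats::acf(grid, lag.max = max_lag, plot = FALSE,
                                 demean = TRUE)$acf)[-1]
      a_s <- smooth_runmean(a, 11L)
      max(a_s[min_lag:(max_lag - 1)])
    }, numeric(1))
  })
  band <- stats::quantile(perm_max, conf, names = FALSE)
  sig <- !is.na(obs[2]) && obs[2] > band
  structure(list(repeat_length = if (sig) obs[1] else NA_real_,
                 raw_peak_lag = obs[1], peak_strength = obs[2],
                 significant = sig, band = band),
            class = "periodicity_estimate")
}

#' @export
print.periodicity_estimate <- function(x, ...) {
  if (x$significant)
    cat(sprintf("periodicity: repeat %g bp (strength %.3f > %.1f%% band %.3f)\n",
                x$repeat_length, x$peak_strength, 95, x$band))
  else cat("periodicity: none detected above the permutation band\n")
  invisible(x)
}

# nearest-neighbour expansion of values at irregular positions to 1 bp grid
grid_nearest <- function(pos, values) {
  o <- order(pos)
  pos <- pos[o]; values <- values[o]
  grid <- seq(min(pos), max(pos))
  mid <- (pos[-1] + pos[-length(pos)]) / 2
  idx <- findInterval(grid, mid) + 1L
  values[idx]
}

smooth_runmean <- function(x, k) {
  if (k <= 1) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  # keep edges unsmoothed rather than NA
  ifelse(is.na(s), x, s)
}

#' Linker vs nucleosome-core methylation enrichment
#'
#' Classifies every emitted call as core (within `core_halfwidth` bp of a
#' nucleosome dyad) or linker, computes the methylated fraction in each
#' class and their ratio, with a bootstrap confidence interval resampling
#' whole reads. Ratios above 1 indicate preferential methylation of
#' linker DNA.
#'
#' @param calls binarized `perread_calls`.
#' @param dyads numeric vector of dyad positions, or data.frame with
#'   `contig`, `pos`.
#' @param core_halfwidth bp (default 73).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed seed for the bootstrap resampling.
#' @return object of class `linker_enrichment`: list with `ratio`,
#'   `ci`, `linker_rate`, `core_rate`, call counts.
#' @export
linker_enrichment <- function(calls, dyads, core_halfwidth = 73,
                              n_boot = 200, conf = 0.95, seed = 1L) {
  if (!is_binarized(calls)) stop("calls must be binarized first")
  dy <- if (is.data.frame(dyads)) dyads$pos else as.numeric(dyads)
  dy <- sort(dy)
  if (length(dy) == 0) stop("no dyads given")
  dmin <- nearest_distance(calls$pos, dy)
  core <- dmin <= core_halfwidth
  if (sum(core) < 100 || sum(!core) < 100)
    stop("need >= 100 calls in each of the core and linker classes")
  rate <- function(idx) {
    cr <- mean(calls$methylated[idx & core])
    lr <- mean(calls$methylated[idx & !core])
    c(core = cr, linker = lr)
  }
  r0 <- rate(rep(TRUE, nrow(calls)))
  if (r0["core"] == 0)
    stop("zero methylated calls in the core class; ratio undefined")
  ids <- unique(calls$read_id)
  boot <- with_seed(derive_seed(seed, "linker-boot"), {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample(ids, length(ids), replace = TRUE)
      cnt <- table(pick)
      idx <- calls$read_id %in% names(cnt)
      w <- as.numeric(cnt[calls$read_id[idx]])
      cm <- calls$methylated[idx]; co <- core[idx]
      cr <- sum(w * (cm & co)) / sum(w * co)
      lr <- sum(w * (cm & !co)) / sum(w * !co)
      if (cr == 0) NA_real_ else lr / cr
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  structure(list(ratio = unname(r0["linker"] / r0["core"]),
                 linker_rate = unname(r0["linker"]),
                 core_rate = unname(r0["core"]),
                 n_linker = sum(!core), n_core = sum(core),
                 ci = stats::quantile(boot, c(alpha, 1 - alpha),
                                      na.rm = TRUE, names = FALSE)),
            class = "linker_enrichment")
}

#' @export
print.linker_enrichment <- function(x, ...) {
  cat(sprintf("linker/core methylation ratio %.2f [%.2f, %.2f] (linker %.3f, core %.3f)\n",
              x$ratio, x$ci[1], x$ci[2], x$linker_rate, x$core_rate))
  invisible(x)
}

nearest_distance <- function(x, sorted_ref) {
  idx <- findInterval(x, sorted_ref)
  d_lo <- ifelse(idx >= 1, x - sorted_ref[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(sorted_ref),
                 sorted_ref[pmin(idx + 1, length(sorted_ref))] - x, Inf)
  pmin(d_lo, d_hi)
}

#' Map establishment onset times across a time course
#'
#' For every position observed at all sampled times, the onset is the
#' earliest sampled time from which the percent methylated exceeds the
#' background level for at least `min_consecutive` consecutive sampled
#' times; positions never satisfying this are censored. Tracks establishment
#' order — recruitment sites saturate before interior (spread-only)
#' positions.
#'
#' @param tracks list of `list(time =, track =)` entries (or the output of
#'   [simulate_timecourse()] aggregated externally), times sorted
#'   ascending, >= 3 time points.
#' @param background background level (percent) or
#'   [estimate_background()] result.
#' @param min_consecutive consecutive exceedances required.
#' @return object of class `onset_table`: data.frame with `contig`,
#'   `pos`, `strand`, `onset_time` (NA when censored), `censored`.
#' @export
onset_times <- function(tracks, background, min_consecutive = 2) {
  times <- vapply(tracks, function(e) e$time, numeric(1))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be sorted ascending")
  if (length(times) < 3) stop("need >= 3 time points")
  bg <- bg_value(background)
  keys <- lapply(tracks, function(e)
    paste(e$track$contig, e$track$pos, e$track$strand))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0) stop("no positions shared across all time points")
  pm <- vapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]$track
    t$percent[match(shared, keys[[i]])]
  }, numeric(length(shared)))
  exceed <- pm > bg
  nt <- length(times)
  onset <- apply(exceed, 1, function(e) {
    runs <- rle(e)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    ok <- which(runs$values & runs$lengths >= min_consecutive)
    if (length(ok) == 0) NA_real_ else times[starts[ok[1]]]
  })
  parts <- do.call(rbind, strsplit(shared, " ", fixed = TRUE))
  out <- data.frame(contig = parts[, 1], pos = as.integer(parts[, 2]),
                    strand = parts[, 3], onset_time = onset,
                    censored = is.na(onset), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "times") <- times
  attr(out, "background") <- bg
  attr(out, "min_consecutive") <- min_consecutive
  class(out) <- c("onset_table", "data.frame")
  out
}

#' Fit an exponential spread model away from an anchor
#'
#' Least-squares fit of `percent(d) = background + A * exp(-d / lambda)`
#' to the smoothed track, where d is the distance from the anchor edge in
#' the scan direction. Quantifies "spread" as a decay length. The decay
#' length is bounded to \[10, 1e5\] bp; if the fitted amplitude is
#' negligible (flat-at-background input) lambda is reported censored.
#'
#' @param track a smoothed `aggregate_track`.
#' @param anchor,direction as in [call_boundary()].
#' @param background background percent or [estimate_background()] result.
#' @param max_distance optional cap on the fitted distance range (bp).
#' @param lambda_bounds bounds for the decay length (bp).
#' @return object of class `spread_fit`: list with `amplitude`, `lambda`,
#'   `residual` (RMS), `censored`, `n`.
#' @export
fit_spread_model <- function(track, anchor, direction, background,
                             max_distance = Inf,
                             lambda_bounds = c(10, 1e5)) {
  if (is.null(track$smoothed)) stop("track must be smoothed first")
  bg <- bg_value(background)
  ai <- anchor_interval(anchor)
  dir <- dir_sign(direction)
  edge <- if (dir > 0) ai[2] else ai[1] - 1
  onside <- if (dir > 0) track$pos >= edge else track$pos <= edge
  d <- abs(track$pos[onside] - edge)
  y <- track$smoothed[onside]
  keep <- d <= max_distance
  d <- d[keep]; y <- y[keep]
  if (sum(y > bg) < 10) {
    if (length(y) < 10) stop("degenerate domain: fewer than 10 positions")
    return(structure(list(amplitude = 0, lambda = NA_real_,
                          residual = stats::sd(y - bg), censored = TRUE,
                          n = length(y)),
                     class = "spread_fit"))
  }
  sse <- function(par) {
    A <- par[1]; lam <- exp(par[2])
    sum((y - bg - A * exp(-d / lam))^2)
  }
  A0 <- max(max(y) - bg, 1e-3)
  fit <- stats::optim(c(A0, log(500)), sse, method = "L-BFGS-B",
                      lower = c(0, log(lambda_bounds[1])),
                      upper = c(200, log(lambda_bounds[2])))
  A <- fit$par[1]; lam <- exp(fit$par[2])
  censored <- A < 0.5
  structure(list(amplitude = A, lambda = if (censored) NA_real_ else lam,
                 residual = sqrt(fit$value / length(y)), censored = censored,
                 n = length(y)),
            class = "spread_fit")
}

#' @export
print.spread_fit <- function(x, ...) {
  if (x$censored)
    cat("spread_fit: flat at background (amplitude ~ 0, lambda censored)\n")
  else
    cat(sprintf("spread_fit: amplitude %.2f%%, lambda %.0f bp (rms %.3f, n %d)\n",
                x$amplitude, x$lambda, x$residual, x$n))
  invisible(x)
}
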