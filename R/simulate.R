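#' Base-caller emission model
#'
#' The modified-base caller emits, for every adenine under a read, a
#' probability that the base is m6A. Downstream analysis binarizes at a
#' threshold (default 0.8, strict). The simulator models only this
#' threshold behaviour plus a smooth class-conditional shape: a truly
#' methylated adenine is emitted above the threshold with probability
#' `tpr`, an unmethylated one with probability `fpr`; within each side of
#' the threshold values are drawn from a truncated Beta law — right-skewed
#' (mass near 1) for the methylated class, left-skewed (mass near 0) for
#' the unmethylated class — so the marginal emission distribution is a
#' realistic unimodal shape with exactly the configured threshold rates.
#'
#' @param tpr probability a methylated adenine is emitted above threshold.
#' @param fpr probability an unmethylated adenine is emitted above
#'   threshold; must be < `tpr`.
#' @param threshold binarization threshold the rates refer to.
#' @param shape_methylated,shape_unmethylated Beta shape pairs for the two
#'   class-conditional emission laws.
#' @return object of class `emission_model`.
#' @export
emission_model <- function(tpr = 0.9, fpr = 0.01, threshold = 0.8,
                           shape_methylated = c(5, 1),
                           shape_unmethylated = c(1, 5)) {
  if (!(fpr < tpr)) stop("fpr must be < tpr")
  if (tpr < 0 || tpr > 1 || fpr < 0 || fpr > 1) stop("rates must be in [0, 1]")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(tpr = tpr, fpr = fpr, threshold = threshold,
                 shape_methylated = shape_methylated,
                 shape_unmethylated = shape_unmethylated),
            class = "emission_model")
}

rbeta_trunc <- function(n, shape1, shape2, lo, hi) {
  if (n == 0) return(numeric(0))
  # closed-form inverse CDF for the one-parameter Beta families used by
  # the default emission shapes; general shapes fall back to qbeta
  if (shape2 == 1) {
    u <- stats::runif(n, lo^shape1, hi^shape1)
    return(u^(1 / shape1))
  }
  if (shape1 == 1) {
    u <- stats::runif(n, 1 - (1 - lo)^shape2, 1 - (1 - hi)^shape2)
    return(1 - (1 - u)^(1 / shape2))
  }
  plo <- stats::pbeta(lo, shape1, shape2)
  phi <- stats::pbeta(hi, shape1, shape2)
  stats::qbeta(stats::runif(n, plo, phi), shape1, shape2)
}

# draw emitted probabilities for a logical truth vector
emit_probs <- function(truth, emission) {
  n <- length(truth)
  p <- numeric(n)
  th <- emission$threshold
  above <- logical(n)
  above[truth] <- stats::runif(sum(truth)) < emission$tpr
  above[!truth] <- stats::runif(sum(!truth)) < emission$fpr
  sm <- emission$shape_methylated
  su <- emission$shape_unmethylated
  i <- truth & above
  p[i] <- rbeta_trunc(sum(i), sm[1], sm[2], th, 1)
  i <- truth & !above
  p[i] <- rbeta_trunc(sum(i), sm[1], sm[2], 0, th)
  i <- !truth & above
  p[i] <- rbeta_trunc(sum(i), su[1], su[2], th, 1)
  i <- !truth & !above
  p[i] <- rbeta_trunc(sum(i), su[1], su[2], 0, th)
  p
}

#' Read sampler configuration
#'
#' @param mean_read_length mean read length in bp (long-read regime;
#'   genomic DNA in the assay is sheared to ~15-20 kb).
#' @param dispersion coefficient of variation of the read-length gamma
#'   distribution.
#' @param target_coverage expected read depth per position *per strand*;
#'   emitted-call coverage at an adenine is approximately this value.
#' @param min_read_length reads shorter than this are discarded.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return object of class `read_sampler`.
#' @export
read_sampler <- function(mean_read_length = 15000, dispersion = 0.25,
                         target_coverage = 30, min_read_length = 1000,
                         seed = 1L) {
  if (target_coverage <= 0) stop("target_coverage must be > 0")
  if (mean_read_length < min_read_length)
    stop("mean_read_length below min_read_length")
  structure(list(mean_read_length = mean_read_length, dispersion = dispersion,
                 target_coverage = target_coverage,
                 min_read_length = min_read_length, seed = as.integer(seed)),
            class = "read_sampler")
}

new_perread_calls <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("perread_calls", "data.frame")
  df
}

#' Simulate a per-read m6A call set
#'
#' Places long reads on each contig to the target per-strand coverage,
#' draws the true methylation state of every adenine under every read as
#' Bernoulli(occupancy x accessibility x rate), and emits a per-call
#' probability from the base-caller emission model. Fully deterministic
#' for a fixed sampler seed.
#'
#' @param annotation a [genome_annotation()].
#' @param model an [occupancy_model()].
#' @param emission an [emission_model()].
#' @param sampler a [read_sampler()].
#' @param time optional time in minutes for establishment time courses.
#' @param contig optionally restrict simulation to one contig.
#' @return a `perread_calls` data.frame with columns `read_id`, `contig`,
#'   `strand`, `pos` (0-based), `prob` (emitted m6A probability) and
#'   `truth` (simulated ground-truth state; dropped on serialization).
#' @export
simulate_reads <- function(annotation, model, emission, sampler,
                           time = NULL, contig = NULL) {
  contigs <- if (is.null(contig)) annotation$contigs$name else contig
  out <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    ct <- contigs[ci]
    L <- contig_length(annotation, ct)
    occ <- occupancy_field(model, annotation, ct, time = time)
    acc <- accessibility_field(annotation, model, ct)
    psite <- occ * acc * model$rate
    # reads may be truncated by either contig end (random shearing of a
    # linear molecule covers the terminus; terminal fragments are shorter),
    # so coverage is uniform out to the very ends
    n_reads <- round(2 * sampler$target_coverage *
                       (L + sampler$mean_read_length) / sampler$mean_read_length)
    if (n_reads < 1) {
      warning("coverage too low on ", ct, ": no reads produced")
      next
    }
    res <- with_seed(derive_seed(sampler$seed, paste0("reads:", ct,
                                                      ":t", time %||% "ss")), {
      shape <- 1 / sampler$dispersion^2
      len <- round(stats::rgamma(n_reads, shape = shape,
                                 scale = sampler$mean_read_length / shape))
      len <- pmax(len, sampler$min_read_length)
      start <- floor(stats::runif(n_reads, -(len - 1), L))
      lo <- pmax(0L, start)
      hi <- pmin(L, start + len)
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      pieces <- vector("list", n_reads)
      for (i in seq_len(n_reads)) {
        mask <- annotation$masks[[ct]][[strand[i]]]
        pos <- which(mask[(lo[i] + 1):hi[i]]) + lo[i] - 1L
        pieces[[i]] <- pos
      }
      npos <- lengths(pieces)
      pos <- unlist(pieces, use.names = FALSE)
      truth <- stats::runif(length(pos)) < psite[pos + 1L]
      prob <- emit_probs(truth, emission)
      data.frame(read_id = rep(sprintf("%s_read_%05d", ct, seq_len(n_reads)), npos),
                 contig = ct,
                 strand = rep(strand, npos),
                 pos = pos, prob = prob, truth = truth,
                 stringsAsFactors = FALSE)
    })
    out[[ci]] <- res
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(read_id = character(0), contig = character(0),
                        strand = character(0), pos = integer(0),
                        prob = numeric(0), truth = logical(0))
  new_perread_calls(calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an establishment time course
#'
#' One call set per sampled time, with the occupancy field scaled by the
#' saturation factors of the model's recruitment and spread halftimes.
#' Each time point draws from its own deterministic seed substream.
#'
#' @inheritParams simulate_reads
#' @param times sorted ascending vector of times in minutes.
#' @return list of `list(time =, calls =)` entries.
#' @export
simulate_timecourse <- function(annotation, model, emission, sampler, times,
                                contig = NULL) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be sorted ascending")
  if (any(times < 0)) stop("times must be >= 0")
  lapply(seq_along(times), function(i) {
    s2 <- sampler
    s2$seed <- derive_seed(sampler$seed, paste0("timecourse:", i))
    list(time = times[i],
         calls = simulate_reads(annotation, model, emission, s2,
                                time = times[i], contig = contig))
  })
}

#' Write simulator ground truth as bedGraph tracks
#'
#' Emits the occupancy and accessibility fields used by the simulator so
#' that downstream estimates can be compared against known truth.
#'
#' @inheritParams simulate_reads
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_truth_tracks <- function(annotation, model, dir, time = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ct in annotation$contigs$name) {
    occ <- occupancy_field(model, annotation, ct, time = time)
    acc <- accessibility_field(annotation, model, ct)
    for (nm in c("occupancy", "accessibility")) {
      v <- if (nm == "occupancy") occ else acc
      p <- file.path(dir, paste0("truth_", nm, "_", ct, ".bedgraph"))
      write_bedgraph(runs_to_bedgraph(ct, v), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

# collapse a per-base vector into bedGraph run-length intervals
runs_to_bedgraph <- function(contig, values) {
  r <- rle(values)
  end <- cumsum(r$lengths)
  data.frame(contig = contig, start = c(0L, end[-length(end)]), end = end,
             value = r$values, stringsAsFactors = FALSE)
}
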