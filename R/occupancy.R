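#' Parametric recruitment/spread/boundary occupancy model
#'
#' Formalizes the two-step picture of heterochromatin formation: sequence-
#' specific recruitment of the silencing protein to discrete elements
#' (silencers, telomeric TG repeats and X elements, some promoters), and
#' sequence-nonspecific spread away from them with an exponential
#' distance decay, attenuated multiplicatively at each boundary element
#' crossed. Occupancy at position x is
#'
#'   occ(x) = clamp(background +
#'                  sum_sites peak * exp(-d(x, site)/lambda) * atten^k, 0, 1)
#'
#' where d is the distance to the nearest edge of the recruitment interval
#' (0 inside it) and k counts boundary elements between the site and x.
#' For establishment time courses each site term is scaled by the
#' saturation factor t/(t + halftime): the in-interval (recruitment) part
#' uses the recruitment halftime, the decayed (spread) part the spread
#' halftime, so recruitment sites saturate first.
#'
#' @param recruitment data.frame with columns `contig`, `start`, `end`,
#'   `kind`, `peak` (peak occupancy in \[0, 1\]). Usually built from an
#'   annotation via [default_recruitment()].
#' @param lambda spread decay length in bp (> 0).
#' @param boundary_attenuation factor in \[0, 1\] applied once per boundary
#'   element crossed.
#' @param background background occupancy in \[0, 1).
#' @param rate per-visit methylation efficiency r in (0, 1].
#' @param linker_accessibility,core_accessibility accessibility of linker
#'   vs nucleosome-core DNA, each in (0, 1], core <= linker.
#' @param core_halfwidth bp around a dyad treated as core (default 73,
#'   half of the 147 bp nucleosomal footprint).
#' @param halftime_recruitment,halftime_spread establishment halftimes in
#'   minutes for the recruitment and spread components.
#'   `halftime_recruitment` may be a named vector keyed by feature kind.
#' @return object of class `occupancy_model`.
#' @export
occupancy_model <- function(recruitment,
                            lambda = 800,
                            boundary_attenuation = 0.1,
                            background = 0.02,
                            rate = 0.8,
                            linker_accessibility = 1,
                            core_accessibility = 0.2,
                            core_halfwidth = 73,
                            halftime_recruitment = 10,
                            halftime_spread = 120) {
  recruitment <- as.data.frame(recruitment)
  stopifnot(all(c("contig", "start", "end", "kind", "peak") %in% names(recruitment)))
  if (any(recruitment$peak < 0 | recruitment$peak > 1))
    stop("peak occupancy must be in [0, 1]")
  if (lambda <= 0) stop("lambda must be > 0")
  if (boundary_attenuation < 0 || boundary_attenuation > 1)
    stop("boundary_attenuation must be in [0, 1]")
  if (background < 0 || background >= 1) stop("background must be in [0, 1)")
  if (rate <= 0 || rate > 1) stop("rate must be in (0, 1]")
  if (linker_accessibility <= 0 || linker_accessibility > 1 ||
      core_accessibility <= 0 || core_accessibility > 1)
    stop("accessibilities must be in (0, 1]")
  if (core_accessibility > linker_accessibility)
    stop("core_accessibility must be <= linker_accessibility")
  if (any(halftime_recruitment < 0) || halftime_spread < 0)
    stop("halftimes must be >= 0")
  structure(list(recruitment = recruitment, lambda = lambda,
                 boundary_attenuation = boundary_attenuation,
                 background = background, rate = rate,
                 linker_accessibility = linker_accessibility,
                 core_accessibility = core_accessibility,
                 core_halfwidth = core_halfwidth,
                 halftime_recruitment = halftime_recruitment,
                 halftime_spread = halftime_spread),
            class = "occupancy_model")
}

#' Default recruitment table from an annotation
#'
#' Silencers, X elements and TG repeats are strong recruitment sites;
#' promoters inside silenced loci recruit more weakly (they carry Rap1
#' sites that contact the silencing proteins directly).
#'
#' @param annotation a [genome_annotation()].
#' @param peak peak occupancy for strong recruitment elements.
#' @param promoter_peak peak occupancy for promoters.
#' @return data.frame usable as the `recruitment` slot of [occupancy_model()].
#' @export
default_recruitment <- function(annotation, peak = 0.9, promoter_peak = 0.6) {
  f <- annotation$features
  r <- f[f$kind %in% c("silencer", "x_element", "tg_repeat", "promoter"),
         c("contig", "start", "end", "kind", "name"), drop = FALSE]
  r$peak <- ifelse(r$kind == "promoter", promoter_peak, peak)
  rownames(r) <- NULL
  r
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat("occupancy_model:", nrow(x$recruitment), "recruitment site(s), lambda =",
      x$lambda, "bp, background =", x$background, "\n")
  invisible(x)
}

time_factor <- function(t, halftime) {
  if (halftime == 0 || is.infinite(t)) return(1)
  t / (t + halftime)
}

#' Per-position occupancy field
#'
#' @param model an [occupancy_model()].
#' @param annotation a [genome_annotation()].
#' @param contig contig name.
#' @param time minutes since induction, or `NULL` for the steady state.
#' @return numeric vector of length `contig length`; element i is the
#'   occupancy at 0-based position i - 1, always in \[0, 1\].
#' @export
occupancy_field <- function(model, annotation, contig, time = NULL) {
  L <- contig_length(annotation, contig)
  if (!is.null(time) && time < 0) stop("time must be >= 0")
  x <- seq_len(L) - 1
  occ <- rep(model$background, L)
  sites <- model$recruitment[model$recruitment$contig == contig, , drop = FALSE]
  bnd <- contig_features(annotation, contig, "boundary")
  bmid <- if (nrow(bnd)) (bnd$start + bnd$end - 1) / 2 else numeric(0)
  bmid <- sort(bmid)
  for (i in seq_len(nrow(sites))) {
    s <- sites$start[i]; e <- sites$end[i]
    d <- pmax(0, pmax(s - x, x - (e - 1)))
    term <- sites$peak[i] * exp(-d / model$lambda)
    if (length(bmid) && model$boundary_attenuation < 1) {
      # k(x) = number of boundary midpoints strictly between the site edge and x
      n_le <- findInterval(x, bmid)        # boundaries at positions <= x
      n_lt_s <- sum(bmid < s)
      n_le_e <- sum(bmid <= (e - 1))
      k <- integer(L)
      left <- x < s
      right <- x > (e - 1)
      k[left] <- n_lt_s - n_le[left]       # midpoints in (x, s)
      k[right] <- n_le[right] - n_le_e     # midpoints in (e-1, x]
      term <- term * model$boundary_attenuation ^ pmax(0L, k)
    }
    if (!is.null(time)) {
      hr <- model$halftime_recruitment
      if (!is.null(names(hr)) && sites$kind[i] %in% names(hr))
        hr <- hr[[sites$kind[i]]]
      else hr <- hr[[1]]
      fac <- ifelse(d == 0, time_factor(time, hr),
                    time_factor(time, model$halftime_spread))
      term <- term * fac
    }
    occ <- occ + term
  }
  pmin(pmax(occ, 0), 1)
}

#' Per-position accessibility field
#'
#' Positions within `core_halfwidth` bp of a nucleosome dyad get
#' `core_accessibility`; all others get `linker_accessibility`. With dyads
#' on the canonical 165 bp repeat this yields 147 bp occluded cores
#' separated by accessible linkers, the source of the periodic methylation
#' pattern seen on single molecules.
#'
#' @inheritParams occupancy_field
#' @param annotation a [genome_annotation()].
#' @return numeric vector of per-position accessibility in (0, 1\].
#' @export
accessibility_field <- function(annotation, model, contig) {
  L <- contig_length(annotation, contig)
  dy <- contig_dyads(annotation, contig)
  acc <- rep(model$linker_accessibility, L)
  if (length(dy)) {
    x <- seq_len(L) - 1
    # distance to nearest dyad
    idx <- findInterval(x, dy)
    d_lo <- ifelse(idx >= 1, x - dy[pmax(idx, 1)], Inf)
    d_hi <- ifelse(idx < length(dy), dy[pmin(idx + 1, length(dy))] - x, Inf)
    dmin <- pmin(d_lo, d_hi)
    acc[dmin <= model$core_halfwidth] <- model$core_accessibility
  }
  acc
}
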