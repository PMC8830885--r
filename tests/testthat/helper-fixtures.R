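# Shared simulation fixtures. All scenario parameters here are the study
# conditions the simulations are run under; tests consume them as given.

# telomere-like contig: X-element anchor, boundary element 5 kb from the
# anchor edge, distal control region; strong-spreading occupancy so the
# boundary element (not the decay length) limits the spread
tel_annotation <- function(length = 16000) {
  ct <- data.frame(name = "tel", length = length)
  feats <- rbind(
    data.frame(contig = "tel", start = 1000, end = 1600, strand = ".",
               kind = "x_element", name = "X"),
    data.frame(contig = "tel", start = 6600, end = 6700, strand = ".",
               kind = "boundary", name = "BND"),
    data.frame(contig = "tel", start = 12000, end = 15500, strand = ".",
               kind = "control_region", name = "CTRL"))
  feats <- feats[feats$end <= length, , drop = FALSE]  # short test contigs
  genome_annotation(ct, feats,
                    dyads = data.frame(contig = "tel",
                                       pos = seq(82, length - 83, by = 165)))
}

tel_model <- function(annotation, peak = 0.9, lambda = 4000,
                      attenuation = 0, ...) {
  sites <- contig_features(annotation, "tel", "x_element")
  occupancy_model(data.frame(contig = sites$contig, start = sites$start,
                             end = sites$end, kind = sites$kind, peak = peak),
                  lambda = lambda, boundary_attenuation = attenuation, ...)
}

no_recruitment_model <- function(...) {
  occupancy_model(data.frame(contig = character(0), start = numeric(0),
                             end = numeric(0), kind = character(0),
                             peak = numeric(0)), ...)
}

# locus-scale contig: silencer-flanked HML-like locus plus an X-element
# anchor and control region; used for the spreading-deficient contrast.
# Anchors sit >= 4 kb from the contig ends so read-end coverage decay does
# not starve the anchor intervals themselves; the contrast annotation
# carries no promoter so anchor-interval methylation is recruitment-only.
locus_annotation <- function(length = 30000) {
  ct <- data.frame(name = "loc", length = length)
  feats <- rbind(
    data.frame(contig = "loc", start = 3000, end = 3600, strand = ".",
               kind = "x_element", name = "X"),
    data.frame(contig = "loc", start = 14000, end = 14500, strand = ".",
               kind = "silencer", name = "E"),
    data.frame(contig = "loc", start = 17800, end = 18300, strand = ".",
               kind = "silencer", name = "I"),
    data.frame(contig = "loc", start = 24000, end = 29000, strand = ".",
               kind = "control_region", name = "CTRL"))
  genome_annotation(ct, feats,
                    dyads = data.frame(contig = "loc",
                                       pos = seq(82, length - 83, by = 165)))
}

# establishment time-course contig: two silencers 10 kb apart so interior
# positions are genuinely spread-limited, plus a distal control region
onset_annotation <- function(length = 26000) {
  ct <- data.frame(name = "on", length = length)
  feats <- rbind(
    data.frame(contig = "on", start = 6000, end = 6500, strand = ".",
               kind = "silencer", name = "E"),
    data.frame(contig = "on", start = 16500, end = 17000, strand = ".",
               kind = "silencer", name = "I"),
    data.frame(contig = "on", start = 20000, end = 25000, strand = ".",
               kind = "control_region", name = "CTRL"))
  genome_annotation(ct, feats,
                    dyads = data.frame(contig = "on",
                                       pos = seq(82, length - 83, by = 165)))
}

locus_model <- function(annotation, lambda = 800, peak = 0.9,
                        promoter_peak = 0.6, ...) {
  occupancy_model(default_recruitment(annotation, peak = peak,
                                      promoter_peak = promoter_peak),
                  lambda = lambda, boundary_attenuation = 0.1, ...)
}

# simulate -> binarize -> aggregate(merged) -> 10x filter -> smooth
sim_smoothed_track <- function(annotation, model, seed, coverage = 30,
                               mean_read_length = 8000, enp = 100,
                               region = NULL, emission = emission_model()) {
  sampler <- read_sampler(mean_read_length = mean_read_length,
                          target_coverage = coverage, seed = seed)
  calls <- binarize_calls(simulate_reads(annotation, model, emission, sampler))
  tr <- filter_coverage(aggregate_fraction(calls, region = region,
                                           merge_strands = TRUE), 10)
  smooth_track(tr, enp_target = enp)
}

# background level from a no-recruitment control simulation
control_background <- function(annotation, seed, coverage = 30,
                               mean_read_length = 8000, k = 2,
                               background = 0.02) {
  ctrl <- no_recruitment_model(background = background)
  tr <- sim_smoothed_track(annotation, ctrl, seed = seed, coverage = coverage,
                           mean_read_length = mean_read_length)
  estimate_background(tr, k = k)
}

# synthetic aggregate track from explicit per-position counts
count_track <- function(pos, coverage, n_meth, contig = "c", strand = ".") {
  df <- data.frame(contig = contig, pos = as.integer(pos), strand = strand,
                   coverage = as.integer(coverage),
                   n_meth = as.integer(n_meth),
                   percent = 100 * n_meth / coverage,
                   stringsAsFactors = FALSE)
  class(df) <- c("aggregate_track", "data.frame")
  df
}

random_perread_calls <- function(n, seed) {
  set.seed(seed)
  data.frame(read_id = sprintf("r%04d", sample(200, n, replace = TRUE)),
             contig = sample(c("chrI", "chrII"), n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             pos = sample(0:99999, n, replace = TRUE),
             prob = runif(n),
             stringsAsFactors = FALSE)
}
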