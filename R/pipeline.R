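#' Run the footprinting pipeline from a single config
#'
#' Orchestrates simulate -> binarize -> aggregate -> filter -> smooth ->
#' background -> boundary calls as one reproducible run. The config is a
#' YAML/JSON document (or an equivalent R list); every stage parameter and
#' seed is recorded in a JSON run manifest together with md5 hashes of all
#' output files, so re-running the same config reproduces every output
#' byte-identically.
#'
#' Config schema (all sections optional except `out_dir`):
#' \describe{
#'   \item{seed}{integer; top-level seed for all randomness.}
#'   \item{simulate}{`coverage`, `mean_read_length`, `dispersion`, and
#'     `model` overrides (`lambda`, `boundary_attenuation`, `background`,
#'     `rate`, `peak`, `promoter_peak`, `linker_accessibility`,
#'     `core_accessibility`).}
#'   \item{input}{`perread` path to an existing per-read text file
#'     (alternative to `simulate`).}
#'   \item{analysis}{`threshold` (0.8), `min_coverage` (10), `enp_target`
#'     (100), `merge_strands` (true), `background_k` (2), `run_length`
#'     (300).}
#'   \item{windows}{list of `{contig, start, end, anchor, direction}`
#'     entries; `anchor` names an annotation feature.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config path to a YAML/JSON config file, or a list.
#' @param out_dir optional override of the config's output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out <- out_dir %||% cfg$out_dir
  if (is.null(out)) stop("config must give out_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  an <- cfg$analysis %||% list()
  threshold <- an$threshold %||% 0.8
  min_cov <- an$min_coverage %||% 10
  enp <- an$enp_target %||% 100
  merge <- isTRUE(an$merge_strands %||% TRUE)
  bg_k <- an$background_k %||% 2
  run_len <- an$run_length %||% 300

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    r
  }

  annotation <- stage("annotation", toy_genome())
  files <- character(0)

  if (!is.null(cfg$input$perread)) {
    calls <- stage("load", read_perread_text(cfg$input$perread))
    model <- NULL
  } else {
    sim <- cfg$simulate %||% list()
    mo <- sim$model %||% list()
    model <- occupancy_model(
      recruitment = default_recruitment(annotation,
                                        peak = mo$peak %||% 0.9,
                                        promoter_peak = mo$promoter_peak %||% 0.6),
      lambda = mo$lambda %||% 800,
      boundary_attenuation = mo$boundary_attenuation %||% 0.1,
      background = mo$background %||% 0.02,
      rate = mo$rate %||% 0.8,
      linker_accessibility = mo$linker_accessibility %||% 1,
      core_accessibility = mo$core_accessibility %||% 0.2)
    emission <- emission_model(tpr = sim$tpr %||% 0.9, fpr = sim$fpr %||% 0.01,
                               threshold = threshold)
    sampler <- read_sampler(
      mean_read_length = sim$mean_read_length %||% 15000,
      dispersion = sim$dispersion %||% 0.25,
      target_coverage = sim$coverage %||% 20,
      seed = seed)
    calls <- stage("simulate",
                   simulate_reads(annotation, model, emission, sampler))
    p <- file.path(out, "perread_calls.txt")
    stage("write-perread", write_perread_text(calls, p))
    files <- c(files, p)
    files <- c(files, stage("truth", write_truth_tracks(annotation, model,
                                                        file.path(out, "truth"))))
  }

  calls <- stage("binarize", binarize_calls(calls, threshold))
  track <- stage("aggregate",
                 aggregate_fraction(calls, merge_strands = merge))
  track <- stage("filter", filter_coverage(track, min_cov))
  p <- file.path(out, "aggregate.bed")
  write_aggregate_bed(track, p)
  files <- c(files, p)

  # smoothing is applied per analysis window (as in the figures), never to
  # the whole contig at once: one enp target describes one window's span
  subset_track <- function(w)
    track[track$contig == w$contig & track$pos >= w$start &
            track$pos < w$end, , drop = FALSE]
  ctrl <- contig_features(annotation, annotation$contigs$name[1],
                          "control_region")
  ctrl_w <- list(contig = ctrl$contig[1], start = ctrl$start[1],
                 end = ctrl$end[1])
  ctrl_sm <- stage("background-smooth",
                   smooth_track(subset_track(ctrl_w), enp_target = enp))
  bg <- stage("background", estimate_background(ctrl_sm, k = bg_k))

  windows <- cfg$windows %||% default_windows(annotation)
  smoothed_parts <- list(ctrl_sm)
  boundaries <- lapply(windows, function(w) {
    feat <- annotation$features[annotation$features$name == w$anchor, , drop = FALSE]
    if (nrow(feat) == 0) stop("unknown anchor feature: ", w$anchor)
    sub <- smooth_track(subset_track(w), enp_target = enp)
    smoothed_parts[[length(smoothed_parts) + 1]] <<- sub
    b <- call_boundary(sub, feat, w$direction, bg, run_length = run_len)
    data.frame(anchor = w$anchor, contig = b$contig, direction = b$direction,
               boundary_position = b$boundary_position,
               spread_extent = b$spread_extent, status = b$status,
               background_level = b$background_level,
               stringsAsFactors = FALSE)
  })
  sm_all <- do.call(rbind, smoothed_parts)
  sm_all <- sm_all[order(sm_all$contig, sm_all$pos), , drop = FALSE]
  sm_all <- sm_all[!duplicated(paste(sm_all$contig, sm_all$pos)), , drop = FALSE]
  p <- file.path(out, "smoothed.bedgraph")
  write_bedgraph(data.frame(contig = sm_all$contig, start = sm_all$pos,
                            end = sm_all$pos + 1L, value = sm_all$smoothed), p)
  files <- c(files, p)
  btab <- do.call(rbind, boundaries)
  p <- file.path(out, "boundaries.tsv")
  utils::write.table(btab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)

  manifest <- list(
    package = "sirspread",
    seed = seed,
    parameters = list(threshold = threshold, min_coverage = min_cov,
                      enp_target = enp, merge_strands = merge,
                      background_k = bg_k, run_length = run_len),
    config = cfg[setdiff(names(cfg), "out_dir")],
    background = list(level = bg$background, mean = bg$mean, sd = bg$sd,
                      n = bg$n),
    n_records = nrow(calls),
    outputs = lapply(sort(files), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  message("wrote ", length(files) + 1, " files to ", out)
  invisible(manifest)
}

default_windows <- function(annotation) {
  list(
    list(contig = "chrS", start = 1200, end = 12000, anchor = "TEL_L_X",
         direction = "+"),
    list(contig = "chrS", start = 12000, end = 28000, anchor = "HML_I",
         direction = "+"),
    list(contig = "chrS", start = 33000, end = 50000, anchor = "HMR_I",
         direction = "+"),
    list(contig = "chrS", start = 50000, end = 58800, anchor = "TEL_R_X",
         direction = "-"))
}

#' Path of the shipped demo pipeline config
#' @return file path of the demo YAML config.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "sirspread",
              mustWork = TRUE)
}
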