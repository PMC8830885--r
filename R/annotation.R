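#' Genome annotation for footprinting analysis and simulation
#'
#' Bundles contigs, interval features (silencers, promoters, telomeric TG
#' repeats and X elements, boundary elements, gene bodies, control regions),
#' nucleosome dyad positions and per-strand adenine masks. All coordinates
#' are 0-based half-open; strand-specific adenine positions are kept
#' distinct because m6A can occur on the A of either strand.
#'
#' @param contigs data.frame with columns `name`, `length` (bp).
#' @param features data.frame with columns `contig`, `start`, `end`,
#'   `strand`, `kind`, `name`. `kind` must be one of the recognised feature
#'   kinds (see [feature_kinds()]).
#' @param dyads optional data.frame with columns `contig`, `pos` giving
#'   nucleosome dyad centres; must be sorted with pairwise distance
#'   >= 100 bp within a contig.
#' @param adenine_density probability in (0, 1] that any given position
#'   carries an adenine on a given strand. Budding yeast is AT-rich
#'   (~62% AT), so ~0.3 of positions on each strand are adenines.
#' @param mask_seed integer seed used (deterministically) to draw the
#'   per-strand adenine masks.
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(contigs, features, dyads = NULL,
                              adenine_density = 0.3, mask_seed = 20L) {
  stopifnot(is.data.frame(contigs), all(c("name", "length") %in% names(contigs)))
  contigs$name <- as.character(contigs$name)
  stopifnot(all(contigs$length >= 1))
  if (adenine_density <= 0 || adenine_density > 1)
    stop("adenine_density must be in (0, 1]")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "kind")
  if (!all(need %in% names(features)))
    stop("features must have columns contig, start, end, kind")
  if (is.null(features$strand)) features$strand <- "."
  if (is.null(features$name)) features$name <- features$kind
  bad <- !(features$kind %in% feature_kinds())
  if (any(bad))
    stop("unknown feature kind(s): ", paste(unique(features$kind[bad]), collapse = ", "))
  len <- contigs$length[match(features$contig, contigs$name)]
  if (anyNA(len)) stop("feature on unknown contig")
  if (any(features$start < 0 | features$end > len | features$start >= features$end))
    stop("feature intervals must be half-open, 0-based and within contig bounds")
  features <- features[order(features$contig, features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL

  if (!is.null(dyads)) {
    dyads <- as.data.frame(dyads)
    stopifnot(all(c("contig", "pos") %in% names(dyads)))
    for (ct in unique(dyads$contig)) {
      p <- dyads$pos[dyads$contig == ct]
      if (is.unsorted(p)) stop("dyads must be sorted within each contig")
      if (length(p) > 1 && min(diff(p)) < 100)
        stop("dyad pairwise distance must be >= 100 bp")
    }
  }

  # deterministic per-strand adenine masks, one RNG substream per contig/strand
  masks <- lapply(seq_len(nrow(contigs)), function(i) {
    L <- contigs$length[i]
    lapply(stats::setNames(c("+", "-"), c("+", "-")), function(s) {
      with_seed(derive_seed(mask_seed, paste0("mask:", contigs$name[i], s)),
                stats::runif(L) < adenine_density)
    })
  })
  names(masks) <- contigs$name

  structure(list(contigs = contigs, features = features, dyads = dyads,
                 adenine_density = adenine_density, masks = masks),
            class = "genome_annotation")
}

#' Recognised feature kinds
#' @return character vector of feature kinds used in annotations.
#' @export
feature_kinds <- function() {
  c("silencer", "promoter", "tg_repeat", "x_element", "boundary",
    "gene_body", "control_region")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$contigs), "contig(s),",
      nrow(x$features), "features,",
      if (is.null(x$dyads)) 0L else nrow(x$dyads), "dyads\n")
  invisible(x)
}

#' Accessors for annotation components
#'
#' @param annotation a [genome_annotation()].
#' @param contig contig name.
#' @param kind optional feature kind filter.
#' @return `contig_length`: integer length; `contig_features`: feature
#'   data.frame; `contig_dyads`: sorted dyad positions.
#' @export
contig_length <- function(annotation, contig) {
  i <- match(contig, annotation$contigs$name)
  if (is.na(i)) stop("unknown contig: ", contig)
  annotation$contigs$length[i]
}

#' @rdname contig_length
#' @export
contig_features <- function(annotation, contig, kind = NULL) {
  f <- annotation$features[annotation$features$contig == contig, , drop = FALSE]
  if (!is.null(kind)) f <- f[f$kind %in% kind, , drop = FALSE]
  f
}

#' @rdname contig_length
#' @export
contig_dyads <- function(annotation, contig) {
  if (is.null(annotation$dyads)) return(numeric(0))
  annotation$dyads$pos[annotation$dyads$contig == contig]
}

#' Desk-scale yeast-like toy genome
#'
#' One 60 kb contig carrying the locus structure the assay maps: an HML-like
#' locus (two silencers 3.3 kb apart flanking a promoter), an HMR-like locus
#' (silencers 2.4 kb apart), two telomere-like ends (TG repeat + X element
#' with a centromere-proximal boundary element), a control region for
#' background methylation, and regularly spaced nucleosome dyads.
#'
#' @param length contig length in bp.
#' @param nucleosome_repeat dyad spacing in bp (default 165, the budding
#'   yeast nucleosome repeat length).
#' @param adenine_density per-strand adenine density.
#' @param mask_seed seed for the adenine masks.
#' @return a [genome_annotation()].
#' @export
toy_genome <- function(length = 60000L, nucleosome_repeat = 165L,
                       adenine_density = 0.3, mask_seed = 20L) {
  ct <- data.frame(name = "chrS", length = as.integer(length))
  f <- function(start, end, kind, name)
    data.frame(contig = "chrS", start = start, end = end, strand = ".",
               kind = kind, name = name, stringsAsFactors = FALSE)
  features <- rbind(
    f(0L,     300L,   "tg_repeat",      "TEL_L_TG"),
    f(500L,   1200L,  "x_element",      "TEL_L_X"),
    f(1700L,  1800L,  "boundary",       "TEL_L_BND"),
    f(4000L,  7000L,  "gene_body",      "GENE_A"),
    f(14000L, 14500L, "silencer",       "HML_E"),
    f(15700L, 16000L, "promoter",       "HML_P"),
    f(17800L, 18300L, "silencer",       "HML_I"),
    f(21000L, 24000L, "gene_body",      "GENE_B"),
    f(28000L, 33000L, "control_region", "CTRL"),
    f(40000L, 40500L, "silencer",       "HMR_E"),
    f(41300L, 41600L, "promoter",       "HMR_P"),
    f(42900L, 43400L, "silencer",       "HMR_I"),
    f(50000L, 54000L, "gene_body",      "GENE_C"),
    f(58200L, 58300L, "boundary",       "TEL_R_BND"),
    f(58800L, 59500L, "x_element",      "TEL_R_X"),
    f(59700L, length, "tg_repeat",      "TEL_R_TG"))
  dy <- seq(82L, length - 83L, by = as.integer(nucleosome_repeat))
  genome_annotation(ct, features,
                    dyads = data.frame(contig = "chrS", pos = dy),
                    adenine_density = adenine_density, mask_seed = mask_seed)
}

# -- deterministic seed substreams ------------------------------------------

#' Derive a reproducible sub-seed from a base seed and a purpose label
#'
#' All randomness in the package flows from one top-level seed; independent
#' substreams (adenine masks, read placement, each time point of a time
#' course) get seeds hashed from (seed, label) so that adding a stage never
#' perturbs another stage's draws.
#'
#' @param seed integer base seed.
#' @param label character purpose label.
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% 2147483647
  s <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483646 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
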