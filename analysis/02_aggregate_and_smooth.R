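#!/usr/bin/env Rscript
# Binarize (> 0.8), aggregate to percent-methylated per position, filter to
# >= 10x coverage and smooth (coverage-weighted loess, enp 100 per window).
# Writes single-base methylation BED and smoothed bedGraph per genotype plus
# a genotype overlay table for the HML-like locus window.

suppressPackageStartupMessages(library(sirspread))

simdir <- "results/sim"
out <- "results/tracks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
genotypes <- c("control", "wildtype", "nospread", "overexpressed")

windows <- list(tel_l = c(1200, 12000), hml = c(12000, 28000),
                ctrl = c(28000, 33000), hmr = c(33000, 50000),
                tel_r = c(50000, 58800))

tracks <- list()
for (g in genotypes) {
  calls <- binarize_calls(
    read_perread_text(file.path(simdir, paste0(g, "_perread.txt"))), 0.8)
  tr <- filter_coverage(aggregate_fraction(calls, merge_strands = TRUE), 10)
  write_aggregate_bed(tr, file.path(out, paste0(g, "_aggregate.bed")))
  sm <- do.call(rbind, lapply(windows, function(w) {
    smooth_track(tr[tr$pos >= w[1] & tr$pos < w[2], ], enp_target = 100)
  }))
  write_bedgraph(data.frame(contig = sm$contig, start = sm$pos,
                            end = sm$pos + 1L, value = sm$smoothed),
                 file.path(out, paste0(g, "_smoothed.bedgraph")))
  tracks[[g]] <- sm
  message(sprintf("%-13s %6d positions retained at >= 10x, mean %% = %.2f",
                  g, nrow(tr), mean(tr$percent)))
}

ov <- genotype_overlay(tracks, region = c("chrS", 12000, 28000),
                       value = "smoothed")
write.table(ov, file.path(out, "hml_overlay.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("done: aggregate tracks and HML overlay in ", out)
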