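#!/usr/bin/env Rscript
# Nucleosome-repeat periodicity of the methylation signal across the
# silenced loci and the linker/core methylation enrichment of the
# wild-type sample.

suppressPackageStartupMessages(library(sirspread))

out <- "results/inference"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
ann <- toy_genome()

calls <- binarize_calls(
  read_perread_text("results/sim/wildtype_perread.txt"), 0.8)
tr <- filter_coverage(aggregate_fraction(calls, merge_strands = TRUE), 10)

res <- list()
for (w in list(c("hml", 13000, 19000), c("hmr", 39000, 45000))) {
  p <- estimate_periodicity(tr, window = c("chrS", as.numeric(w[2]),
                                           as.numeric(w[3])))
  print(p)
  res[[w[1]]] <- list(repeat_length = p$repeat_length,
                      peak_strength = p$peak_strength,
                      significant = p$significant, band = p$band)
}

# linker enrichment restricted to the silenced loci, where occupancy is high
loci <- calls[(calls$pos >= 13000 & calls$pos < 19000) |
                (calls$pos >= 39000 & calls$pos < 45000), ]
le <- linker_enrichment(loci, contig_dyads(ann, "chrS"))
print(le)
res$linker <- list(ratio = le$ratio, ci = le$ci,
                   linker_rate = le$linker_rate, core_rate = le$core_rate)

jsonlite::write_json(res, file.path(out, "periodicity_linkers.json"),
                     auto_unbox = TRUE, digits = NA)
message("done: periodicity and linker enrichment in ", out)
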