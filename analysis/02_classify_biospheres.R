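#!/usr/bin/env Rscript
# Stage 2: partition OTUs into abundant / intermediate / rare biospheres.
#
# Abundant: relative abundance >= 0.1% in more than half the samples AND
# occurring in more than 80% of samples. Rare: < 0.1% everywhere. The rare
# tail should dominate the OTU count in both presets (skewed SAD).

suppressPackageStartupMessages(library(commtrait))

for (preset in c("sediment", "ocean")) {
  dir <- file.path("results", "data", preset)
  tab <- read_otu_table(file.path(dir, "otu.tsv"))
  labels <- classify_biospheres(tab)
  out <- file.path("results", preset)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(labels),
                     file.path(out, "biosphere_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- biosphere_summary(labels, tab)
  cat(sprintf(
    "%s: %.1f%% abundant, %.1f%% intermediate, %.1f%% rare (of %d OTUs)\n",
    preset, sm$percent[["abundant"]], sm$percent[["intermediate"]],
    sm$percent[["rare"]], n_otus(tab)))
  summed <- rowMeans(sm$rel_abund_by_sample)
  cat(sprintf("  mean share of reads: abundant %.2f, intermediate %.2f, rare %.2f\n",
              summed[["abundant"]], summed[["intermediate"]], summed[["rare"]]))
}
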