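#!/usr/bin/env Rscript
# Statistical roll-up: Bayes-factor ANOVAs over the decoding tables written
# by 02_decoding.R (attention x target frequency x time-on-task) and a
# shuffled-null Bayes factor for the grand-average distance decoding.
# Run after 02_decoding.R.
#
# Writes: results/analysis/bf_decoding.csv

suppressMessages(library(momdecode))

out_dir <- "results/analysis"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
dist_file <- "results/run/distance_decoding.csv"
if (!file.exists(dist_file)) stop("run analysis/02_decoding.R first")
dist_tab <- read.csv(dist_file)

# mean accuracy per subject x condition cell
parts <- strsplit(dist_tab$cell, ".", fixed = TRUE)
dist_tab$attention <- sapply(parts, `[`, 1)
dist_tab$frequency <- sapply(parts, `[`, 2)
dist_tab$half <- sapply(parts, `[`, 3)
cellmean <- aggregate(accuracy ~ subject + attention + frequency + half,
                      dist_tab, mean)
names(cellmean)[names(cellmean) == "accuracy"] <- "value"

rows <- list()
for (eff in c("attention", "frequency", "half",
              "attention:frequency", "frequency:half", "attention:half",
              "attention:frequency:half")) {
  bf <- bf_anova_effect(cellmean, eff, seed = 99L)
  rows[[eff]] <- data.frame(effect = eff, location = "mean_over_distances",
                            bf10 = bf$bf10, category = bf$category)
  message(sprintf("%-28s BF10 = %10.3g  (%s)", eff, bf$bf10, bf$category))
}
write.csv(do.call(rbind, rows), file.path(out_dir, "bf_decoding.csv"),
          row.names = FALSE)
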