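#!/usr/bin/env Rscript
# Pool-based normalization (log2 CPM with pseudocount), trimming of
# unreliable cells, and the screen QC: Pearson correlations of normalized
# values within and between replicates. Within-replicate day14-vs-day0
# correlations should be high (no widespread Dox-independent dropout);
# between-replicate correlations are lower by design because replicates are
# independent transductions.

source("analysis/00_common.R")

lib <- read_library(path_of("library.tsv"))

qc_all <- NULL
for (id in SCREENS) {
  sheet <- read_sample_sheet(path_of(id, "_samples.tsv"))
  counts <- read_count_matrix(path_of(id, "_counts.tsv"), lib)
  norm <- normalize_pool(counts, lib, sheet, pseudocount = 1, scale = 1e6)
  norm <- trim_extremes(norm, counts, lib, sheet,
                        min_day0_count = 30, ratio_cap = 8)
  qc <- qc_correlations(norm, sheet)
  qc$screen <- id
  qc_all <- rbind(qc_all, qc)
  message(id, ": retained ", sum(norm$mask), " of ",
          sum(!is.na(norm$values)), " in-pool cells after trimming")
}
write.table(qc_all, path_of("qc_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(qc_all[, c("screen", "pair", "replicate", "n", "r")])
message("within-replicate Pearson R range: ",
        paste(round(range(qc_all$r[qc_all$pair == "Day14_vs_Day0"]), 3),
              collapse = " - "))
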