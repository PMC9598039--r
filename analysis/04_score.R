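#!/usr/bin/env Rscript
# Effect-size scoring: per-replicate FGR/BGR, pooled robust background
# (medianBGR, MAD), SSMD* per replicate, AvSSMD* per construct and
# AvSSMD*/protease per gene. Also checks the internal controls against the
# +/-1 SD_AvSSMD* band: shRpa3 depletion controls should fall below -1 SD,
# shRenilla/shLuciferase stability controls inside the band.

source("analysis/00_common.R")

lib <- read_library(path_of("library.tsv"))

ctrl_all <- stats_all <- NULL
for (id in SCREENS) {
  sheet <- read_sample_sheet(path_of(id, "_samples.tsv"))
  counts <- read_count_matrix(path_of(id, "_counts.tsv"), lib)
  norm <- trim_extremes(normalize_pool(counts, lib, sheet), counts, lib, sheet,
                        min_day0_count = 30, ratio_cap = 8)
  res <- score_constructs(norm, lib, sheet, convention = "divide",
                          include_controls = TRUE)
  write.table(res$scores, path_of(id, "_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gene_scores <- aggregate_genes(res$scores)
  write.table(gene_scores, path_of(id, "_gene_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ctrl <- qc_controls(res$scores, res$stats$sd_avssmd, lib)
  ctrl$screen <- id
  ctrl_all <- rbind(ctrl_all, ctrl)
  stats_all <- rbind(stats_all, data.frame(
    screen = id, median_bgr = res$stats$median_bgr,
    mad_bgr = res$stats$mad_bgr, sd_avssmd = res$stats$sd_avssmd,
    n_constructs_scored = res$stats$n_constructs_scored,
    n_genes_scored = nrow(gene_scores)))
  message(sprintf("%s: SD_AvSSMD* = %.3f over %d scored constructs", id,
                  res$stats$sd_avssmd, res$stats$n_constructs_scored))
}
write.table(stats_all, path_of("screen_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ctrl_all, path_of("qc_controls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(ctrl_all)
message("note: the leaky normoxia screen is expected to show the weakest ",
        "depletion-control separation")
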