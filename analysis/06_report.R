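#!/usr/bin/env Rscript
# Final accounting: per screen, the number of genes scored, first-filter
# hits, expression-filtered hits, and how the hits recover the planted
# ground truth (sensitivity among planted depletion genes, false calls among
# neutral genes).

source("analysis/00_common.R")

summary_tab <- NULL
for (id in SCREENS) {
  gene_scores <- read.delim(path_of(id, "_gene_scores.tsv"))
  tab <- read.delim(path_of(id, "_dual_flashlight.tsv"))
  filtered <- read.delim(path_of(id, "_hits_expressed.tsv"))
  truth <- read.delim(path_of(id, "_truth_genes.tsv"))

  called <- tab$gene[tab$hit]
  planted <- truth$gene[truth$label == "depletion"]
  neutral <- truth$gene[truth$label == "neutral"]
  summary_tab <- rbind(summary_tab, data.frame(
    screen = id,
    genes_scored = nrow(gene_scores),
    first_filter_hits = length(called),
    second_filter_hits = nrow(filtered),
    planted_depletion_genes = length(planted),
    sensitivity = round(mean(planted %in% called), 3),
    neutral_call_rate = round(mean(neutral %in% called), 4)))
}
venn <- read.delim(path_of("venn_regions.tsv"))
write.table(summary_tab, path_of("summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(summary_tab, row.names = FALSE)
message("cross-screen union: ", sum(venn$n_genes), " genes over ",
        nrow(venn), " Venn regions")
message("full tables under ", OUT)
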