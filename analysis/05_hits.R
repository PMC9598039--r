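#!/usr/bin/env Rscript
# Hit selection. First filter: a gene needs >= 2 constructs with |AvSSMD*|
# strictly outside the screen's +/-1 SD_AvSSMD* band. Second filter: the
# target must be sufficiently expressed in every cell line (synthetic
# expression tables stand in for the study's RNA-seq FPKM > 0.5 and
# microarray log2 > 6.2 thresholds). Cross-screen accounting then tabulates
# the Venn regions, classifies genes depletion/mixed and drops
# enrichment-only genes from the final heat-map table.

source("analysis/00_common.R")

lib <- read_library(path_of("library.tsv"))
genes <- sort(unique(lib$target_gene[lib$role == "target"]))

# synthetic expression tables (one RNA-seq-like, one microarray-like);
# a fixed slice of genes falls below threshold in each platform
set.seed(SEED)
expr_rnaseq <- data.frame(
  gene = genes,
  value = round(stats::rlnorm(length(genes), meanlog = 2, sdlog = 1.5), 3))
expr_rnaseq$value[seq(5, length(genes), by = 23)] <- 0.1   # not expressed
expr_array <- data.frame(
  gene = genes,
  value = round(stats::rnorm(length(genes), mean = 9, sd = 1.5), 3))
expr_array$value[seq(11, length(genes), by = 29)] <- 5.0   # not expressed
write.table(expr_rnaseq, path_of("expression_rnaseq_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(expr_array, path_of("expression_microarray_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
expression <- list(rnaseq = expr_rnaseq, microarray = expr_array)
thresholds <- c(rnaseq = 0.5, microarray = 6.2)

stats_tab <- read.delim(path_of("screen_stats.tsv"))
hit_tables <- list()
for (id in SCREENS) {
  scores <- read.delim(path_of(id, "_scores.tsv"))
  gene_scores <- read.delim(path_of(id, "_gene_scores.tsv"))
  sd_av <- stats_tab$sd_avssmd[stats_tab$screen == id]
  tab <- dual_flashlight_table(gene_scores, scores, sd = sd_av,
                               min_frequency = 2)
  write.table(tab, path_of(id, "_dual_flashlight.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  filtered <- expression_filter(tab[tab$hit, ], expression, thresholds)
  write.table(filtered, path_of(id, "_hits_expressed.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d first-filter hits -> %d after expression filter",
                  id, sum(tab$hit), nrow(filtered)))
  hit_tables[[id]] <- tab
}

cs <- cross_screen(hit_tables)
write.table(cs$regions, path_of("venn_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cs$classes, path_of("cross_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
hm <- heatmap_table(cs, hit_tables)
write.table(hm, path_of("heatmap_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(cs)
mixed <- cs$classes$gene[cs$classes$class == "mixed"]
message("union of first-filter hits across screens: ", cs$n_union,
        "; mixed hits: ", if (length(mixed)) paste(mixed, collapse = ", ")
        else "none")
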