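# Shared setup for the analysis scripts: study-scale parameters and paths.
# The workflow emulates the published study design at a computationally
# lighter scale: three competitive growth screens (one epithelial-like line,
# one stem-cell-like line under hypoxia and after transfer to normoxia) over
# a shared construct library, two replicates each.

library(mirescreen)

OUT <- "results/analysis"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

SEED <- 20260927L

# library and sequencing scale: 300 genes x 4-7 constructs in 4 pools,
# 1,000x representation, 1e6 reads per sample (the study's per-sample depth)
study_config <- function(leakiness = 0, seed = SEED) {
  sim_config(n_genes = 300, guides_min = 4, guides_max = 7, n_pools = 4,
             representation = 1000, depth = 1e6, leakiness = leakiness,
             seed = seed)
}

# planted biology: a shared essential core plus condition-specific
# dependencies, one mixed gene (depleted under hypoxia, enriched under
# normoxia, as observed for some deubiquitinases in the study)
plant_for_screen <- function(library, screen) {
  genes <- sort(unique(library$target_gene[library$role == "target"]))
  core <- genes[1:12]
  only_a <- genes[13:30]
  only_b <- genes[31:48]
  only_c <- genes[49:54]
  mixed <- genes[55]
  e <- plant_gene_effects(library, genes = character(0), control_effect = -6)
  set_eff <- function(e, gs, val) {
    e[library$target_gene %in% gs] <- val
    e
  }
  e <- switch(screen,
    PyB6 = set_eff(set_eff(e, core, -4), only_a, -3),
    PyMG_hypoxia = set_eff(set_eff(set_eff(e, core, -4), only_b, -3),
                           mixed, -3),
    PyMG_normoxia = set_eff(set_eff(set_eff(e, core, -3), only_c, -2),
                            mixed, +3)
  )
  e
}

SCREENS <- c("PyB6", "PyMG_hypoxia", "PyMG_normoxia")
# the normoxia screen showed signs of Dox-independent vector activity
SCREEN_LEAKINESS <- c(PyB6 = 0, PyMG_hypoxia = 0, PyMG_normoxia = 0.3)

path_of <- function(...) file.path(OUT, paste0(...))
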