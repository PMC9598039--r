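#' Plant fitness effects on library constructs
#'
#' Builds the per-construct effect map for [simulate_counts()]. Effects are
#' total log2 fold-changes of clone abundance over the growth window under
#' fully induced knockdown. All constructs of a planted gene receive the
#' gene's effect; depletion controls receive a strong negative effect
#' (Rpa3 knockdown kills proliferating cells), stability controls stay at 0.
#'
#' @param library a library table from [build_library()].
#' @param genes character vector of target genes to plant, or a fraction in
#'   `(0, 1)` of genes to draw at random (requires a seeded RNG for
#'   reproducibility).
#' @param effect log2 fold-change over the growth window for planted genes.
#' @param control_effect effect for depletion controls (default -6,
#'   an shRpa3-like near-complete dropout).
#' @return named numeric vector of effects, one entry per construct.
#' @export
plant_gene_effects <- function(library, genes = character(0), effect = -4,
                               control_effect = -6) {
  validate_library(library)
  all_genes <- unique(library$target_gene[library$role == "target"])
  if (is.numeric(genes)) {
    stopifnot(length(genes) == 1, genes >= 0, genes <= 1)
    genes <- sample(all_genes, round(genes * length(all_genes)))
  }
  unknown <- setdiff(genes, all_genes)
  if (length(unknown)) {
    stop("genes not in library: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  e <- stats::setNames(numeric(nrow(library)), library$construct_id)
  e[library$target_gene %in% genes] <- effect
  e[library$role == "depletion_control"] <- control_effect
  e
}

#' Simulate sequencing counts for a competitive growth screen
#'
#' Latent day-0 clone abundances are drawn per replicate as
#' `representation * LogNormal(0, baseline_dispersion)` (replicates model
#' independent transductions and therefore redraw abundances while sharing
#' the biology, i.e. the effect map). Over the growth window a clone's
#' abundance changes deterministically by `2^(e * k)` where `k = 1` in the
#' dox-treated arm, `k = leakiness` in the untreated day-14 arm and `k = 0`
#' at day 0. Each sample is sequenced by a multinomial draw of `depth` reads
#' over its pool's relative abundances (optionally Dirichlet-multinomial if
#' `dm_overdispersion > 0`).
#'
#' @param library library table ([build_library()]).
#' @param sheet sample sheet ([build_sample_sheet()]).
#' @param config a [sim_config()].
#' @param effects named per-construct effect vector ([plant_gene_effects()]);
#'   constructs not named default to 0. `NULL` means no effects anywhere
#'   (controls included).
#' @return a list with elements
#'   \describe{
#'     \item{counts}{integer matrix, constructs x samples; cells of
#'       constructs outside a sample's pool are structural zeros.}
#'     \item{truth}{a `sim_truth` list: `effects` (named vector),
#'       `gene_labels` (`data.frame` of gene and
#'       depletion/enrichment/neutral label) and `baseline` (latent day-0
#'       abundance matrix, constructs x replicates).}
#'   }
#' @export
simulate_counts <- function(library, sheet, config, effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_library(library)
  validate_sample_sheet(sheet)
  assert_single_screen(sheet)
  if (config$depth <= 0 || config$representation <= 0) {
    stop("depth and representation must be positive", call. = FALSE)
  }
  missing_pools <- setdiff(library$pool_id, sheet$pool_id)
  if (length(missing_pools)) {
    stop("sample sheet lacks pools: ", paste(missing_pools, collapse = ", "),
         call. = FALSE)
  }

  n <- nrow(library)
  e <- stats::setNames(numeric(n), library$construct_id)
  if (!is.null(effects)) {
    unknown <- setdiff(names(effects), library$construct_id)
    if (length(unknown)) {
      stop("effects refer to unknown constructs: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    e[names(effects)] <- effects
  }

  seed <- derive_seed(config$seed, 13L)
  if (!is.null(seed)) set.seed(seed)

  reps <- unique(sheet$replicate)
  baseline <- matrix(NA_real_, n, length(reps),
                     dimnames = list(library$construct_id, reps))
  for (r in reps) {
    baseline[, r] <- config$representation *
      stats::rlnorm(n, meanlog = 0, sdlog = config$baseline_dispersion)
  }

  arm <- sample_arm(sheet)
  k_arm <- c(Day0 = 0, Day14 = config$leakiness, Day14Dox = 1)
  counts <- matrix(0L, n, nrow(sheet),
                   dimnames = list(library$construct_id, sheet$sample_id))
  for (s in seq_len(nrow(sheet))) {
    rows <- which(library$pool_id == sheet$pool_id[s])
    abundance <- baseline[rows, sheet$replicate[s]] * 2^(e[rows] * k_arm[[arm[s]]])
    prob <- abundance / sum(abundance)
    if (config$dm_overdispersion > 0) {
      w <- stats::rgamma(length(prob), shape = prob / config$dm_overdispersion)
      prob <- w / sum(w)
    }
    counts[rows, s] <- stats::rmultinom(1, size = config$depth, prob = prob)
  }

  gene_e <- tapply(e[library$role == "target"],
                   library$target_gene[library$role == "target"], sum)
  labels <- ifelse(gene_e < 0, "depletion",
                   ifelse(gene_e > 0, "enrichment", "neutral"))
  truth <- structure(list(
    effects = e,
    gene_labels = data.frame(gene = names(gene_e), label = as.vector(labels),
                             stringsAsFactors = FALSE),
    baseline = baseline
  ), class = "sim_truth")
  list(counts = counts, truth = truth)
}
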