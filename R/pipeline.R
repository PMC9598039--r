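#' Run the full screen pipeline from one configuration
#'
#' Orchestrates simulate (or load counts) -> normalize -> trim -> QC ->
#' score -> call hits -> optional expression filter -> cross-screen
#' accounting, writing every stage output under `outdir` with deterministic
#' names plus a JSON manifest echoing all effective parameter values. Rerun
#' with an identical configuration and seed is byte-identical. Progress is
#' logged to standard error; machine outputs never go there.
#'
#' @param config a named list, or the path of a YAML file with the same
#'   structure. Top-level keys (all optional unless noted):
#'   \describe{
#'     \item{outdir}{output directory (required).}
#'     \item{seed}{integer seed for all randomness.}
#'     \item{sim}{arguments for [sim_config()] (simulation mode).}
#'     \item{screens}{list of per-screen entries. Simulation mode: `id`,
#'       `depleted_fraction`, `effect`, `control_effect`, optional
#'       `leakiness` override. File mode: `id`, `counts`, `samples` paths
#'       (plus top-level `library` path).}
#'     \item{library}{path to a library TSV (file mode).}
#'     \item{normalize}{`pseudocount`, `scale`.}
#'     \item{trim}{`min_day0_count`, `ratio_cap`.}
#'     \item{score}{`convention` (`divide`/`multiply`), `include_controls`.}
#'     \item{hits}{`min_frequency`.}
#'     \item{expression}{`enabled`, `tables` (named paths), `thresholds`
#'       (named numbers).}
#'     \item{write_fastq}{if `TRUE`, simulated reads are written to FASTQ
#'       and re-counted by [demux_and_count()] instead of using the
#'       simulated matrix directly (full round trip).}
#'   }
#' @return the manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)
  if (is.null(cfg$outdir)) stop("config must name an 'outdir'", call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  simulate_mode <- is.null(cfg$library)
  manifest <- list(package = "mirescreen",
                   version = as.character(utils::packageVersion("mirescreen")),
                   parameters = cfg, stages = list())

  if (simulate_mode) {
    sc <- stage("simulate", do.call(sim_config, cfg$sim))
    library_tab <- stage("simulate", build_library(sc))
    write_library(library_tab, file.path(cfg$outdir, "library.tsv"))
  } else {
    library_tab <- stage("load", read_library(cfg$library))
  }
  manifest$stages$library <- list(n_constructs = nrow(library_tab),
                                  n_pools = length(unique(library_tab$pool_id)))

  screens <- list()
  for (i in seq_along(cfg$screens)) {
    scr <- cfg$screens[[i]]
    id <- scr$id %||% paste0("screen", i)
    if (simulate_mode) {
      sim_args <- cfg$sim
      sim_args$seed <- derive_seed(cfg$seed, 100L * i)
      if (!is.null(scr$leakiness)) sim_args$leakiness <- scr$leakiness
      sc_i <- do.call(sim_config, sim_args)
      sheet <- stage("simulate", build_sample_sheet(sc_i, screen_id = id))
      if (!is.null(sc_i$seed)) set.seed(derive_seed(sc_i$seed, 31L))
      effects <- stage("simulate", plant_gene_effects(
        library_tab, genes = scr$depleted_fraction %||% 0,
        effect = scr$effect %||% -4,
        control_effect = scr$control_effect %||% -6))
      sim <- stage("simulate", simulate_counts(library_tab, sheet, sc_i, effects))
      counts <- sim$counts
      truth <- sim$truth
      if (isTRUE(cfg$write_fastq)) {
        fq <- file.path(cfg$outdir, paste0(id, ".fastq"))
        stage("fastq", write_screen_fastq(counts, library_tab, sheet, fq))
        dq <- stage("quantify", demux_and_count(fq, library_tab, sheet))
        counts <- dq$counts
        utils::write.table(dq$stats,
                           file.path(cfg$outdir, paste0(id, "_demux_stats.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      utils::write.table(
        data.frame(construct_id = names(truth$effects),
                   effect = truth$effects, stringsAsFactors = FALSE),
        file.path(cfg$outdir, paste0(id, "_truth_effects.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(truth$gene_labels,
                         file.path(cfg$outdir, paste0(id, "_truth_genes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      if (is.null(scr$counts) || is.null(scr$samples)) {
        stop("file-mode screen entries need 'counts' and 'samples' paths",
             call. = FALSE)
      }
      sheet <- stage("load", read_sample_sheet(scr$samples))
      counts <- stage("load", read_count_matrix(scr$counts, library_tab))
      truth <- NULL
    }
    write_sample_sheet(sheet, file.path(cfg$outdir, paste0(id, "_samples.tsv")))
    write_count_matrix(counts, file.path(cfg$outdir, paste0(id, "_counts.tsv")))

    norm <- stage("normalize", normalize_pool(
      counts, library_tab, sheet,
      pseudocount = cfg$normalize$pseudocount, scale = cfg$normalize$scale))
    norm <- stage("trim", trim_extremes(
      norm, counts, library_tab, sheet,
      min_day0_count = cfg$trim$min_day0_count,
      ratio_cap = cfg$trim$ratio_cap))
    qc <- stage("qc", qc_correlations(norm, sheet))
    utils::write.table(qc, file.path(cfg$outdir, paste0(id, "_qc_correlations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    sres <- stage("score", score_constructs(
      norm, library_tab, sheet,
      convention = cfg$score$convention,
      include_controls = cfg$score$include_controls))
    utils::write.table(sres$scores, file.path(cfg$outdir, paste0(id, "_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats_df <- data.frame(key = names(unlist(sres$stats)),
                           value = as.character(unlist(sres$stats)),
                           stringsAsFactors = FALSE)
    utils::write.table(stats_df, file.path(cfg$outdir, paste0(id, "_stats.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ctrl <- stage("qc", qc_controls(sres$scores, sres$stats$sd_avssmd, library_tab))
    utils::write.table(ctrl, file.path(cfg$outdir, paste0(id, "_qc_controls.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    gene_scores <- stage("score", aggregate_genes(sres$scores))
    hits <- stage("call_hits", dual_flashlight_table(
      gene_scores, sres$scores, sres$stats$sd_avssmd,
      min_frequency = cfg$hits$min_frequency))
    utils::write.table(hits, file.path(cfg$outdir, paste0(id, "_hits.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    filtered <- NULL
    if (isTRUE(cfg$expression$enabled)) {
      if (length(cfg$expression$tables) == 0) {
        stop("expression filter enabled but config$expression$tables is empty",
             call. = FALSE)
      }
      tabs <- lapply(cfg$expression$tables, function(p) {
        if (!file.exists(p)) {
          stop("expression table not found: ", p, call. = FALSE)
        }
        read_expression_table(p)
      })
      filtered <- stage("expression_filter", expression_filter(
        hits[hits$hit, , drop = FALSE], tabs,
        unlist(cfg$expression$thresholds)))
      utils::write.table(filtered,
                         file.path(cfg$outdir, paste0(id, "_hits_expressed.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    manifest$stages[[id]] <- list(
      n_samples = nrow(sheet), n_counts = nrow(counts),
      n_scored = sres$stats$n_constructs_scored,
      sd_avssmd = sres$stats$sd_avssmd,
      median_bgr = sres$stats$median_bgr, mad_bgr = sres$stats$mad_bgr,
      n_genes_scored = nrow(gene_scores),
      n_first_filter_hits = sum(hits$hit),
      n_second_filter_hits = if (is.null(filtered)) NA else nrow(filtered))
    screens[[id]] <- list(hits = hits, filtered = filtered)
  }

  if (length(screens) >= 1) {
    cross <- stage("cross_screen",
                   cross_screen(lapply(screens, function(s) s$hits)))
    utils::write.table(cross$regions, file.path(cfg$outdir, "venn_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cross$classes, file.path(cfg$outdir, "cross_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hm <- stage("cross_screen",
                heatmap_table(cross, lapply(screens, function(s) s$hits)))
    utils::write.table(hm, file.path(cfg$outdir, "heatmap_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$cross_screen <- list(n_union = cross$n_union)
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  message("[done] outputs in ", cfg$outdir)
  invisible(manifest)
}

#' @noRd
pipeline_defaults <- function(config) {
  cfg <- config
  cfg$seed <- cfg$seed %||% NULL
  cfg$sim <- utils::modifyList(list(seed = cfg$seed), cfg$sim %||% list())
  cfg$screens <- cfg$screens %||% list(list(id = "screen1"))
  cfg$normalize <- utils::modifyList(list(pseudocount = 1, scale = 1e6),
                                     cfg$normalize %||% list())
  cfg$trim <- utils::modifyList(list(min_day0_count = 30, ratio_cap = 8),
                                cfg$trim %||% list())
  cfg$score <- utils::modifyList(list(convention = "divide",
                                      include_controls = TRUE),
                                 cfg$score %||% list())
  cfg$hits <- utils::modifyList(list(min_frequency = 2L), cfg$hits %||% list())
  cfg$expression <- utils::modifyList(list(enabled = FALSE, tables = list(),
                                           thresholds = list()),
                                      cfg$expression %||% list())
  cfg$write_fastq <- cfg$write_fastq %||% FALSE
  cfg
}

#' Summarize a completed pipeline run
#'
#' Reads a run directory produced by [run_pipeline()] and tabulates, per
#' screen: genes with at least one scored construct, first-filter hits,
#' second-filter (expression-filtered) hits, plus union and all-screen
#' intersection sizes across screens.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list with `per_screen` (`data.frame`) and `cross` (`data.frame`
#'   of Venn regions, or `NULL`); also written to `report.tsv` in `run_dir`.
#' @export
screen_report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", run_dir, "; not a completed run", call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  ids <- setdiff(names(manifest$stages), c("library", "cross_screen"))
  per_screen <- do.call(rbind, lapply(ids, function(id) {
    s <- manifest$stages[[id]]
    data.frame(screen = id,
               genes_scored = s$n_genes_scored,
               first_filter_hits = s$n_first_filter_hits,
               second_filter_hits = if (is.null(s$n_second_filter_hits))
                 NA_integer_ else s$n_second_filter_hits,
               stringsAsFactors = FALSE)
  }))
  cross <- NULL
  venn_path <- file.path(run_dir, "venn_regions.tsv")
  if (file.exists(venn_path)) {
    cross <- utils::read.delim(venn_path, stringsAsFactors = FALSE)
  }
  utils::write.table(per_screen, file.path(run_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(per_screen = per_screen, cross = cross)
}
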