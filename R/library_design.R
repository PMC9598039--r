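#' Build a synthetic miR-E library table
#'
#' Constructs the catalog of a pooled knockdown library: every target gene is
#' covered by several constructs (all in the same pool), genes are distributed
#' over pools so that pool sizes stay balanced, and each pool additionally
#' carries four spiked control constructs -- two stability controls targeting
#' transcripts absent from the cells (shRenilla, shLuciferase) and two
#' depletion controls against the essential replication factor Rpa3
#' (shRpa3-218, shRpa3-457).
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` with columns `construct_id`, `guide_seq`,
#'   `target_gene` (empty string for controls), `pool_id` (integer, 1-based)
#'   and `role` (`target`, `stability_control` or `depletion_control`).
#' @export
build_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n_genes <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(n_genes))
  guides_per_gene <- if (config$guides_min == config$guides_max) {
    rep(config$guides_min, n_genes)
  } else {
    sample(seq(config$guides_min, config$guides_max), n_genes, replace = TRUE)
  }

  # greedy balancing: largest genes first, each into the currently lightest
  # pool, so pool sizes differ by at most max(guides_per_gene)
  ord <- order(-guides_per_gene, genes)
  pool_load <- integer(config$n_pools)
  gene_pool <- integer(n_genes)
  for (g in ord) {
    p <- which.min(pool_load)
    gene_pool[g] <- p
    pool_load[p] <- pool_load[p] + guides_per_gene[g]
  }

  controls <- c("shRenilla", "shLuciferase", "shRpa3-218", "shRpa3-457")
  roles <- c("stability_control", "stability_control",
             "depletion_control", "depletion_control")
  n_targets <- sum(guides_per_gene)
  n_ctrl <- 4L * config$n_pools
  guides <- random_kmers(n_targets + n_ctrl, config$guide_length)

  target_tab <- data.frame(
    construct_id = unlist(lapply(seq_len(n_genes), function(g) {
      sprintf("%s.%d", genes[g], seq_len(guides_per_gene[g]))
    })),
    guide_seq = guides[seq_len(n_targets)],
    target_gene = rep(genes, guides_per_gene),
    pool_id = rep(gene_pool, guides_per_gene),
    role = "target",
    stringsAsFactors = FALSE
  )
  ctrl_tab <- data.frame(
    construct_id = as.vector(vapply(seq_len(config$n_pools), function(p) {
      sprintf("%s_p%02d", controls, p)
    }, character(4))),
    guide_seq = guides[n_targets + seq_len(n_ctrl)],
    target_gene = "",
    pool_id = rep(seq_len(config$n_pools), each = 4L),
    role = rep(roles, config$n_pools),
    stringsAsFactors = FALSE
  )
  lib <- rbind(target_tab, ctrl_tab)
  lib <- lib[order(lib$pool_id, lib$role == "target", lib$construct_id), ]
  rownames(lib) <- NULL
  validate_library(lib)
  lib
}

#' @noRd
validate_library <- function(lib) {
  need <- c("construct_id", "guide_seq", "target_gene", "pool_id", "role")
  if (!all(need %in% names(lib))) {
    stop("library table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lib$construct_id)) stop("duplicate construct_id in library", call. = FALSE)
  if (anyDuplicated(lib$guide_seq)) stop("duplicate guide_seq in library", call. = FALSE)
  bad_role <- setdiff(lib$role, c("target", "stability_control", "depletion_control"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  # each gene confined to one pool
  tg <- lib[lib$role == "target", ]
  if (nrow(tg)) {
    pools_per_gene <- tapply(tg$pool_id, tg$target_gene, function(p) length(unique(p)))
    if (any(pools_per_gene != 1L)) {
      stop("gene(s) split across pools: ",
           paste(names(pools_per_gene)[pools_per_gene != 1L], collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(lib)
}

#' Build a sample sheet for one screen
#'
#' A screen consists of three arms per pool and replicate: the day-0 baseline,
#' day 14 without doxycycline (untreated reference) and day 14 with
#' doxycycline (knockdown induced). Replicates model independent
#' transductions. Each sample receives a unique barcode with a guaranteed
#' minimum pairwise Hamming distance, so mismatch-tolerant demultiplexing
#' stays unambiguous.
#'
#' @param config a [sim_config()] object (supplies `n_pools`,
#'   `barcode_length`, `seed`).
#' @param screen_id label of the screen (cell line + condition).
#' @param replicates replicate labels; default `c("R1", "R2")`.
#' @param barcode_min_dist minimum pairwise Hamming distance between
#'   barcodes (default 5, safe for up to 2 allowed mismatches).
#' @return a `data.frame` with columns `sample_id`, `screen_id`, `pool_id`,
#'   `replicate`, `timepoint` (`Day0`/`Day14`), `dox` (logical) and `barcode`.
#' @export
build_sample_sheet <- function(config, screen_id = "screen1",
                               replicates = c("R1", "R2"),
                               barcode_min_dist = 5L) {
  stopifnot(inherits(config, "sim_config"))
  seed <- derive_seed(config$seed, 7L)
  if (!is.null(seed)) set.seed(seed)
  arms <- data.frame(
    timepoint = c("Day0", "Day14", "Day14Dox"),
    tp = c("Day0", "Day14", "Day14"),
    dox = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(arm = seq_len(3), replicate = replicates,
                      pool_id = seq_len(config$n_pools),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- data.frame(
    sample_id = sprintf("%s_p%02d_%s_%s", screen_id, grid$pool_id,
                        grid$replicate, arms$timepoint[grid$arm]),
    screen_id = screen_id,
    pool_id = grid$pool_id,
    replicate = grid$replicate,
    timepoint = arms$tp[grid$arm],
    dox = arms$dox[grid$arm],
    stringsAsFactors = FALSE
  )
  sheet$barcode <- random_barcodes(nrow(sheet), config$barcode_length,
                                   min_dist = barcode_min_dist)
  validate_sample_sheet(sheet)
  sheet
}

#' @noRd
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "screen_id", "pool_id", "replicate", "timepoint",
            "dox", "barcode")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id", call. = FALSE)
  key <- interaction(sheet$screen_id, sheet$pool_id, sheet$replicate,
                     sheet$timepoint, sheet$dox, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("(pool, replicate, timepoint, dox) must be unique within a screen",
         call. = FALSE)
  }
  if (any(sheet$timepoint == "Day0" & sheet$dox)) {
    stop("Day0 samples cannot be dox-treated", call. = FALSE)
  }
  invisible(sheet)
}
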