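# fixture builders shared across test files; everything is generated in code

# deterministic distinct k-mers (integer -> base-4 over ACGT)
det_kmers <- function(n, k = 22) {
  stopifnot(n <= 4^min(k, 15))
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(k)
    for (j in seq_len(k)) {
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

# distinct k-mers with pairwise Hamming distance >= k/2 (for tests that
# exercise mismatch-tolerant matching)
far_kmers <- function(n, k = 22) {
  stopifnot(n <= 16, k %% 2 == 0)
  vapply(det_kmers(n, 2), function(x) {
    paste0(strrep(substr(x, 1, 1), k / 2), strrep(substr(x, 2, 2), k / 2))
  }, character(1), USE.NAMES = FALSE)
}

# a hand-built single- or multi-pool library with optional controls
hand_library <- function(genes, guides_per_gene = 2L, pool = 1L,
                         controls = FALSE, guide_length = 22L) {
  tg <- data.frame(
    construct_id = unlist(lapply(genes, function(g)
      paste0(g, ".", seq_len(guides_per_gene)))),
    target_gene = rep(genes, each = guides_per_gene),
    pool_id = as.integer(pool),
    role = "target",
    stringsAsFactors = FALSE
  )
  if (controls) {
    ctrl <- data.frame(
      construct_id = c("shRenilla", "shLuciferase", "shRpa3-218", "shRpa3-457"),
      target_gene = "",
      pool_id = as.integer(pool[1]),
      role = c("stability_control", "stability_control",
               "depletion_control", "depletion_control"),
      stringsAsFactors = FALSE
    )
    tg <- rbind(tg, ctrl)
  }
  tg$guide_seq <- det_kmers(nrow(tg), guide_length)
  tg[, c("construct_id", "guide_seq", "target_gene", "pool_id", "role")]
}

# sample sheet with deterministic, well-separated barcodes
hand_sheet <- function(pools = 1L, reps = c("R1", "R2"), screen = "s1",
                       barcode_length = 10L) {
  grid <- expand.grid(arm = c("Day0", "Day14", "Day14Dox"),
                      replicate = reps, pool_id = pools,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  # spread barcodes: distinct 5-mers over ACGT repeated twice -> pairwise
  # Hamming distance >= 2 per differing digit block (>= 2 blocks differ)
  stopifnot(barcode_length == 10L, n <= 4^5)
  bc <- vapply(det_kmers(n, 5), function(x) paste0(x, x), character(1))
  data.frame(
    sample_id = sprintf("%s_p%02d_%s_%s", screen, grid$pool_id,
                        grid$replicate, grid$arm),
    screen_id = screen,
    pool_id = as.integer(grid$pool_id),
    replicate = grid$replicate,
    timepoint = ifelse(grid$arm == "Day0", "Day0", "Day14"),
    dox = grid$arm == "Day14Dox",
    barcode = unname(bc),
    stringsAsFactors = FALSE
  )
}

# wrap a values matrix as a norm_matrix; mask = non-NA cells
manual_norm <- function(values, mask = NULL) {
  structure(list(values = values,
                 mask = if (is.null(mask)) !is.na(values) else mask,
                 pseudocount = 1, scale = 1e6, trim = NULL),
            class = "norm_matrix")
}

# per-construct score table for hit-selection tests
mk_scores <- function(genes, avssmd, role = "target") {
  data.frame(construct_id = paste0("c", seq_along(avssmd)),
             target_gene = genes, role = role, pool_id = 1L,
             avssmd = avssmd, replicates_used = 1L, fallback_used = FALSE,
             stringsAsFactors = FALSE)
}

# a small simulated screen, one call
quick_screen <- function(seed = 1, n_genes = 20, n_pools = 2, depth = 5e4,
                         guides_min = 4, guides_max = 5, leakiness = 0,
                         effects = NULL, screen_id = "s1", ...) {
  sc <- sim_config(n_genes = n_genes, guides_min = guides_min,
                   guides_max = guides_max, n_pools = n_pools, depth = depth,
                   leakiness = leakiness, seed = seed, ...)
  lib <- build_library(sc)
  sheet <- build_sample_sheet(sc, screen_id = screen_id)
  sim <- simulate_counts(lib, sheet, sc, effects)
  list(config = sc, library = lib, sheet = sheet,
       counts = sim$counts, truth = sim$truth)
}
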