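# one pool, one sample triple per replicate, built by hand
one_sample_norm <- function(counts_vec) {
  lib <- hand_library(paste0("g", seq_along(counts_vec)), guides_per_gene = 1)
  sheet <- hand_sheet(reps = "R1")[1, , drop = FALSE]
  counts <- matrix(as.integer(counts_vec), ncol = 1,
                   dimnames = list(lib$construct_id, sheet$sample_id))
  list(norm = normalize_pool(counts, lib, sheet), lib = lib, sheet = sheet,
       counts = counts)
}

test_that("normalization matches the log2 CPM-with-pseudocount formula", {
  res <- one_sample_norm(c(100, 300, 600))
  # total 1000, scale 1e6, pseudocount 1 -> log2(c(100001, 300001, 600001))
  expect_equal(unname(res$norm$values[, 1]),
               c(16.6096549, 18.1946078, 19.1946054), tolerance = 1e-6)
})

test_that("normalization is exactly invariant to sequencing depth", {
  a <- one_sample_norm(c(7, 13, 40, 1, 0))
  b <- one_sample_norm(10L * c(7, 13, 40, 1, 0))
  expect_identical(a$norm$values, b$norm$values)
})

test_that("a single-construct sample normalizes to log2(scale + pseudocount)", {
  res <- one_sample_norm(12345)
  expect_equal(unname(res$norm$values[1, 1]), log2(1e6 + 1))
})

test_that("a zero-total sample is fully masked with a warning", {
  lib <- hand_library(c("g1", "g2"), guides_per_gene = 1)
  sheet <- hand_sheet(reps = "R1")[1:2, ]
  counts <- matrix(c(5L, 5L, 0L, 0L), 2, 2,
                   dimnames = list(lib$construct_id, sheet$sample_id))
  expect_warning(norm <- normalize_pool(counts, lib, sheet), "zero total")
  expect_true(all(norm$mask[, 1]))
  expect_false(any(norm$mask[, 2]))
})

test_that("cells outside a sample's pool are structurally missing", {
  lib <- hand_library(c("g1", "g2"), guides_per_gene = 1, pool = c(1L, 2L))
  sheet <- hand_sheet(pools = 1:2, reps = "R1")
  counts <- matrix(10L, 2, nrow(sheet),
                   dimnames = list(lib$construct_id, sheet$sample_id))
  norm <- normalize_pool(counts, lib, sheet)
  pool1_samples <- sheet$sample_id[sheet$pool_id == 1]
  expect_true(all(is.na(norm$values["g2.1", pool1_samples])))
  expect_false(any(norm$mask["g2.1", pool1_samples]))
})

# a 2-replicate screen for trimming tests
trim_fixture <- function(day0_counts, day14_mult = 1) {
  n <- length(day0_counts[[1]])
  lib <- hand_library(paste0("g", seq_len(n)), guides_per_gene = 1)
  sheet <- hand_sheet()
  arm <- ifelse(sheet$timepoint == "Day0", "Day0",
                ifelse(sheet$dox, "Day14Dox", "Day14"))
  counts <- matrix(0L, n, nrow(sheet),
                   dimnames = list(lib$construct_id, sheet$sample_id))
  for (s in seq_len(nrow(sheet))) {
    base <- day0_counts[[sheet$replicate[s]]]
    counts[, s] <- as.integer(if (arm[s] == "Day0") base else
      pmax(base * day14_mult, 0))
  }
  list(lib = lib, sheet = sheet, counts = counts,
       norm = normalize_pool(counts, lib, sheet))
}

test_that("low day-0 constructs are masked per replicate", {
  fx <- trim_fixture(list(R1 = c(50, 100, 100), R2 = c(0, 100, 100)))
  trimmed <- trim_extremes(fx$norm, fx$counts, fx$lib, fx$sheet,
                           min_day0_count = 30, ratio_cap = Inf)
  r1 <- fx$sheet$sample_id[fx$sheet$replicate == "R1"]
  r2 <- fx$sheet$sample_id[fx$sheet$replicate == "R2"]
  expect_true(all(trimmed$mask["g1.1", r1]))
  expect_false(any(trimmed$mask["g1.1", r2]))
  expect_true(all(trimmed$mask[c("g2.1", "g3.1"), ]))
})

test_that("trimming with no-op thresholds leaves the mask unchanged", {
  fx <- trim_fixture(list(R1 = c(5, 10, 20), R2 = c(5, 10, 20)))
  trimmed <- trim_extremes(fx$norm, fx$counts, fx$lib, fx$sheet,
                           min_day0_count = 0, ratio_cap = Inf)
  expect_identical(trimmed$mask, fx$norm$mask)
  expect_identical(trimmed$values, fx$norm$values)
})

test_that("a single extreme log2 change masks exactly that cell", {
  fx <- trim_fixture(list(R1 = c(1000, 1000, 1000, 1000, 1000),
                          R2 = c(1000, 1000, 1000, 1000, 1000)))
  # push one Day14Dox cell far from its day-0 value
  dox_r1 <- fx$sheet$sample_id[fx$sheet$replicate == "R1" & fx$sheet$dox]
  counts <- fx$counts
  counts["g1.1", dox_r1] <- 1L
  norm <- normalize_pool(counts, fx$lib, fx$sheet)
  trimmed <- trim_extremes(norm, counts, fx$lib, fx$sheet,
                           min_day0_count = 0, ratio_cap = 8)
  masked <- which(norm$mask & !trimmed$mask, arr.ind = TRUE)
  expect_identical(nrow(masked), 1L)
  expect_identical(rownames(counts)[masked[1, 1]], "g1.1")
  expect_identical(colnames(counts)[masked[1, 2]], dox_r1)
})

test_that("tightening trim thresholds only grows the masked set", {
  scr <- quick_screen(seed = 31, n_genes = 15, n_pools = 1, depth = 3e4,
                      baseline_dispersion = 1.5)
  norm <- normalize_pool(scr$counts, scr$library, scr$sheet)
  prev_masked <- !norm$mask
  for (thr in list(c(0, Inf), c(10, 6), c(30, 4), c(100, 2))) {
    trimmed <- trim_extremes(norm, scr$counts, scr$library, scr$sheet,
                             min_day0_count = thr[1], ratio_cap = thr[2])
    now_masked <- !trimmed$mask
    expect_true(all(now_masked[prev_masked]))
    prev_masked <- now_masked
  }
})

test_that("Pearson QC reproduces hand-computed correlations", {
  lib <- hand_library(paste0("g", 1:4), guides_per_gene = 1)
  sheet <- hand_sheet(reps = "R1")
  arm <- ifelse(sheet$timepoint == "Day0", "Day0",
                ifelse(sheet$dox, "Day14Dox", "Day14"))
  v <- matrix(NA_real_, 4, 3, dimnames = list(lib$construct_id, sheet$sample_id))
  v[, sheet$sample_id[arm == "Day0"]] <- c(1, 2, 4, 3)
  v[, sheet$sample_id[arm == "Day14"]] <- c(1, 2, 3, 4)
  v[, sheet$sample_id[arm == "Day14Dox"]] <- c(1, 2, 3, 4)
  qc <- qc_correlations(manual_norm(v), sheet)
  r <- qc$r[qc$pair == "Day14_vs_Day0"]
  expect_equal(r, 0.8, tolerance = 1e-12)

  # identity and perfect anticorrelation
  v[, sheet$sample_id[arm == "Day0"]] <- c(1, 2, 3, 4)
  expect_equal(qc_correlations(manual_norm(v), sheet)$r[1], 1)
  v[1:3, sheet$sample_id[arm == "Day0"]] <- c(3, 2, 1)
  v[4, sheet$sample_id[arm == "Day0"]] <- NA
  expect_equal(qc_correlations(manual_norm(v), sheet)$r[1], -1)
})

test_that("pairs with fewer than 3 shared constructs are undefined", {
  lib <- hand_library(paste0("g", 1:4), guides_per_gene = 1)
  sheet <- hand_sheet(reps = "R1")
  arm <- ifelse(sheet$timepoint == "Day0", "Day0",
                ifelse(sheet$dox, "Day14Dox", "Day14"))
  v <- matrix(NA_real_, 4, 3, dimnames = list(lib$construct_id, sheet$sample_id))
  v[1:2, sheet$sample_id[arm == "Day0"]] <- c(1, 2)
  v[, sheet$sample_id[arm == "Day14"]] <- c(1, 2, 3, 4)
  qc <- qc_correlations(manual_norm(v), sheet)
  row <- qc[qc$pair == "Day14_vs_Day0", ]
  expect_identical(row$n, 2L)
  expect_true(is.na(row$r))
})

test_that("high-depth null screens give within-replicate R >= 0.9", {
  scr <- quick_screen(seed = 41, n_genes = 40, n_pools = 1, depth = 5e5)
  norm <- normalize_pool(scr$counts, scr$library, scr$sheet)
  norm <- trim_extremes(norm, scr$counts, scr$library, scr$sheet)
  qc <- qc_correlations(norm, scr$sheet)
  within <- qc$r[qc$pair == "Day14_vs_Day0"]
  expect_true(all(within >= 0.9))
})

test_that("control QC reports the expected fractions", {
  # 29 depletion controls, 28 below -1 SD; stability controls at 0
  scores <- mk_scores(
    genes = rep("", 31),
    avssmd = c(rep(-5, 28), -0.5, 0, 0),
    role = c(rep("depletion_control", 29), rep("stability_control", 2))
  )
  lib <- data.frame(construct_id = scores$construct_id, guide_seq = det_kmers(31),
                    target_gene = "", pool_id = 1L, role = scores$role,
                    stringsAsFactors = FALSE)
  qc <- qc_controls(scores, sd_avssmd = 2, library = lib)
  dep <- qc[qc$class == "depletion_control", ]
  expect_identical(dep$n, 29L)
  expect_identical(dep$n_expected, 28L)
  expect_equal(dep$fraction, 28 / 29, tolerance = 1e-12)
  stab <- qc[qc$class == "stability_control", ]
  expect_equal(stab$fraction, 1)
})

test_that("strong depletion controls are detected below -1 SD in simulation", {
  # shRpa3-like controls (e = -6), no leakiness; threshold fixed at 0.9
  frac <- vapply(1:3, function(seed) {
    sc <- sim_config(n_genes = 30, n_pools = 2, depth = 2e5, seed = seed)
    lib <- build_library(sc)
    sheet <- build_sample_sheet(sc, "s1")
    sim <- simulate_counts(lib, sheet, sc,
                           plant_gene_effects(lib, control_effect = -6))
    norm <- normalize_pool(sim$counts, lib, sheet)
    res <- score_constructs(norm, lib, sheet)
    qc <- qc_controls(res$scores, res$stats$sd_avssmd, lib)
    qc$fraction[qc$class == "depletion_control"]
  }, numeric(1))
  expect_true(mean(frac) >= 0.9)
})
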