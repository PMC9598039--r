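# layout with short flanks keeps hand-written reads readable
short_layout <- read_layout(barcode_length = 10, flank5 = "ACGT",
                            flank3 = "TT", guide_length = 22)

make_read <- function(barcode, guide, layout = short_layout) {
  paste0(barcode, layout$flank5, guide, layout$flank3)
}

write_fastq_lines <- function(seqs, path) {
  lines <- as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                           strrep("I", nchar(seqs))))
  writeLines(lines, path)
  path
}

flip_base <- function(s, pos) {
  base <- substr(s, pos, pos)
  substr(s, pos, pos) <- if (base == "A") "C" else "A"
  s
}

test_that("generator FASTQ round trip reproduces counts bit-exactly", {
  scr <- quick_screen(seed = 13, n_genes = 12, n_pools = 2, depth = 2e4)
  fq <- tempfile(fileext = ".fastq")
  write_screen_fastq(scr$counts, scr$library, scr$sheet, fq)
  dq <- demux_and_count(fq, scr$library, scr$sheet)
  expect_identical(dq$counts, scr$counts)
  expect_identical(dq$stats$reads[dq$stats$category == "assigned"],
                   as.integer(sum(scr$counts)))
  expect_true(all(dq$stats$reads[dq$stats$category != "assigned"] == 0L))
})

test_that("gzipped FASTQ reads back identically", {
  scr <- quick_screen(seed = 13, n_genes = 5, n_pools = 1, depth = 5e3)
  fq <- tempfile(fileext = ".fastq.gz")
  write_screen_fastq(scr$counts, scr$library, scr$sheet, fq)
  dq <- demux_and_count(fq, scr$library, scr$sheet)
  expect_identical(dq$counts, scr$counts)
})

test_that("barcode mismatch tolerance is a sharp boundary", {
  lib <- hand_library("g1", guides_per_gene = 1)
  sheet <- hand_sheet()[1, , drop = FALSE]
  read <- make_read(flip_base(sheet$barcode, 1), lib$guide_seq)
  fq <- write_fastq_lines(read, tempfile(fileext = ".fastq"))

  strict <- demux_and_count(fq, lib, sheet, short_layout, barcode_mismatch = 0)
  expect_identical(sum(strict$counts), 0L)
  expect_identical(
    strict$stats$reads[strict$stats$category == "unassigned_barcode"], 1L)

  loose <- demux_and_count(fq, lib, sheet, short_layout, barcode_mismatch = 1)
  expect_identical(unname(loose$counts[1, 1]), 1L)
})

test_that("guide mismatch tolerance is a sharp boundary", {
  lib <- hand_library(c("g1", "g2"), guides_per_gene = 2)
  lib$guide_seq <- far_kmers(nrow(lib))
  sheet <- hand_sheet()[1, , drop = FALSE]
  read <- make_read(sheet$barcode, flip_base(lib$guide_seq[1], 22))
  fq <- write_fastq_lines(read, tempfile(fileext = ".fastq"))

  strict <- demux_and_count(fq, lib, sheet, short_layout, guide_mismatch = 0)
  expect_identical(sum(strict$counts), 0L)
  expect_identical(
    strict$stats$reads[strict$stats$category == "unmatched_guide"], 1L)

  loose <- demux_and_count(fq, lib, sheet, short_layout, guide_mismatch = 5)
  expect_identical(unname(loose$counts[1, 1]), 1L)
})

test_that("hand-built fixture: stats categories partition all 10 reads", {
  lib <- hand_library(c("g1", "g2"), guides_per_gene = 2)
  sheet <- hand_sheet()[1:3, ]
  bad_barcode <- strrep("N", 10)
  bad_guide <- strrep("N", 22)
  reads <- c(
    make_read(sheet$barcode[1], lib$guide_seq[1]),   # valid x3
    make_read(sheet$barcode[1], lib$guide_seq[1]),
    make_read(sheet$barcode[1], lib$guide_seq[2]),
    make_read(sheet$barcode[2], lib$guide_seq[3]),   # valid x4
    make_read(sheet$barcode[2], lib$guide_seq[4]),
    make_read(sheet$barcode[3], lib$guide_seq[1]),
    make_read(sheet$barcode[3], lib$guide_seq[4]),
    make_read(bad_barcode, lib$guide_seq[1]),        # bad barcode x2
    make_read(bad_barcode, lib$guide_seq[2]),
    make_read(sheet$barcode[1], bad_guide)           # bad guide x1
  )
  fq <- write_fastq_lines(reads, tempfile(fileext = ".fastq"))
  dq <- demux_and_count(fq, lib, sheet, short_layout)
  stats <- stats::setNames(dq$stats$reads, dq$stats$category)
  expect_identical(sum(stats), 10L)
  expect_identical(unname(stats["assigned"]), 7L)
  expect_identical(unname(stats["unassigned_barcode"]), 2L)
  expect_identical(unname(stats["unmatched_guide"]), 1L)
  expect_identical(unname(stats["multi_hit_guide"]), 0L)
  expect_identical(sum(dq$counts), 7L)
})

test_that("reads shorter than the layout are counted unassigned", {
  lib <- hand_library("g1", guides_per_gene = 1)
  sheet <- hand_sheet()[1, , drop = FALSE]
  fq <- write_fastq_lines(substr(make_read(sheet$barcode, lib$guide_seq), 1, 20),
                          tempfile(fileext = ".fastq"))
  dq <- demux_and_count(fq, lib, sheet, short_layout)
  expect_identical(dq$stats$reads[dq$stats$category == "unassigned_barcode"], 1L)
  expect_identical(sum(dq$counts), 0L)
})

test_that("counts only accrue to samples of a construct's own pool", {
  lib <- hand_library(c("g1", "g2"), guides_per_gene = 1, pool = c(1L, 2L))
  sheet <- hand_sheet(pools = 1:2)
  s1 <- sheet[sheet$pool_id == 1, ][1, ]
  # guide of pool 2 arriving with a pool-1 barcode must not be counted
  fq <- write_fastq_lines(make_read(s1$barcode, lib$guide_seq[2]),
                          tempfile(fileext = ".fastq"))
  dq <- demux_and_count(fq, lib, sheet, short_layout)
  expect_identical(sum(dq$counts), 0L)
  expect_identical(dq$stats$reads[dq$stats$category == "unmatched_guide"], 1L)
})

test_that("ambiguous barcode separation is refused up front", {
  lib <- hand_library("g1", guides_per_gene = 1)
  sheet <- hand_sheet()[1:2, ]
  b <- sheet$barcode[1]
  sheet$barcode[2] <- flip_base(b, 1)  # pairwise distance 1 <= 2*1
  fq <- write_fastq_lines(make_read(b, lib$guide_seq),
                          tempfile(fileext = ".fastq"))
  expect_error(demux_and_count(fq, lib, sheet, short_layout,
                               barcode_mismatch = 1),
               "ambiguous")
})

test_that("shuffling read order changes no counts", {
  scr <- quick_screen(seed = 17, n_genes = 6, n_pools = 1, depth = 3e3)
  fq <- tempfile(fileext = ".fastq")
  write_screen_fastq(scr$counts, scr$library, scr$sheet, fq)
  lines <- readLines(fq)
  recs <- split(lines, rep(seq_len(length(lines) / 4), each = 4))
  set.seed(1)
  shuffled <- unlist(recs[sample(length(recs))], use.names = FALSE)
  fq2 <- tempfile(fileext = ".fastq")
  writeLines(shuffled, fq2)
  expect_identical(demux_and_count(fq2, scr$library, scr$sheet)$counts,
                   demux_and_count(fq, scr$library, scr$sheet)$counts)
})

test_that("raising mismatch tolerance never decreases assigned counts", {
  lib <- hand_library(c("g1", "g2"), guides_per_gene = 2)
  lib$guide_seq <- far_kmers(nrow(lib))
  sheet <- hand_sheet()[1, , drop = FALSE]
  reads <- c(
    make_read(sheet$barcode, lib$guide_seq[1]),
    make_read(sheet$barcode, flip_base(lib$guide_seq[2], 5)),
    make_read(flip_base(sheet$barcode, 3), lib$guide_seq[3])
  )
  fq <- write_fastq_lines(reads, tempfile(fileext = ".fastq"))
  prev <- -1L
  for (tol in 0:2) {
    dq <- demux_and_count(fq, lib, sheet, short_layout,
                          barcode_mismatch = min(tol, 1), guide_mismatch = tol)
    expect_gte(sum(dq$counts), prev)
    prev <- sum(dq$counts)
  }
  expect_identical(prev, 3L)
})

test_that("count matrix TSV round trip is lossless and validated", {
  scr <- quick_screen(seed = 19, n_genes = 5, n_pools = 1, depth = 1e3)
  zero_row <- scr$counts
  zero_row[1, ] <- 0L
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(zero_row, path)
  back <- read_count_matrix(path, scr$library)
  expect_identical(back, zero_row)
  expect_true(all(back[1, ] == 0L))

  bad <- zero_row
  bad[2, 1] <- -1L
  path2 <- tempfile(fileext = ".tsv")
  write_count_matrix(bad, path2)
  expect_error(read_count_matrix(path2),
               rownames(bad)[2], fixed = TRUE)

  rownames(zero_row)[1] <- "not_in_library"
  path3 <- tempfile(fileext = ".tsv")
  write_count_matrix(zero_row, path3)
  expect_error(read_count_matrix(path3, scr$library), "not in the library")
})

test_that("library and sample sheet TSVs round trip", {
  scr <- quick_screen(seed = 23, n_genes = 4, n_pools = 1)
  lp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_library(scr$library, lp)
  write_sample_sheet(scr$sheet, sp)
  expect_identical(read_library(lp), scr$library)
  expect_identical(read_sample_sheet(sp), scr$sheet)
})
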