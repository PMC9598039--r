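#' Demultiplex screen reads and count guides
#'
#' Assigns each read to a sample by its inline barcode and to a construct by
#' the guide sequence at the layout's fixed offset, both by Hamming distance
#' (substitutions only; the amplicon has a fixed structure, so indel-tolerant
#' matching is deliberately not attempted). Guide matching is restricted to
#' the library constructs of the assigned sample's pool, so counts can only
#' accrue to samples of a construct's own pool. Reads are never fractionally
#' assigned: any ambiguity (two equally near barcodes or guides within
#' tolerance) discards the read into the corresponding tally.
#'
#' @param fastq path(s) to FASTQ file(s); gzip is read transparently.
#' @param library library table.
#' @param sheet sample sheet; barcodes must be pairwise more than
#'   `2 * barcode_mismatch` apart, otherwise demultiplexing would be
#'   ambiguous by construction and the call is refused.
#' @param layout a [read_layout()].
#' @param barcode_mismatch,guide_mismatch maximum Hamming distance tolerated
#'   for barcode and guide matching.
#' @return a list with `counts` (integer matrix constructs x samples, zeros
#'   included) and `stats`, a `data.frame` with one row per category:
#'   `assigned`, `unassigned_barcode`, `unmatched_guide`, `multi_hit_guide`;
#'   the categories always sum to the number of reads processed. Per-sample
#'   assigned read counts are `colSums(counts)`.
#' @export
demux_and_count <- function(fastq, library, sheet, layout = read_layout(),
                            barcode_mismatch = 0L, guide_mismatch = 0L) {
  validate_library(library)
  validate_sample_sheet(sheet)
  stopifnot(barcode_mismatch >= 0, guide_mismatch >= 0)
  if (min_pairwise_hamming(sheet$barcode) <= 2 * barcode_mismatch) {
    stop("barcodes are not pairwise more than ", 2 * barcode_mismatch,
         " apart; demultiplexing at ", barcode_mismatch,
         " mismatches would be ambiguous", call. = FALSE)
  }
  if (guide_mismatch > 0) {
    for (p in unique(library$pool_id)) {
      g <- library$guide_seq[library$pool_id == p]
      if (min_pairwise_hamming(g) <= 2 * guide_mismatch) {
        stop("guides of pool ", p, " are not pairwise more than ",
             2 * guide_mismatch, " apart", call. = FALSE)
      }
    }
  }

  reads <- unlist(lapply(fastq, function(f) {
    con <- gzfile(f, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (length(lines) %% 4 != 0) {
      stop("truncated FASTQ: ", f, " has ", length(lines),
           " lines (not a multiple of 4)", call. = FALSE)
    }
    lines[seq(2, length(lines), by = 4)]
  }), use.names = FALSE)

  n_total <- length(reads)
  counts <- matrix(0L, nrow(library), nrow(sheet),
                   dimnames = list(library$construct_id, sheet$sample_id))
  stats_row <- c(assigned = 0L, unassigned_barcode = 0L,
                 unmatched_guide = 0L, multi_hit_guide = 0L)
  if (n_total == 0) {
    return(list(counts = counts, stats = demux_stats(stats_row, n_total)))
  }

  blen <- layout$barcode_length
  g_start <- blen + nchar(layout$flank5) + 1L
  g_end <- g_start + layout$guide_length - 1L

  long_enough <- nchar(reads) >= layout$read_length
  stats_row["unassigned_barcode"] <- sum(!long_enough)
  reads <- reads[long_enough]

  ## barcode assignment on unique observed barcodes
  bc_obs <- substr(reads, 1L, blen)
  bc_uni <- unique(bc_obs)
  sample_of <- match(bc_uni, sheet$barcode)
  if (barcode_mismatch > 0) {
    for (j in which(is.na(sample_of))) {
      d <- hamming_to_all(bc_uni[j], sheet$barcode)
      hit <- which(d <= barcode_mismatch & d == min(d))
      if (length(hit) == 1L) sample_of[j] <- hit
    }
  }
  read_sample <- sample_of[match(bc_obs, bc_uni)]
  stats_row["unassigned_barcode"] <- stats_row["unassigned_barcode"] +
    sum(is.na(read_sample))
  ok <- !is.na(read_sample)
  reads <- reads[ok]
  read_sample <- read_sample[ok]
  if (!length(reads)) {
    return(list(counts = counts, stats = demux_stats(stats_row, n_total)))
  }

  ## guide assignment, restricted to the assigned sample's pool
  guide_obs <- substr(reads, g_start, g_end)
  read_pool <- sheet$pool_id[read_sample]
  key <- paste0(read_pool, ":", guide_obs)
  key_uni <- unique(key)
  sep <- regexpr(":", key_uni, fixed = TRUE)
  uni_pool <- as.integer(substr(key_uni, 1L, sep - 1L))
  uni_guide <- substring(key_uni, sep + 1L)

  construct_global <- match(uni_guide, library$guide_seq)
  construct_of <- ifelse(!is.na(construct_global) &
                           library$pool_id[construct_global] == uni_pool,
                         construct_global, NA_integer_)
  multi <- rep(FALSE, length(key_uni))
  if (guide_mismatch > 0) {
    for (j in which(is.na(construct_of))) {
      rows <- which(library$pool_id == uni_pool[j])
      d <- hamming_to_all(uni_guide[j], library$guide_seq[rows])
      near <- which(d <= guide_mismatch & d == min(d))
      if (length(near) == 1L) {
        construct_of[j] <- rows[near]
      } else if (length(near) > 1L) {
        multi[j] <- TRUE
      }
    }
  }
  idx <- match(key, key_uni)
  read_construct <- construct_of[idx]
  read_multi <- multi[idx]
  stats_row["multi_hit_guide"] <- sum(read_multi)
  stats_row["unmatched_guide"] <- sum(is.na(read_construct) & !read_multi)

  hit <- !is.na(read_construct)
  stats_row["assigned"] <- sum(hit)
  if (any(hit)) {
    flat <- (read_sample[hit] - 1L) * nrow(library) + read_construct[hit]
    tab <- tabulate(flat, nbins = nrow(library) * nrow(sheet))
    counts <- matrix(as.integer(tab), nrow(library), nrow(sheet),
                     dimnames = dimnames(counts))
  }

  list(counts = counts, stats = demux_stats(stats_row, n_total))
}

#' @noRd
demux_stats <- function(stats_row, n_total) {
  stopifnot(sum(stats_row) == n_total)
  data.frame(category = names(stats_row), reads = as.integer(stats_row),
             stringsAsFactors = FALSE)
}
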