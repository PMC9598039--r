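#' Amplicon read layout
#'
#' Describes the fixed structure of a screen sequencing read: an inline
#' sample barcode, a constant 5' flank (the miR-30 context upstream of the
#' guide in the amplicon), the guide itself, and a constant 3' flank (the
#' loop side). Demultiplexing and guide matching use fixed offsets derived
#' from this layout.
#'
#' @param barcode_length barcode length in nt.
#' @param flank5,flank3 constant sequences around the guide.
#' @param guide_length guide length in nt.
#' @return a `read_layout` list.
#' @export
read_layout <- function(barcode_length = 10L,
                        flank5 = "TGCTGTTGACAGTGAGCG",
                        flank3 = "TAGTGAAGCCACAGATGTA",
                        guide_length = 22L) {
  structure(list(
    barcode_length = as.integer(barcode_length),
    flank5 = flank5,
    flank3 = flank3,
    guide_length = as.integer(guide_length),
    read_length = as.integer(barcode_length + nchar(flank5) + guide_length +
                               nchar(flank3))
  ), class = "read_layout")
}

#' Write simulated screen reads to FASTQ
#'
#' Emits exactly `counts[i, s]` reads for construct `i` in sample `s`, each
#' read being `barcode + flank5 + guide + flank3` at constant quality
#' (Phred+33 'I'). The output is the exact inverse of
#' [demux_and_count()] at zero allowed mismatches.
#'
#' @param counts integer count matrix (constructs x samples).
#' @param library library table; `guide_seq` must match
#'   `layout$guide_length`.
#' @param sheet sample sheet covering the count matrix columns; barcodes
#'   must be unique within the output file.
#' @param path output file; a `.gz` suffix writes gzip-compressed.
#' @param layout a [read_layout()].
#' @return `path`, invisibly.
#' @export
write_screen_fastq <- function(counts, library, sheet, path,
                               layout = read_layout()) {
  validate_library(library)
  validate_sample_sheet(sheet)
  if (anyDuplicated(sheet$barcode)) {
    stop("duplicate barcodes within one FASTQ output are not allowed",
         call. = FALSE)
  }
  if (any(nchar(library$guide_seq) != layout$guide_length)) {
    stop("guide_seq lengths do not match layout$guide_length", call. = FALSE)
  }
  if (any(nchar(sheet$barcode) != layout$barcode_length)) {
    stop("barcode lengths do not match layout$barcode_length", call. = FALSE)
  }
  samples <- intersect(colnames(counts), sheet$sample_id)
  qual <- strrep("I", layout$read_length)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  guide_of <- stats::setNames(library$guide_seq, library$construct_id)
  for (s in samples) {
    bc <- sheet$barcode[sheet$sample_id == s]
    cnt <- counts[, s]
    keep <- which(cnt > 0)
    if (!length(keep)) next
    ids <- rownames(counts)[keep]
    seqs <- paste0(bc, layout$flank5, guide_of[ids], layout$flank3)
    n_each <- cnt[keep]
    read_seq <- rep(seqs, n_each)
    read_id <- paste0("@", s, ":", rep(ids, n_each), ":",
                      sequence(n_each))
    lines <- as.vector(rbind(read_id, read_seq, "+", qual))
    writeLines(lines, con)
  }
  invisible(path)
}
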