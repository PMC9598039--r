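# Tab-delimited readers/writers for the pipeline's tables. All formats are
# plain TSV with a header row; the count matrix carries constructs in the
# first column and one column per sample.

#' Read and write library tables, sample sheets and count matrices
#'
#' @param path file path (TSV).
#' @param x object to write.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
write_library <- function(x, path) {
  validate_library(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  lib$pool_id <- as.integer(lib$pool_id)
  lib$target_gene[is.na(lib$target_gene)] <- ""
  validate_library(lib)
  lib
}

#' @rdname screen_io
#' @export
write_sample_sheet <- function(x, path) {
  validate_sample_sheet(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  sheet$pool_id <- as.integer(sheet$pool_id)
  sheet$dox <- as.logical(sheet$dox)
  validate_sample_sheet(sheet)
  sheet
}

#' @rdname screen_io
#' @param library optional library table; if given, constructs in the file
#'   that are not in the library are rejected.
#' @export
read_count_matrix <- function(path, library = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "construct_id") {
    stop("count matrix file must have 'construct_id' as its first column",
         call. = FALSE)
  }
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid count at construct '", ids[bad[1, 1]], "', sample '",
         colnames(m)[bad[1, 2]], "': counts must be nonnegative integers",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (!is.null(library)) {
    unknown <- setdiff(ids, library$construct_id)
    if (length(unknown)) {
      stop("count matrix contains constructs not in the library: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  m
}

#' @rdname screen_io
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(construct_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene expression table
#'
#' Two-column TSV (`gene`, `value`), e.g. RNA-seq FPKM or microarray log2
#' intensities, used by [expression_filter()].
#'
#' @param path file path.
#' @return `data.frame` with columns `gene` and `value`.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "value") %in% names(tab))) {
    stop("expression table needs columns 'gene' and 'value'", call. = FALSE)
  }
  tab[, c("gene", "value")]
}
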