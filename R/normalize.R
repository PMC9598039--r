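#' Pool-based normalization and log2 transform
#'
#' Within each sample (a sample always covers exactly one pool), raw counts
#' are converted to reads-per-`scale` and log2-transformed with a
#' pseudocount: `value = log2(count / pool_total * scale + pseudocount)`.
#' Adding the pseudocount after scaling keeps the transform exactly invariant
#' to sequencing depth. Cells of constructs outside a sample's pool are
#' structurally missing; a sample whose pool total is zero is fully masked
#' with a warning.
#'
#' @param counts integer count matrix (constructs x samples).
#' @param library library table.
#' @param sheet sample sheet.
#' @param pseudocount added after scaling (default 1).
#' @param scale reads-per-unit scale (default `1e6`, i.e. log2 CPM).
#' @return an object of class `norm_matrix`: list with `values` (numeric
#'   matrix, NA outside pools), `mask` (logical matrix, `TRUE` = retained),
#'   and the normalization/trimming parameters used.
#' @export
normalize_pool <- function(counts, library, sheet, pseudocount = 1,
                           scale = 1e6) {
  validate_library(library)
  validate_sample_sheet(sheet)
  stopifnot(scale > 0, pseudocount >= 0)
  counts <- counts[library$construct_id, sheet$sample_id, drop = FALSE]
  values <- matrix(NA_real_, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  mask <- matrix(FALSE, nrow(counts), ncol(counts),
                 dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    rows <- which(library$pool_id == sheet$pool_id[s])
    tot <- sum(counts[rows, s])
    if (tot == 0) {
      warning("sample '", sheet$sample_id[s],
              "' has zero total counts; all its cells are masked",
              call. = FALSE)
      next
    }
    values[rows, s] <- log2(counts[rows, s] / tot * scale + pseudocount)
    mask[rows, s] <- TRUE
  }
  structure(list(values = values, mask = mask,
                 pseudocount = pseudocount, scale = scale,
                 trim = NULL),
            class = "norm_matrix")
}

#' Trim extreme values
#'
#' Masks unreliable cells before scoring: (1) a construct whose *raw* day-0
#' count in a replicate falls below `min_day0_count` is masked in all
#' samples of that replicate (too few cells at baseline for a meaningful
#' ratio); (2) any day-14 cell whose log2 change versus its replicate's
#' day-0 value exceeds `ratio_cap` in absolute value is masked as an
#' outlier. Masked cells are recorded, never deleted, and propagate as
#' missing values into scoring, where they trigger the single-replicate
#' fallbacks.
#'
#' @param norm a `norm_matrix` from [normalize_pool()].
#' @param counts the raw count matrix the normalization was computed from.
#' @param library library table.
#' @param sheet sample sheet.
#' @param min_day0_count minimum raw day-0 count per replicate (default 30).
#' @param ratio_cap maximum |log2 change| versus day 0 (default 8); `Inf`
#'   disables the rule.
#' @return the `norm_matrix` with an updated mask and the trim thresholds
#'   recorded in `$trim`.
#' @export
trim_extremes <- function(norm, counts, library, sheet,
                          min_day0_count = 30, ratio_cap = 8) {
  stopifnot(inherits(norm, "norm_matrix"),
            min_day0_count >= 0, ratio_cap >= 0)
  counts <- counts[rownames(norm$values), colnames(norm$values), drop = FALSE]
  mask <- norm$mask
  arm <- sample_arm(sheet)
  for (r in unique(sheet$replicate)) {
    for (p in unique(sheet$pool_id)) {
      in_rep <- sheet$replicate == r & sheet$pool_id == p
      d0 <- which(in_rep & arm == "Day0")
      if (!length(d0)) next
      rows <- which(library$pool_id == p)
      low <- rows[counts[rows, d0] < min_day0_count]
      if (length(low)) mask[low, which(in_rep)] <- FALSE
      for (s in which(in_rep & arm != "Day0")) {
        delta <- abs(norm$values[rows, s] - norm$values[rows, d0])
        out <- rows[!is.na(delta) & delta > ratio_cap]
        if (length(out)) mask[out, s] <- FALSE
      }
    }
  }
  if (!any(mask)) warning("trimming masked every cell", call. = FALSE)
  norm$mask <- mask
  norm$trim <- list(min_day0_count = min_day0_count, ratio_cap = ratio_cap)
  norm
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix:", nrow(x$values), "constructs x", ncol(x$values),
      "samples; log2(count/pool_total *", format(x$scale), "+",
      x$pseudocount, ")\n")
  cat("retained cells:", sum(x$mask), "of", sum(!is.na(x$values)),
      "in-pool cells\n")
  if (!is.null(x$trim)) {
    cat("trimmed with min_day0_count =", x$trim$min_day0_count,
        ", ratio_cap =", x$trim$ratio_cap, "\n")
  }
  invisible(x)
}
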