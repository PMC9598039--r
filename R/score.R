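#' Foreground and background log ratios
#'
#' On the log2 scale, per construct and replicate:
#' \itemize{
#'   \item `FGR = value(Day14Dox) - value(Day14)` -- the knockdown effect,
#'     i.e. the log2 abundance change attributable to induction;
#'   \item `BGR = value(Day0) - value(Day14)` -- the background drift of a
#'     clone over the growth window without induction, used to estimate the
#'     screen's noise.
#' }
#' If a replicate's untreated day-14 value is masked or absent, the fallback
#' `FGR = value(Day14Dox) - value(Day0)` is used and the replicate
#' contributes no BGR; the fallback is flagged. A replicate whose Day14Dox
#' value is missing is unscored in that replicate.
#'
#' @param norm a `norm_matrix` (after [trim_extremes()], typically).
#' @param library library table.
#' @param sheet sample sheet (single screen).
#' @return list with matrices `fgr`, `bgr` (constructs x replicates) and
#'   logical `fallback` of the same shape.
#' @export
compute_log_ratios <- function(norm, library, sheet) {
  assert_single_screen(sheet)
  v <- masked_values(norm)
  arm <- sample_arm(sheet)
  reps <- sort(unique(sheet$replicate))
  n <- nrow(v)
  ids <- rownames(v)

  # value of each construct in (replicate, arm): constructs live in exactly
  # one pool, so this collapses the per-pool sample columns into one vector
  vec_of <- function(r, a) {
    out <- rep(NA_real_, n)
    for (s in which(sheet$replicate == r & arm == a)) {
      rows <- which(library$pool_id == sheet$pool_id[s])
      out[rows] <- v[rows, s]
    }
    out
  }

  fgr <- matrix(NA_real_, n, length(reps), dimnames = list(ids, reps))
  bgr <- fgr
  fallback <- matrix(FALSE, n, length(reps), dimnames = list(ids, reps))
  for (r in reps) {
    d0 <- vec_of(r, "Day0")
    d14 <- vec_of(r, "Day14")
    d14dox <- vec_of(r, "Day14Dox")
    primary <- !is.na(d14dox) & !is.na(d14)
    fgr[primary, r] <- d14dox[primary] - d14[primary]
    bgr_ok <- !is.na(d0) & !is.na(d14)
    bgr[bgr_ok, r] <- d0[bgr_ok] - d14[bgr_ok]
    fb <- !is.na(d14dox) & is.na(d14) & !is.na(d0)
    fgr[fb, r] <- d14dox[fb] - d0[fb]
    fallback[fb, r] <- TRUE
  }
  list(fgr = fgr, bgr = bgr, fallback = fallback)
}

#' Robust background statistics
#'
#' The background location and spread of a screen are estimated from all
#' finite BGR values pooled over every construct and both replicates:
#' `medianBGR` is their median, and `MAD = 1.4826 * median(|BGR -
#' medianBGR|)` (the Gaussian-consistent median absolute deviation).
#'
#' @param bgr matrix (or vector) of BGR values; NAs ignored.
#' @return list with `median_bgr`, `mad_bgr` and `n_bgr`.
#' @export
background_stats <- function(bgr) {
  x <- as.vector(bgr)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite BGR values; cannot estimate background",
                       call. = FALSE)
  med <- stats::median(x)
  mad <- stats::mad(x, center = med, constant = 1.4826)
  if (mad == 0) {
    stop("MAD of BGR is 0 (degenerate background); review trimming ",
         "thresholds and sequencing depth", call. = FALSE)
  }
  list(median_bgr = med, mad_bgr = mad, n_bgr = length(x))
}

#' Per-replicate SSMD*
#'
#' The robust strictly standardized mean difference of a construct's
#' foreground ratio against the screen's pooled background:
#' `SSMD* = (FGR - medianBGR) / (sqrt(2) * MAD)` under the default
#' `"divide"` convention (the standard scaling for a paired difference
#' against a robust background). The alternate `"multiply"` convention,
#' `(FGR - medianBGR) / MAD * sqrt(2)`, reads the same formula
#' left-to-right and differs from the default by exactly a factor of 2;
#' because the hit cutoff is itself one standard deviation of the scores,
#' hit sets are identical under either convention.
#'
#' @param fgr foreground ratio(s), log2 units.
#' @param median_bgr,mad_bgr pooled background statistics
#'   ([background_stats()]); `mad_bgr` must be positive.
#' @param convention `"divide"` (default) or `"multiply"`.
#' @return dimensionless score(s), strictly increasing in `fgr` and zero
#'   iff `fgr == median_bgr`.
#' @export
ssmd_star <- function(fgr, median_bgr, mad_bgr,
                      convention = c("divide", "multiply")) {
  convention <- match.arg(convention)
  if (!is.finite(mad_bgr) || mad_bgr <= 0) {
    stop("mad_bgr must be positive", call. = FALSE)
  }
  if (convention == "divide") {
    (fgr - median_bgr) / (sqrt(2) * mad_bgr)
  } else {
    (fgr - median_bgr) / mad_bgr * sqrt(2)
  }
}

#' Average SSMD* over replicates
#'
#' Mean of the available per-replicate scores; a construct with one missing
#' replicate keeps the other replicate's value (recorded in
#' `replicates_used`), and a construct with no scored replicate is unscored.
#'
#' @param ssmd matrix of per-replicate SSMD* (constructs x replicates).
#' @return list with `avssmd` (vector) and `replicates_used` (integer
#'   vector).
#' @export
avssmd <- function(ssmd) {
  used <- rowSums(is.finite(ssmd))
  av <- rowMeans(ssmd, na.rm = TRUE)
  av[used == 0] <- NA_real_
  list(avssmd = av, replicates_used = as.integer(used))
}

#' Score all constructs of a screen
#'
#' Runs the full per-construct scoring chain: log ratios
#' ([compute_log_ratios()]), pooled background ([background_stats()]),
#' per-replicate SSMD* ([ssmd_star()]) and the replicate average
#' ([avssmd()]), plus the screen-level score spread used as hit cutoff
#' ([sd_cutoff()]).
#'
#' @inheritParams compute_log_ratios
#' @param convention see [ssmd_star()].
#' @param include_controls if `TRUE` (default) control constructs enter the
#'   pooled background and the SD of scores, like any other construct.
#' @return list of class `screen_scores` with
#'   \describe{
#'     \item{scores}{`data.frame`: `construct_id`, `target_gene`, `role`,
#'       `pool_id`, per-replicate `fgr_*`, `bgr_*`, `ssmd_*`, `avssmd`,
#'       `replicates_used`, `fallback_used`.}
#'     \item{stats}{list: `median_bgr`, `mad_bgr`, `sd_avssmd`,
#'       `n_constructs_scored`, `convention`, `include_controls`.}
#'   }
#' @export
score_constructs <- function(norm, library, sheet,
                             convention = c("divide", "multiply"),
                             include_controls = TRUE) {
  convention <- match.arg(convention)
  lr <- compute_log_ratios(norm, library, sheet)
  bg_rows <- if (include_controls) seq_len(nrow(lr$bgr)) else
    which(library$role == "target")
  bg <- background_stats(lr$bgr[bg_rows, , drop = FALSE])
  ssmd <- ssmd_star(lr$fgr, bg$median_bgr, bg$mad_bgr, convention)
  av <- avssmd(ssmd)

  reps <- colnames(lr$fgr)
  scores <- data.frame(construct_id = library$construct_id,
                       target_gene = library$target_gene,
                       role = library$role,
                       pool_id = library$pool_id,
                       stringsAsFactors = FALSE)
  for (r in reps) {
    scores[[paste0("fgr_", r)]] <- lr$fgr[, r]
    scores[[paste0("bgr_", r)]] <- lr$bgr[, r]
    scores[[paste0("ssmd_", r)]] <- ssmd[, r]
  }
  scores$avssmd <- av$avssmd
  scores$replicates_used <- av$replicates_used
  scores$fallback_used <- rowSums(lr$fallback) > 0

  sd_rows <- if (include_controls) seq_len(nrow(scores)) else
    which(scores$role == "target")
  sd_av <- sd_cutoff(scores$avssmd[sd_rows])
  structure(list(
    scores = scores,
    stats = list(median_bgr = bg$median_bgr, mad_bgr = bg$mad_bgr,
                 n_bgr = bg$n_bgr, sd_avssmd = sd_av,
                 n_constructs_scored = sum(av$replicates_used > 0),
                 convention = convention,
                 include_controls = include_controls)
  ), class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  s <- x$stats
  cat("screen_scores:", s$n_constructs_scored, "constructs scored (",
      s$convention, "sqrt(2) convention )\n")
  cat(sprintf("  medianBGR = %.4f, MAD = %.4f, SD_AvSSMD* = %.4f\n",
              s$median_bgr, s$mad_bgr, s$sd_avssmd))
  invisible(x)
}

#' Gene-level score
#'
#' Unweighted mean of the AvSSMD* values of a gene's scored constructs
#' (`AvSSMD*/Protease`). Controls carry no target gene and are excluded;
#' genes without a single scored construct are absent from the output.
#'
#' @param scores per-construct score table (`screen_scores$scores`).
#' @return `data.frame` with `gene`, `avssmd_protease`, `n_scored`.
#' @export
aggregate_genes <- function(scores) {
  tg <- scores[scores$role == "target" & is.finite(scores$avssmd), ]
  if (!nrow(tg)) {
    return(data.frame(gene = character(0), avssmd_protease = numeric(0),
                      n_scored = integer(0), stringsAsFactors = FALSE))
  }
  agg <- tapply(tg$avssmd, tg$target_gene, mean)
  n <- tapply(tg$avssmd, tg$target_gene, length)
  out <- data.frame(gene = names(agg), avssmd_protease = as.vector(agg),
                    n_scored = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene), ]
}
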