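#' Screen-wide score cutoff
#'
#' One sample standard deviation (n-1 denominator) of all constructs'
#' AvSSMD* values. The `±1 SD_AvSSMD*` band is read as the screen's
#' intrinsic variability; constructs outside it are outliers.
#'
#' @param scores per-construct score table (with an `avssmd` column) or a
#'   numeric vector of AvSSMD* values.
#' @return the standard deviation (>= 0); 0 is flagged degenerate with a
#'   warning.
#' @export
sd_cutoff <- function(scores) {
  x <- if (is.data.frame(scores)) scores$avssmd else scores
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    stop("need at least 2 scored constructs to estimate SD_AvSSMD*",
         call. = FALSE)
  }
  s <- stats::sd(x)
  if (s == 0) warning("SD_AvSSMD* is 0 (all scores equal); cutoff degenerate",
                      call. = FALSE)
  s
}

#' First selection filter: frequency-based hit calling
#'
#' A gene's `frequency` is the number of its scored constructs with
#' `|AvSSMD*|` strictly greater than `sd` (outliers of either sign count;
#' the outlier band is symmetric). A gene is a hit iff `frequency >=
#' min_frequency` -- requiring at least two independent constructs guards
#' against single-construct off-target artifacts. The hit direction comes
#' from the sign of the gene-level score: negative means the knockdown
#' depletes the clones (the gene supports growth/survival), positive means
#' enrichment.
#'
#' @param gene_scores gene table from [aggregate_genes()].
#' @param scores per-construct score table.
#' @param sd the cutoff from [sd_cutoff()]; must be positive.
#' @param min_frequency minimum outlier constructs per gene (default 2).
#' @return `data.frame`: `gene`, `avssmd_protease`, `n_scored`, `frequency`,
#'   `hit`, `direction` (`depletion`/`enrichment`, NA when the gene score is
#'   exactly 0, which is logged).
#' @export
call_hits <- function(gene_scores, scores, sd, min_frequency = 2L) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  tg <- scores[scores$role == "target" & is.finite(scores$avssmd), ]
  out_count <- tapply(abs(tg$avssmd) > sd, tg$target_gene, sum)
  hits <- gene_scores
  hits$frequency <- as.integer(out_count[hits$gene])
  hits$frequency[is.na(hits$frequency)] <- 0L
  hits$hit <- hits$frequency >= min_frequency
  hits$direction <- ifelse(hits$avssmd_protease < 0, "depletion",
                           ifelse(hits$avssmd_protease > 0, "enrichment",
                                  NA_character_))
  zero <- which(is.na(hits$direction))
  if (length(zero)) {
    message(length(zero), " gene(s) with AvSSMD*/protease exactly 0; ",
            "direction undefined")
  }
  rownames(hits) <- NULL
  hits
}

#' Second selection filter: target mRNA expression
#'
#' Lowly expressed targets inflate the false-positive risk (there is little
#' transcript to knock down, so a scoring construct is suspect). A gene is
#' retained iff its expression is strictly above the threshold in *every*
#' configured expression table; a gene absent from any table fails (absence
#' of evidence of expression is not sufficient expression). Genes excluded
#' for absence are reported via a message.
#'
#' @param hits a hit table from [call_hits()] (any gene table with a `gene`
#'   column works).
#' @param expression named list of expression tables, each a `data.frame`
#'   with columns `gene` and `value` (see [read_expression_table()]).
#' @param thresholds named numeric vector, same names as `expression`;
#'   strictly-greater-than comparisons.
#' @return the filtered table, with one logical column `expressed_<name>`
#'   per table appended.
#' @export
expression_filter <- function(hits, expression, thresholds) {
  if (length(expression) == 0) {
    stop("expression filtering requested but no expression tables given",
         call. = FALSE)
  }
  if (!all(names(expression) %in% names(thresholds))) {
    stop("every expression table needs a threshold", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(hits))
  missing_any <- rep(FALSE, nrow(hits))
  for (nm in names(expression)) {
    tab <- expression[[nm]]
    if (!nrow(tab)) stop("expression table '", nm, "' is empty", call. = FALSE)
    val <- tab$value[match(hits$gene, tab$gene)]
    missing_any <- missing_any | is.na(val)
    pass <- !is.na(val) & val > thresholds[[nm]]
    hits[[paste0("expressed_", nm)]] <- pass
    keep <- keep & pass
  }
  if (any(missing_any & !keep)) {
    message(sum(missing_any), " gene(s) absent from at least one ",
            "expression table; excluded")
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-screen accounting
#'
#' Combines the hit tables of several screens: computes every region of the
#' Venn partition of the hit sets, and classifies each gene of the union by
#' the signs of its gene-level scores in the screens where it is a hit --
#' `depletion` if negative everywhere it hits, `enrichment` if positive
#' everywhere (flagged for exclusion from the final reported list), `mixed`
#' if both signs occur (depleted in one condition, enriched in another).
#'
#' @param hit_tables named list of [call_hits()] tables, one per screen.
#' @return list of class `cross_screen` with `sets` (hit gene sets),
#'   `regions` (`data.frame` of membership pattern and count), `union`
#'   (character vector), `classes` (`data.frame` gene/class) and
#'   `n_union`.
#' @export
cross_screen <- function(hit_tables) {
  stopifnot(length(hit_tables) >= 1)
  if (is.null(names(hit_tables)) || any(names(hit_tables) == "")) {
    names(hit_tables) <- paste0("screen", seq_along(hit_tables))
  }
  sets <- lapply(hit_tables, function(t) t$gene[t$hit])
  all_genes <- sort(unique(unlist(sets)))
  if (!length(all_genes)) {
    return(structure(list(
      sets = sets,
      regions = data.frame(region = character(0), n_genes = integer(0),
                           stringsAsFactors = FALSE),
      union = character(0), n_union = 0L,
      classes = data.frame(gene = character(0), class = character(0),
                           stringsAsFactors = FALSE)
    ), class = "cross_screen"))
  }
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1,
                                                dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) {
    paste(names(sets)[m], collapse = "&")
  })
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("region", "n_genes")

  sign_in <- vapply(names(sets), function(nm) {
    t <- hit_tables[[nm]]
    s <- sign(t$avssmd_protease[match(all_genes, t$gene)])
    s[!(all_genes %in% sets[[nm]])] <- NA_real_
    s
  }, numeric(length(all_genes)))
  if (length(all_genes) == 1L) sign_in <- matrix(sign_in, nrow = 1)
  cls <- apply(sign_in, 1, function(s) {
    s <- s[!is.na(s)]
    if (all(s < 0)) "depletion"
    else if (all(s > 0)) "enrichment"
    else "mixed"
  })
  structure(list(
    sets = sets,
    regions = regions,
    union = all_genes,
    n_union = length(all_genes),
    classes = data.frame(gene = all_genes, class = cls,
                         stringsAsFactors = FALSE)
  ), class = "cross_screen")
}

#' @export
print.cross_screen <- function(x, ...) {
  cat("cross_screen:", length(x$sets), "screens;",
      x$n_union, "genes in the union\n")
  for (nm in names(x$sets)) cat("  ", nm, ":", length(x$sets[[nm]]), "hits\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Dual-flashlight table
#'
#' One row per gene of a single screen: gene-level score against outlier
#' frequency, with the hit flag -- the tabular form of the dual-flashlight
#' plot used to visualize effect size versus reproducibility. Rows are
#' ordered by score, ties broken by gene name.
#'
#' @inheritParams call_hits
#' @return `data.frame` like [call_hits()] output, deterministically
#'   ordered.
#' @export
dual_flashlight_table <- function(gene_scores, scores, sd,
                                  min_frequency = 2L) {
  tab <- call_hits(gene_scores, scores, sd, min_frequency)
  tab <- tab[order(tab$avssmd_protease, tab$gene), ]
  rownames(tab) <- NULL
  tab
}

#' Heatmap table of cross-screen hits
#'
#' Per-gene, per-screen grid of gene-level scores for the final reported
#' hits. A cell where the gene did not pass the first filter in that screen
#' is marked `ns` (not significant) and its score is reported for context
#' only. Genes classified enrichment-only are excluded from the final list;
#' rows are ordered by the minimum score across screens, then gene name.
#'
#' @param cross a [cross_screen()] object.
#' @param hit_tables the same named list of hit tables used to build it.
#' @return `data.frame` with `gene`, `class`, then per screen
#'   `score_<name>` and `ns_<name>` columns.
#' @export
heatmap_table <- function(cross, hit_tables) {
  stopifnot(inherits(cross, "cross_screen"))
  keep <- cross$classes$gene[cross$classes$class != "enrichment"]
  if (!length(keep)) {
    out <- data.frame(gene = character(0), class = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(gene = keep,
                    class = cross$classes$class[match(keep, cross$classes$gene)],
                    stringsAsFactors = FALSE)
  for (nm in names(hit_tables)) {
    t <- hit_tables[[nm]]
    idx <- match(keep, t$gene)
    out[[paste0("score_", nm)]] <- t$avssmd_protease[idx]
    is_hit <- rep(FALSE, length(keep))
    ok <- !is.na(idx)
    is_hit[ok] <- t$hit[idx[ok]]
    out[[paste0("ns_", nm)]] <- !is_hit
  }
  score_cols <- grep("^score_", names(out))
  min_score <- apply(as.matrix(out[, score_cols, drop = FALSE]), 1,
                     function(x) if (all(is.na(x))) Inf else min(x, na.rm = TRUE))
  out <- out[order(min_score, out$gene), ]
  rownames(out) <- NULL
  out
}
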