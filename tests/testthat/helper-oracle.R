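# Independent brute-force reimplementation of the scoring chain, used as the
# oracle: explicit per-construct loops, hand-rolled median, no code shared
# with the package internals.

oracle_median <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_scores <- function(norm, library, sheet, convention = "divide") {
  v <- norm$values
  v[!norm$mask] <- NA_real_
  arm <- ifelse(sheet$timepoint == "Day0", "Day0",
                ifelse(sheet$dox, "Day14Dox", "Day14"))
  reps <- sort(unique(sheet$replicate))
  n <- nrow(v)
  fgr <- bgr <- matrix(NA_real_, n, length(reps))
  for (i in seq_len(n)) {
    for (ri in seq_along(reps)) {
      val <- function(a) {
        s <- which(sheet$pool_id == library$pool_id[i] &
                     sheet$replicate == reps[ri] & arm == a)
        if (length(s) == 1 && !is.na(v[i, s])) v[i, s] else NA_real_
      }
      dox <- val("Day14Dox"); unt <- val("Day14"); d0 <- val("Day0")
      if (!is.na(dox) && !is.na(unt)) {
        fgr[i, ri] <- dox - unt
      } else if (!is.na(dox) && is.na(unt) && !is.na(d0)) {
        fgr[i, ri] <- dox - d0
      }
      if (!is.na(d0) && !is.na(unt)) bgr[i, ri] <- d0 - unt
    }
  }
  all_bgr <- as.vector(bgr)
  med <- oracle_median(all_bgr)
  mad <- 1.4826 * oracle_median(abs(all_bgr - med))
  ssmd <- matrix(NA_real_, n, length(reps))
  for (i in seq_len(n)) {
    for (ri in seq_along(reps)) {
      if (!is.na(fgr[i, ri])) {
        ssmd[i, ri] <- if (convention == "divide") {
          (fgr[i, ri] - med) / (sqrt(2) * mad)
        } else {
          (fgr[i, ri] - med) / mad * sqrt(2)
        }
      }
    }
  }
  av <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- ssmd[i, !is.na(ssmd[i, ])]
    if (length(s)) av[i] <- sum(s) / length(s)
  }
  # sample SD of all AvSSMD*, n-1 denominator, by hand
  fin <- av[is.finite(av)]
  m <- sum(fin) / length(fin)
  sd_av <- sqrt(sum((fin - m)^2) / (length(fin) - 1))
  # per-gene means
  genes <- unique(library$target_gene[library$role == "target"])
  gene_av <- rep(NA_real_, length(genes))
  for (gi in seq_along(genes)) {
    rows <- which(library$target_gene == genes[gi] & library$role == "target")
    vals <- av[rows][is.finite(av[rows])]
    if (length(vals)) gene_av[gi] <- sum(vals) / length(vals)
  }
  list(fgr = fgr, bgr = bgr, median_bgr = med, mad_bgr = mad,
       ssmd = ssmd, avssmd = av, sd_avssmd = sd_av,
       genes = genes, gene_avssmd = gene_av)
}
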