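#' Replicate and timepoint correlations
#'
#' Pearson correlations of the normalized, trimmed, log2-transformed read
#' counts, pooled over all pools of a screen: day 14 (untreated) versus
#' day 0 within each replicate (a drop here indicates Dox-independent loss
#' of clones, e.g. promoter leakiness), and day 14 between the replicates
#' (expected lower, since replicates are independent transductions). Only
#' cells retained in both members of a pair enter; pairs with fewer than 3
#' shared constructs are reported as undefined.
#'
#' @param norm a `norm_matrix`.
#' @param sheet sample sheet.
#' @return `data.frame` with columns `pair`, `replicate`, `n`, `r`, `p`.
#' @export
qc_correlations <- function(norm, sheet) {
  assert_single_screen(sheet)
  v <- masked_values(norm)
  arm <- sample_arm(sheet)
  reps <- sort(unique(sheet$replicate))

  # per (replicate, arm) vector across all pools: each construct appears in
  # exactly one pool, hence exactly one sample of that (replicate, arm)
  vec_of <- function(r, a) {
    cols <- which(sheet$replicate == r & arm == a)
    if (!length(cols)) return(rep(NA_real_, nrow(v)))
    apply(v[, cols, drop = FALSE], 1, function(x) {
      ok <- !is.na(x)
      if (any(ok)) x[ok][1] else NA_real_
    })
  }

  one_pair <- function(label, r_label, x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      return(data.frame(pair = label, replicate = r_label, n = sum(ok),
                        r = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(pair = label, replicate = r_label, n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(reps, function(r) {
    one_pair("Day14_vs_Day0", r, vec_of(r, "Day14"), vec_of(r, "Day0"))
  }))
  if (length(reps) >= 2) {
    for (i in seq_len(length(reps) - 1)) {
      for (j in seq(i + 1, length(reps))) {
        out <- rbind(out, one_pair(
          "Day14_R_vs_R", paste(reps[i], reps[j], sep = "/"),
          vec_of(reps[i], "Day14"), vec_of(reps[j], "Day14")))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Control-construct behavior
#'
#' Checks the two spiked control classes against the screen's intrinsic
#' variability band (`±1 SD_AvSSMD*`): depletion controls (shRpa3) should
#' score below `-1 SD` because Rpa3 knockdown removes clones from the
#' induced population, while stability controls (shRenilla/shLuciferase,
#' targets absent from the cells) should stay inside the band.
#'
#' @param scores per-construct score table ([score_constructs()]`$scores`).
#' @param sd_avssmd the screen's score cutoff, from [sd_cutoff()].
#' @param library library table.
#' @return `data.frame` with one row per control class: number scored,
#'   number behaving as expected, and the fraction.
#' @export
qc_controls <- function(scores, sd_avssmd, library) {
  role <- library$role[match(scores$construct_id, library$construct_id)]
  dep <- scores[role == "depletion_control" & is.finite(scores$avssmd), ]
  stab <- scores[role == "stability_control" & is.finite(scores$avssmd), ]
  if (nrow(dep) + nrow(stab) == 0) {
    warning("no scored control constructs in the library", call. = FALSE)
    return(data.frame(class = character(0), n = integer(0),
                      n_expected = integer(0), fraction = numeric(0)))
  }
  data.frame(
    class = c("depletion_control", "stability_control"),
    n = c(nrow(dep), nrow(stab)),
    n_expected = c(sum(dep$avssmd < -sd_avssmd),
                   sum(abs(stab$avssmd) <= sd_avssmd)),
    fraction = c(
      if (nrow(dep)) sum(dep$avssmd < -sd_avssmd) / nrow(dep) else NA_real_,
      if (nrow(stab)) sum(abs(stab$avssmd) <= sd_avssmd) / nrow(stab) else NA_real_),
    stringsAsFactors = FALSE
  )
}
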