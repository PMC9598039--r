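# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
derive_seed <- function(seed, offset = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L)) + 1L
}

# Hamming distance between one string and a vector of equal-length strings.
# Amplicon reads have a fixed layout, so substitution-only distance is the
# right metric; indels are out of scope.
#' @noRd
hamming_to_all <- function(x, pool) {
  xi <- utf8ToInt(x)
  vapply(pool, function(p) sum(utf8ToInt(p) != xi), integer(1), USE.NAMES = FALSE)
}

# all pairwise Hamming distances; n is expected to be small (barcodes,
# guides of one pool)
#' @noRd
min_pairwise_hamming <- function(x) {
  n <- length(x)
  if (n < 2) return(Inf)
  m <- vapply(x, utf8ToInt, integer(nchar(x[1])))
  best <- Inf
  for (i in seq_len(n - 1)) {
    d <- colSums(m[, (i + 1):n, drop = FALSE] != m[, i])
    best <- min(best, d)
  }
  best
}

# draw `n` distinct random k-mers over ACGT
#' @noRd
random_kmers <- function(n, k) {
  if (n > 4^k) {
    stop("cannot draw ", n, " distinct sequences of length ", k,
         " (alphabet allows only 4^", k, ")", call. = FALSE)
  }
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    batch <- vapply(seq_len(need * 1.1 + 10), function(i) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, batch))
  }
  out[seq_len(n)]
}

# random barcodes with a guaranteed minimum pairwise Hamming distance
#' @noRd
random_barcodes <- function(n, k, min_dist = 5L) {
  if (n > 4^k) stop("too many barcodes requested for length ", k, call. = FALSE)
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    if (length(out) == 0 || min(hamming_to_all(cand, out)) >= min_dist) {
      out <- c(out, cand)
    }
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("could not place ", n, " barcodes of length ", k,
           " at minimum pairwise distance ", min_dist, call. = FALSE)
    }
  }
  out
}

# sample arm label: Day0 / Day14 / Day14Dox
#' @noRd
sample_arm <- function(sheet) {
  ifelse(sheet$timepoint == "Day0", "Day0",
         ifelse(sheet$dox, "Day14Dox", "Day14"))
}

#' @noRd
assert_single_screen <- function(sheet) {
  if (length(unique(sheet$screen_id)) != 1L) {
    stop("expected samples from a single screen; got screen_ids: ",
         paste(unique(sheet$screen_id), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# values with the trim/retention mask applied (masked cells -> NA)
#' @noRd
masked_values <- function(norm) {
  v <- norm$values
  v[!norm$mask] <- NA_real_
  v
}
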