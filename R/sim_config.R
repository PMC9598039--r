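#' Configuration for a synthetic competitive growth screen
#'
#' Bundles the design and sequencing parameters of a simulated pooled miR-E
#' dropout screen. Defaults emulate the degradome-focused screen design:
#' 658 target genes covered by 4--7 constructs each, split over 16 pools of
#' roughly 300 constructs, transduced at 1,000-fold representation
#' (about 1,000 independently infected cells per construct), grown for 14
#' days, and sequenced to about one million reads per sample.
#'
#' @param n_genes number of target genes in the library.
#' @param guides_min,guides_max per-gene construct count is drawn uniformly
#'   from this range (inclusive).
#' @param n_pools number of sub-library pools; each pool is an independent
#'   cell population and sequencing sample.
#' @param guide_length length of the guide (mature shRNA) sequence in nt.
#' @param barcode_length length of the sample barcode in nt.
#' @param representation expected number of transduced cells per construct
#'   at day 0 (cells/construct).
#' @param depth sequencing reads per sample.
#' @param baseline_dispersion log-normal sdlog of day-0 clone abundances
#'   around `representation`; captures unequal transduction and bottleneck
#'   noise. Dimensionless (log scale).
#' @param leakiness fraction in `[0, 1]` of a construct's knockdown effect
#'   expressed without doxycycline (Dox-independent promoter activity).
#' @param growth_days length of the growth window in days; effects are
#'   parameterized as total log2 fold-change over this window.
#' @param dm_overdispersion optional Dirichlet-multinomial overdispersion;
#'   `0` (default) gives pure multinomial sequencing noise, larger values add
#'   extra-multinomial variance (the per-sample proportions are perturbed by
#'   a Dirichlet draw with precision `1/dm_overdispersion`).
#' @param seed integer seed making library construction and count simulation
#'   reproducible; `NULL` leaves the RNG state untouched.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 658L, guides_min = 4L, guides_max = 7L,
                       n_pools = 16L, guide_length = 22L, barcode_length = 10L,
                       representation = 1000, depth = 1e6,
                       baseline_dispersion = 0.5, leakiness = 0,
                       growth_days = 14, dm_overdispersion = 0, seed = NULL) {
  stopifnot(n_genes >= 1, n_pools >= 1, guide_length >= 1)
  if (guides_min < 1 || guides_max > 20 || guides_min > guides_max) {
    stop("guides_min/guides_max must satisfy 1 <= min <= max <= 20", call. = FALSE)
  }
  if (leakiness < 0 || leakiness > 1) stop("leakiness must be in [0, 1]", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (representation <= 0) stop("representation must be positive", call. = FALSE)
  if (dm_overdispersion < 0) stop("dm_overdispersion must be >= 0", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes),
    guides_min = as.integer(guides_min),
    guides_max = as.integer(guides_max),
    n_pools = as.integer(n_pools),
    guide_length = as.integer(guide_length),
    barcode_length = as.integer(barcode_length),
    representation = representation,
    depth = depth,
    baseline_dispersion = baseline_dispersion,
    leakiness = leakiness,
    growth_days = growth_days,
    dm_overdispersion = dm_overdispersion,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes x", x$guides_min, "-", x$guides_max,
      "constructs in", x$n_pools, "pools;",
      "representation", x$representation, "; depth", format(x$depth),
      "; leakiness", x$leakiness, "\n")
  invisible(x)
}
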