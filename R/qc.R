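#' Median absolute pairwise difference (MAPD) of the log2 ratio
#'
#' The median, over genome-ordered consecutive probe pairs, of the
#' absolute difference in log2 ratio. Pairs never straddle a chromosome
#' boundary. MAPD measures local noise and — unlike a plain standard
#' deviation — is nearly unaffected by true copy-number segments, which
#' contribute only two large differences each.
#'
#' For i.i.d. Gaussian noise of standard deviation `s` the expected MAPD
#' is `s * sqrt(2) * qnorm(0.75)` (~ 0.954 s), which is also how the
#' pipeline converts an observed MAPD back into a noise estimate.
#'
#' @param signals A `sample_signals` object (>= 2 probes).
#' @return MAPD (non-negative scalar); 0 for constant input.
#' @export
compute_mapd <- function(signals) {
  stopifnot(inherits(signals, "sample_signals"))
  p <- signals$probes
  if (nrow(p) < 2) stop("compute_mapd: need at least 2 probes")
  d <- unlist(lapply(split(p$log2, p$chrom), function(x) {
    if (length(x) < 2) numeric(0) else abs(diff(x))
  }), use.names = FALSE)
  if (!length(d)) stop("compute_mapd: no within-chromosome probe pairs")
  stats::median(d)
}

#' Genotype-cluster separation score (SNPQC)
#'
#' Quality score for the genotyping channel: SNP-probe BAF values are
#' assigned to the nearest of the three diploid genotype bands
#' \{0, 0.5, 1\}, and for each adjacent band pair (0 vs 0.5, 0.5 vs 1)
#' the separation `|mean difference| / pooled sd` is computed; the score
#' is the minimum over available pairs. Well-genotyped samples have
#' tight, well-separated clusters and a high score.
#'
#' @param signals A `sample_signals` object with >= 50 SNP probes.
#' @param sentinel Value reported when a pooled sd is exactly zero
#'   (perfect separation); default `1e6` keeps ordering without Inf.
#' @return Non-negative separation score.
#' @export
compute_snpqc <- function(signals, sentinel = 1e6) {
  stopifnot(inherits(signals, "sample_signals"))
  baf <- signals$probes$baf[signals$probes$is_snp]
  baf <- baf[!is.na(baf)]
  if (length(baf) < 50) stop("compute_snpqc: need at least 50 SNP probes")
  # nearest of the {0, 0.5, 1} genotype bands
  cl <- findInterval(baf, c(0.25, 0.75)) + 1L
  sep_pair <- function(i, j) {
    a <- baf[cl == i]; b <- baf[cl == j]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) return(sentinel)
    abs(mean(a) - mean(b)) / sp
  }
  seps <- c(sep_pair(1, 2), sep_pair(2, 3))
  seps <- seps[!is.na(seps)]
  if (!length(seps))
    stop("compute_snpqc: fewer than two populated genotype clusters")
  min(seps)
}

#' Per-sample QC metrics
#'
#' @param signals A `sample_signals` object.
#' @return One-row data frame: `sample_id`, `patient`, `organ`,
#'   `platform`, `mapd`, `snpqc`.
#' @export
qc_metrics <- function(signals) {
  data.frame(
    sample_id = paste(signals$patient, signals$organ, signals$platform, sep = "."),
    patient = signals$patient, organ = signals$organ,
    platform = signals$platform,
    mapd = compute_mapd(signals),
    snpqc = compute_snpqc(signals)
  )
}

#' Apply QC thresholds to a set of samples
#'
#' A sample is kept iff `mapd <= mapd_max` AND `snpqc >= snpqc_min`
#' (both comparisons inclusive). Failing samples are excluded from all
#' downstream analysis, with the failed metric(s) recorded.
#'
#' @param samples Named list of `sample_signals` objects.
#' @param mapd_max Maximum acceptable MAPD (default 0.25, the
#'   vendor-style gate).
#' @param snpqc_min Minimum acceptable SNPQC (default 15).
#' @return List with `metrics` (per-sample data frame including `pass`
#'   and `reason`), `kept` (names of passing samples) and `excluded`
#'   (data frame of failing samples with reasons).
#' @export
apply_qc <- function(samples, mapd_max = 0.25, snpqc_min = 15) {
  stopifnot(mapd_max > 0, snpqc_min > 0)
  m <- do.call(rbind, lapply(samples, qc_metrics))
  rownames(m) <- NULL
  fail_mapd <- m$mapd > mapd_max
  fail_snpqc <- m$snpqc < snpqc_min
  m$pass <- !(fail_mapd | fail_snpqc)
  m$reason <- ifelse(m$pass, "",
                     trimws(paste(ifelse(fail_mapd, "MAPD", ""),
                                  ifelse(fail_snpqc, "SNPQC", ""))))
  list(metrics = m,
       kept = m$sample_id[m$pass],
       excluded = m[!m$pass, c("sample_id", "mapd", "snpqc", "reason")])
}
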