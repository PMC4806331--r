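# Half-open interval arithmetic (0-based, BED convention). These few
# primitives are the backbone of the cross-platform and germline logic,
# so they are written out explicitly and checked against a per-base
# oracle in the test suite.

#' Intersection of two half-open intervals
#'
#' @param a,b Numeric length-2 vectors `c(start, end)`, half-open.
#' @return `c(start, end)` of the intersection, or `NULL` if disjoint.
#' @export
interval_intersect <- function(a, b) {
  s <- max(a[1], b[1]); e <- min(a[2], b[2])
  if (s >= e) NULL else c(s, e)
}

#' Reciprocal overlap of two half-open intervals
#'
#' Returns the overlap length as a fraction of each interval's own
#' length. The concordance criterion passes only if BOTH fractions reach
#' the configured threshold — a large segment cannot validate a tiny one.
#'
#' @param a,b Numeric length-2 vectors `c(start, end)`; must be non-empty.
#' @return Numeric length-2 vector `c(overlap/len(a), overlap/len(b))`.
#' @export
#' @examples
#' reciprocal_overlap(c(0, 100), c(50, 150))  # 0.5 0.5
#' reciprocal_overlap(c(0, 100), c(40, 60))   # 0.2 1.0
reciprocal_overlap <- function(a, b) {
  la <- a[2] - a[1]; lb <- b[2] - b[1]
  if (la <= 0 || lb <= 0) stop("reciprocal_overlap: zero-length interval")
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  c(ov / la, ov / lb)
}

reciprocal_pass <- function(a, b, fraction) {
  all(reciprocal_overlap(a, b) >= fraction)
}

#' Merge directly adjacent segments of the same event type
#'
#' Within each chromosome, runs of segments whose intervals abut exactly
#' (`end == next start`) and share `event_type` are merged into one
#' segment with summed probe count and probe-weighted mean log2.
#' Differing types or gapped segments are left untouched. Overlapping
#' input segments violate the upstream tiling invariant and are an error.
#'
#' @param segments Segments data frame (one sample), sorted by
#'   chromosome and start.
#' @return Merged segments data frame.
#' @export
merge_adjacent <- function(segments) {
  if (!nrow(segments)) return(segments)
  parts <- lapply(split(segments, segments$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("merge_adjacent: overlapping segments in input")
    grp <- cumsum(c(1, (g$start[-1] != g$end[-nrow(g)]) |
                      (g$event_type[-1] != g$event_type[-nrow(g)])))
    do.call(rbind, lapply(split(g, grp), function(run) {
      out <- run[1, , drop = FALSE]
      out$end <- run$end[nrow(run)]
      if ("last_probe" %in% names(run)) out$last_probe <- run$last_probe[nrow(run)]
      out$n_probes <- sum(run$n_probes)
      out$mean_log2 <- sum(run$mean_log2 * run$n_probes) / sum(run$n_probes)
      out
    }))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with exact enumeration of the
#' permutation distribution of U (midranks for ties) when the combined
#' size is at most `exact_max`, and the normal approximation with tie
#' correction otherwise. The two-sided p-value is twice the smaller tail
#' probability, capped at 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest combined sample size for exact enumeration
#'   (default 20).
#' @return List with `U` (number of (x, y) pairs with x > y, counting
#'   ties as 1/2), `p` (two-sided), and `method`.
#' @export
#' @examples
#' mann_whitney_u(c(0, 0, 0, 0), c(2, 2, 3))$p  # 2/35
mann_whitney_u <- function(x, y, exact_max = 20) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (all(pooled == pooled[1]))
    return(list(U = U_obs, p = 1, method = "degenerate"))
  if (N <= exact_max) {
    idx <- utils::combn(N, m)
    Us <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
    eps <- 1e-9
    p_lo <- mean(Us <= U_obs + eps)
    p_hi <- mean(Us >= U_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U_obs, p = p, method = "exact"))
  }
  mu <- m * n / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U_obs, p = 1, method = "normal"))
  z <- (U_obs - mu) / sqrt(sigma2)
  list(U = U_obs, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}
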