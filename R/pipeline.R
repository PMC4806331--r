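#' Pipeline configuration
#'
#' Bundles the tunable parameters of the calling cascade. The probe-count
#' threshold is 50 for the primary analysis and 10 for the secondary,
#' relaxed analysis; the cross-platform criterion is 50% reciprocal
#' overlap, the concordance measure used for array-platform comparison.
#'
#' @param min_probes Minimum consecutive markers per retained segment
#'   (inclusive; default 50).
#' @param reciprocal_fraction Reciprocal-overlap threshold in `(0, 1]`
#'   (default 0.5). Used both for between-platform validation and for the
#'   germline all-organ matching.
#' @param mapd_max,snpqc_min QC gates (see [apply_qc()]).
#' @param tau HMM leave-state probability per probe.
#' @param fraction_grid Mosaic sub-state grid for the HMM.
#' @param center Median-center log2 before segmentation (default off).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_probes = 50, reciprocal_fraction = 0.5,
                            mapd_max = 0.25, snpqc_min = 15,
                            tau = 1e-6,
                            fraction_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            center = FALSE) {
  stopifnot(min_probes >= 1, reciprocal_fraction > 0, reciprocal_fraction <= 1)
  structure(list(min_probes = min_probes,
                 reciprocal_fraction = reciprocal_fraction,
                 mapd_max = mapd_max, snpqc_min = snpqc_min,
                 tau = tau, fraction_grid = fraction_grid, center = center),
            class = "pipeline_config")
}

#' Remove short and copy-neutral segments
#'
#' Keeps segments spanning at least `min_probes` consecutive markers
#' (inclusive bound); diploid (`normal`) segments are dropped regardless
#' of size.
#'
#' @param segments Segments data frame with `n_probes` attached.
#' @param min_probes Inclusive minimum marker count.
#' @return Filtered segments.
#' @export
filter_min_probes <- function(segments, min_probes) {
  segments[segments$event_type != "normal" &
             segments$n_probes >= min_probes, , drop = FALSE]
}

#' Remove non-copy-number segments
#'
#' Drops allelic-imbalance / LOH segments; losses and gains pass. These
#' events are copy-neutral and are excluded from CNV calling.
#'
#' @param segments Segments data frame.
#' @return Segments with `event_type` in `{loss, gain}` (and `normal`,
#'   if still present).
#' @export
drop_non_cnv <- function(segments) {
  segments[segments$event_type != "allelic_imbalance_or_loh", , drop = FALSE]
}

#' Cross-platform validation of one organ's segments
#'
#' Pairs every segment from platform A with every same-type,
#' same-chromosome segment from platform B and keeps pairs passing the
#' reciprocal-overlap criterion on both sides. Matching is one-to-one
#' and greedy by descending overlap-fraction product (ties broken by
#' leftmost interval), so one large segment cannot validate many
#' fragments. Each retained pair becomes a call whose interval is the
#' intersection of the two supports (conservative).
#'
#' @param segs_a,segs_b Post-filter segments of the same (patient, organ)
#'   from the two platforms.
#' @param config A [pipeline_config()].
#' @return Data frame of calls: `chrom`, `start`, `end`, `event_type`,
#'   `n_probes_a`, `n_probes_b`, `mean_log2` (average of the two
#'   supports), plus support intervals.
#' @export
cross_platform_validate <- function(segs_a, segs_b, config = pipeline_config()) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      event_type = character(), n_probes_a = integer(),
                      n_probes_b = integer(), mean_log2 = numeric(),
                      a_start = numeric(), a_end = numeric(),
                      b_start = numeric(), b_end = numeric())
  if (!nrow(segs_a) || !nrow(segs_b)) return(empty)
  cand <- NULL
  for (i in seq_len(nrow(segs_a))) for (j in seq_len(nrow(segs_b))) {
    if (segs_a$chrom[i] != segs_b$chrom[j]) next
    if (segs_a$event_type[i] != segs_b$event_type[j]) next
    ro <- reciprocal_overlap(c(segs_a$start[i], segs_a$end[i]),
                             c(segs_b$start[j], segs_b$end[j]))
    if (all(ro >= config$reciprocal_fraction))
      cand <- rbind(cand, data.frame(i = i, j = j, score = ro[1] * ro[2],
                                     left = min(segs_a$start[i], segs_b$start[j])))
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(-cand$score, cand$left, cand$i, cand$j), , drop = FALSE]
  used_a <- logical(nrow(segs_a)); used_b <- logical(nrow(segs_b))
  out <- NULL
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    iv <- interval_intersect(c(segs_a$start[i], segs_a$end[i]),
                             c(segs_b$start[j], segs_b$end[j]))
    out <- rbind(out, data.frame(
      chrom = segs_a$chrom[i], start = iv[1], end = iv[2],
      event_type = segs_a$event_type[i],
      n_probes_a = segs_a$n_probes[i], n_probes_b = segs_b$n_probes[j],
      mean_log2 = (segs_a$mean_log2[i] + segs_b$mean_log2[j]) / 2,
      a_start = segs_a$start[i], a_end = segs_a$end[i],
      b_start = segs_b$start[j], b_end = segs_b$end[j]))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify calls of one patient as germline, shared-mosaic or private
#'
#' A call is `germline` iff every other assayed organ of the patient has
#' a same-type call passing the reciprocal-overlap criterion with it
#' (the all-organ intersection that removes constitutional variants);
#' `private` iff no other organ has such a call — the operational
#' signature of somatic mosaicism; `shared_mosaic` otherwise. The rule
#' is pairwise and therefore invariant to organ ordering. With a single
#' assayed organ sharing is undefined and all calls are `unclassified`.
#'
#' @param calls Calls data frame for ONE patient, with an `organ` column.
#' @param organs_assayed Character vector of all QC-passing organs of the
#'   patient (including organs with zero calls).
#' @param config A [pipeline_config()].
#' @return `calls` with a `sharing_class` column added.
#' @export
classify_sharing <- function(calls, organs_assayed, config = pipeline_config()) {
  if (!nrow(calls)) { calls$sharing_class <- character(0); return(calls) }
  organs_assayed <- unique(organs_assayed)
  if (length(organs_assayed) < 2) {
    warning("classify_sharing: single assayed organ; sharing undefined")
    calls$sharing_class <- "unclassified"
    return(calls)
  }
  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    others <- setdiff(organs_assayed, calls$organ[i])
    matched <- vapply(others, function(o) {
      cand <- calls[calls$organ == o &
                      calls$chrom == calls$chrom[i] &
                      calls$event_type == calls$event_type[i], , drop = FALSE]
      if (!nrow(cand)) return(FALSE)
      any(vapply(seq_len(nrow(cand)), function(j)
        reciprocal_pass(c(calls$start[i], calls$end[i]),
                        c(cand$start[j], cand$end[j]),
                        config$reciprocal_fraction), TRUE))
    }, TRUE)
    cls[i] <- if (all(matched)) "germline"
    else if (!any(matched)) "private"
    else "shared_mosaic"
  }
  calls$sharing_class <- cls
  calls
}

#' Annotate calls overlapping T-cell receptor loci
#'
#' A call is annotated with a TCR locus name iff its interval overlaps
#' the configured locus by at least 1 bp (the locus with the largest
#' overlap, should a call span two). Deletions at these loci represent
#' physiological RAG-mediated V(D)J rearrangements rather than
#' pathological mosaicism.
#'
#' @param calls Calls data frame.
#' @param genome A [genome_model()] with `tcr_loci`.
#' @return `calls` with a `tcr_locus` column (`NA` when none overlaps).
#' @export
annotate_tcr <- function(calls, genome) {
  ann <- rep(NA_character_, nrow(calls))
  if (nrow(calls)) for (i in seq_len(nrow(calls))) {
    best <- 0
    for (loc in genome$tcr_loci) {
      if (loc$chrom != calls$chrom[i]) next
      ov <- min(calls$end[i], loc$end) - max(calls$start[i], loc$start)
      if (ov >= 1 && ov > best) { best <- ov; ann[i] <- loc$name }
    }
  }
  calls$tcr_locus <- ann
  calls
}

#' Estimate the mosaic cell fraction of a call from its log2 depth
#'
#' Inverts the single-copy mixture dosage model: for a one-copy loss
#' `f = 2 - 2^(1+L)`, for a one-copy gain `f = 2^(1+L) - 2`, with
#' `L` the call's mean log2 ratio; results are clipped to `(0, 1]`.
#' A log2 of the wrong sign for the event type yields `NA` with a
#' warning. Multi-copy events are not solved, only clipped.
#'
#' @param event_type Character vector, `"loss"` or `"gain"`.
#' @param mean_log2 Numeric vector of call mean log2 ratios.
#' @return Numeric vector of estimated fractions in `(0, 1]`, `NA` where
#'   undefined.
#' @export
#' @examples
#' estimate_mosaic_fraction("loss", -1)          # 1: clonal loss
#' estimate_mosaic_fraction("loss", log2(0.75))  # 0.5
#' estimate_mosaic_fraction("gain", log2(1.5))   # 1: clonal gain
estimate_mosaic_fraction <- function(event_type, mean_log2) {
  f <- ifelse(event_type == "loss", 2 - 2^(1 + mean_log2), 2^(1 + mean_log2) - 2)
  bad <- (event_type == "loss" & mean_log2 > 0) |
    (event_type == "gain" & mean_log2 < 0)
  if (any(bad, na.rm = TRUE))
    warning("estimate_mosaic_fraction: log2 sign inconsistent with event type")
  f[bad] <- NA_real_
  pmin(1, pmax(f, 1e-12))
}

#' Compare per-organ private-CNV rates between two groups
#'
#' Two-sided Mann-Whitney U comparison of per-organ organ-private CNV
#' counts (e.g. a fetal cohort against an adult reference averaging
#' ~2.2 CNVs per organ). Exact enumeration for combined n <= 20, normal
#' approximation with tie correction otherwise.
#'
#' @param counts_a,counts_b Non-empty numeric vectors of per-organ counts.
#' @return List with `U` and two-sided `p` (see [mann_whitney_u()]).
#' @export
compare_organ_rates <- function(counts_a, counts_b) {
  mann_whitney_u(counts_a, counts_b)
}
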