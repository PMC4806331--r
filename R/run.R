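#' Run the calling cascade on pre-computed segments
#'
#' Applies, per sample: probe-count filtering, removal of non-CNV
#' (AI/LOH) segments, merging of directly adjacent same-type segments;
#' then per (patient, organ): between-platform intersection at 50%
#' reciprocal overlap; then per patient: the all-organ intersection that
#' classifies calls as germline / shared-mosaic / private, TCR locus
#' annotation and mosaic-fraction estimation. Exists separately from
#' [run_pipeline()] so the two probe-count thresholds (50 and 10) can be
#' compared without re-segmenting.
#'
#' @param segments_by_sample Named list (sample_id -> segments data
#'   frame) as produced by [segment_sample()].
#' @param sheet Sample sheet data frame (`sample_id`, `patient`, `organ`,
#'   `platform`) covering the segmented samples.
#' @param genome A [genome_model()].
#' @param config A [pipeline_config()].
#' @return List with `calls` (all validated calls with sharing class),
#'   `private_calls`, `candidates` (per-platform merged filtered
#'   segments with sample annotation) and `stage_counts`.
#' @export
run_calling <- function(segments_by_sample, sheet, genome,
                        config = pipeline_config()) {
  platforms <- sort(unique(sheet$platform))
  if (length(platforms) != 2)
    stop("run_calling: exactly two platforms are required, got ",
         length(platforms))
  n_seg <- 0; n_filt <- 0; n_merge <- 0
  candidates <- NULL
  merged_by_sample <- list()
  for (sid in names(segments_by_sample)) {
    segs <- segments_by_sample[[sid]]
    n_seg <- n_seg + nrow(segs)
    segs <- filter_min_probes(segs, config$min_probes)
    segs <- drop_non_cnv(segs)
    n_filt <- n_filt + nrow(segs)
    segs <- merge_adjacent(segs)
    n_merge <- n_merge + nrow(segs)
    merged_by_sample[[sid]] <- segs
    if (nrow(segs)) {
      row <- sheet[sheet$sample_id == sid, ]
      candidates <- rbind(candidates,
                          cbind(data.frame(sample_id = sid, patient = row$patient,
                                           organ = row$organ,
                                           platform = row$platform), segs))
    }
  }

  calls <- NULL
  for (pid in unique(sheet$patient)) {
    psheet <- sheet[sheet$patient == pid, ]
    organs <- unique(psheet$organ)
    pcalls <- NULL
    organs_used <- character(0)
    for (org in organs) {
      sids <- psheet$sample_id[psheet$organ == org]
      pf <- psheet$platform[psheet$organ == org]
      if (length(sids) < 2 || !setequal(pf, platforms)) {
        warning("run_calling: ", pid, "/", org,
                " lacks both platforms; organ skipped")
        next
      }
      organs_used <- c(organs_used, org)
      sa <- merged_by_sample[[sids[pf == platforms[1]]]]
      sb <- merged_by_sample[[sids[pf == platforms[2]]]]
      oc <- cross_platform_validate(sa, sb, config)
      if (nrow(oc))
        pcalls <- rbind(pcalls, cbind(data.frame(patient = pid, organ = org), oc))
    }
    if (is.null(pcalls))
      pcalls <- data.frame(patient = character(), organ = character(),
                           chrom = character(), start = numeric(),
                           end = numeric(), event_type = character(),
                           n_probes_a = integer(), n_probes_b = integer(),
                           mean_log2 = numeric(), a_start = numeric(),
                           a_end = numeric(), b_start = numeric(),
                           b_end = numeric())
    if (length(organs_used) >= 2 || nrow(pcalls)) {
      pcalls <- classify_sharing(pcalls, organs_used, config)
      calls <- rbind(calls, pcalls)
    }
  }
  if (is.null(calls))
    calls <- data.frame(patient = character(), organ = character(),
                        chrom = character(), start = numeric(), end = numeric(),
                        event_type = character(), n_probes_a = integer(),
                        n_probes_b = integer(), mean_log2 = numeric(),
                        a_start = numeric(), a_end = numeric(),
                        b_start = numeric(), b_end = numeric(),
                        sharing_class = character())
  calls <- annotate_tcr(calls, genome)
  calls$est_fraction <- if (nrow(calls))
    estimate_mosaic_fraction(calls$event_type, calls$mean_log2) else numeric(0)
  rownames(calls) <- NULL
  private <- calls[calls$sharing_class == "private", , drop = FALSE]
  stage_counts <- data.frame(
    stage = c("segments", "after_probe_and_type_filter", "after_merge",
              "validated_calls", "private_calls"),
    n = c(n_seg, n_filt, n_merge, nrow(calls), nrow(private)))
  list(calls = calls, private_calls = private, candidates = candidates,
       stage_counts = stage_counts)
}

#' Run the full organ-private CNV pipeline on a cohort
#'
#' Executes QC (MAPD + SNPQC gates), joint log2/BAF HMM segmentation of
#' every passing sample, and the calling cascade of [run_calling()].
#' Only organs with both platforms passing QC enter cross-platform
#' validation; the germline test uses all such organs of a patient.
#' Per-sample HMM noise parameters are estimated from the data (log2 sd
#' from MAPD via the Gaussian closed form; BAF sd from the heterozygous
#' cluster spread).
#'
#' @param cohort A `mosaic_cohort` from [simulate_cohort()], or a list
#'   with `signals` (named list of `sample_signals`) and `sheet`.
#' @param genome A [genome_model()].
#' @param config A [pipeline_config()].
#' @return An object of class `mosaicnv_report`: `qc`, `segments`
#'   (per-sample list), `calls`, `private_calls`, `candidates`,
#'   `stage_counts`, `config`.
#' @export
run_pipeline <- function(cohort, genome = default_genome(),
                         config = pipeline_config()) {
  stopifnot(!is.null(cohort$signals), !is.null(cohort$sheet))
  qc <- apply_qc(cohort$signals, mapd_max = config$mapd_max,
                 snpqc_min = config$snpqc_min)
  kept <- qc$kept
  sheet <- cohort$sheet[cohort$sheet$sample_id %in% kept, , drop = FALSE]
  segments <- list()
  for (sid in sheet$sample_id) {
    sig <- cohort$signals[[sid]]
    mapd <- qc$metrics$mapd[qc$metrics$sample_id == sid]
    noise_sd <- max(0.02, mapd / (sqrt(2) * stats::qnorm(0.75)))
    baf <- sig$probes$baf
    het <- baf[!is.na(baf) & baf > 0.4 & baf < 0.6]
    baf_sd <- max(0.01, if (length(het) >= 50) stats::sd(het) else 0.03)
    params <- hmm_params(noise_sd = noise_sd, baf_sd = baf_sd,
                         tau = config$tau,
                         fraction_grid = config$fraction_grid)
    segments[[sid]] <- segment_sample(sig, params, genome = genome,
                                      center = config$center)
  }
  res <- run_calling(segments, sheet, genome, config)
  structure(c(list(qc = qc, segments = segments, config = config), res),
            class = "mosaicnv_report")
}

#' @export
print.mosaicnv_report <- function(x, ...) {
  cat("mosaicnv report\n")
  cat("  samples passing QC:", length(x$qc$kept), "of", nrow(x$qc$metrics), "\n")
  cat("  stage counts:\n")
  for (i in seq_len(nrow(x$stage_counts)))
    cat(sprintf("    %-28s %d\n", x$stage_counts$stage[i], x$stage_counts$n[i]))
  if (nrow(x$private_calls)) {
    cat("  private calls:\n")
    pc <- x$private_calls
    for (i in seq_len(nrow(pc)))
      cat(sprintf("    %s/%s %s:%g-%g %s%s f=%.2f\n", pc$patient[i], pc$organ[i],
                  pc$chrom[i], pc$start[i], pc$end[i], pc$event_type[i],
                  ifelse(is.na(pc$tcr_locus[i]), "",
                         paste0(" [", pc$tcr_locus[i], "]")),
                  pc$est_fraction[i]))
  } else cat("  no private calls\n")
  invisible(x)
}
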