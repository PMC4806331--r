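# On-disk formats: probe signals as gzipped TSV (chrom, pos, log2, baf;
# baf empty for copy-number-only probes), sample sheet as TSV, truth as
# BED6+ with a JSON-ish sidecar left to the caller, segments as SEG-like
# TSV, calls as TSV, private calls as BED. Coordinates are 0-based
# half-open throughout.

#' Write one sample's probe signals as gzipped TSV
#'
#' @param signals A `sample_signals` object.
#' @param path Output path (`.tsv.gz`).
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  p <- signals$probes
  out <- data.frame(chrom = p$chrom, pos = p$pos, log2 = p$log2,
                    baf = ifelse(is.na(p$baf), "", format(p$baf, digits = 8)))
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe signals written by [write_signals()]
#'
#' @param path Input path.
#' @param patient,organ,platform Sample annotation to attach.
#' @return A `sample_signals` object.
#' @export
read_signals <- function(path, patient = "NA", organ = "NA", platform = "NA") {
  d <- utils::read.table(gzfile(path), header = TRUE, sep = "\t",
                         colClasses = c("character", "numeric", "numeric",
                                        "character"))
  baf <- suppressWarnings(as.numeric(d$baf))
  probes <- data.frame(chrom = d$chrom, pos = d$pos, is_snp = !is.na(baf),
                       log2 = d$log2, baf = baf)
  structure(list(patient = patient, organ = organ, platform = platform,
                 probes = probes), class = "sample_signals")
}

#' Write a cohort to a directory
#'
#' One gzipped signal file per (patient, organ, platform), a sample
#' sheet TSV with file paths, and the truth set as BED6+.
#'
#' @param cohort A `mosaic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- cohort$sheet
  sheet$path <- file.path(dir, paste0(sheet$sample_id, ".tsv.gz"))
  for (i in seq_len(nrow(sheet)))
    write_signals(cohort$signals[[sheet$sample_id[i]]], sheet$path[i])
  utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_truth_bed(cohort$truth, file.path(dir, "truth.bed"))
  invisible(dir)
}

#' Write a truth set as BED6+
#'
#' Columns: chrom, start, end, event_id, cell_fraction, type, patient,
#' organ. TCR clone realizations are appended with `tcr_clone` type.
#'
#' @param truth A `truth_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  ev <- truth$events
  bed <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                    name = ev$event_id, score = ev$cell_fraction,
                    type = ifelse(ev$copies < 2, "loss", "gain"),
                    patient = ev$patient, organ = ev$organ)
  cl <- truth$clones
  if (nrow(cl))
    bed <- rbind(bed, data.frame(
      chrom = cl$chrom, start = cl$start, end = cl$end,
      name = paste0(cl$locus, "_clone", cl$clone), score = cl$fraction,
      type = "tcr_clone", patient = cl$patient, organ = cl$organ))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write segments as SEG-like TSV
#'
#' @param segments_by_sample Named list of segments data frames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments_by_sample, path) {
  rows <- lapply(names(segments_by_sample), function(sid) {
    s <- segments_by_sample[[sid]]
    cbind(data.frame(sample = sid),
          s[, c("chrom", "start", "end", "n_probes", "state", "event_type",
                "mean_log2")])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write validated calls as TSV
#'
#' @param calls Calls data frame from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  cols <- c("patient", "organ", "chrom", "start", "end", "event_type",
            "n_probes_a", "n_probes_b", "mean_log2", "sharing_class",
            "tcr_locus", "est_fraction")
  utils::write.table(calls[, intersect(cols, names(calls)), drop = FALSE],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
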