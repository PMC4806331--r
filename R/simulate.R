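#' Expected log2 ratio of a mosaic copy-number event
#'
#' Standard mixture model for array intensity: a fraction `f` of cells
#' carries `copies` copies of the segment, the remainder is diploid, and
#' the probe reports the log2 of mean dosage over cells relative to
#' diploid: `log2((2 * (1 - f) + copies * f) / 2)`. A homozygous clonal
#' deletion would be -Inf; the value is floored at -5 (signal saturation).
#'
#' @param copies Integer copy number in carrier cells (>= 0).
#' @param fraction Carrier cell fraction in `[0, 1]`. Vectorised over both.
#' @return Expected log2 ratio (floored at -5).
#' @export
#' @examples
#' expected_log2(1, 1)    # -1: clonal heterozygous loss
#' expected_log2(1, 0.5)  # log2(0.75)
#' expected_log2(3, 0)    # 0: no carriers
expected_log2 <- function(copies, fraction) {
  stopifnot(all(copies >= 0), all(fraction >= 0), all(fraction <= 1))
  dosage <- (2 * (1 - fraction) + copies * fraction) / 2
  pmax(log2(dosage), -5)
}

#' Lay out probe positions for a platform
#'
#' Distributes `platform$n_probes` markers over the genome proportionally
#' to chromosome length (largest-remainder rounding, at least one probe
#' per chromosome), draws distinct sorted positions uniformly within each
#' chromosome, and flags each marker as SNP or copy-number-only according
#' to `platform$snp_fraction`. Deterministic for a fixed seed.
#'
#' @param genome A [genome_model()].
#' @param platform A [platform_spec()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A data frame of class `probe_map` with columns `chrom`, `pos`
#'   (0-based bp), `is_snp`; attribute `platform` carries the name.
#' @export
build_probe_map <- function(genome, platform, seed = NULL) {
  stopifnot(inherits(genome, "genome_model"), inherits(platform, "platform_spec"))
  if (!is.null(seed)) set.seed(seed)
  chroms <- genome$chromosomes
  n <- platform$n_probes
  if (n < nrow(chroms))
    stop("build_probe_map: n_probes (", n, ") smaller than number of chromosomes")
  # largest-remainder apportionment, min 1 per chromosome
  share <- n * chroms$length / sum(chroms$length)
  alloc <- pmax(1L, floor(share))
  rem <- n - sum(alloc)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(alloc, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      if (alloc[ord[i]] > 1L) { alloc[ord[i]] <- alloc[ord[i]] - 1L; rem <- rem + 1 }
      i <- if (i == length(ord)) 1 else i + 1
    }
  }
  parts <- lapply(seq_len(nrow(chroms)), function(i) {
    pos <- sort(sample.int(chroms$length[i], alloc[i])) - 1
    data.frame(chrom = chroms$name[i], pos = pos)
  })
  map <- do.call(rbind, parts)
  map$is_snp <- stats::runif(nrow(map)) < platform$snp_fraction
  rownames(map) <- NULL
  attr(map, "platform") <- platform$name
  class(map) <- c("probe_map", "data.frame")
  map
}

#' Specify a copy-number event to embed in a simulated patient
#'
#' @param event_id Unique identifier.
#' @param patient Patient id the event belongs to.
#' @param chrom,start,end Half-open genomic interval of the event.
#' @param copies Copy number in carrier cells: integer >= 0, not 2.
#' @param cell_fraction Carrier fraction in `(0, 1]`.
#' @param scope `"germline"` (all organs of the patient, forces
#'   `cell_fraction = 1`) or a character vector of carrier organs.
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(event_id, patient, chrom, start, end, copies,
                       cell_fraction = 1, scope = "germline") {
  copies <- as.integer(copies)
  if (copies == 2L) stop("event_spec: copies must differ from 2")
  if (copies < 0L) stop("event_spec: copies must be >= 0")
  if (!(cell_fraction > 0 && cell_fraction <= 1))
    stop("event_spec: cell_fraction must be in (0, 1]")
  if (!(start < end)) stop("event_spec: start must be < end")
  germline <- identical(scope, "germline")
  if (germline && cell_fraction != 1)
    stop("event_spec: germline events must have cell_fraction = 1")
  structure(list(event_id = as.character(event_id), patient = as.character(patient),
                 chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), copies = copies,
                 cell_fraction = cell_fraction,
                 scope = if (germline) "germline" else as.character(scope)),
            class = "event_spec")
}

#' Specify a polyclonal TCR deletion mixture for one thymus sample
#'
#' Models the physiological outcome of V(D)J recombination in a polyclonal
#' thymus: many independent T-cell clones each carry a one-copy deletion of
#' a different sub-interval of a TCR locus, so the per-probe deleted cell
#' fraction is a step function (the sum of fractions of clones whose
#' deletion covers the probe). Clone intervals are drawn at simulation
#' time: start uniform within the locus, width uniform between `min_width`
#' and `max_width_frac` of the locus width, truncated at the locus end.
#'
#' @param patient,organ Sample the mixture applies to (default organ
#'   `"thymus"`).
#' @param locus TCR locus name (must exist in the genome model).
#' @param clone_fractions Numeric vector of per-clone cell fractions;
#'   must sum to <= 1.
#' @param min_width Minimum clone deletion width in bp (default 5000,
#'   the scale of the smallest rearrangements the pipeline should see).
#' @param max_width_frac Maximum clone width as a fraction of locus width.
#' @return An object of class `tcr_polyclonal_spec`.
#' @export
tcr_polyclonal_spec <- function(patient, locus, clone_fractions,
                                organ = "thymus", min_width = 5000,
                                max_width_frac = 1) {
  stopifnot(length(clone_fractions) >= 1, all(clone_fractions > 0))
  if (sum(clone_fractions) > 1 + 1e-12)
    stop("tcr_polyclonal_spec: clone fractions must sum to <= 1")
  structure(list(patient = as.character(patient), organ = as.character(organ),
                 locus = as.character(locus),
                 clone_fractions = as.numeric(clone_fractions),
                 min_width = min_width, max_width_frac = max_width_frac),
            class = "tcr_polyclonal_spec")
}

probes_in <- function(map, chrom, start, end) {
  which(map$chrom == chrom & map$pos >= start & map$pos < end)
}

# Per-probe deleted cell fraction under a clone mixture: sum of fractions
# of clones whose deletion interval covers the probe.
clone_deleted_fraction <- function(map, clones) {
  f <- numeric(nrow(map))
  for (k in seq_len(nrow(clones))) {
    idx <- probes_in(map, clones$chrom[k], clones$start[k], clones$end[k])
    f[idx] <- f[idx] + clones$fraction[k]
  }
  f
}

# Shift het-probe BAF means for a one-copy loss / one-copy gain at
# fraction f; the lost/gained physical allele is random per probe because
# phase is arbitrary marker to marker.
shift_het_baf <- function(baf_mean, idx_het, f, kind) {
  if (!length(idx_het)) return(baf_mean)
  side <- stats::runif(length(idx_het)) < 0.5
  if (kind == "loss") {
    mu <- 0.5 * (1 - f) / (1 - f / 2)       # B allele lost
  } else {
    mu <- (1 + f) / (2 + f)                 # B allele gained (upper band)
    mu <- 1 - mu                            # expressed as lower band below
  }
  baf_mean[idx_het] <- ifelse(side, mu, 1 - mu)
  baf_mean
}

#' Simulate a multi-patient, multi-organ, dual-platform cohort
#'
#' Each (patient, organ) pair is assayed once on every platform: the two
#' platforms share the same underlying truth (genotypes are redrawn per
#' probe since the probe maps differ, but embedded events are identical)
#' while probe positions and noise are independent. Per-probe log2 ratio
#' is the expected mixture dosage of the locally applicable events plus
#' Gaussian noise; BAF is generated from genotypes drawn AA/AB/BB at
#' 0.25/0.5/0.25, shifted by the event's allelic state, plus Gaussian
#' noise, clipped to `[0, 1]` (NA for copy-number-only probes). TCR loci
#' with a polyclonal clone mixture use the per-probe deleted fraction.
#'
#' @param genome A [genome_model()].
#' @param platforms List of [platform_spec()] objects.
#' @param patients List of `list(id =, organs =)` entries.
#' @param events List of [event_spec()] objects. Events applying to the
#'   same (patient, organ) must not overlap.
#' @param tcr List of [tcr_polyclonal_spec()] objects.
#' @param seed Integer seed fixing every random draw.
#' @return An object of class `mosaic_cohort`: a list with `signals`
#'   (named list of `sample_signals`), `sheet` (sample sheet data frame),
#'   `maps` (per-platform probe maps) and `truth` (a `truth_set`).
#' @export
simulate_cohort <- function(genome, platforms, patients, events = list(),
                            tcr = list(), seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.null(seed)) set.seed(seed)
  organ_of <- stats::setNames(
    lapply(patients, `[[`, "organs"),
    vapply(patients, function(p) as.character(p$id), "")
  )
  if (anyDuplicated(names(organ_of))) stop("simulate_cohort: duplicated patient ids")

  # --- validate event scopes and pairwise overlap per (patient, organ)
  ev_rows <- lapply(events, function(e) {
    if (!e$patient %in% names(organ_of))
      stop("event ", e$event_id, ": unknown patient ", e$patient)
    organs <- if (identical(e$scope, "germline")) organ_of[[e$patient]] else e$scope
    bad <- setdiff(organs, organ_of[[e$patient]])
    if (length(bad))
      stop("event ", e$event_id, ": organs not assayed for patient: ",
           paste(bad, collapse = ", "))
    ci <- match(e$chrom, genome$chromosomes$name)
    if (is.na(ci)) stop("event ", e$event_id, ": unknown chromosome ", e$chrom)
    if (e$start < 0 || e$end > genome$chromosomes$length[ci])
      stop("event ", e$event_id, ": interval outside chromosome")
    data.frame(event_id = e$event_id, patient = e$patient, organ = organs,
               chrom = e$chrom, start = e$start, end = e$end,
               copies = e$copies, cell_fraction = e$cell_fraction,
               scope_class = if (identical(e$scope, "germline")) "germline" else "mosaic")
  })
  ev <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event_id = character(), patient = character(), organ = character(),
               chrom = character(), start = numeric(), end = numeric(),
               copies = integer(), cell_fraction = numeric(),
               scope_class = character())
  if (nrow(ev) > 1) {
    sp <- split(ev, list(ev$patient, ev$organ), drop = TRUE)
    for (g in sp) if (nrow(g) > 1) {
      g <- g[order(g$chrom, g$start), ]
      for (i in seq_len(nrow(g) - 1))
        if (g$chrom[i] == g$chrom[i + 1] && g$end[i] > g$start[i + 1])
          stop("simulate_cohort: overlapping events ", g$event_id[i], " and ",
               g$event_id[i + 1], " in ", g$patient[i], "/", g$organ[i])
    }
  }
  loci <- stats::setNames(genome$tcr_loci,
                          vapply(genome$tcr_loci, `[[`, "", "name"))
  for (tp in tcr) {
    if (!tp$locus %in% names(loci))
      stop("tcr spec: locus ", tp$locus, " not in genome model")
    if (!tp$patient %in% names(organ_of) || !tp$organ %in% organ_of[[tp$patient]])
      stop("tcr spec: patient/organ not in cohort: ", tp$patient, "/", tp$organ)
    loc <- loci[[tp$locus]]
    hit <- ev$patient == tp$patient & ev$organ == tp$organ &
      ev$chrom == loc$chrom & ev$start < loc$end & ev$end > loc$start
    if (any(hit))
      stop("simulate_cohort: event overlaps TCR locus ", tp$locus,
           " carrying a clone mixture in ", tp$patient, "/", tp$organ)
  }

  # --- realize TCR clone intervals (before per-sample noise, so the two
  # platforms of one sample share identical clones)
  clone_rows <- lapply(tcr, function(tp) {
    loc <- loci[[tp$locus]]
    width_lo <- tp$min_width
    width_hi <- max(width_lo, tp$max_width_frac * (loc$end - loc$start))
    n <- length(tp$clone_fractions)
    w <- stats::runif(n, width_lo, width_hi)
    s <- loc$start + stats::runif(n) * pmax(0, (loc$end - loc$start) - w)
    e <- pmin(loc$end, s + w)
    data.frame(patient = tp$patient, organ = tp$organ, locus = tp$locus,
               clone = seq_len(n), chrom = loc$chrom,
               start = floor(s), end = ceiling(e),
               fraction = tp$clone_fractions)
  })
  clones <- if (length(clone_rows)) do.call(rbind, clone_rows) else
    data.frame(patient = character(), organ = character(), locus = character(),
               clone = integer(), chrom = character(), start = numeric(),
               end = numeric(), fraction = numeric())

  maps <- lapply(platforms, function(p) build_probe_map(genome, p))
  names(maps) <- vapply(platforms, `[[`, "", "name")
  maps <- disjoint_maps(maps, genome)

  signals <- list()
  sheet <- NULL
  for (pid in names(organ_of)) for (org in organ_of[[pid]]) {
    ev_here <- ev[ev$patient == pid & ev$organ == org, , drop = FALSE]
    cl_here <- clones[clones$patient == pid & clones$organ == org, , drop = FALSE]
    for (pf in platforms) {
      map <- maps[[pf$name]]
      sig <- simulate_sample(map, pf, ev_here, cl_here, pid, org)
      sid <- paste(pid, org, pf$name, sep = ".")
      signals[[sid]] <- sig
      sheet <- rbind(sheet, data.frame(sample_id = sid, patient = pid,
                                       organ = org, platform = pf$name))
    }
  }
  truth <- structure(list(events = ev, clones = clones), class = "truth_set")
  structure(list(signals = signals, sheet = sheet, maps = maps, truth = truth),
            class = "mosaic_cohort")
}

# one (patient, organ, platform) draw; consumes the ambient RNG stream
simulate_sample <- function(map, platform, ev_here, cl_here, patient, organ) {
  n <- nrow(map)
  geno <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  l2_mean <- numeric(n)
  baf_mean <- geno / 2
  uniform_baf <- logical(n)
  for (i in seq_len(nrow(ev_here))) {
    idx <- probes_in(map, ev_here$chrom[i], ev_here$start[i], ev_here$end[i])
    if (!length(idx)) next
    cp <- ev_here$copies[i]; f <- ev_here$cell_fraction[i]
    l2_mean[idx] <- expected_log2(cp, f)
    het <- idx[geno[idx] == 1L]
    if (cp == 1L) baf_mean <- shift_het_baf(baf_mean, het, f, "loss")
    if (cp == 3L) baf_mean <- shift_het_baf(baf_mean, het, f, "gain")
    if (cp == 0L && f == 1) uniform_baf[idx] <- TRUE
    # cp == 0 mosaic leaves het BAF at 0.5 (both alleles lost equally);
    # cp == 4 modelled as doubling both alleles: bands unchanged
  }
  if (nrow(cl_here)) {
    fdel <- clone_deleted_fraction(map, cl_here)
    idx <- which(fdel > 0)
    l2_mean[idx] <- pmax(log2(1 - fdel[idx] / 2), -5)
    for (j in idx[geno[idx] == 1L]) {
      side <- stats::runif(1) < 0.5
      mu <- 0.5 * (1 - fdel[j]) / (1 - fdel[j] / 2)
      baf_mean[j] <- if (side) mu else 1 - mu
    }
  }
  log2r <- l2_mean + stats::rnorm(n, 0, platform$noise_sd)
  baf_mean[uniform_baf] <- stats::runif(sum(uniform_baf))
  baf <- pmin(1, pmax(0, baf_mean + stats::rnorm(n, 0, platform$baf_sd)))
  baf[!map$is_snp] <- NA_real_
  probes <- data.frame(chrom = map$chrom, pos = map$pos, is_snp = map$is_snp,
                       log2 = log2r, baf = baf)
  structure(list(patient = patient, organ = organ, platform = platform$name,
                 probes = probes),
            class = "sample_signals")
}

#' @export
print.sample_signals <- function(x, ...) {
  cat(sprintf("sample_signals: %s / %s on %s — %d probes (%d SNP)\n",
              x$patient, x$organ, x$platform, nrow(x$probes),
              sum(x$probes$is_snp)))
  invisible(x)
}

#' @export
print.mosaic_cohort <- function(x, ...) {
  cat(sprintf("mosaic_cohort: %d samples, %d truth events, %d TCR clones\n",
              length(x$signals), nrow(x$truth$events), nrow(x$truth$clones)))
  invisible(x)
}

# Different platforms interrogate different physical markers: nudge any
# cross-platform position collision so the maps share no probe position.
disjoint_maps <- function(maps, genome) {
  len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  keys <- unlist(lapply(maps, function(m) paste0(m$chrom, ":", m$pos)))
  n_per <- vapply(maps, nrow, 0L)
  platform_of <- rep(seq_along(maps), n_per)
  row_of <- unlist(lapply(n_per, seq_len))
  taken <- new.env(hash = TRUE)
  for (k in which(!duplicated(keys))) taken[[keys[k]]] <- TRUE
  for (k in which(duplicated(keys))) {
    m <- platform_of[k]; i <- row_of[k]
    key <- keys[k]
    while (!is.null(taken[[key]])) {
      maps[[m]]$pos[i] <- if (maps[[m]]$pos[i] + 1 < len[[maps[[m]]$chrom[i]]])
        maps[[m]]$pos[i] + 1 else maps[[m]]$pos[i] - 2
      key <- paste0(maps[[m]]$chrom[i], ":", maps[[m]]$pos[i])
    }
    taken[[key]] <- TRUE
  }
  lapply(maps, function(m) {
    m <- m[order(match(m$chrom, genome$chromosomes$name), m$pos), ]
    rownames(m) <- NULL
    m
  })
}

#' Simulate interphase FISH signal counts
#'
#' Per nucleus and per probe, the observed count equals the true count
#' minus one with probability `p_loss` (probe overlap or hybridisation
#' failure), plus one with probability `p_gain` (split signals), and is
#' exact otherwise; counts are floored at zero. In dual mode the two
#' probes err independently given the nucleus.
#'
#' @param true_count True signal count per nucleus (>= 0).
#' @param n_nuclei Number of nuclei to score.
#' @param p_loss,p_gain Per-probe error probabilities, `p_loss + p_gain <= 1`.
#' @param dual If `TRUE`, two probes on the same chromosome per nucleus.
#' @param tissue Optional tissue label attached to the output.
#' @param seed Optional integer seed.
#' @return Data frame with columns `tissue`, `nucleus`, `count1` and, in
#'   dual mode, `count2`; attribute `mode` is `"single"` or `"dual"`.
#' @export
simulate_fish_counts <- function(true_count, n_nuclei, p_loss, p_gain,
                                 dual = FALSE, tissue = "tissue", seed = NULL) {
  stopifnot(true_count >= 0, n_nuclei >= 1, p_loss >= 0, p_gain >= 0,
            p_loss + p_gain <= 1)
  if (!is.null(seed)) set.seed(seed)
  draw <- function() {
    delta <- sample(c(-1L, 0L, 1L), n_nuclei, replace = TRUE,
                    prob = c(p_loss, 1 - p_loss - p_gain, p_gain))
    pmax(0L, true_count + delta)
  }
  out <- data.frame(tissue = tissue, nucleus = seq_len(n_nuclei),
                    count1 = draw())
  if (dual) out$count2 <- draw()
  attr(out, "mode") <- if (dual) "dual" else "single"
  out
}
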