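#' Hidden Markov model parameters for joint log2/BAF segmentation
#'
#' Builds the state set for a copy-number HMM that uses both the
#' log2-ratio and the B-allele-frequency channel. The core states are
#' copy numbers 0-4 plus a copy-neutral allelic-imbalance/LOH state;
#' copy 1 (loss) and copy 3 (gain) are expanded over a grid of carrier
#' cell fractions into mosaic sub-states so that subclonal events can be
#' decoded — a pure-clonal state set cannot represent them. The reported
#' `event_type` collapses sub-states back to loss/gain.
#'
#' Each state carries a Gaussian log2 emission (mean = expected dosage of
#' the state's copy/fraction, sd = `noise_sd`) and a Gaussian-mixture BAF
#' emission over genotype bands:
#' * diploid: bands 0 / 0.5 / 1 with weights 0.25 / 0.5 / 0.25;
#' * mosaic one-copy loss at fraction f: the heterozygous band splits to
#'   `0.5 (1-f) / (1-f/2)` and its mirror (allelic dosage algebra);
#' * mosaic one-copy gain at f: het bands at `1/(2+f)` and `(1+f)/(2+f)`;
#' * AI/LOH: homozygote bands plus mirrored het bands at
#'   `0.5 +/- ai_offsets`, log2 mean 0;
#' * copy 0 (clonal homozygous deletion): no genotype signal — uniform
#'   BAF emission.
#' Copy-number-only probes contribute the log2 term only.
#'
#' @param noise_sd Log2-ratio sd per probe.
#' @param baf_sd BAF sd per probe.
#' @param tau Per-probe probability of leaving the current state (shared
#'   uniformly among the other states). The default 1e-6 encodes a strong
#'   persistence prior, appropriate at high marker density.
#' @param fraction_grid Cell fractions for the mosaic loss/gain sub-states.
#' @param ai_offsets Het-band offsets from 0.5 for the AI/LOH state.
#' @return An object of class `hmm_params` with elements `states` (data
#'   frame: `state`, `copies`, `fraction`, `event_type`, `log2_mean`),
#'   `baf_bands` (per-state list of `means`/`weights`, `NULL` = uniform),
#'   `noise_sd`, `baf_sd`, `tau`.
#' @export
hmm_params <- function(noise_sd = 0.21, baf_sd = 0.03, tau = 1e-6,
                       fraction_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                       ai_offsets = c(0.15, 0.35)) {
  stopifnot(noise_sd > 0, baf_sd > 0, tau > 0, tau < 0.5,
            all(fraction_grid > 0), all(fraction_grid <= 1))
  fraction_grid <- sort(unique(fraction_grid))
  rows <- list(data.frame(state = "CN2", copies = 2L, fraction = 1,
                          event_type = "normal"))
  bands <- list(CN2 = list(means = c(0, 0.5, 1), weights = c(0.25, 0.5, 0.25)))
  for (f in fraction_grid) {
    nm <- sprintf("CN1_f%02d", round(100 * f))
    rows[[length(rows) + 1]] <- data.frame(state = nm, copies = 1L, fraction = f,
                                           event_type = "loss")
    mu <- 0.5 * (1 - f) / (1 - f / 2)
    bands[[nm]] <- list(means = c(0, mu, 1 - mu, 1), weights = rep(0.25, 4))
  }
  for (f in fraction_grid) {
    nm <- sprintf("CN3_f%02d", round(100 * f))
    rows[[length(rows) + 1]] <- data.frame(state = nm, copies = 3L, fraction = f,
                                           event_type = "gain")
    lo <- 1 / (2 + f)
    bands[[nm]] <- list(means = c(0, lo, 1 - lo, 1), weights = rep(0.25, 4))
  }
  rows[[length(rows) + 1]] <- data.frame(state = "CN0", copies = 0L, fraction = 1,
                                         event_type = "loss")
  bands$CN0 <- NULL  # uniform BAF: no genotype signal in a homozygous deletion
  rows[[length(rows) + 1]] <- data.frame(state = "CN4", copies = 4L, fraction = 1,
                                         event_type = "gain")
  bands$CN4 <- list(means = c(0, 0.25, 0.5, 0.75, 1),
                    weights = c(0.25, 0.125, 0.25, 0.125, 0.25))
  rows[[length(rows) + 1]] <- data.frame(state = "AILOH", copies = 2L, fraction = 1,
                                         event_type = "allelic_imbalance_or_loh")
  het <- sort(c(0.5 - ai_offsets, 0.5 + ai_offsets))
  bands$AILOH <- list(means = c(0, het, 1),
                      weights = c(0.25, rep(0.5 / length(het), length(het)), 0.25))
  states <- do.call(rbind, rows)
  states$log2_mean <- expected_log2(states$copies, states$fraction)
  states$log2_mean[states$state == "AILOH"] <- 0
  structure(list(states = states,
                 baf_bands = bands[states$state],
                 noise_sd = noise_sd, baf_sd = baf_sd, tau = tau),
            class = "hmm_params")
}

# n x K matrix of per-probe per-state emission log densities
emission_matrix <- function(probes, params) {
  st <- params$states
  n <- nrow(probes); K <- nrow(st)
  E <- matrix(0, n, K)
  snp <- probes$is_snp & !is.na(probes$baf)
  for (k in seq_len(K)) {
    E[, k] <- stats::dnorm(probes$log2, st$log2_mean[k], params$noise_sd, log = TRUE)
    band <- params$baf_bands[[k]]
    if (any(snp) && !is.null(band)) {
      dens <- numeric(sum(snp))
      for (j in seq_along(band$means))
        dens <- dens + band$weights[j] *
          stats::dnorm(probes$baf[snp], band$means[j], params$baf_sd)
      E[snp, k] <- E[snp, k] + log(pmax(dens, 1e-300))
    }
    # uniform-BAF states (band NULL): density 1 on [0,1] -> log contribution 0
  }
  colnames(E) <- st$state
  E
}

#' Emission log-likelihood of one probe under one HMM state
#'
#' Sum of the Gaussian log density of the log2 ratio around the state's
#' expected dosage and, for SNP probes, the log density of the BAF under
#' the state's genotype-band mixture.
#'
#' @param log2 Probe log2 ratio.
#' @param baf Probe BAF (`NA` for a copy-number-only probe).
#' @param state State name from `params$states$state`.
#' @param params An [hmm_params()] object.
#' @return Scalar log density.
#' @export
emission_loglik <- function(log2, baf, state, params = hmm_params()) {
  k <- match(state, params$states$state)
  if (is.na(k)) stop("emission_loglik: unknown state ", state)
  probes <- data.frame(chrom = "x", pos = 0, is_snp = !is.na(baf),
                       log2 = log2, baf = baf)
  unname(emission_matrix(probes, params)[1, k])
}

viterbi_decode <- function(E, params) {
  K <- ncol(E)
  log_init <- rep(-log(K), K)
  lt <- matrix(log(params$tau / (K - 1)), K, K)
  diag(lt) <- log(1 - params$tau)
  .viterbi_cpp(E, log_init, lt)
}

#' Segment one sample with the joint log2/BAF HMM
#'
#' Runs per-chromosome Viterbi decoding under `params` and collapses runs
#' of probes sharing a state into segments. Segment bp boundaries are the
#' midpoints between adjacent probes of differing state, so that the
#' coordinates are platform-independent (needed for cross-platform
#' reciprocal overlap); terminal segments extend to the chromosome ends
#' when a genome model is supplied, otherwise to the probe span.
#'
#' @param signals A `sample_signals` object (probes sorted by position
#'   within chromosome; the sample should have passed QC).
#' @param params An [hmm_params()]; default built from the signal's
#'   platform defaults.
#' @param genome Optional [genome_model()] supplying chromosome lengths
#'   for terminal segment boundaries.
#' @param center If `TRUE`, median-center the log2 ratios first (off by
#'   default; simulated data are already centred).
#' @return Data frame of class `segments`: `chrom`, `start`, `end`,
#'   `first_probe`, `last_probe`, `n_probes`, `state`, `event_type`,
#'   `mean_log2`. Segments tile each chromosome.
#' @export
segment_sample <- function(signals, params = hmm_params(), genome = NULL,
                           center = FALSE) {
  stopifnot(inherits(signals, "sample_signals"))
  probes <- signals$probes
  if (center) probes$log2 <- probes$log2 - stats::median(probes$log2)
  chrom_len <- NULL
  if (!is.null(genome))
    chrom_len <- stats::setNames(genome$chromosomes$length,
                                 genome$chromosomes$name)
  out <- list()
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    p <- probes[idx, , drop = FALSE]
    if (is.unsorted(p$pos, strictly = TRUE))
      stop("segment_sample: probe positions not strictly increasing on ", ch)
    cstart <- 0
    cend <- if (!is.null(chrom_len) && ch %in% names(chrom_len))
      unname(chrom_len[ch]) else max(p$pos) + 1
    if (nrow(p) < 2) {
      warning("segment_sample: chromosome ", ch,
              " has < 2 probes; emitting a single diploid segment")
      out[[ch]] <- data.frame(chrom = ch, start = cstart, end = cend,
                              first_probe = idx[1], last_probe = idx[length(idx)],
                              n_probes = nrow(p), state = "CN2",
                              event_type = "normal",
                              mean_log2 = mean(p$log2))
      next
    }
    E <- emission_matrix(p, params)
    path <- viterbi_decode(E, params)
    r <- rle(path)
    last <- cumsum(r$lengths)
    first <- c(1L, utils::head(last, -1) + 1L)
    mid <- floor((p$pos[utils::head(last, -1)] + p$pos[utils::head(last, -1) + 1L]) / 2)
    seg_start <- c(cstart, mid)
    seg_end <- c(mid, cend)
    st <- params$states[r$values, ]
    out[[ch]] <- data.frame(
      chrom = ch, start = seg_start, end = seg_end,
      first_probe = idx[first], last_probe = idx[last],
      n_probes = r$lengths, state = st$state, event_type = st$event_type,
      mean_log2 = vapply(seq_along(first), function(i)
        mean(p$log2[first[i]:last[i]]), 0)
    )
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  class(segs) <- c("segments", "data.frame")
  segs
}

#' Recount probes per segment against a probe map
#'
#' Sets each segment's `n_probes` to the number of map probes whose
#' position falls in the segment's half-open interval.
#'
#' @param segments A segments data frame.
#' @param probe_map A `probe_map` (or any data frame with `chrom`, `pos`).
#' @return The segments with `n_probes` recomputed.
#' @export
attach_probe_counts <- function(segments, probe_map) {
  segments$n_probes <- vapply(seq_len(nrow(segments)), function(i) {
    sum(probe_map$chrom == segments$chrom[i] &
          probe_map$pos >= segments$start[i] &
          probe_map$pos < segments$end[i])
  }, 0L)
  segments
}
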