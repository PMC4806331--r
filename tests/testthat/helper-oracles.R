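# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles deliberately avoid the package's own code paths.

# --- per-base interval oracle (integer coordinates, half-open)
bases_of <- function(iv) if (iv[1] >= iv[2]) integer(0) else seq(iv[1], iv[2] - 1)

oracle_overlap_len <- function(a, b) length(intersect(bases_of(a), bases_of(b)))

oracle_reciprocal <- function(a, b) {
  ov <- oracle_overlap_len(a, b)
  c(ov / length(bases_of(a)), ov / length(bases_of(b)))
}

oracle_intersect <- function(a, b) {
  ab <- intersect(bases_of(a), bases_of(b))
  if (!length(ab)) NULL else c(min(ab), max(ab) + 1)
}

# merge abutting same-type runs by painting bases
oracle_merge <- function(df) {
  out <- NULL
  for (ty in unique(df$event_type)) {
    g <- df[df$event_type == ty, , drop = FALSE]
    covered <- sort(unique(unlist(lapply(seq_len(nrow(g)), function(i)
      bases_of(c(g$start[i], g$end[i]))))))
    if (!length(covered)) next
    brk <- cumsum(c(1, diff(covered) != 1))
    for (b in unique(brk)) {
      seg <- covered[brk == b]
      # only merged if the original segments abut exactly; gaps break runs
      out <- rbind(out, data.frame(start = min(seg), end = max(seg) + 1,
                                   event_type = ty))
    }
  }
  out[order(out$start, out$event_type), , drop = FALSE]
}

# --- exhaustive Viterbi oracle: enumerate all K^n paths
oracle_viterbi <- function(E, log_init, log_trans) {
  n <- nrow(E); K <- ncol(E)
  score <- log_init + E[1, ]
  paths <- matrix(seq_len(K), ncol = 1)
  for (t in seq_len(n - 1) + 1) {
    m <- nrow(paths)
    prev_last <- paths[, ncol(paths)]
    score <- rep(score, each = K) +
      log_trans[cbind(rep(prev_last, each = K), rep.int(seq_len(K), m))] +
      rep.int(E[t, ], m)
    paths <- cbind(paths[rep(seq_len(m), each = K), , drop = FALSE],
                   rep.int(seq_len(K), m))
  }
  best <- which.max(score)
  list(path = paths[best, ], score = score[best])
}

# --- full-enumeration Mann-Whitney oracle (midranks for ties)
oracle_mwu_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  pooled <- c(x, y); r <- rank(pooled)
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  Us <- apply(utils::combn(N, m), 2, function(id) sum(r[id]) - m * (m + 1) / 2)
  eps <- 1e-9
  min(1, 2 * min(mean(Us <= U_obs + eps), mean(Us >= U_obs - eps)))
}

# --- Fisher 2x2 oracle: sum hypergeometric probabilities <= observed
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# --- small fixture builders
make_signals <- function(log2, baf = rep(NA_real_, length(log2)),
                         chrom = rep("chr1", length(log2)),
                         pos = NULL, patient = "p", organ = "o",
                         platform = "pf") {
  if (is.null(pos))
    pos <- unlist(lapply(split(seq_along(log2), chrom)[unique(chrom)],
                         seq_along)) * 1000
  structure(list(patient = patient, organ = organ, platform = platform,
                 probes = data.frame(chrom = chrom, pos = pos,
                                     is_snp = !is.na(baf), log2 = log2,
                                     baf = baf)),
            class = "sample_signals")
}

small_genome <- function(len = 20e6, tcr = FALSE) {
  loci <- if (tcr) list(tcr_locus("TCRG", "chr1", 8e6, 8.3e6)) else list()
  genome_model(data.frame(name = "chr1", length = len), loci)
}

# cohort used by several end-to-end tests: 2 patients x 3 organs,
# germline-only events, scaled platforms
germline_only_cohort <- function(seed, scale = 0.4) {
  genome <- default_genome()
  platforms <- default_platforms(scale = scale)
  patients <- list(list(id = "p1", organs = c("heart", "liver", "thymus")),
                   list(id = "p2", organs = c("heart", "lung", "kidney")))
  events <- list(
    event_spec("g1", "p1", "chr1", 30e6, 32.5e6, copies = 1, scope = "germline"),
    event_spec("g2", "p1", "chr3", 5e6, 7.5e6, copies = 3, scope = "germline"),
    event_spec("g3", "p2", "chr2", 30e6, 33e6, copies = 1, scope = "germline"),
    event_spec("g4", "p2", "chr1", 45e6, 47.5e6, copies = 3, scope = "germline"))
  list(genome = genome,
       cohort = simulate_cohort(genome, platforms, patients, events,
                                seed = seed))
}

# cohort with organ-private mosaic deletions and thymus TCRG/TCRD clone
# mixtures of aggregate fraction >= 0.4
private_event_cohort <- function(seed, scale = 0.6) {
  genome <- default_genome()
  platforms <- default_platforms(scale = scale)
  patients <- list(list(id = "p1", organs = c("heart", "liver", "thymus")))
  events <- list(
    event_spec("germ", "p1", "chr1", 40e6, 42.5e6, copies = 1, scope = "germline"),
    event_spec("priv_liver", "p1", "chr3", 5e6, 7e6, copies = 1,
               cell_fraction = 0.6, scope = "liver"),
    event_spec("priv_heart", "p1", "chr2", 30e6, 32.5e6, copies = 1,
               cell_fraction = 0.4, scope = "heart"))
  tcr <- list(
    tcr_polyclonal_spec("p1", "TCRG", rep(0.2, 3), min_width = 225e3,
                        max_width_frac = 0.95),
    tcr_polyclonal_spec("p1", "TCRD", rep(0.2, 3), min_width = 300e3,
                        max_width_frac = 0.95))
  list(genome = genome,
       cohort = simulate_cohort(genome, platforms, patients, events, tcr,
                                seed = seed))
}
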