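#' Single-probe aneusomy index
#'
#' Fraction of scored nuclei whose signal count differs from the
#' expected (disomic) count. With a single probe, every technical
#' hybridisation failure or split signal is indistinguishable from a
#' genuine monosomy/trisomy, so the index carries the full per-probe
#' error rate as background.
#'
#' @param counts Integer vector of per-nucleus signal counts, or a data
#'   frame from [simulate_fish_counts()] in single mode.
#' @param expected_count Disomic expectation (default 2).
#' @return Aneusomy index in `[0, 1]`.
#' @export
aneusomy_index <- function(counts, expected_count = 2) {
  if (is.data.frame(counts)) counts <- counts$count1
  if (!length(counts)) stop("aneusomy_index: no observations")
  mean(counts != expected_count)
}

#' Classify a dual-probe FISH signal pattern
#'
#' Two probes on the same chromosome: `(2, 2)` is disomic; the same
#' non-disomic count for both probes (`(k, k)`, k != 2) is true
#' aneusomy — both probes agree the chromosome is missing or extra;
#' unequal counts are technical noise, which would have been a false
#' positive under single-probe scoring. Counts above 5 are binned to 5
#' before classification (scoring practice caps distinguishable
#' signals). The rule is symmetric in the two counts.
#'
#' @param count1,count2 Non-negative integer vectors of per-nucleus
#'   signal counts (vectorised).
#' @param expected_count Disomic expectation (default 2).
#' @return Character vector: `"disomic"`, `"true_aneusomy"` or `"noise"`.
#' @export
#' @examples
#' classify_dual(2, 2)  # disomic
#' classify_dual(1, 1)  # true_aneusomy (monosomy)
#' classify_dual(2, 3)  # noise
classify_dual <- function(count1, count2, expected_count = 2) {
  stopifnot(all(count1 >= 0), all(count2 >= 0))
  c1 <- pmin(count1, 5L); c2 <- pmin(count2, 5L)
  ifelse(c1 != c2, "noise",
         ifelse(c1 == expected_count, "disomic", "true_aneusomy"))
}

#' Summarise FISH observations for one tissue
#'
#' @param observations Data frame from [simulate_fish_counts()] (or with
#'   the same columns); attribute `mode` or presence of `count2` decides
#'   single vs dual scoring.
#' @param expected_count Disomic expectation (default 2).
#' @param min_nuclei Scoring-depth flag threshold (default 200 nuclei).
#' @return One-row data frame of class `fish_summary`: `tissue`,
#'   `n_nuclei`, `mode`, and either `aneusomy_index` (single) or the
#'   `disomic` / `true_aneusomy` / `noise` tallies (dual), plus
#'   `depth_ok`.
#' @export
summarize_fish <- function(observations, expected_count = 2, min_nuclei = 200) {
  dual <- "count2" %in% names(observations)
  tissue <- if ("tissue" %in% names(observations))
    as.character(observations$tissue[1]) else "tissue"
  n <- nrow(observations)
  out <- data.frame(tissue = tissue, n_nuclei = n,
                    mode = if (dual) "dual" else "single",
                    depth_ok = n >= min_nuclei)
  if (dual) {
    cls <- classify_dual(observations$count1, observations$count2, expected_count)
    out$disomic <- sum(cls == "disomic")
    out$true_aneusomy <- sum(cls == "true_aneusomy")
    out$noise <- sum(cls == "noise")
  } else {
    out$aneusomy_index <- aneusomy_index(observations$count1, expected_count)
  }
  class(out) <- c("fish_summary", "data.frame")
  out
}

#' Compare dual-probe noise rates between two tissues
#'
#' Builds the 2x2 table `[noise, non-noise] x [tissue A, tissue B]` from
#' dual-mode tallies and tests it with Fisher's exact test (two-sided by
#' the convention of summing all tables whose hypergeometric probability
#' does not exceed the observed one). Elevated noise in one tissue
#' indicates method artefact rather than genuine aneusomy.
#'
#' @param summary_a,summary_b Dual-mode rows from [summarize_fish()].
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `p`, the 2x2 `table`, and the tallies used.
#' @export
compare_noise <- function(summary_a, summary_b, alternative = "two.sided") {
  for (s in list(summary_a, summary_b))
    if (!all(c("noise", "disomic", "true_aneusomy") %in% names(s)))
      stop("compare_noise: dual-mode tallies required")
  tab <- matrix(c(summary_a$noise,
                  summary_a$disomic + summary_a$true_aneusomy,
                  summary_b$noise,
                  summary_b$disomic + summary_b$true_aneusomy),
                nrow = 2,
                dimnames = list(c("noise", "non_noise"),
                                c(summary_a$tissue, summary_b$tissue)))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
  else stats::fisher.test(tab, alternative = alternative)$p.value
  list(p = p, table = tab)
}
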