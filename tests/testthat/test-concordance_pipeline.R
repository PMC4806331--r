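mk_seg <- function(chrom, start, end, type, n = 100, l2 = -0.5)
  data.frame(chrom = chrom, start = start, end = end, n_probes = n,
             event_type = type, mean_log2 = l2)

test_that("probe-count filter is inclusive and drops diploid segments", {
  segs <- rbind(mk_seg("chr1", 0, 1e5, "loss", n = 49),
                mk_seg("chr1", 2e5, 3e5, "loss", n = 50),
                mk_seg("chr1", 4e5, 5e5, "gain", n = 500),
                mk_seg("chr1", 5e5, 9e5, "normal", n = 5000))
  out <- filter_min_probes(segs, 50)
  expect_equal(out$start, c(2e5, 4e5))
  # monotonicity: the 10-probe set contains the 50-probe set
  out10 <- filter_min_probes(segs, 10)
  expect_true(all(out$start %in% out10$start))
})

test_that("allelic imbalance / LOH segments are excluded from CNV calling", {
  segs <- rbind(mk_seg("chr1", 0, 1e5, "allelic_imbalance_or_loh"),
                mk_seg("chr1", 2e5, 3e5, "loss"))
  expect_equal(drop_non_cnv(segs)$event_type, "loss")
  expect_equal(nrow(drop_non_cnv(segs[0, ])), 0)
})

test_that("cross-platform validation intersects reciprocal matches of same type", {
  cfg <- pipeline_config(reciprocal_fraction = 0.5)
  a <- mk_seg("chr1", 0, 100, "loss")
  b <- mk_seg("chr1", 50, 150, "loss")
  calls <- cross_platform_validate(a, b, cfg)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(50, 100))
  expect_equal(calls$event_type, "loss")
  # no partner on the other platform -> no call
  expect_equal(nrow(cross_platform_validate(a, a[0, ], cfg)), 0)
  # same interval, opposite type -> no call
  expect_equal(nrow(cross_platform_validate(
    a, mk_seg("chr1", 0, 100, "gain"), cfg)), 0)
  # reciprocity: a fragment inside a big segment fails at 0.5
  expect_equal(nrow(cross_platform_validate(
    mk_seg("chr1", 0, 1000, "loss"), mk_seg("chr1", 400, 600, "loss"), cfg)), 0)
})

test_that("greedy matching is one-to-one with deterministic tie-breaks", {
  cfg <- pipeline_config(reciprocal_fraction = 0.5)
  # one A segment cannot validate two B fragments
  a <- mk_seg("chr1", 0, 200, "loss")
  b <- rbind(mk_seg("chr1", 0, 190, "loss"), mk_seg("chr1", 10, 200, "loss"))
  calls <- cross_platform_validate(a, b, cfg)
  expect_equal(nrow(calls), 1)
  # the better-overlapping partner (equal product -> leftmost) wins
  expect_equal(calls$b_start, 0)
  # swap of platform arguments yields the same intervals
  calls_sw <- cross_platform_validate(b, a, cfg)
  expect_equal(calls_sw[, c("chrom", "start", "end", "event_type")],
               calls[, c("chrom", "start", "end", "event_type")])
})

test_that("validated calls stay inside both supports with conserved type", {
  set.seed(301)
  cfg <- pipeline_config(reciprocal_fraction = 0.5)
  for (i in 1:50) {
    na <- sample(1:4, 1); nb <- sample(1:4, 1)
    mk <- function(n) {
      s <- sort(sample.int(1e4, 2 * n))
      data.frame(chrom = "chr1", start = s[seq(1, 2 * n, 2)],
                 end = s[seq(2, 2 * n, 2)],
                 n_probes = 100,
                 event_type = sample(c("loss", "gain"), n, TRUE),
                 mean_log2 = -0.5)
    }
    a <- mk(na); b <- mk(nb)
    calls <- cross_platform_validate(a, b, cfg)
    if (!nrow(calls)) next
    expect_true(all(calls$start >= calls$a_start & calls$end <= calls$a_end))
    expect_true(all(calls$start >= calls$b_start & calls$end <= calls$b_end))
    for (k in seq_len(nrow(calls)))
      expect_true(all(reciprocal_overlap(
        c(calls$a_start[k], calls$a_end[k]),
        c(calls$b_start[k], calls$b_end[k])) >= 0.5))
  }
})

test_that("sharing classification: germline, private, shared-mosaic", {
  cfg <- pipeline_config()
  organs <- c("heart", "liver", "thymus", "kidney", "spleen")
  base <- function(org, start = 0, end = 100, type = "loss", chrom = "chr1")
    cbind(data.frame(patient = "p", organ = org),
          mk_seg(chrom, start, end, type))
  # matched in all 5 organs -> germline
  calls <- do.call(rbind, lapply(organs, base))
  out <- classify_sharing(calls, organs, cfg)
  expect_true(all(out$sharing_class == "germline"))
  # thymus-only call in a 5-organ patient -> private
  out2 <- classify_sharing(base("thymus"), organs, cfg)
  expect_equal(out2$sharing_class, "private")
  # matched in 2 of 5 organs -> shared_mosaic
  out3 <- classify_sharing(rbind(base("heart"), base("liver")), organs, cfg)
  expect_true(all(out3$sharing_class == "shared_mosaic"))
  # a same-interval call of the other type does not match
  out4 <- classify_sharing(rbind(base("heart"), base("liver", type = "gain")),
                           organs, cfg)
  expect_equal(out4$sharing_class, c("private", "private"))
  # single assayed organ: sharing undefined
  expect_warning(out5 <- classify_sharing(base("heart"), "heart", cfg),
                 "single assayed organ")
  expect_equal(out5$sharing_class, "unclassified")
})

test_that("sharing classification is invariant to organ order and symmetric", {
  cfg <- pipeline_config()
  set.seed(302)
  organs <- c("a", "b", "c", "d")
  calls <- do.call(rbind, lapply(1:12, function(i) {
    s <- sample.int(5e3, 1)
    data.frame(patient = "p", organ = sample(organs, 1), chrom = "chr1",
               start = s, end = s + sample.int(2e3, 1), n_probes = 60,
               event_type = sample(c("loss", "gain"), 1), mean_log2 = -0.4)
  }))
  ref <- classify_sharing(calls, organs, cfg)
  for (perm in list(rev(organs), sample(organs))) {
    alt <- classify_sharing(calls, perm, cfg)
    expect_equal(alt$sharing_class, ref$sharing_class)
  }
  shuf <- sample(nrow(calls))
  alt2 <- classify_sharing(calls[shuf, ], organs, cfg)
  expect_equal(alt2$sharing_class, ref$sharing_class[shuf])
})

test_that("classification against the per-base germline oracle", {
  cfg <- pipeline_config(reciprocal_fraction = 0.5)
  set.seed(303)
  organs <- c("a", "b", "c")
  for (i in 1:60) {
    calls <- do.call(rbind, lapply(seq_len(sample(2:6, 1)), function(j) {
      s <- sample.int(9e3, 1)
      data.frame(patient = "p", organ = sample(organs, 1), chrom = "chr1",
                 start = s, end = s + sample.int(1e3, 1), n_probes = 60,
                 event_type = sample(c("loss", "gain"), 1), mean_log2 = -0.4)
    }))
    got <- classify_sharing(calls, organs, cfg)$sharing_class
    want <- vapply(seq_len(nrow(calls)), function(k) {
      others <- setdiff(organs, calls$organ[k])
      hit <- vapply(others, function(o) {
        rows <- which(calls$organ == o &
                        calls$event_type == calls$event_type[k])
        any(vapply(rows, function(r) {
          ro <- oracle_reciprocal(c(calls$start[k], calls$end[k]),
                                  c(calls$start[r], calls$end[r]))
          all(ro >= 0.5)
        }, TRUE))
      }, TRUE)
      if (all(hit)) "germline" else if (!any(hit)) "private" else "shared_mosaic"
    }, "")
    expect_equal(got, want)
  }
})

test_that("TCR annotation uses >= 1 bp overlap with configured loci", {
  g <- default_genome()  # TCRG chr1:20.0-20.3 Mb
  calls <- data.frame(patient = "p", organ = "thymus",
                      chrom = c("chr1", "chr1", "chr2", "chr3"),
                      start = c(20.05e6, 19.0e6, 1e6, 18.4999e6),
                      end = c(20.2e6, 20.0e6 + 1, 2e6, 19e6),
                      event_type = "loss", n_probes_a = 60, n_probes_b = 70,
                      mean_log2 = -0.5)
  out <- annotate_tcr(calls, g)
  expect_equal(out$tcr_locus, c("TCRG", "TCRG", NA, "TCRB"))
})

test_that("mosaic fraction inverts the dosage model and flags wrong signs", {
  expect_equal(estimate_mosaic_fraction("loss", -1), 1)
  expect_equal(estimate_mosaic_fraction("loss", log2(0.75)), 0.5)
  expect_equal(estimate_mosaic_fraction("gain", log2(1.5)), 1)
  expect_equal(estimate_mosaic_fraction("gain", log2(1.25)), 0.5)
  # round-trip through expected_log2
  for (f in c(0.1, 0.3, 0.7, 1)) {
    expect_equal(estimate_mosaic_fraction("loss", expected_log2(1, f)), f)
    expect_equal(estimate_mosaic_fraction("gain", expected_log2(3, f)), f)
  }
  expect_warning(out <- estimate_mosaic_fraction("loss", 0.2), "sign")
  expect_true(is.na(out))
})

test_that("organ-rate comparison wraps the exact U test", {
  res <- compare_organ_rates(c(0, 0, 0, 0), c(2, 2, 3))
  expect_equal(res$p, 2 / 35)
})

test_that("run_calling on a minimal hand-built cohort flags only the private call", {
  env <- private_event_cohort(seed = 71, scale = 0.4)
  rep <- run_pipeline(env$cohort, env$genome, pipeline_config(min_probes = 50))
  priv <- rep$private_calls
  expect_gte(nrow(priv), 2)
  expect_true(all(priv$event_type == "loss"))
  expect_true(any(priv$organ == "liver"))
  # germline deletion is never private
  germ <- rep$calls[rep$calls$chrom == "chr1" &
                      rep$calls$start < 42.5e6 & rep$calls$end > 40e6, ]
  expect_true(all(germ$sharing_class == "germline"))
})
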