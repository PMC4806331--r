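test_that("probe maps cover the genome proportionally and deterministically", {
  g1 <- small_genome(1e6)
  pf <- platform_spec("p", 1000, snp_fraction = 0.5)
  map <- build_probe_map(g1, pf, seed = 7)
  expect_equal(nrow(map), 1000)
  expect_true(all(map$pos >= 0 & map$pos < 1e6))
  expect_false(is.unsorted(map$pos, strictly = TRUE))

  expect_identical(build_probe_map(g1, pf, seed = 7), map)

  g3 <- default_genome()
  pf3 <- platform_spec("p", 3000)
  map3 <- build_probe_map(g3, pf3, seed = 1)
  counts <- table(map3$chrom)[g3$chromosomes$name]
  expect_equal(as.vector(counts),
               round(3000 * g3$chromosomes$length / sum(g3$chromosomes$length)),
               tolerance = 0.01)
  # different seeds: same coverage, different positions
  map3b <- build_probe_map(g3, pf3, seed = 2)
  expect_setequal(unique(map3b$chrom), unique(map3$chrom))
  expect_false(identical(map3$pos, map3b$pos))

  expect_error(build_probe_map(g3, platform_spec("tiny", 2)), "smaller")
})

test_that("expected_log2 follows the cell-fraction mixture model", {
  expect_equal(expected_log2(1, 1.0), -1)
  expect_equal(expected_log2(5, 0.0), 0)
  expect_equal(expected_log2(1, 0.5), log2(0.75))
  expect_equal(expected_log2(3, 1.0), log2(1.5))
  # homozygous clonal deletion saturates instead of -Inf
  expect_equal(expected_log2(0, 1.0), -5)
  # cross-check against direct cell-population averaging at f = 0.5
  f <- 0.5
  cells <- c(rep(2, 1e6 * (1 - f)), rep(1, 1e6 * f))
  expect_equal(expected_log2(1, f), log2(mean(cells) / 2), tolerance = 1e-9)
})

test_that("a germline deletion depresses both organs on both platforms", {
  g <- default_genome()
  pf <- default_platforms(scale = 0.2)
  co <- simulate_cohort(
    g, pf, list(list(id = "p1", organs = c("heart", "liver"))),
    list(event_spec("g1", "p1", "chr1", 30e6, 34e6, copies = 1,
                    scope = "germline")),
    seed = 11)
  expect_equal(length(co$signals), 4)
  for (sig in co$signals) {
    p <- sig$probes
    idx <- p$chrom == "chr1" & p$pos >= 30e6 & p$pos < 34e6
    expect_gt(sum(idx), 50)
    se <- 0.21 / sqrt(sum(idx))
    expect_lt(abs(mean(p$log2[idx]) - (-1)), 3 * se)
    expect_lt(abs(mean(p$log2[!idx])), 3 * 0.21 / sqrt(sum(!idx)))
  }
})

test_that("mean log2 over a clonal loss converges to -1 (law of large numbers)", {
  sigma <- 0.21
  g <- small_genome(1e7)
  pf <- platform_spec("p", 1e4, noise_sd = sigma)
  co <- simulate_cohort(g, list(pf), list(list(id = "p", organs = "o")),
                        list(event_spec("e", "p", "chr1", 0, 1e7, copies = 1,
                                        scope = "germline")),
                        seed = 3)
  x <- co$signals[[1]]$probes$log2
  expect_lt(abs(mean(x) + 1), 3 * sigma / sqrt(length(x)))
})

test_that("TCR per-probe deleted fraction is the sum of covering clone fractions", {
  g <- small_genome(2e7, tcr = TRUE)  # TCRG at 8.0-8.3 Mb
  pf <- platform_spec("p", 5000, noise_sd = 0.05)
  # 3 clones at 0.2, forced to wide nested-ish intervals via min_width
  tcr <- list(tcr_polyclonal_spec("p", "TCRG", rep(0.2, 3),
                                  min_width = 250e3, max_width_frac = 1))
  co <- simulate_cohort(g, list(pf), list(list(id = "p", organs = "thymus")),
                        tcr = tcr, seed = 5)
  cl <- co$truth$clones
  expect_equal(nrow(cl), 3)
  expect_true(all(cl$start >= 8e6 & cl$end <= 8.3e6))
  map <- co$maps[[1]]
  fdel <- rep(0, nrow(map))
  for (k in 1:3) {
    hit <- map$pos >= cl$start[k] & map$pos < cl$end[k]
    fdel <- fdel + 0.2 * hit
  }
  expect_true(all(fdel <= sum(cl$fraction) + 1e-12))
  # probes covered by all three clones sit at the aggregate fraction
  idx <- which(fdel > 0.55)
  expect_gt(length(idx), 20)
  x <- co$signals[[1]]$probes$log2[idx]
  expect_lt(abs(mean(x) - log2(1 - 0.6 / 2)), 3 * 0.05 / sqrt(length(x)))
  # flank probes covered by no clone stay diploid
  out_locus <- which(map$pos < 8e6 | map$pos >= 8.3e6)
  expect_lt(abs(mean(co$signals[[1]]$probes$log2[out_locus])),
            3 * 0.05 / sqrt(length(out_locus)))
})

test_that("two platforms share the truth but not probes, and seeds fix everything", {
  env <- germline_only_cohort(seed = 21, scale = 0.15)
  co <- env$cohort
  a <- co$signals[["p1.heart.arrayA"]]; b <- co$signals[["p1.heart.arrayB"]]
  expect_equal(length(intersect(paste(a$probes$chrom, a$probes$pos),
                                paste(b$probes$chrom, b$probes$pos))), 0)
  # interval-averaged log2 over the embedded germline loss agrees
  ma <- mean(a$probes$log2[a$probes$chrom == "chr1" & a$probes$pos >= 30e6 &
                             a$probes$pos < 32.5e6])
  mb <- mean(b$probes$log2[b$probes$chrom == "chr1" & b$probes$pos >= 30e6 &
                             b$probes$pos < 32.5e6])
  expect_lt(abs(ma - mb), 0.15)
  # byte-level determinism
  co2 <- germline_only_cohort(seed = 21, scale = 0.15)$cohort
  expect_identical(serialize(co, NULL), serialize(co2, NULL))
})

test_that("overlapping events on one organ are rejected; scopes validated", {
  g <- default_genome()
  pats <- list(list(id = "p1", organs = c("heart", "liver")))
  ev <- list(
    event_spec("a", "p1", "chr1", 1e6, 3e6, copies = 1, scope = "germline"),
    event_spec("b", "p1", "chr1", 2e6, 4e6, copies = 3, scope = "heart"))
  expect_error(simulate_cohort(g, default_platforms(0.05), pats, ev, seed = 1),
               "overlapping")
  expect_error(
    simulate_cohort(g, default_platforms(0.05), pats,
                    list(event_spec("c", "p1", "chr1", 1e6, 2e6, copies = 1,
                                    scope = "brain")), seed = 1),
    "organs not assayed")
  expect_error(event_spec("d", "p", "chr1", 1, 2, copies = 2), "copies")
  expect_error(event_spec("e", "p", "chr1", 1, 2, copies = 1,
                          cell_fraction = 0.5, scope = "germline"),
               "germline")
})

test_that("FISH count simulation matches its analytic error model", {
  # error-free: all exact
  obs <- simulate_fish_counts(2, 500, 0, 0, dual = FALSE, seed = 1)
  expect_true(all(obs$count1 == 2))
  # single probe: non-disomic fraction ~ p_loss + p_gain
  n <- 1e4; pl <- 0.05; pg <- 0.02
  obs <- simulate_fish_counts(2, n, pl, pg, dual = FALSE, seed = 2)
  frac <- mean(obs$count1 != 2)
  expect_lt(abs(frac - (pl + pg)), 3 * sqrt(0.07 * 0.93 / n))
  # dual probes err independently: P(1,1) ~ p_loss^2
  obs2 <- simulate_fish_counts(2, n, pl, pg, dual = TRUE, seed = 3)
  f11 <- mean(obs2$count1 == 1 & obs2$count2 == 1)
  expect_lt(abs(f11 - pl^2), 3 * sqrt(pl^2 * (1 - pl^2) / n))
  # floor at zero
  obs3 <- simulate_fish_counts(0, 1000, 0.5, 0, dual = FALSE, seed = 4)
  expect_true(all(obs3$count1 == 0))
})
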