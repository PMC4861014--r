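test_that("cytosine report parsing validates and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".tsv")

  file.create(tmp)
  expect_identical(nrow(read_cytosine_report(tmp)), 0L)  # empty file

  rec <- make_records(c(5, 17, 400), meth = c(3, 0, 7), unmeth = c(2, 4, 0),
                      context = c("CG", "CHG", "CHH"),
                      strand = c("+", "-", "+"))
  write_cytosine_report(rec, tmp)
  expect_identical(read_cytosine_report(tmp), rec)       # round-trip

  writeLines(c("2\t5\t+\t3\t2\tCG\tNNN", "2\t9\t+\t1\t1\tCHN\tNNN"), tmp)
  expect_error(read_cytosine_report(tmp), "line 2.*context")

  writeLines("2\t5\t+\t-3\t2\tCG\tNNN", tmp)
  expect_error(read_cytosine_report(tmp), "line 1.*methylated")

  writeLines(c("2\t5\t+\t3\t2\tCG\tNNN", "2\t5\t+\t3"), tmp)
  expect_error(read_cytosine_report(tmp), "line 2.*columns")
})

test_that("binning pools strands into half-open 200-bp bins and conserves counts", {
  expect_error(bin_counts(make_records(1, 1, 1), bin_size = 0), "positive")

  # positions 1 and 200 share bin [0,200); 201 opens bin [200,400)
  rec <- make_records(c(1, 200, 201), meth = c(1, 2, 4), unmeth = c(1, 0, 0),
                      strand = c("+", "-", "+"))
  b <- bin_counts(rec)
  expect_identical(b$start, c(0L, 200L))
  expect_identical(b$end, c(200L, 400L))
  expect_identical(b$meth, c(3L, 4L))
  expect_identical(b$total, c(4L, 4L))

  # conservation oracle on a random 10,000-record input
  set.seed(21)
  n <- 10000
  rnd <- make_records(sample(1e6, n, replace = TRUE),
                      meth = rpois(n, 2), unmeth = rpois(n, 3),
                      context = sample(c("CG", "CHG", "CHH"), n, TRUE),
                      strand = sample(c("+", "-"), n, TRUE))
  bb <- bin_counts(rnd)
  for (ctx in c("CG", "CHG", "CHH")) {
    expect_identical(sum(bb$meth[bb$context == ctx]),
                     sum(rnd$meth[rnd$context == ctx]))
    expect_identical(sum(bb$total[bb$context == ctx]),
                     sum(rnd$meth[rnd$context == ctx] +
                           rnd$unmeth[rnd$context == ctx]))
  }
})

test_that("bin filtering applies the 10-count rule per sample or pooled", {
  bins <- merge_bins(list(
    a = make_bins(0, "CG", 5, 9), b = make_bins(0, "CG", 5, 50),
    c = make_bins(0, "CG", 5, 50), d = make_bins(0, "CG", 5, 50)))
  expect_identical(nrow(filter_bins(bins, 10)), 0L)      # (9,50,50,50) out
  expect_identical(nrow(filter_bins(bins, 10, mode = "pooled")), 1L)

  at_bound <- merge_bins(list(
    a = make_bins(0, "CG", 5, 10), b = make_bins(0, "CG", 5, 10),
    c = make_bins(0, "CG", 5, 10), d = make_bins(0, "CG", 5, 10)))
  expect_identical(nrow(filter_bins(at_bound, 10)), 1L)  # boundary retained

  zero <- merge_bins(list(
    a = make_bins(0, "CG", 0, 0), b = make_bins(0, "CG", 0, 0),
    c = make_bins(0, "CG", 0, 0), d = make_bins(0, "CG", 0, 0)))
  expect_identical(nrow(filter_bins(zero, 10)), 0L)
})

test_that("chisq_2x2 is the uncorrected Pearson test with degenerate margins at p=1", {
  eq <- chisq_2x2(10, 90, 20, 180)             # equal proportions
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  t1 <- chisq_2x2(10, 90, 50, 50)              # hand-computed E = 30/70
  expect_equal(t1$statistic, 400 * (2 / 30 + 2 / 70), tolerance = 1e-12)
  expect_equal(t1$p_value, 6.698e-10, tolerance = 1e-3)

  t2 <- chisq_2x2(50, 50, 10, 90)              # sample-order symmetry
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p_value, t2$p_value)

  expect_error(chisq_2x2(-1, 5, 2, 2), "non-negative")
  degen <- chisq_2x2(0, 0, 5, 5)               # empty row margin
  expect_equal(degen$p_value, 1)
  expect_equal(chisq_2x2(0, 10, 0, 20)$p_value, 1)  # empty column margin

  # brute-force oracle equivalence on random tables
  set.seed(31)
  for (i in 1:200) {
    tb <- rpois(4, 20)
    got <- chisq_2x2(tb[1], tb[2], tb[3], tb[4])
    want <- chisq_oracle(tb[1], tb[2], tb[3], tb[4])
    expect_lt(abs(got$statistic - want$statistic), 1e-8)
    expect_lt(abs(got$p_value - want$p_value), 1e-8)
  }
})

test_that("the dual chi-square rule requires both replicate pairs below alpha", {
  # pair 1 strongly significant, pair 2 not -> no DMR
  wt1 <- make_bins(0, "CG", 10, 100); sulf1 <- make_bins(0, "CG", 50, 100)
  wt2 <- make_bins(0, "CG", 20, 100); sulf2 <- make_bins(0, "CG", 30, 100)
  mixed <- call_dmrs(wt1, sulf1, wt2, sulf2)
  expect_lt(mixed$p_pair1, 0.01)
  expect_gt(mixed$p_pair2, 0.01)
  expect_false(mixed$is_dmr)
  expect_equal(mixed$max_p, pmax(mixed$p_pair1, mixed$p_pair2))

  # both pairs significant with sulf higher -> hyper_in_sulf, diff < 0
  hyper <- call_dmrs(wt1, sulf1, make_bins(0, "CG", 12, 100), sulf1)
  expect_true(hyper$is_dmr)
  expect_identical(hyper$direction, "hyper_in_sulf")
  expect_lt(hyper$diff, 0)

  # significant but discordant replicate signs -> flagged, not directional
  disc <- call_dmrs(wt1, sulf1, sulf1, wt1)
  expect_identical(disc$direction, "discordant")
})

test_that("exchanging wt and sulf negates diffs and preserves p-values", {
  set.seed(32)
  mk <- function() {
    tot <- rpois(50, 60) + 10
    make_bins(seq(0, by = 200, length.out = 50), "CG",
              rbinom(50, tot, runif(50, 0.1, 0.9)), tot)
  }
  a <- mk(); b <- mk(); c_ <- mk(); d <- mk()
  fwd <- call_dmrs(a, b, c_, d)
  rev <- call_dmrs(b, a, d, c_)
  expect_equal(rev$diff, -fwd$diff)
  expect_equal(rev$max_p, fwd$max_p)
  expect_equal(rev$is_dmr, fwd$is_dmr)
})

test_that("weighted level is the pooled count ratio with NA for no coverage", {
  rec <- make_records(c(10, 20), meth = c(14, 200), unmeth = c(36, 750))
  expect_equal(weighted_level(rec, 0, 100, "CG"), 21.4)  # 214/1000
  all_m <- make_records(5, 30, 0)
  expect_equal(weighted_level(all_m, 0, 100, "CG"), 100)
  expect_true(is.na(weighted_level(rec, 0, 100, "CHH")))  # zero coverage
  expect_true(is.na(weighted_level(rec, 5000, 5100, "CG")))
})

test_that("sliding windows tile from 0 with step 100 and flag empty windows", {
  rec <- make_records(c(50, 150, 250, 390), meth = c(1, 1, 1, 1),
                      unmeth = c(1, 1, 1, 1))
  prof <- sliding_window_profile(rec)
  cg <- prof[prof$context == "CG", ]
  expect_identical(cg$start, c(0L, 100L, 200L, 300L))
  expect_identical(cg$end, cg$start + 200L)
  expect_true(all(is.na(prof$level[prof$context != "CG"])))

  # uniform 50% methylation -> flat profile at 50
  set.seed(33)
  uni <- make_records(1:400, meth = 5, unmeth = 5)
  puni <- sliding_window_profile(uni)
  expect_true(all(puni$level[puni$context == "CG"] == 50))

  # each call lands in two windows except within the first step of the chrom
  expect_identical(sum(cg$total), 14L)

  # planted step function transitions within one window of the boundary
  step_rec <- make_records(1:1000, meth = c(rep(0, 500), rep(10, 500)),
                           unmeth = c(rep(10, 500), rep(0, 500)))
  ps <- sliding_window_profile(step_rec)
  pcg <- ps[ps$context == "CG", ]
  expect_true(all(pcg$level[pcg$start + 200 <= 500] == 0))
  expect_true(all(pcg$level[pcg$start >= 500] == 100))

  expect_error(sliding_window_profile(rec, window = 50, step = 100))
})

test_that("region binomial regression matches the likelihood-ratio null and oracle", {
  # identical proportions in all samples -> LRT 0, p = 1
  null <- region_glm_test(c(20, 20, 20, 20), c(80, 80, 80, 80),
                          c("wt", "wt", "sulf", "sulf"))
  expect_equal(null$deviance, 0, tolerance = 1e-10)
  expect_equal(null$p_value, 1, tolerance = 1e-8)

  # levels at the promoter-DMR CHG scale (wt ~4%, sulf ~62%), >=300 calls
  strong <- region_glm_test(meth = c(12, 18, 190, 186),
                            unmeth = c(288, 282, 110, 114),
                            genotype = c("wt", "wt", "sulf", "sulf"))
  expect_lt(strong$p_value, 1e-10)
  expect_equal(strong$levels, c(4, 6, 190 / 3, 62), tolerance = 1e-8)

  # independent oracle: binomial log-likelihood evaluated directly
  ll <- function(meth, unmeth, p) sum(meth * log(p) + unmeth * log(1 - p))
  m <- c(12, 18, 190, 186); u <- c(288, 282, 110, 114)
  g <- c(1, 1, 2, 2)
  p_alt <- tapply(m, g, sum) / tapply(m + u, g, sum)
  dev_oracle <- 2 * (ll(m, u, p_alt[g]) - ll(m, u, rep(sum(m) / sum(m + u), 4)))
  expect_equal(strong$deviance, unname(dev_oracle), tolerance = 1e-8)

  # label symmetry
  swap <- region_glm_test(meth = m, unmeth = u,
                          genotype = c("sulf", "sulf", "wt", "wt"))
  expect_equal(swap$p_value, strong$p_value, tolerance = 1e-12)

  expect_error(region_glm_test(c(0, 0), c(0, 0), c("wt", "sulf")),
               "zero coverage")
  expect_error(region_glm_test(c(1, 1), c(1, 1), c("wt", "wt")),
               "genotype levels")
})

test_that("DMR tallies split by context and direction", {
  empty <- call_dmrs(make_bins(0, "CG", 10, 40), make_bins(0, "CG", 11, 40),
                     make_bins(0, "CG", 10, 40), make_bins(0, "CG", 12, 40))
  t0 <- classify_dmrs(empty)
  expect_true(all(t0[c("hyper_in_sulf", "hypo_in_sulf", "discordant")] == 0))

  one <- call_dmrs(make_bins(0, "CHH", 2, 100), make_bins(0, "CHH", 40, 100),
                   make_bins(0, "CHH", 3, 100), make_bins(0, "CHH", 45, 100))
  t1 <- classify_dmrs(one)
  expect_identical(t1$hyper_in_sulf[t1$context == "CHH"], 1)
  expect_identical(sum(t1$hypo_in_sulf), 0)
})

test_that("planted hyper and hypo CHG regions are recovered in equal number", {
  # 10 hyper + 10 hypo CHG regions at strong effect sizes, one bin each
  starts <- seq(0, by = 1000, length.out = 20)
  regions <- lapply(seq_along(starts), function(i) {
    lv <- if (i <= 10) c(wt = 0.05, sulf = 0.65) else c(wt = 0.65, sulf = 0.05)
    planted_region(starts[i], starts[i] + 200, list(CHG = lv))
  })
  spec <- methylome_sim_spec(chrom_length = 2e4, mean_depth = 30,
                             background_level = c(CG = 0.3, CHG = 0.1, CHH = 0.05),
                             planted_regions = regions, seed = 44L)
  bins <- lapply(c(101, 102, 103, 104), function(s) {
    g <- if (s %% 2 == 1) "wt" else "sulf"
    bin_counts(simulate_cytosine_report(spec, g, seed = s))
  })
  calls <- call_dmrs(bins[[1]], bins[[2]], bins[[3]], bins[[4]])
  in_regions <- calls$start %in% starts & calls$context == "CHG"
  tal <- classify_dmrs(calls[in_regions, ])
  expect_identical(tal$hyper_in_sulf[tal$context == "CHG"], 10)
  expect_identical(tal$hypo_in_sulf[tal$context == "CHG"], 10)
})

test_that("DMR BED output is 0-based half-open and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  none <- call_dmrs(make_bins(0, "CG", 10, 40), make_bins(0, "CG", 11, 40),
                    make_bins(0, "CG", 10, 40), make_bins(0, "CG", 12, 40))
  write_dmr_bed(none, tmp)
  expect_identical(length(readLines(tmp)), 0L)          # empty calls

  one <- call_dmrs(make_bins(200, "CG", 5, 100), make_bins(200, "CG", 60, 100),
                   make_bins(200, "CG", 6, 100), make_bins(200, "CG", 55, 100))
  write_dmr_bed(one, tmp)
  bed <- read.table(tmp, sep = "\t")
  expect_identical(bed$V2, 200L)
  expect_identical(bed$V3, 400L)
  expect_identical(bed$V4, "CG:hyper_in_sulf")
  expect_identical(bed$V6, ".")
  expect_true(bed$V5 >= 20 && bed$V5 <= 1000)  # -10 log10(max_p), capped
  # intervals round-trip against the calls table
  expect_identical(bed$V2, one$start[one$is_dmr])
  expect_identical(bed$V3, one$end[one$is_dmr])
})
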