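test_that("site placement respects density, uniqueness and determinism", {
  # zero density -> empty site list
  spec0 <- methylome_sim_spec(chrom_length = 1e4,
                              context_density = c(CG = 0, CHG = 0, CHH = 0))
  expect_identical(nrow(simulate_cytosine_sites(spec0)), 0L)
  expect_identical(nrow(simulate_cytosine_sites(
    methylome_sim_spec(chrom_length = 0))), 0L)

  # identical spec + seed -> identical site list
  spec <- methylome_sim_spec(chrom_length = 1e4,
                             context_density = c(CG = 0.02, CHG = 0, CHH = 0),
                             seed = 99L)
  expect_identical(simulate_cytosine_sites(spec), simulate_cytosine_sites(spec))

  # sites sorted and unique per strand
  s <- simulate_cytosine_sites(methylome_sim_spec(chrom_length = 5e4, seed = 3L))
  expect_false(is.unsorted(s$pos))
  expect_false(any(duplicated(s[c("pos", "strand")])))

  # binomial sampling oracle: CG site count within 3 SDs of L * density
  L <- 1e6; d <- 0.02
  big <- methylome_sim_spec(chrom_length = L,
                            context_density = c(CG = d, CHG = 0, CHH = 0),
                            seed = 42L)
  n_cg <- sum(simulate_cytosine_sites(big)$context == "CG")
  sd3 <- 3 * sqrt(2 * L * (d / 2) * (1 - d / 2))
  expect_lt(abs(n_cg - L * d), sd3)
})

test_that("cytosine reports follow the depth and level model", {
  spec <- methylome_sim_spec(chrom_length = 2e4, mean_depth = 0, seed = 5L)
  rep0 <- simulate_cytosine_report(spec, "wt")
  expect_true(all(rep0$meth == 0 & rep0$unmeth == 0))  # no coverage

  # count conservation: one record per simulated site
  expect_identical(nrow(rep0), nrow(simulate_cytosine_sites(spec)))

  # background level 0 -> weighted level exactly 0
  spec_z <- methylome_sim_spec(chrom_length = 2e4, mean_depth = 10,
                               background_level = c(CG = 0, CHG = 0, CHH = 0),
                               seed = 6L)
  rz <- simulate_cytosine_report(spec_z, "wt")
  expect_identical(sum(rz$meth), 0L)
  expect_equal(weighted_level(rz, 0, 2e4, "CG"), 0)

  # planted 73% CG over a 727-bp region at depth 50, rho 0:
  # empirical weighted level within 3 SE of the planted probability
  reg <- planted_region(5000, 5727, list(CG = c(wt = 0.24, sulf = 0.73)))
  spec_p <- methylome_sim_spec(chrom_length = 2e4, mean_depth = 50,
                               planted_regions = list(reg), seed = 7L)
  rs <- simulate_cytosine_report(spec_p, "sulf", seed = 8L)
  keep <- rs$context == "CG" & rs$pos - 1 >= 5000 & rs$pos - 1 < 5727
  n_calls <- sum(rs$meth[keep] + rs$unmeth[keep])
  lev <- weighted_level(rs, 5000, 5727, "CG")
  se3 <- 3 * 100 * sqrt(0.73 * 0.27 / n_calls)
  expect_lt(abs(lev - 73), se3)

  # genotype switches the planted level
  rw <- simulate_cytosine_report(spec_p, "wt", seed = 8L)
  expect_lt(weighted_level(rw, 5000, 5727, "CG"), 40)

  # determinism
  expect_identical(simulate_cytosine_report(spec_p, "sulf", seed = 8L), rs)

  # overdispersion widens but respects the mean (sanity at rho = 0.3)
  spec_od <- methylome_sim_spec(chrom_length = 5e4, mean_depth = 20,
                                overdispersion = 0.3, seed = 9L)
  ro <- simulate_cytosine_report(spec_od, "wt")
  expect_true(all(ro$meth <= ro$meth + ro$unmeth))
  lev_od <- weighted_level(ro, 0, 5e4, "CG")
  expect_lt(abs(lev_od - 30), 5)  # background CG is 30%
})

test_that("srna count simulator follows the Poisson scaling model", {
  null_spec <- srna_sim_spec(n_loci = 300, effect_loci = list(), seed = 11L)
  sim <- simulate_srna_counts(null_spec)
  expect_identical(dim(sim$counts), c(300L, 6L))
  expect_true(all(sim$truth[-1] == 1))

  # equal folds and sizes -> per-genotype means equal within sampling error
  gm <- sapply(levels(sim$genotype), function(g)
    mean(sim$counts[, sim$genotype == g]))
  expect_lt(max(abs(gm - 20)), 3 * sqrt(20 / 600))

  # one library size doubled -> its column total ~ 2x the others
  sizes <- c(wt1 = 1, wt2 = 1, het1 = 1, het2 = 1, sulf1 = 1, sulf2 = 2)
  sim2 <- simulate_srna_counts(srna_sim_spec(n_loci = 2000, baseline_mean = 50,
                                             library_sizes = sizes,
                                             effect_loci = list(), seed = 12L))
  tot <- colSums(sim2$counts)
  expect_lt(abs(tot[["sulf2"]] / mean(tot[1:5]) - 2), 0.05)

  # fixed seed -> identical matrix
  expect_identical(simulate_srna_counts(null_spec)$counts, sim$counts)
})

test_that("expression simulator recovers planted classes and emits DE/annotation", {
  # noiseless limit: sign patterns recovered exactly
  cls <- rep(c("I", "II", "III", "IV"), each = 5)
  spec <- expression_sim_spec(n_genes = 20, class_assignment = cls,
                              noise_sd = 0, seed = 13L)
  sim <- simulate_expression(spec)
  wt <- sim$genotype == "wt"; sulf <- sim$genotype == "sulf"
  het <- sim$genotype == "sulf/+"
  d_sulf <- rowMeans(sim$matrix[, sulf]) - rowMeans(sim$matrix[, wt])
  d_het <- rowMeans(sim$matrix[, het]) - rowMeans(sim$matrix[, wt])
  expect_true(all(d_sulf[cls %in% c("I", "II")] < 0))
  expect_true(all(d_sulf[cls %in% c("III", "IV")] > 0))
  expect_true(all(d_het[cls == "I"] < 0 & d_het[cls == "III"] > 0))
  expect_true(all(abs(d_het[cls %in% c("II", "IV")]) < 1e-12))

  # all-null genes -> empty DE table at any positive threshold
  null_sim <- simulate_expression(expression_sim_spec(
    n_genes = 30, class_assignment = rep("null", 30), noise_sd = 0,
    seed = 14L))
  expect_identical(sum(null_sim$de$padj < 0.9), 0L)

  # Gaussian tail oracle: class II at -2 log2, noise 0.1, n = 200 genes
  spec2 <- expression_sim_spec(n_genes = 200,
                               class_assignment = rep("II", 200),
                               noise_sd = 0.1, seed = 15L)
  sim2 <- simulate_expression(spec2)
  wt2 <- sim2$genotype == "wt"; sulf2 <- sim2$genotype == "sulf"
  down <- rowMeans(sim2$matrix[, sulf2]) < rowMeans(sim2$matrix[, wt2])
  expect_gte(mean(down), 0.95)

  # annotation invariants and determinism
  expect_true(all(sim$annotation$start < sim$annotation$end))
  expect_identical(simulate_expression(spec)$matrix, sim$matrix)
})
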