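test_that("transcript placement puts the expected fraction inside the inversion", {
  p <- sim_params(n_transcripts = 10000, seed = 31)
  lay <- simulate_layout(p)
  inv_frac <- (lay$layout$inversion$end - lay$layout$inversion$start) /
    sum(lay$layout$linkage_groups$length)
  expect_equal(inv_frac, 0.10, tolerance = 1e-6)
  inside <- assign_region(lay$map, lay$layout)$region_label == "inversion"
  expect_lt(abs(mean(inside) - 0.10), 3 * sqrt(0.1 * 0.9 / 10000) + 1e-3)

  # zero inversion fraction: nothing inside
  p0 <- sim_params(n_transcripts = 2000, inversion_fraction = 0, seed = 32)
  lay0 <- simulate_layout(p0)
  expect_equal(sum(assign_region(lay0$map, lay0$layout)$region_label == "inversion"), 0)

  # same seed reproduces the map exactly
  expect_identical(simulate_layout(p)$map, lay$map)
})

test_that("marginal count means match the analytic NB means and the dominance construction", {
  # many pools per karyotype so group means are tight; no pop/sex variation
  p <- sim_params(n_transcripts = 40,
                  n_adults = c(AA_male = 2, AA_female = 2, BB_male = 2, BB_female = 2),
                  n_larval_pools = c(AA = 200, AB = 200, BB = 200),
                  adult_pop2_n = 0, pop_effect_sd = 0,
                  frac_kar_de = 0.5, frac_sex_de = 0, cis_fraction = 0.5,
                  dominance_mix = c(additive = 1, alpha_dominant = 0,
                                    beta_dominant = 0, underdominant = 0,
                                    overdominant = 0),
                  seed = 33)
  lay <- simulate_layout(p)
  sim <- simulate_counts(p, lay$layout, lay$map)
  m <- as.matrix(sim$counts[-1])
  meta <- sim$meta
  tr <- sim$truth
  k <- p$dispersion_k
  checks <- 0; within3 <- 0
  for (kar in c("AA", "AB", "BB")) {
    idx <- meta$life_stage == "larva" & meta$karyotype == kar
    n_s <- sum(idx)
    mu1 <- 2^(tr$base_log2 + dplyr::case_when(
      kar == "AA" ~ tr$kar_lfc, kar == "AB" ~ tr$kar_lfc / 2, TRUE ~ 0))
    mu_pool <- 3 * mu1                      # pools sum three individual draws
    se <- sqrt(3 * (mu1 + mu1^2 / k) / n_s)
    dev <- abs(rowMeans(m[, meta$sample_id[idx], drop = FALSE]) - mu_pool)
    checks <- checks + length(dev)
    within3 <- within3 + sum(dev <= 3 * se)
    expect_true(all(dev <= 5 * se))
  }
  expect_gte(within3 / checks, 0.95)

  # additive heterokaryotes sit at the log2 midpoint of the homokaryotes
  de <- which(tr$kar_de & abs(tr$kar_lfc) > 3)
  ab_mean <- rowMeans(m[de, meta$sample_id[meta$karyotype == "AB" & meta$life_stage == "larva"]])
  expect_lt(max(abs(log2(ab_mean / 3) - (tr$base_log2[de] + tr$kar_lfc[de] / 2))), 0.2)
})

test_that("cis_fraction 1 places every karyotype-DE gene inside the inversion", {
  p <- sim_params(n_transcripts = 1000, cis_fraction = 1, frac_kar_de = 0.05, seed = 34)
  lay <- simulate_layout(p)
  sim <- simulate_counts(p, lay$layout, lay$map)
  expect_true(all(sim$truth$inside_inversion[sim$truth$kar_de]))
})

test_that("heterokaryote allele reads are unbiased binomial when bias is zero", {
  p <- sim_params(n_transcripts = 600, frac_ase_biased = 0, seed = 35)
  lay <- simulate_layout(p)
  sim <- simulate_counts(p, lay$layout, lay$map)
  ase <- simulate_ase_reads(p, lay$map, sim$truth, sim$meta)
  ac <- ase$allele_counts
  tot <- ac$alpha_reads + ac$beta_reads
  frac <- ac$alpha_reads[tot > 0] / tot[tot > 0]
  expect_lt(abs(mean(frac) - 0.5), 4 * sd(frac) / sqrt(length(frac)))
})

test_that("degenerate depth 1 yields only all-or-nothing allele fractions", {
  p <- sim_params(n_transcripts = 300, ase_depth_mean = 1, ase_depth_fixed = TRUE,
                  n_snps_per_transcript = 1, seed = 36)
  lay <- simulate_layout(p)
  sim <- simulate_counts(p, lay$layout, lay$map)
  ase <- simulate_ase_reads(p, lay$map, sim$truth, sim$meta)
  ac <- ase$allele_counts
  expect_true(all(ac$alpha_reads + ac$beta_reads == 1))
  fr <- per_transcript_fractions(ac, ase$snp_map)
  expect_true(all(fr$alpha_frac %in% c(0, 1)))
})

test_that("outlier SNP placement honours the linked fraction", {
  p <- sim_params(n_transcripts = 800, linked_fraction = 1, n_outlier_snps = 150, seed = 37)
  sim <- simulate_dataset(p)
  near <- transcripts_near_snps(sim$map, sim$outliers$snps, window = p$window)
  de_tx <- sim$truth$transcript_id[sim$truth$kar_de | sim$truth$sex_de]
  expect_true(all(near$near[near$transcript_id %in%
                              sim$outliers$linkage$transcript_id]))
  expect_true(all(sim$outliers$linkage$transcript_id %in% de_tx))

  p0 <- sim_params(n_transcripts = 200, n_outlier_snps = 0, seed = 38)
  lay0 <- simulate_layout(p0)
  cnt0 <- simulate_counts(p0, lay0$layout, lay0$map)
  out0 <- simulate_outlier_snps(p0, lay0$map, cnt0$truth, lay0$layout)
  expect_equal(nrow(out0$snps), 0)
  near0 <- transcripts_near_snps(lay0$map, out0$snps, window = 5000)
  expect_equal(sum(near0$near), 0)
})

test_that("the consistency auditor passes on a default simulation", {
  sim <- simulate_dataset(sim_params(n_transcripts = 400, seed = 39))
  expect_true(audit_simulation(sim))
  # and the emitted files pass io validation on re-read
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_equal(read_counts(paths["counts"]), sim$counts)
  expect_equal(read_sample_meta(paths["meta"]), sim$meta)
  map_back <- read_intervals(paths["transcripts"], "transcripts", sim$layout)
  expect_equal(map_back$start, sim$map$start)
  expect_equal(map_back$transcript_id, sim$map$transcript_id)
})
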