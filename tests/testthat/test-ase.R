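# compact builders for allele-count and genotype fixtures
ac_row <- function(snp, pool, a, b) {
  tibble::tibble(snp_id = snp, pool_id = pool, alpha_reads = a, beta_reads = b)
}
geno_block <- function(snp, freq_aa = 1, freq_bb = 0, n_each = 3, na_idx = integer()) {
  g <- tibble::tibble(
    snp_id = snp,
    sample_id = c(sprintf("aa%d", 1:n_each), sprintf("bb%d", 1:n_each)),
    karyotype = rep(c("AA", "BB"), each = n_each),
    allele_freq = c(rep(freq_aa, n_each), rep(freq_bb, n_each)))
  g$allele_freq[na_idx] <- NA
  g
}

test_that("fixed-difference filtering retains fixed SNPs and rejects violations", {
  ac <- dplyr::bind_rows(lapply(sprintf("p%d", 1:4), function(p) {
    dplyr::bind_rows(ac_row("fixed", p, 10, 10), ac_row("polymorphic", p, 10, 10),
                     ac_row("shallow", p, 2, 2), ac_row("reversed", p, 3, 17))
  }))
  gt <- dplyr::bind_rows(
    geno_block("fixed"),
    geno_block("polymorphic", freq_aa = 2 / 3), # one AA sample carries the other allele
    geno_block("shallow"),
    geno_block("reversed", freq_aa = 0, freq_bb = 1))
  kept <- filter_fixed_snps(ac, gt)
  expect_setequal(unique(kept$snp_id), c("fixed", "reversed"))
  # reversed SNP has its read columns swapped so alpha follows the alpha arrangement
  rev_rows <- kept[kept$snp_id == "reversed", ]
  expect_true(all(rev_rows$alpha_reads == 17 & rev_rows$beta_reads == 3))
  # mean depth 4 <= 5 removed "shallow"; polymorphic removed by fixedness
})

test_that("filter counts match a brute-force oracle on a randomized fixture", {
  set.seed(71)
  n_snp <- 100
  snps <- sprintf("s%03d", 1:n_snp)
  pools <- sprintf("p%d", 1:6)
  ac <- tidyr::crossing(snp_id = snps, pool_id = pools)
  depth <- rpois(nrow(ac), lambda = sample(c(2, 12), nrow(ac), TRUE))
  ac$alpha_reads <- rbinom(nrow(ac), depth, 0.5)
  ac$beta_reads <- depth - ac$alpha_reads
  gt <- dplyr::bind_rows(lapply(snps, function(s) {
    fa <- sample(c(1, 1, 1, 2 / 3), 1)  # some SNPs not fixed
    geno_block(s, freq_aa = fa, na_idx = if (runif(1) < 0.3) sample(6, 2) else integer())
  }))
  kept <- filter_fixed_snps(ac, gt, min_mean_depth = 5, max_missing = 0.25,
                            min_individuals = 3)

  oracle <- vapply(snps, function(s) {
    g <- gt[gt$snp_id == s, ]
    f_aa <- mean(g$allele_freq[g$karyotype == "AA"], na.rm = TRUE)
    f_bb <- mean(g$allele_freq[g$karyotype == "BB"], na.rm = TRUE)
    n_aa <- sum(!is.na(g$allele_freq[g$karyotype == "AA"]))
    n_bb <- sum(!is.na(g$allele_freq[g$karyotype == "BB"]))
    fixed <- n_aa > 0 && n_bb > 0 &&
      ((identical(f_aa, 1) && identical(f_bb, 0)) || (identical(f_aa, 0) && identical(f_bb, 1)))
    rows <- ac[ac$snp_id == s, ]
    md <- mean(rows$alpha_reads + rows$beta_reads)
    np <- sum(rows$alpha_reads + rows$beta_reads > 0)
    fixed && mean(is.na(g$allele_freq)) <= 0.25 && md > 5 && np >= 3
  }, logical(1))
  expect_setequal(unique(kept$snp_id), snps[oracle])
})

test_that("per-transcript fractions average depths across SNPs per pool", {
  snp_map <- tibble::tibble(snp_id = c("s1", "s2"), transcript_id = "tx")
  f1 <- per_transcript_fractions(ac_row("s1", "p1", 30, 10), snp_map)
  expect_equal(f1$alpha_frac, 0.75)

  f2 <- per_transcript_fractions(
    dplyr::bind_rows(ac_row("s1", "p1", 30, 10), ac_row("s2", "p1", 10, 30)), snp_map)
  expect_equal(f2$alpha_frac, 0.5)
  expect_equal(f2$mean_alpha, 20)

  set.seed(72)
  snps <- sprintf("s%d", 1:5)
  smap <- tibble::tibble(snp_id = snps, transcript_id = rep(c("t1", "t2"), c(2, 3)))
  ac <- tidyr::crossing(snp_id = snps, pool_id = c("p1", "p2"))
  ac$alpha_reads <- rpois(10, 20); ac$beta_reads <- rpois(10, 20)
  fr <- per_transcript_fractions(ac, smap)
  for (i in seq_len(nrow(fr))) {
    rows <- ac[ac$snp_id %in% smap$snp_id[smap$transcript_id == fr$transcript_id[i]] &
                 ac$pool_id == fr$pool_id[i], ]
    expect_equal(fr$alpha_frac[i],
                 mean(rows$alpha_reads) / (mean(rows$alpha_reads) + mean(rows$beta_reads)),
                 tolerance = 1e-12)
  }
})

test_that("the pooled binomial test is exact at 1:1 and powerful under strong bias", {
  fr_even <- tibble::tibble(transcript_id = "t", pool_id = sprintf("p%d", 1:4),
                            mean_alpha = 22, mean_beta = 22, alpha_frac = 0.5,
                            n_snps = 1)
  expect_equal(ase_test(fr_even)$p, 1)

  fr_bias <- tibble::tibble(transcript_id = "t", pool_id = sprintf("p%d", 1:6),
                            mean_alpha = 33, mean_beta = 11, alpha_frac = 0.75,
                            n_snps = 1)
  expect_lt(ase_test(fr_bias)$p, 1e-10)
})

test_that("the pooled binomial test holds its size on null fractions", {
  set.seed(73)
  n_tx <- 2000
  rows <- tidyr::crossing(transcript_id = sprintf("t%04d", 1:n_tx),
                          pool_id = sprintf("p%d", 1:6))
  depth <- rpois(nrow(rows), 44)
  a <- rbinom(nrow(rows), depth, 0.5)
  rows$mean_alpha <- a; rows$mean_beta <- depth - a
  rows <- rows[depth > 0, ]
  rows$alpha_frac <- rows$mean_alpha / (rows$mean_alpha + rows$mean_beta)
  rows$n_snps <- 1
  res <- ase_test(rows)
  expect_gt(mean(res$p < 0.05), 0.03)
  expect_lt(mean(res$p < 0.05), 0.07)
})

test_that("directional classification follows the strict pool-majority rule", {
  mk_fr <- function(fracs) tibble::tibble(
    transcript_id = "t", pool_id = sprintf("p%d", seq_along(fracs)),
    mean_alpha = 44 * fracs, mean_beta = 44 * (1 - fracs),
    alpha_frac = fracs, n_snps = 1)
  sig <- tibble::tibble(transcript_id = "t", n_pools = 6, mean_depth = 44,
                        mean_frac = 0.6, p = 1e-5, padj = 1e-4, significant = TRUE)

  expect_equal(as.character(classify_ase(sig, mk_fr(rep(0.7, 6)))$call), "alpha_biased")
  # exactly half the pools above the cutoff is not a strict majority
  expect_equal(as.character(classify_ase(sig, mk_fr(c(0.6, 0.6, 0.6, 0.5, 0.5, 0.5)))$call),
               "allele_biased")
  # inconsistent direction
  expect_equal(as.character(classify_ase(sig, mk_fr(c(0.8, 0.8, 0.2, 0.2, 0.5, 0.5)))$call),
               "allele_biased")
  # non-significant transcripts are never classified directionally
  ns <- dplyr::mutate(sig, significant = FALSE)
  expect_equal(as.character(classify_ase(ns, mk_fr(rep(0.9, 6)))$call), "not_significant")
})

test_that("binomial calibration reproduces the exact tails and matches simulation", {
  cal55 <- calibrate_fp(depth = 44, cutoff = 0.55, n_trials = 10000, seed = 74)
  expect_equal(cal55$fp_rate_exact, pbinom(24, 44, 0.5, lower.tail = FALSE))
  expect_equal(round(100 * cal55$fp_rate_exact, 1), 22.6)
  cal50 <- calibrate_fp(depth = 44, cutoff = 0.50, n_trials = 10000, seed = 75)
  expect_equal(round(100 * cal50$fp_rate_exact, 0), 44)
  cal1 <- calibrate_fp(depth = 1, cutoff = 0.55, n_trials = 1000, seed = 76)
  expect_equal(cal1$fp_rate_exact, 0.5)

  for (cal in list(cal55, cal50)) {
    se <- sqrt(cal$fp_rate_exact * (1 - cal$fp_rate_exact) / cal$n_trials)
    expect_lt(abs(cal$fp_rate_simulated - cal$fp_rate_exact), 4 * se)
  }

  # exact rate is non-increasing in the cutoff at fixed depth
  rates <- sapply(seq(0.5, 0.9, by = 0.05), function(ct)
    calibrate_fp(44, ct, n_trials = 10, seed = 1)$fp_rate_exact)
  expect_true(all(diff(rates) <= 1e-12))
})

test_that("scheme-level error is the exact binomial tail over pools", {
  expect_equal(scheme_error(0), 0)
  expect_equal(scheme_error(1), 1)
  # direct summation oracle for P(K >= 4 of 6)
  fp <- 0.226
  oracle <- sum(sapply(4:6, function(k) choose(6, k) * fp^k * (1 - fp)^(6 - k)))
  expect_equal(scheme_error(fp, n_pools = 6), oracle, tolerance = 1e-12)
})

test_that("swapping alpha and beta reads swaps directional calls and keeps p-values", {
  sim <- simulate_dataset(sim_params(n_transcripts = 400, frac_ase_biased = 0.6,
                                     seed = 77))
  ac <- sim$ase$allele_counts
  gt <- sim$ase$genotypes
  run <- function(ac_in, gt_in) {
    kept <- filter_fixed_snps(ac_in, gt_in)
    fr <- per_transcript_fractions(kept, sim$ase$snp_map)
    classify_ase(ase_test(fr), fr)
  }
  fwd <- run(ac, gt)
  ac_sw <- dplyr::mutate(ac, tmp = alpha_reads, alpha_reads = beta_reads,
                         beta_reads = tmp, tmp = NULL)
  rev <- run(ac_sw, gt)
  j <- dplyr::inner_join(fwd, rev, by = "transcript_id", suffix = c("_f", "_r"))
  expect_equal(j$p_f, j$p_r, tolerance = 1e-12)
  swap <- c(alpha_biased = "beta_biased", beta_biased = "alpha_biased",
            allele_biased = "allele_biased", not_significant = "not_significant")
  expect_equal(as.character(j$call_r), unname(swap[as.character(j$call_f)]))
})
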