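# Allele-specific expression in heterokaryotypes: fixed-difference SNP
# filtering, per-transcript allele fractions, a pooled exact binomial test
# (the significance stand-in; the module boundary lets users substitute
# another test), the directional-bias classifier, and exact/simulated
# binomial calibration of its single-pool false-positive rate.
#
# TSV dialect: allele counts are long tables (snp_id, pool_id, alpha_reads,
# beta_reads) where "alpha" is the allele carried by the α arrangement;
# homokaryote genotypes are long tables (snp_id, sample_id, karyotype,
# allele_freq) with allele_freq the within-sample frequency of that same
# allele (0/1 in homokaryotes, NA = missing).

#' Filter SNPs to fixed differences between arrangements
#'
#' Retains SNPs that are fixed for alternate alleles between the AA and BB
#' homokaryote groups (allele frequency 1 vs 0 — the FST = 1 condition; a
#' SNP fixed in the opposite orientation is kept with its alpha/beta read
#' columns swapped), have mean read depth across heterokaryote pools strictly
#' greater than `min_mean_depth`, at most `max_missing` of homokaryote
#' samples missing a genotype, and at least `min_individuals` heterokaryote
#' pools with nonzero depth.
#'
#' @param allele_counts Long tibble `snp_id`, `pool_id`, `alpha_reads`,
#'   `beta_reads`.
#' @param genotypes Long tibble `snp_id`, `sample_id`, `karyotype` (AA/BB),
#'   `allele_freq` (NA = missing).
#' @param min_mean_depth Minimum mean depth over pools, strict (default 5).
#' @param max_missing Maximum missing-genotype fraction (default 0.25).
#' @param min_individuals Minimum heterokaryote pools with data (default 3).
#' @return The retained rows of `allele_counts` (orientation-corrected),
#'   with attribute `"snps"`: tibble of retained snp ids.
#' @export
filter_fixed_snps <- function(allele_counts, genotypes,
                              min_mean_depth = 5, max_missing = 0.25,
                              min_individuals = 3) {
  gt <- dplyr::filter(as_tibble(genotypes), .data$karyotype %in% c("AA", "BB"))
  if (!all(c("AA", "BB") %in% gt$karyotype)) {
    rlang::abort("both AA and BB homokaryotes are required to assess fixed differences")
  }
  geno <- gt |>
    group_by(.data$snp_id) |>
    summarise(
      freq_AA = mean(.data$allele_freq[.data$karyotype == "AA"], na.rm = TRUE),
      freq_BB = mean(.data$allele_freq[.data$karyotype == "BB"], na.rm = TRUE),
      n_AA = sum(.data$karyotype == "AA" & !is.na(.data$allele_freq)),
      n_BB = sum(.data$karyotype == "BB" & !is.na(.data$allele_freq)),
      missing_frac = mean(is.na(.data$allele_freq)),
      .groups = "drop")
  geno$fixed_fwd <- geno$n_AA > 0 & geno$n_BB > 0 &
    geno$freq_AA == 1 & geno$freq_BB == 0
  geno$fixed_rev <- geno$n_AA > 0 & geno$n_BB > 0 &
    geno$freq_AA == 0 & geno$freq_BB == 1

  ac <- as_tibble(allele_counts)
  depth_stats <- ac |>
    group_by(.data$snp_id) |>
    summarise(mean_depth = mean(.data$alpha_reads + .data$beta_reads),
              n_pools = sum(.data$alpha_reads + .data$beta_reads > 0),
              .groups = "drop")
  keep <- geno |>
    inner_join(depth_stats, by = "snp_id") |>
    dplyr::filter((.data$fixed_fwd | .data$fixed_rev),
                  .data$missing_frac <= max_missing,
                  .data$mean_depth > min_mean_depth,
                  .data$n_pools >= min_individuals)
  out <- ac[ac$snp_id %in% keep$snp_id, , drop = FALSE]
  flip <- out$snp_id %in% keep$snp_id[keep$fixed_rev]
  if (any(flip)) {
    tmp <- out$alpha_reads[flip]
    out$alpha_reads[flip] <- out$beta_reads[flip]
    out$beta_reads[flip] <- tmp
  }
  attr(out, "snps") <- dplyr::select(keep, "snp_id", "mean_depth", "n_pools")
  out
}

#' Per-transcript, per-pool allele fractions
#'
#' Read depths are averaged across a transcript's retained SNPs within each
#' pool; the α-allele fraction is mean(alpha) / (mean(alpha) + mean(beta)).
#' Pools with zero total depth for a transcript are excluded.
#'
#' @param allele_counts Retained allele counts (from [filter_fixed_snps()]).
#' @param snp_map Tibble `snp_id`, `transcript_id` linking SNPs to
#'   transcripts.
#' @return Tibble `transcript_id`, `pool_id`, `mean_alpha`, `mean_beta`,
#'   `alpha_frac`, `n_snps`.
#' @export
per_transcript_fractions <- function(allele_counts, snp_map) {
  d <- inner_join(as_tibble(allele_counts),
                  dplyr::select(as_tibble(snp_map), "snp_id", "transcript_id"),
                  by = "snp_id")
  d |>
    group_by(.data$transcript_id, .data$pool_id) |>
    summarise(mean_alpha = mean(.data$alpha_reads),
              mean_beta = mean(.data$beta_reads),
              n_snps = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$mean_alpha + .data$mean_beta > 0) |>
    mutate(alpha_frac = .data$mean_alpha / (.data$mean_alpha + .data$mean_beta))
}

#' Pooled exact binomial test for allelic imbalance
#'
#' Per transcript, the per-pool mean alpha and total depths are summed
#' (rounded to counts) and tested against a 1:1 ratio with an exact
#' two-sided binomial test; BH adjustment across transcripts.
#'
#' @param fractions Tibble from [per_transcript_fractions()].
#' @param min_individuals Minimum pools with data per transcript (default 3).
#' @param ase_alpha Adjusted-p significance threshold (default 0.1).
#' @return Tibble `transcript_id`, `n_pools`, `mean_depth`, `mean_frac`,
#'   `p`, `padj`, `significant`.
#' @export
ase_test <- function(fractions, min_individuals = 3, ase_alpha = 0.1) {
  res <- fractions |>
    group_by(.data$transcript_id) |>
    summarise(n_pools = dplyr::n(),
              mean_depth = mean(.data$mean_alpha + .data$mean_beta),
              mean_frac = mean(.data$alpha_frac),
              x = round(sum(.data$mean_alpha)),
              n = round(sum(.data$mean_alpha)) + round(sum(.data$mean_beta)),
              .groups = "drop") |>
    dplyr::filter(.data$n_pools >= min_individuals)
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    if (res$n[i] == 0) return(1)
    stats::binom.test(res$x[i], res$n[i], p = 0.5)$p.value
  }, numeric(1))
  res$padj <- adjust_bh(res$p)
  res$significant <- res$padj < ase_alpha
  dplyr::select(res, "transcript_id", "n_pools", "mean_depth", "mean_frac",
                "p", "padj", "significant")
}

#' Classify significant transcripts by direction of allelic bias
#'
#' A significant transcript is `alpha_biased` when strictly more than
#' `pool_majority` of its pools have an α fraction strictly above `cutoff`;
#' `beta_biased` symmetrically on the β fraction; significant transcripts
#' meeting neither condition (inconsistent direction) are `allele_biased`;
#' non-significant transcripts are `not_significant`.
#'
#' @param test Tibble from [ase_test()].
#' @param fractions Tibble from [per_transcript_fractions()].
#' @param cutoff Per-pool read-fraction cutoff (default 0.55, strict).
#' @param pool_majority Required fraction of pools (default 0.5, strict).
#' @return `test` with a `call` column (factor: `alpha_biased`,
#'   `beta_biased`, `allele_biased`, `not_significant`).
#' @export
classify_ase <- function(test, fractions, cutoff = 0.55, pool_majority = 0.5) {
  dir <- fractions |>
    group_by(.data$transcript_id) |>
    summarise(k_alpha = sum(.data$alpha_frac > cutoff),
              k_beta = sum((1 - .data$alpha_frac) > cutoff),
              n = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(test, dir, by = "transcript_id")
  out$call <- factor(dplyr::case_when(
    !out$significant ~ "not_significant",
    out$k_alpha / out$n > pool_majority ~ "alpha_biased",
    out$k_beta / out$n > pool_majority ~ "beta_biased",
    TRUE ~ "allele_biased"
  ), levels = c("alpha_biased", "beta_biased", "allele_biased", "not_significant"))
  dplyr::select(out, -"k_alpha", -"k_beta", -"n")
}

# smallest integer count strictly exceeding fraction `cutoff` of `n`
strict_count_threshold <- function(n, cutoff) {
  cn <- cutoff * n
  if (abs(cn - round(cn)) < 1e-9) round(cn) + 1 else ceiling(cn)
}

#' Single-pool false-positive calibration of the read-fraction cutoff
#'
#' Under true 1:1 allelic expression, the probability that a pool's α
#' fraction strictly exceeds `cutoff` at the given read depth: estimated
#' from `n_trials` binomial draws, and exactly as the binomial upper tail
#' P(X >= k) with k the smallest count strictly exceeding `cutoff * depth`.
#'
#' @param depth Read depth per pool (default 44, the study's mean depth).
#' @param cutoff Read-fraction cutoff (default 0.55).
#' @param n_trials Number of simulated draws (default 10000).
#' @param seed RNG seed.
#' @return One-row tibble `depth`, `cutoff`, `n_trials`, `seed`,
#'   `fp_rate_simulated`, `fp_rate_exact`.
#' @export
calibrate_fp <- function(depth = 44, cutoff = 0.55, n_trials = 10000, seed = 1) {
  stopifnot(depth >= 1, cutoff > 0, cutoff < 1)
  k <- strict_count_threshold(depth, cutoff)
  fp_exact <- stats::pbinom(k - 1, depth, 0.5, lower.tail = FALSE)
  set.seed(seed)
  x <- stats::rbinom(n_trials, depth, 0.5)
  fp_sim <- mean(x / depth > cutoff)
  tibble(depth = depth, cutoff = cutoff, n_trials = n_trials, seed = seed,
         fp_rate_simulated = fp_sim, fp_rate_exact = fp_exact)
}

#' Chance rate of a directional call under the full classification scheme
#'
#' With per-pool false-positive rate `per_pool_fp` and `n_pools` independent
#' pools, the probability that strictly more than `pool_majority` of the
#' pools exceed the cutoff in one fixed direction: the exact binomial upper
#' tail P(K >= k) with k the smallest count strictly exceeding
#' `pool_majority * n_pools`.
#'
#' @param per_pool_fp Single-pool false-positive rate (e.g. from
#'   [calibrate_fp()]).
#' @param n_pools Number of heterokaryote pools (default 6).
#' @param pool_majority Required fraction of pools (default 0.5, strict).
#' @return Probability in \[0, 1\].
#' @export
scheme_error <- function(per_pool_fp, n_pools = 6, pool_majority = 0.5) {
  stopifnot(per_pool_fp >= 0, per_pool_fp <= 1)
  k <- strict_count_threshold(n_pools, pool_majority)
  stats::pbinom(k - 1, n_pools, per_pool_fp, lower.tail = FALSE)
}

#' Calibration table over depths and cutoffs
#'
#' @param depths,cutoffs Vectors of depths and cutoffs to cross.
#' @param n_pools Pools used for the scheme-level error column.
#' @param n_trials,seed Passed to [calibrate_fp()].
#' @return Tibble keyed by (`depth`, `cutoff`) with simulated and exact
#'   single-pool rates and the scheme-level error at `n_pools`.
#' @export
calibration_table <- function(depths = 44, cutoffs = c(0.5, 0.55),
                              n_pools = 6, n_trials = 10000, seed = 1) {
  grid <- expand.grid(depth = depths, cutoff = cutoffs)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cal <- calibrate_fp(grid$depth[i], grid$cutoff[i], n_trials, seed + i)
    cal$n_pools <- n_pools
    cal$scheme_error <- scheme_error(cal$fp_rate_exact, n_pools)
    cal
  })
}
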