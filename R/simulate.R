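# Synthetic-data generator emulating the study design: a 6-linkage-group
# genome with a large inversion on LG1 (60% of LG1, 10% of the genome),
# 17 adults sequenced singly, 27 larval pools of three with unbalanced
# karyotypes (2 AA / 10 AB / 15 BB), negative-binomial counts with sex- and
# karyotype-biased genes (heterokaryote means set by each gene's dominance
# class), fixed-difference SNP allele reads in heterokaryote pools, and
# outlier SNPs optionally placed near truly-DE transcripts. Ground truth is
# retained for recovery tests.

#' Simulation parameters
#'
#' Defaults mirror the study design (sample plan, pool sizes, genome/
#' inversion geometry, read depth 44 at ASE SNPs); generative-model
#' conventions (negative-binomial with dispersion k, variance mu + mu^2/k;
#' log-normal baseline means) are documented in the methods vignette.
#'
#' @param n_transcripts Number of transcripts.
#' @param lg_length Length (bp) of each of `n_linkage_groups` linkage groups.
#' @param n_linkage_groups Number of linkage groups (default 6).
#' @param inversion_fraction Fraction of LG1 covered by the inversion
#'   (default 0.60; with 6 equal groups this is 10% of the genome).
#' @param transcript_meanlog,transcript_sdlog Log-normal parameters of
#'   transcript length.
#' @param n_adults Named counts of adult samples per sex x homokaryotype
#'   cell.
#' @param n_larval_pools Named counts of larval pools per karyotype.
#' @param pool_size Larvae per pool (default 3).
#' @param adult_pop2_n Adults drawn from the second population (default 4 of
#'   17).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline mean
#'   counts.
#' @param dispersion_k NB dispersion (variance mu + mu^2/k; default 10).
#' @param frac_sex_de,frac_kar_de Fractions of transcripts truly sex- /
#'   karyotype-DE.
#' @param sex_lfc_range,kar_lfc_range Ranges of true |log2FC| magnitudes.
#' @param p_male_up,p_bb_up Probability a sex-DE gene is male-upregulated /
#'   a karyotype-DE gene is ββ-upregulated.
#' @param cis_fraction Probability a karyotype-DE gene lies inside the
#'   inversion (default 0.8).
#' @param dominance_mix Named proportions (summing to 1) of dominance
#'   classes among karyotype-DE genes.
#' @param dominance_dev log2 deviation beyond the homokaryote range for
#'   over-/underdominant genes (default 1).
#' @param pop_effect_sd SD of per-gene log2 population effects (default 0.2).
#' @param n_snps_per_transcript Fixed-difference SNPs per inversion
#'   transcript (default 3).
#' @param ase_depth_mean Mean (Poisson) read depth per SNP per pool
#'   (default 44).
#' @param ase_depth_fixed Use `ase_depth_mean` as an exact depth instead of
#'   a Poisson mean (default FALSE).
#' @param frac_ase_biased Fraction of inversion transcripts with true
#'   allelic bias (default 0.5).
#' @param ase_bias Allele-fraction deviation from 0.5 for biased
#'   transcripts (default 0.2).
#' @param ase_frac_nonfixed Fraction of simulated SNPs violating fixedness
#'   (so the filter is exercised; default 0.05).
#' @param geno_missing_rate Missing-genotype rate in homokaryotes
#'   (default 0.05).
#' @param n_outlier_snps Number of outlier SNPs (default 500).
#' @param linked_fraction Fraction of outlier SNPs placed within `window` of
#'   a truly-DE transcript (default 0.5).
#' @param window Placement/overlap window in bp (default 5000).
#' @param seed RNG seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_transcripts = 2000,
                       lg_length = 40e6,
                       n_linkage_groups = 6,
                       inversion_fraction = 0.60,
                       transcript_meanlog = log(1000), transcript_sdlog = 0.6,
                       n_adults = c(AA_male = 4, AA_female = 4, BB_male = 4, BB_female = 5),
                       n_larval_pools = c(AA = 2, AB = 10, BB = 15),
                       pool_size = 3,
                       adult_pop2_n = 4,
                       base_meanlog = 4, base_sdlog = 1.5,
                       dispersion_k = 10,
                       frac_sex_de = 0.10, frac_kar_de = 0.05,
                       sex_lfc_range = c(2.5, 5), kar_lfc_range = c(2.5, 5),
                       p_male_up = 0.68, p_bb_up = 0.6,
                       cis_fraction = 0.8,
                       dominance_mix = c(additive = 0.35, alpha_dominant = 0.30,
                                         beta_dominant = 0.30, underdominant = 0.025,
                                         overdominant = 0.025),
                       dominance_dev = 1,
                       pop_effect_sd = 0.2,
                       n_snps_per_transcript = 3,
                       ase_depth_mean = 44,
                       ase_depth_fixed = FALSE,
                       frac_ase_biased = 0.5,
                       ase_bias = 0.2,
                       ase_frac_nonfixed = 0.05,
                       geno_missing_rate = 0.05,
                       n_outlier_snps = 500,
                       linked_fraction = 0.5,
                       window = 5000,
                       seed = 42) {
  p <- as.list(environment())
  stopifnot(p$n_transcripts >= 1,
            p$inversion_fraction >= 0, p$inversion_fraction <= 1,
            p$frac_sex_de >= 0, p$frac_sex_de <= 1,
            p$frac_kar_de >= 0, p$frac_kar_de <= 1,
            p$cis_fraction >= 0, p$cis_fraction <= 1,
            p$linked_fraction >= 0, p$linked_fraction <= 1,
            p$frac_ase_biased >= 0, p$frac_ase_biased <= 1,
            p$ase_depth_mean >= 1,
            abs(sum(p$dominance_mix) - 1) < 1e-8)
  structure(p, class = "sim_params")
}

#' Simulate the genome layout and transcript map
#'
#' Transcripts are placed uniformly along linkage groups with probability
#' proportional to group length; the inversion covers `inversion_fraction`
#' of LG1 (placed away from the chromosome ends), so the expected fraction
#' of transcripts overlapping it equals the inversion's genome fraction.
#'
#' @param params A [sim_params()] list.
#' @return List with `layout` ([genome_layout()]) and `map` (transcript map
#'   tibble).
#' @export
simulate_layout <- function(params) {
  set.seed(params$seed)
  lgs <- tibble(lg = paste0("LG", seq_len(params$n_linkage_groups)),
                length = rep(params$lg_length, params$n_linkage_groups))
  inv_len <- round(params$inversion_fraction * lgs$length[1])
  if (inv_len >= 1) {
    inv_start <- round((lgs$length[1] - inv_len) * 0.4)
    layout <- genome_layout(lgs, list(lg = "LG1", start = inv_start,
                                      end = inv_start + inv_len))
  } else {
    # fraction 0: a 1-bp sentinel interval at the chromosome end, which no
    # simulated transcript can overlap
    layout <- genome_layout(lgs, list(lg = "LG1", start = lgs$length[1] - 1,
                                      end = lgs$length[1]))
  }
  lens <- pmax(round(stats::rlnorm(params$n_transcripts,
                                   params$transcript_meanlog, params$transcript_sdlog)), 200)
  if (any(lens >= params$lg_length)) rlang::abort("genome too short for simulated transcript lengths")
  lg_idx <- sample.int(nrow(lgs), params$n_transcripts, replace = TRUE,
                       prob = lgs$length)
  start <- floor(stats::runif(params$n_transcripts) * (lgs$length[lg_idx] - lens))
  map <- tibble(transcript_id = sprintf("tx%05d", seq_len(params$n_transcripts)),
                region = lgs$lg[lg_idx],
                start = as.integer(start), end = as.integer(start + lens),
                strand = sample(c("+", "-"), params$n_transcripts, replace = TRUE))
  list(layout = layout, map = map)
}

sim_sample_meta <- function(params) {
  adults <- purrr::imap_dfr(as.list(params$n_adults), function(n, cell) {
    parts <- strsplit(cell, "_")[[1]]
    tibble(karyotype = parts[1], sex = parts[2], n = n)
  })
  adult_meta <- adults |>
    tidyr::uncount(.data$n) |>
    mutate(sample_id = sprintf("ad%02d", dplyr::row_number()),
           life_stage = "adult", pool_size = 1L)
  npop2 <- min(params$adult_pop2_n, nrow(adult_meta))
  adult_meta$population <- "pop1"
  if (npop2 > 0) adult_meta$population[seq_len(npop2)] <- "pop2"
  larvae <- purrr::imap_dfr(as.list(params$n_larval_pools), function(n, k) {
    tibble(karyotype = rep(k, n))
  }) |>
    mutate(sample_id = sprintf("lv%02d", dplyr::row_number()),
           life_stage = "larva", sex = "unknown",
           pool_size = as.integer(params$pool_size))
  larvae$population <- rep_len(c("pop1", "pop2"), nrow(larvae))
  validate_sample_meta(dplyr::bind_rows(
    dplyr::select(adult_meta, "sample_id", "life_stage", "sex", "karyotype",
                  "population", "pool_size"),
    dplyr::select(larvae, "sample_id", "life_stage", "sex", "karyotype",
                  "population", "pool_size")))
}

# per-gene log2 mean for a sample given truth row
sim_log2_mean <- function(truth, meta_row) {
  mu <- truth$base_log2
  if (meta_row$life_stage == "adult" && truth$sex_de) {
    if (meta_row$sex == "male") mu <- mu + truth$sex_lfc
  }
  mu
}

#' Simulate counts, metadata and ground truth
#'
#' Counts follow a negative binomial with log-link: the log2 mean is
#' baseline + sex effect (adult males only; larvae have unknown sex and no
#' sex effect) + karyotype effect, where the heterokaryote mean follows the
#' gene's dominance class (additive = log2 midpoint of the homokaryotes;
#' α-/β-dominant = the matching homokaryote mean; over/under = beyond the
#' homokaryote range by `dominance_dev`). Larval pool counts are sums of
#' `pool_size` independent individual draws. Karyotype-DE genes are placed
#' inside the inversion with probability `cis_fraction`.
#'
#' @param params A [sim_params()] list.
#' @param layout,map From [simulate_layout()].
#' @return List with `counts`, `meta`, `truth` (per-transcript tibble:
#'   `sex_de`, `sex_lfc`, `kar_de`, `kar_lfc`, `dominance`, `inside_inversion`).
#' @export
simulate_counts <- function(params, layout, map) {
  set.seed(params$seed + 1L)
  meta <- sim_sample_meta(params)
  n <- params$n_transcripts
  labels <- assign_region(map, layout)
  inside <- labels$region_label == "inversion"

  n_kar <- round(params$frac_kar_de * n)
  kar_de <- rep(FALSE, n)
  if (n_kar > 0) {
    from_inside <- stats::rbinom(n_kar, 1, params$cis_fraction) == 1
    n_in <- min(sum(from_inside), sum(inside))
    n_out <- min(n_kar - n_in, sum(!inside))
    kar_de[sample(which(inside), n_in)] <- TRUE
    kar_de[sample(which(!inside), n_out)] <- TRUE
  }
  n_sex <- round(params$frac_sex_de * n)
  sex_de <- rep(FALSE, n)
  if (n_sex > 0) sex_de[sample.int(n, n_sex)] <- TRUE

  dom <- rep("additive", n)
  dom[kar_de] <- sample(names(params$dominance_mix), sum(kar_de), replace = TRUE,
                        prob = params$dominance_mix)
  kar_mag <- stats::runif(n, params$kar_lfc_range[1], params$kar_lfc_range[2])
  kar_sign <- ifelse(stats::rbinom(n, 1, params$p_bb_up) == 1, -1, 1) # negative = higher in BB
  kar_lfc <- ifelse(kar_de, kar_sign * kar_mag, 0)
  sex_mag <- stats::runif(n, params$sex_lfc_range[1], params$sex_lfc_range[2])
  sex_sign <- ifelse(stats::rbinom(n, 1, params$p_male_up) == 1, 1, -1)
  sex_lfc <- ifelse(sex_de, sex_sign * sex_mag, 0)
  base_log2 <- log2(stats::rlnorm(n, params$base_meanlog, params$base_sdlog))
  pop_lfc <- stats::rnorm(n, 0, params$pop_effect_sd)

  truth <- tibble(transcript_id = map$transcript_id,
                  base_log2 = base_log2,
                  sex_de = sex_de, sex_lfc = sex_lfc,
                  kar_de = kar_de, kar_lfc = kar_lfc,
                  dominance = ifelse(kar_de, dom, NA_character_),
                  pop_lfc = pop_lfc,
                  inside_inversion = inside,
                  region = labels$region_label)

  # per-gene log2 means by karyotype: BB = base, AA = base + kar_lfc,
  # AB by dominance class
  m_bb <- base_log2
  m_aa <- base_log2 + kar_lfc
  lo <- pmin(m_aa, m_bb); hi <- pmax(m_aa, m_bb)
  m_ab <- (m_aa + m_bb) / 2
  m_ab[kar_de & dom == "alpha_dominant"] <- m_aa[kar_de & dom == "alpha_dominant"]
  m_ab[kar_de & dom == "beta_dominant"] <- m_bb[kar_de & dom == "beta_dominant"]
  m_ab[kar_de & dom == "overdominant"] <- hi[kar_de & dom == "overdominant"] + params$dominance_dev
  m_ab[kar_de & dom == "underdominant"] <- lo[kar_de & dom == "underdominant"] - params$dominance_dev
  kar_means <- cbind(AA = m_aa, AB = m_ab, BB = m_bb)

  cmat <- matrix(0, nrow = n, ncol = nrow(meta),
                 dimnames = list(map$transcript_id, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    mj <- meta[j, ]
    lmu <- kar_means[, mj$karyotype]
    if (mj$life_stage == "adult" && mj$sex == "male") lmu <- lmu + sex_lfc
    if (mj$population == "pop2") lmu <- lmu + pop_lfc
    mu <- 2^lmu
    draws <- stats::rnbinom(n * mj$pool_size, size = params$dispersion_k,
                            mu = rep(mu, mj$pool_size))
    cmat[, j] <- rowSums(matrix(draws, nrow = n))
  }
  list(counts = matrix_to_counts(cmat), meta = meta, truth = truth)
}

#' Simulate allele read counts at fixed-difference SNPs
#'
#' For each transcript overlapping the inversion, `n_snps_per_transcript`
#' SNP positions are drawn inside its interval; in each heterokaryote (AB)
#' pool the total depth is Poisson(`ase_depth_mean`) and α-allele reads are
#' binomial(depth, p) with p = 0.5 for unbiased transcripts and 0.5 ± `ase_bias`
#' for truly biased ones. Homokaryote genotype columns (allele frequency of
#' the α-associated allele, with missingness and a small fraction of
#' non-fixed SNPs) are emitted so the fixed-difference filter is exercised.
#'
#' @param params A [sim_params()] list.
#' @param map Transcript map.
#' @param truth Truth tibble from [simulate_counts()].
#' @param meta Sample metadata from [simulate_counts()].
#' @return List with `allele_counts`, `genotypes`, `snp_map` (snp_id,
#'   transcript_id, region, pos) and `ase_truth` (per-transcript `biased`,
#'   `direction`, `bias`).
#' @export
simulate_ase_reads <- function(params, map, truth, meta) {
  set.seed(params$seed + 2L)
  inv_tx <- truth$transcript_id[truth$inside_inversion]
  if (length(inv_tx) == 0) rlang::abort("no transcripts overlap the inversion")
  het_pools <- meta$sample_id[meta$karyotype == "AB" & meta$life_stage == "larva"]
  homos <- meta[meta$karyotype %in% c("AA", "BB"), , drop = FALSE]

  biased <- stats::rbinom(length(inv_tx), 1, params$frac_ase_biased) == 1
  direction <- ifelse(stats::rbinom(length(inv_tx), 1, 0.5) == 1, "alpha", "beta")
  direction[!biased] <- NA_character_
  p_alpha <- ifelse(biased, ifelse(direction == "alpha",
                                   0.5 + params$ase_bias, 0.5 - params$ase_bias), 0.5)
  ase_truth <- tibble(transcript_id = inv_tx, biased = biased,
                      direction = direction,
                      bias = ifelse(biased, params$ase_bias, 0))

  snp_map <- purrr::map_dfr(seq_along(inv_tx), function(i) {
    tx <- map[map$transcript_id == inv_tx[i], ]
    pos <- sort(sample(seq.int(tx$start, tx$end - 1L),
                       min(params$n_snps_per_transcript, tx$end - tx$start)))
    tibble(snp_id = sprintf("%s_snp%d", inv_tx[i], seq_along(pos)),
           transcript_id = inv_tx[i], region = tx$region, pos = pos)
  })
  nonfixed <- stats::rbinom(nrow(snp_map), 1, params$ase_frac_nonfixed) == 1

  p_by_tx <- stats::setNames(p_alpha, inv_tx)
  allele_counts <- tidyr::crossing(snp_id = snp_map$snp_id, pool_id = het_pools) |>
    left_join(dplyr::select(snp_map, "snp_id", "transcript_id"), by = "snp_id")
  depth <- if (isTRUE(params$ase_depth_fixed)) {
    rep(round(params$ase_depth_mean), nrow(allele_counts))
  } else stats::rpois(nrow(allele_counts), params$ase_depth_mean)
  alpha <- stats::rbinom(nrow(allele_counts), depth,
                         p_by_tx[allele_counts$transcript_id])
  allele_counts$alpha_reads <- alpha
  allele_counts$beta_reads <- depth - alpha
  allele_counts <- dplyr::select(allele_counts, "snp_id", "pool_id",
                                 "alpha_reads", "beta_reads")

  genotypes <- tidyr::crossing(snp_id = snp_map$snp_id,
                               sample_id = homos$sample_id) |>
    left_join(dplyr::select(homos, "sample_id", "karyotype"), by = "sample_id")
  genotypes$allele_freq <- ifelse(genotypes$karyotype == "AA", 1, 0)
  # non-fixed SNPs: one AA individual carries the wrong allele
  bad_snps <- snp_map$snp_id[nonfixed]
  aa_ids <- homos$sample_id[homos$karyotype == "AA"]
  if (length(bad_snps) && length(aa_ids)) {
    flip <- genotypes$snp_id %in% bad_snps &
      genotypes$sample_id == aa_ids[1]
    genotypes$allele_freq[flip] <- 0
  }
  genotypes$allele_freq[stats::runif(nrow(genotypes)) < params$geno_missing_rate] <- NA
  list(allele_counts = allele_counts, genotypes = genotypes,
       snp_map = snp_map, ase_truth = ase_truth)
}

#' Simulate environmentally associated outlier SNPs
#'
#' `linked_fraction` of the SNPs are placed strictly within `window` bp of a
#' truly-DE transcript (karyotype- or sex-DE); the remainder are uniform on
#' the genome.
#'
#' @param params A [sim_params()] list.
#' @param map Transcript map.
#' @param truth Truth tibble from [simulate_counts()].
#' @param layout A [genome_layout()].
#' @return List with `snps` (snp_id, region, pos) and `linkage` (snp_id,
#'   linked, transcript_id).
#' @export
simulate_outlier_snps <- function(params, map, truth, layout) {
  set.seed(params$seed + 3L)
  n <- params$n_outlier_snps
  if (n == 0) {
    return(list(snps = tibble(snp_id = character(), region = character(),
                              pos = integer()),
                linkage = tibble(snp_id = character(), linked = logical(),
                                 transcript_id = character())))
  }
  de_ids <- truth$transcript_id[truth$kar_de | truth$sex_de]
  linked <- stats::rbinom(n, 1, params$linked_fraction) == 1
  if (length(de_ids) == 0) linked[] <- FALSE
  lgs <- layout$linkage_groups
  region <- character(n); pos <- integer(n); tx <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (linked[i]) {
      t_id <- sample(de_ids, 1)
      row <- map[map$transcript_id == t_id, ]
      L <- lgs$length[lgs$lg == row$region]
      lo <- max(0, row$start - params$window + 1)
      hi <- min(L - 1, row$end + params$window - 2)
      region[i] <- row$region
      pos[i] <- sample(seq.int(lo, hi), 1)
      tx[i] <- t_id
    } else {
      li <- sample.int(nrow(lgs), 1, prob = lgs$length)
      region[i] <- lgs$lg[li]
      pos[i] <- floor(stats::runif(1) * lgs$length[li])
    }
  }
  snps <- tibble(snp_id = sprintf("out%04d", seq_len(n)), region = region,
                 pos = as.integer(pos))
  list(snps = snps,
       linkage = tibble(snp_id = snps$snp_id, linked = linked, transcript_id = tx))
}

#' Run the full simulation
#'
#' @param params A [sim_params()] list.
#' @return List with `layout`, `map`, `counts`, `meta`, `truth`, `ase`
#'   (allele counts, genotypes, snp map, truth) and `outliers`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  lay <- simulate_layout(params)
  cnt <- simulate_counts(params, lay$layout, lay$map)
  ase <- simulate_ase_reads(params, lay$map, cnt$truth, cnt$meta)
  out <- simulate_outlier_snps(params, lay$map, cnt$truth, lay$layout)
  list(layout = lay$layout, map = lay$map, counts = cnt$counts,
       meta = cnt$meta, truth = cnt$truth, ase = ase, outliers = out,
       params = params)
}

#' Audit simulated data against its ground truth
#'
#' Consistency checks: emitted files pass validation; truth rows match the
#' transcript map; ASE truth covers exactly the inversion transcripts;
#' linked outlier SNPs really are within the window of their transcript.
#'
#' @param sim Result of [simulate_dataset()].
#' @return TRUE invisibly; aborts on any inconsistency.
#' @export
audit_simulation <- function(sim) {
  validate_counts(sim$counts)
  validate_sample_meta(sim$meta)
  stopifnot(identical(sim$counts$transcript_id, sim$map$transcript_id),
            identical(sim$truth$transcript_id, sim$map$transcript_id),
            setdiff(names(sim$counts)[-1], sim$meta$sample_id) == character(0))
  labels <- assign_region(sim$map, sim$layout)
  if (!identical(labels$region_label == "inversion", sim$truth$inside_inversion)) {
    rlang::abort("truth/region label mismatch")
  }
  if (!setequal(sim$ase$ase_truth$transcript_id,
                sim$truth$transcript_id[sim$truth$inside_inversion])) {
    rlang::abort("ASE truth does not cover the inversion transcripts")
  }
  link <- sim$outliers$linkage
  if (any(link$linked)) {
    near <- transcripts_near_snps(sim$map,
                                  sim$outliers$snps[link$linked, , drop = FALSE],
                                  window = sim$params$window)
    ok <- near$near[match(link$transcript_id[link$linked], near$transcript_id)]
    if (!all(ok)) rlang::abort("a linked outlier SNP is not within the window of its transcript")
  }
  invisible(TRUE)
}

#' Write a simulated dataset to disk in the package's file formats
#'
#' Emits counts TSV, metadata TSV, transcript BED, outlier-SNP BED, allele
#' counts TSV, genotypes TSV, SNP map TSV and ground-truth TSV.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    meta = file.path(dir, "samples.tsv"),
    transcripts = file.path(dir, "transcripts.bed"),
    outlier_snps = file.path(dir, "outlier_snps.bed"),
    allele_counts = file.path(dir, "ase_allele_counts.tsv"),
    genotypes = file.path(dir, "ase_genotypes.tsv"),
    snp_map = file.path(dir, "ase_snp_map.tsv"),
    truth = file.path(dir, "ground_truth.tsv"))
  write_counts(sim$counts, paths["counts"])
  readr::write_tsv(sim$meta, paths["meta"], progress = FALSE)
  write_intervals(sim$map, paths["transcripts"])
  write_intervals(sim$outliers$snps, paths["outlier_snps"])
  readr::write_tsv(sim$ase$allele_counts, paths["allele_counts"], progress = FALSE)
  readr::write_tsv(sim$ase$genotypes, paths["genotypes"], progress = FALSE)
  readr::write_tsv(sim$ase$snp_map, paths["snp_map"], progress = FALSE)
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
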