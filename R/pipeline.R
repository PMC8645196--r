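# End-to-end orchestration: one call runs every analysis stage on a dataset
# (simulated or read from disk) with recorded seeds and thresholds.

#' Pipeline configuration
#'
#' Thresholds and seeds for a full [run_all()] run. All randomized stages
#' derive their seeds from `seed`, so a rerun with the same configuration
#' reproduces every statistic exactly.
#'
#' @param lfc_threshold,de_alpha DE call thresholds (defaults 2, 0.05).
#' @param min_total_count Low-count filter threshold (default 10).
#' @param ase_alpha ASE significance threshold on adjusted p (default 0.1).
#' @param ase_cutoff,pool_majority ASE classifier cutoffs (0.55, 0.5).
#' @param min_mean_depth,max_missing,min_individuals ASE SNP filters.
#' @param overlap_window Overlap window in bp (default 5000).
#' @param n_iterations Resampling iterations for the overlap null
#'   (default 10000).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param pca_n_top Transcripts for the PCA summary (default 500).
#' @param seed Master seed.
#' @param sim [sim_params()] used when no input paths are given.
#' @param paths Optional named list of input files (`counts`, `meta`,
#'   `transcripts`, `outlier_snps`, `allele_counts`, `genotypes`,
#'   `snp_map`) plus a `layout` object; when NULL the dataset is simulated.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lfc_threshold = 2, de_alpha = 0.05,
                            min_total_count = 10,
                            ase_alpha = 0.1, ase_cutoff = 0.55, pool_majority = 0.5,
                            min_mean_depth = 5, max_missing = 0.25, min_individuals = 3,
                            overlap_window = 5000, n_iterations = 10000,
                            n_permutations = 999, pca_n_top = 500,
                            seed = 42,
                            sim = sim_params(seed = seed),
                            paths = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$lfc_threshold > 0, cfg$de_alpha > 0, cfg$ase_alpha > 0,
            cfg$min_total_count > 0, cfg$overlap_window > 0,
            cfg$n_iterations > 0, cfg$n_permutations > 0)
  structure(cfg, class = "pipeline_config")
}

load_or_simulate <- function(config) {
  if (is.null(config$paths)) return(simulate_dataset(config$sim))
  p <- config$paths
  for (key in c("counts", "meta", "transcripts")) {
    if (is.null(p[[key]]) || !file.exists(p[[key]])) {
      rlang::abort(paste0("input file for '", key, "' is missing"))
    }
  }
  layout <- p$layout
  out <- list(layout = layout,
              map = read_intervals(p$transcripts, "transcripts", layout),
              counts = read_counts(p$counts),
              meta = read_sample_meta(p$meta),
              truth = NULL, params = NULL)
  if (!is.null(p$outlier_snps)) out$outliers <- list(snps = read_intervals(p$outlier_snps, "snps", layout))
  if (!is.null(p$allele_counts)) {
    out$ase <- list(
      allele_counts = readr::read_tsv(p$allele_counts, show_col_types = FALSE, progress = FALSE),
      genotypes = readr::read_tsv(p$genotypes, show_col_types = FALSE, progress = FALSE),
      snp_map = readr::read_tsv(p$snp_map, show_col_types = FALSE, progress = FALSE))
  }
  out
}

#' Run the full inversion-expression pipeline
#'
#' Executes the seven analysis stages — sample PCA, the differential-
#' expression contrasts, dominance classification of the larval contrasts,
#' localization/enrichment relative to the inversion, allele-specific
#' expression, DE x outlier-SNP overlap, and PERMANOVA per subgroup — and
#' returns all stage outputs with provenance (seed, thresholds, config
#' hash, package version). Any stage failure aborts naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return A named list of class `invexpr_report` with elements `pca`, `de`,
#'   `dominance`, `localization`, `ase`, `overlap`, `permanova`, `data`,
#'   `provenance`.
#' @export
run_all <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  dat <- stage("input", load_or_simulate(config))
  counts <- stage("filter", filter_low_counts(dat$counts, config$min_total_count))
  labels <- assign_region(dat$map, dat$layout)

  pca <- stage("pca", pca_top_variance(counts, n_top = min(config$pca_n_top, nrow(counts)),
                                       meta = dat$meta))

  contrasts <- default_contrasts(include_sex = TRUE)
  de <- stage("de", purrr::map(contrasts, function(ct) {
    nb_contrast(counts, dat$meta, ct,
                lfc_threshold = config$lfc_threshold, de_alpha = config$de_alpha)
  }))

  dominance <- stage("dominance", {
    eligible <- unique(unlist(purrr::map(
      de[c("larva_AA_vs_BB", "larva_AB_vs_BB", "larva_AA_vs_AB")],
      function(r) r$transcript_id[r$de_flag])))
    means <- karyotype_means(counts, dat$meta)
    calls <- classify_dominance(de$larva_AA_vs_AB, de$larva_AB_vs_BB, means,
                                eligible_ids = eligible)
    list(calls = calls, summary = summarize_dominance(calls, labels))
  })

  localization <- stage("localization", {
    tested <- de$adult_AA_vs_BB$transcript_id
    lab_sub <- labels[match(tested, labels$transcript_id), ]
    kar_de_ids <- tested[de$adult_AA_vs_BB$de_flag]
    sex_de_ids <- de$adult_male_vs_female$transcript_id[de$adult_male_vs_female$de_flag]
    list(
      labels = labels,
      enrichment = enrichment_test(de$adult_AA_vs_BB$de_flag, lab_sub$region_label),
      table = localization_table(labels, list(tested = tested,
                                              karyotype_de = kar_de_ids,
                                              sex_de = sex_de_ids)),
      breakpoints = breakpoint_distances(dat$map, dat$layout, ids = kar_de_ids),
      lfc = compare_lfc_distributions(
        list(female = de$female_AA_vs_BB, male = de$male_AA_vs_BB,
             larvae = de$larva_AA_vs_BB), labels))
  })

  ase <- stage("ase", {
    if (is.null(dat$ase)) NULL else {
      kept <- filter_fixed_snps(dat$ase$allele_counts, dat$ase$genotypes,
                                min_mean_depth = config$min_mean_depth,
                                max_missing = config$max_missing,
                                min_individuals = config$min_individuals)
      fr <- per_transcript_fractions(kept, dat$ase$snp_map)
      tst <- ase_test(fr, min_individuals = config$min_individuals,
                      ase_alpha = config$ase_alpha)
      cls <- classify_ase(tst, fr, cutoff = config$ase_cutoff,
                          pool_majority = config$pool_majority)
      cal <- calibration_table(depths = round(mean(tst$mean_depth)),
                               cutoffs = c(0.5, config$ase_cutoff),
                               n_pools = round(mean(tst$n_pools)),
                               seed = config$seed + 10L)
      list(fractions = fr, test = tst, calls = cls, calibration = cal)
    }
  })

  overlap <- stage("overlap", {
    if (is.null(dat$outliers)) NULL else {
      de_ids <- unique(unlist(purrr::map(de[setdiff(names(de), "adult_male_vs_female")],
                                         function(r) r$transcript_id[r$de_flag])))
      map_tested <- dat$map[dat$map$transcript_id %in% counts$transcript_id, ]
      inv_ids <- labels$transcript_id[labels$region_label == "inversion"]
      all_tx <- overlap_test(map_tested, de_ids, dat$outliers$snps,
                             window = config$overlap_window,
                             n_iterations = config$n_iterations,
                             seed = config$seed + 20L)
      inv_only <- if (length(intersect(de_ids, inv_ids)) > 0) {
        overlap_test(map_tested, de_ids, dat$outliers$snps,
                     window = config$overlap_window,
                     n_iterations = config$n_iterations,
                     seed = config$seed + 21L, restriction_ids = inv_ids)
      } else NULL
      list(all = all_tx, inversion_only = inv_only)
    }
  })

  perma <- stage("permanova", {
    norm <- normalize_counts(counts)
    subgroups <- list(
      males = list(subset = list(life_stage = "adult", sex = "male"),
                   terms = "karyotype"),
      females = list(subset = list(life_stage = "adult", sex = "female"),
                     terms = "karyotype"),
      adults = list(subset = list(life_stage = "adult"),
                    terms = c("karyotype", "sex")),
      larvae = list(subset = list(life_stage = "larva"),
                    terms = c("karyotype", "population")))
    purrr::imap(subgroups, function(sg, nm) {
      sub <- subset_samples(dat$meta, sg$subset)
      terms <- sg$terms[vapply(sg$terms, function(tm) length(unique(sub[[tm]])) >= 2,
                               logical(1))]
      expr <- norm[c("transcript_id", sub$sample_id)]
      permanova(manhattan_matrix(expr), sub, terms,
                n_permutations = config$n_permutations,
                seed = config$seed + 30L)
    })
  })

  structure(list(
    pca = pca, de = de, dominance = dominance, localization = localization,
    ase = ase, overlap = overlap, permanova = perma, data = dat,
    provenance = list(seed = config$seed,
                      thresholds = config[c("lfc_threshold", "de_alpha",
                                            "min_total_count", "ase_alpha",
                                            "ase_cutoff", "pool_majority",
                                            "overlap_window")],
                      config_hash = rlang::hash(unclass(config)),
                      package_version = as.character(utils::packageVersion("invexpr")))),
    class = "invexpr_report")
}

#' @export
print.invexpr_report <- function(x, ...) {
  cat("invexpr pipeline report (seed", x$provenance$seed, ")\n")
  cat("  stages: pca, de (", length(x$de), "contrasts ), dominance,",
      "localization, ase, overlap, permanova\n")
  n_de <- vapply(x$de, function(r) sum(r$de_flag), numeric(1))
  cat("  DE transcripts per contrast:\n")
  for (nm in names(n_de)) cat(sprintf("    %-22s %d\n", nm, n_de[nm]))
  invisible(x)
}

#' Write every stage's tables to a directory
#'
#' One TSV per stage output; every file name carries the configuration
#' hash so outputs from different runs cannot be mixed silently.
#'
#' @param report An `invexpr_report` from [run_all()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- substr(report$provenance$config_hash, 1, 8)
  wr <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(dir, paste0(name, ".", h, ".tsv")), progress = FALSE)
  }
  wr(tidy(report$pca), "pca_scores")
  for (nm in names(report$de)) wr(report$de[[nm]], paste0("de_", nm))
  wr(report$dominance$calls, "dominance_calls")
  wr(report$dominance$summary, "dominance_summary")
  wr(report$localization$enrichment, "enrichment")
  wr(report$localization$table, "localization_table")
  wr(report$localization$lfc, "lfc_distributions")
  if (!is.null(report$ase)) {
    wr(report$ase$calls, "ase_calls")
    wr(report$ase$calibration, "ase_calibration")
  }
  if (!is.null(report$overlap)) {
    wr(report$overlap$all, "overlap_all")
    if (!is.null(report$overlap$inversion_only)) wr(report$overlap$inversion_only, "overlap_inversion")
  }
  for (nm in names(report$permanova)) wr(tidy(report$permanova[[nm]]), paste0("permanova_", nm))
  invisible(dir)
}
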