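# Simplified negative-binomial differential-expression engine.
#
# The contract is statistical calibration (type-I error near nominal, unbiased
# log2FC recovery), not numerical agreement with any particular DE package:
# median-of-ratios size factors, a method-of-moments dispersion estimate with
# a mild shrink toward the mean-dispersion trend, per-gene NB log-linear fits
# with fixed dispersion, Wald tests, and BH adjustment.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over transcripts (restricted to
#' transcripts with a strictly positive geometric mean across samples) of the
#' ratio count / geometric mean.
#'
#' @param counts Count tibble (`transcript_id` + one column per sample).
#' @return Tibble with `sample_id`, `size_factor`.
#' @export
compute_size_factors <- function(counts) {
  m <- counts_to_matrix(validate_counts(counts))
  if (any(colSums(m) == 0)) {
    rlang::abort(paste0("sample(s) with all-zero counts: ",
                        paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  log_geo <- rowMeans(log(m))          # -Inf where any zero
  use <- is.finite(log_geo)
  if (!any(use)) rlang::abort("no transcript has a positive geometric mean; cannot normalize")
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - log_geo[use]))
  })
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Remove transcripts with low total counts
#'
#' Transcripts whose total raw count across all samples is strictly less than
#' `min_total` are removed (a total of exactly `min_total` is retained).
#'
#' @param counts Count tibble.
#' @param min_total Minimum total raw count (default 10).
#' @return Filtered count tibble.
#' @export
filter_low_counts <- function(counts, min_total = 10) {
  counts <- validate_counts(counts)
  tot <- rowSums(counts_to_matrix(counts))
  out <- counts[tot >= min_total, , drop = FALSE]
  if (nrow(out) == 0) rlang::warn("no transcript passes the low-count filter")
  out
}

#' Define a differential-expression contrast
#'
#' @param name Contrast label (used to name outputs).
#' @param factor Column of the metadata compared (e.g. `"karyotype"`).
#' @param levels Character vector of the two levels compared, `c(level1,
#'   level2)`; the log2 fold change is log2(level1 / level2), so for an
#'   AA-vs-BB karyotype contrast a negative value means higher expression in
#'   the ββ homokaryotype.
#' @param subset Named list restricting samples, e.g.
#'   `list(life_stage = "adult", sex = "male")`.
#' @param covariates Character vector of additional metadata columns entered
#'   as design covariates; covariates constant within the subset are dropped
#'   with a message.
#' @return A `de_contrast` object.
#' @export
de_contrast <- function(name, factor = "karyotype", levels = c("AA", "BB"),
                        subset = list(), covariates = character()) {
  stopifnot(length(levels) == 2, is.character(factor))
  structure(list(name = name, factor = factor, levels = levels,
                 subset = subset, covariates = covariates),
            class = "de_contrast")
}

#' The six standard karyotype/sex contrasts of the study design
#'
#' Adult AA vs BB (sexes combined, sex as covariate), male and female AA vs
#' BB, and the three larval contrasts (AA vs BB, AB vs BB, AA vs AB) with
#' population as covariate. A sex contrast (adult males vs females) is
#' included when `include_sex = TRUE`.
#'
#' @param include_sex Also return the adult male-vs-female contrast.
#' @return Named list of [de_contrast()] objects.
#' @export
default_contrasts <- function(include_sex = TRUE) {
  cs <- list(
    adult_AA_vs_BB  = de_contrast("adult_AA_vs_BB", subset = list(life_stage = "adult"),
                                  covariates = "sex"),
    male_AA_vs_BB   = de_contrast("male_AA_vs_BB",
                                  subset = list(life_stage = "adult", sex = "male")),
    female_AA_vs_BB = de_contrast("female_AA_vs_BB",
                                  subset = list(life_stage = "adult", sex = "female")),
    larva_AA_vs_BB  = de_contrast("larva_AA_vs_BB", subset = list(life_stage = "larva"),
                                  covariates = "population"),
    larva_AB_vs_BB  = de_contrast("larva_AB_vs_BB", levels = c("AB", "BB"),
                                  subset = list(life_stage = "larva"), covariates = "population"),
    larva_AA_vs_AB  = de_contrast("larva_AA_vs_AB", levels = c("AA", "AB"),
                                  subset = list(life_stage = "larva"), covariates = "population")
  )
  if (include_sex) {
    cs$adult_male_vs_female <- de_contrast("adult_male_vs_female", factor = "sex",
                                           levels = c("male", "female"),
                                           subset = list(life_stage = "adult"),
                                           covariates = "karyotype")
  }
  cs
}

subset_samples <- function(meta, subset) {
  keep <- rep(TRUE, nrow(meta))
  for (col in names(subset)) keep <- keep & meta[[col]] %in% subset[[col]]
  meta[keep, , drop = FALSE]
}

# Method-of-moments NB dispersion (alpha, variance = mu + alpha mu^2) per gene
# on normalized counts, with residual variance taken within design cells.
# When >= 50 genes are available the gene-wise estimate is averaged (weight
# 0.5) with a lowess trend on the base mean.
estimate_dispersions <- function(norm, cells, floor = 1e-8) {
  cells <- as.integer(factor(cells))
  n_cells <- max(cells)
  n <- ncol(norm)
  base_mean <- rowMeans(norm)
  ss_resid <- numeric(nrow(norm))
  ss_mu2 <- numeric(nrow(norm))
  mean_term <- numeric(nrow(norm))
  for (g in seq_len(n_cells)) {
    idx <- which(cells == g)
    if (length(idx) < 2) next
    sub <- norm[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    ss_resid <- ss_resid + rowSums((sub - mu)^2)
    mean_term <- mean_term + (length(idx) - 1) * mu
    ss_mu2 <- ss_mu2 + (length(idx) - 1) * mu^2
  }
  # E[ss_resid] = sum_g (n_g - 1)(mu_g + alpha mu_g^2)
  alpha <- (ss_resid - mean_term) / pmax(ss_mu2, 1e-12)
  alpha <- pmax(alpha, floor)
  if (length(alpha) >= 50) {
    ok <- base_mean > 0
    tr <- stats::lowess(log(base_mean[ok]), log(alpha[ok]), f = 0.5)
    trend <- exp(stats::approx(tr$x, tr$y, xout = log(pmax(base_mean, min(base_mean[ok]))),
                               rule = 2, ties = mean)$y)
    alpha <- 0.5 * alpha + 0.5 * trend
  }
  pmax(alpha, floor)
}

# One NB GLM with fixed dispersion; returns coef, se for the first column of
# interest. X includes intercept; offset = log size factors.
nb_glm_wald <- function(y, X, offset, alpha) {
  theta <- 1 / max(alpha, 1e-8)
  fam <- MASS::negative.binomial(theta = theta)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, offset = offset, family = fam,
                                    control = list(maxit = 50, epsilon = 1e-8))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged && is.null(fit$coefficients)) return(NULL)
  p1 <- seq_len(fit$rank)
  Qr <- fit$qr
  cov_unscaled <- tryCatch(chol2inv(Qr$qr[p1, p1, drop = FALSE]), error = function(e) NULL)
  if (is.null(cov_unscaled)) return(NULL)
  coefs <- fit$coefficients
  se <- rep(NA_real_, length(coefs))
  se[Qr$pivot[p1]] <- sqrt(diag(cov_unscaled))
  list(coef = coefs, se = se, df_resid = fit$df.residual)
}

#' Per-transcript negative-binomial contrast
#'
#' Fits, for every transcript, an NB log-linear model with the contrast
#' factor and any covariates as design columns (log size factors as offset,
#' per-gene method-of-moments dispersion held fixed), and tests the contrast
#' coefficient with a two-sided Wald test referred to a t distribution on the
#' residual degrees of freedom. Transcripts with zero counts in both contrast
#' levels get `log2fc = 0`, `p = 1`.
#'
#' @param counts Count tibble (already low-count filtered).
#' @param meta Sample metadata tibble.
#' @param contrast A [de_contrast()].
#' @param lfc_threshold,de_alpha Thresholds passed to [call_de()].
#' @return Tibble with `transcript_id`, `base_mean`, `log2fc`, `se`,
#'   `wald_stat`, `p`, `padj`, `de_flag`.
#' @export
nb_contrast <- function(counts, meta, contrast, lfc_threshold = 2, de_alpha = 0.05) {
  meta <- validate_sample_meta(meta)
  counts <- validate_counts(counts)
  sub <- subset_samples(meta, contrast$subset)
  fac <- sub[[contrast$factor]]
  sub <- sub[fac %in% contrast$levels, , drop = FALSE]
  # canonical orientation (sorted levels) so that swapping the requested
  # levels negates the estimate exactly; the sign is flipped afterwards
  lev_sorted <- sort(contrast$levels)
  sign_fc <- if (contrast$levels[1] == lev_sorted[2]) 1 else -1
  fac <- factor(sub[[contrast$factor]], levels = lev_sorted) # sorted[1] = reference
  if (any(table(fac) < 2)) {
    rlang::abort(sprintf("contrast '%s': both levels need >= 2 samples", contrast$name))
  }
  m <- counts_to_matrix(counts)[, sub$sample_id, drop = FALSE]
  keep_cov <- character()
  for (cv in contrast$covariates) {
    if (length(unique(sub[[cv]])) >= 2) keep_cov <- c(keep_cov, cv)
    else message(sprintf("contrast '%s': covariate '%s' constant in subset, dropped",
                         contrast$name, cv))
  }
  dat <- data.frame(.contrast = fac)
  for (cv in keep_cov) dat[[cv]] <- factor(sub[[cv]])
  X <- stats::model.matrix(stats::reformulate(c(".contrast", keep_cov)), dat)
  if (qr(X)$rank < ncol(X)) {
    rlang::abort(sprintf("contrast '%s': design is collinear (columns: %s)",
                         contrast$name, paste(colnames(X), collapse = ", ")))
  }
  coef_idx <- which(colnames(X) == paste0(".contrast", lev_sorted[2]))
  sf <- compute_size_factors(matrix_to_counts(m))$size_factor
  off <- log(sf)
  norm <- sweep(m, 2, sf, "/")
  cells <- interaction(dat, drop = TRUE)
  alpha <- estimate_dispersions(norm, cells)
  base_mean <- rowMeans(norm)

  n_g <- nrow(m)
  log2fc <- numeric(n_g); se <- rep(NA_real_, n_g)
  stat <- rep(NA_real_, n_g); p <- rep(1, n_g)
  in_l1 <- fac == contrast$levels[1]
  for (i in seq_len(n_g)) {
    y <- m[i, ]
    if (sum(y) == 0 || (sum(y[in_l1]) == 0 && sum(y[!in_l1]) == 0)) next
    res <- nb_glm_wald(y, X, off, alpha[i])
    if (is.null(res) || is.na(res$se[coef_idx])) next
    log2fc[i] <- sign_fc * res$coef[coef_idx] / log(2)
    se[i] <- res$se[coef_idx] / log(2)
    stat[i] <- res$coef[coef_idx] / res$se[coef_idx]
    p[i] <- 2 * stats::pt(abs(stat[i]), df = max(res$df_resid, 1), lower.tail = FALSE)
  }
  out <- tibble(transcript_id = rownames(m), base_mean = base_mean,
                log2fc = log2fc, se = se, wald_stat = stat, p = p)
  out$padj <- adjust_bh(out$p)
  call_de(out, lfc_threshold = lfc_threshold, de_alpha = de_alpha)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; `NaN`/`NA` p-values propagate with a
#' warning.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p)) rlang::warn("NA/NaN p-values propagate through BH adjustment")
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed transcripts
#'
#' A transcript is DE iff `|log2fc| > lfc_threshold` (strict) and
#' `padj < de_alpha` (strict).
#'
#' @param results Contrast result tibble with `log2fc` and `padj`.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 2).
#' @param de_alpha Adjusted-p threshold (default 0.05).
#' @return `results` with a logical `de_flag` column.
#' @export
call_de <- function(results, lfc_threshold = 2, de_alpha = 0.05) {
  results$de_flag <- abs(results$log2fc) > lfc_threshold &
    !is.na(results$padj) & results$padj < de_alpha
  results
}

#' Normalized group means of expression by karyotype
#'
#' Size-factor-normalized mean counts per karyotype for a metadata subset
#' (typically larvae), used by the dominance classifier.
#'
#' @param counts Count tibble.
#' @param meta Metadata tibble.
#' @param subset Named list restricting samples (default: larvae).
#' @return Tibble `transcript_id`, `m_AA`, `m_AB`, `m_BB`.
#' @export
karyotype_means <- function(counts, meta, subset = list(life_stage = "larva")) {
  meta <- subset_samples(validate_sample_meta(meta), subset)
  m <- counts_to_matrix(validate_counts(counts))[, meta$sample_id, drop = FALSE]
  sf <- compute_size_factors(matrix_to_counts(m))$size_factor
  norm <- sweep(m, 2, sf, "/")
  out <- tibble(transcript_id = rownames(m))
  for (k in KARYOTYPES) {
    idx <- meta$karyotype == k
    out[[paste0("m_", k)]] <- if (any(idx)) rowMeans(norm[, idx, drop = FALSE]) else NA_real_
  }
  out
}
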