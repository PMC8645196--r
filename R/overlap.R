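# Overlap between DE transcripts and outlier SNPs within a distance window,
# against a resampling null over the tested transcript set.

#' Flag transcripts near an outlier SNP
#'
#' A transcript is "near" iff the minimum gap between its interval and any
#' SNP position on the same region is strictly less than `window` bp (0 when
#' the SNP lies inside the interval). Distances ignore strand. SNPs on
#' regions with no mapped transcript are ignored with a warning.
#'
#' @param map Transcript map tibble (`transcript_id`, `region`, `start`,
#'   `end`).
#' @param snps SNP tibble (`snp_id`, `region`, `pos`).
#' @param window Distance window in bp, strict (default 5000).
#' @return Tibble `transcript_id`, `dist_snp` (NA when no SNP shares the
#'   region), `near` (logical).
#' @export
transcripts_near_snps <- function(map, snps, window = 5000) {
  snps <- as_tibble(snps)
  orphan <- setdiff(unique(snps$region), unique(map$region))
  if (length(orphan)) {
    rlang::warn(paste0("outlier SNP(s) on region(s) without transcripts ignored: ",
                       paste(orphan, collapse = ", ")))
  }
  dist_min <- rep(NA_real_, nrow(map))
  for (reg in intersect(unique(map$region), unique(snps$region))) {
    ti <- which(map$region == reg)
    p <- snps$pos[snps$region == reg]
    s <- map$start[ti]; e <- map$end[ti]
    # gap between point p and half-open interval [s, e)
    d <- vapply(seq_along(ti), function(j) {
      dj <- ifelse(p >= s[j] & p < e[j], 0, ifelse(p < s[j], s[j] - p, p - (e[j] - 1)))
      min(dj)
    }, numeric(1))
    dist_min[ti] <- d
  }
  tibble(transcript_id = map$transcript_id,
         dist_snp = dist_min,
         near = !is.na(dist_min) & dist_min < window)
}

#' Resampling null for DE / outlier-SNP overlap
#'
#' Each iteration draws `n_de` transcripts without replacement from the
#' tested set (optionally restricted, e.g. to inversion transcripts) and
#' counts how many carry the near-SNP flag. Reports the null mean, sd, the
#' standard error of the null mean (sd / sqrt(iterations)), and the add-one
#' empirical p-value (1 + #\{null >= observed\}) / (1 + iterations).
#'
#' @param near_flags Tibble from [transcripts_near_snps()] covering the
#'   tested transcripts, or a named logical vector.
#' @param n_de Number of DE transcripts drawn per iteration.
#' @param observed Observed overlap count (DE transcripts with `near`).
#' @param n_iterations Number of resampling iterations (default 10000).
#' @param seed RNG seed.
#' @param restriction_ids Optional transcript ids restricting the sampled
#'   pool (e.g. inversion-only).
#' @return One-row tibble: `observed`, `n_de`, `n_tested`, `window` (NA if
#'   unknown), `n_iterations`, `null_mean`, `null_sd`, `null_se`,
#'   `empirical_p`, `restriction`.
#' @export
resampling_null <- function(near_flags, n_de, observed, n_iterations = 10000,
                            seed = 1, restriction_ids = NULL) {
  if (is.data.frame(near_flags)) {
    flags <- near_flags$near
    names(flags) <- near_flags$transcript_id
  } else flags <- near_flags
  restriction <- "none"
  if (!is.null(restriction_ids)) {
    flags <- flags[names(flags) %in% restriction_ids]
    restriction <- "restricted"
  }
  n_pool <- length(flags)
  if (n_de > n_pool) {
    rlang::abort(sprintf("cannot draw %d transcripts from a pool of %d", n_de, n_pool))
  }
  set.seed(seed)
  null_counts <- vapply(seq_len(n_iterations), function(i) {
    sum(flags[sample.int(n_pool, n_de)])
  }, numeric(1))
  null_sd <- stats::sd(null_counts)
  tibble(observed = observed, n_de = n_de, n_tested = n_pool,
         n_iterations = n_iterations,
         null_mean = mean(null_counts), null_sd = null_sd,
         null_se = null_sd / sqrt(n_iterations),
         empirical_p = (1 + sum(null_counts >= observed)) / (1 + n_iterations),
         restriction = restriction)
}

#' DE / outlier-SNP overlap test
#'
#' Convenience wrapper: computes near-SNP flags for the tested transcripts,
#' the observed overlap for the DE set, and the resampling null.
#'
#' @param map Transcript map restricted to the tested transcripts.
#' @param de_ids Character vector of DE transcript ids (any union of
#'   contrasts).
#' @param snps Outlier SNP tibble (`snp_id`, `region`, `pos`).
#' @param window Distance window in bp (default 5000).
#' @param n_iterations,seed Passed to [resampling_null()].
#' @param restriction_ids Optional pool restriction (e.g. inversion
#'   transcripts); the DE set is restricted accordingly.
#' @return One-row [resampling_null()] tibble with `window` filled in, plus
#'   attribute `"near"`: the per-transcript flag table.
#' @export
overlap_test <- function(map, de_ids, snps, window = 5000,
                         n_iterations = 10000, seed = 1, restriction_ids = NULL) {
  near <- transcripts_near_snps(map, snps, window)
  de_use <- intersect(de_ids, map$transcript_id)
  if (!is.null(restriction_ids)) de_use <- intersect(de_use, restriction_ids)
  observed <- sum(near$near[near$transcript_id %in% de_use])
  out <- resampling_null(near, n_de = length(de_use), observed = observed,
                         n_iterations = n_iterations, seed = seed,
                         restriction_ids = restriction_ids)
  out$window <- window
  attr(out, "near") <- near
  out
}
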