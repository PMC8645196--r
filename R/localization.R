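# Localization of DE transcripts relative to the inversion: region labels,
# cis/trans enrichment (2x2 odds ratio + Fisher exact test), per-region
# percentage tables, breakpoint-distance profiles, and KS comparison of
# log2 fold-change distributions.

#' Assign each transcript to a genomic region label
#'
#' A transcript is labelled `inversion` iff its interval overlaps the
#' inversion interval by at least 1 bp (any-overlap rule, so a transcript
#' straddling a breakpoint counts as inside); otherwise it is labelled by its
#' linkage group (the inversion's linkage group becomes `<lg>_collinear`);
#' transcripts on regions absent from the layout are `unplaced`.
#'
#' @param map Transcript map tibble (`transcript_id`, `region`, `start`, `end`).
#' @param layout A [genome_layout()].
#' @return Tibble `transcript_id`, `region_label`.
#' @export
assign_region <- function(map, layout) {
  inv <- layout$inversion
  lgs <- layout$linkage_groups$lg
  lab <- ifelse(
    map$region == inv$lg & map$start < inv$end & map$end > inv$start,
    "inversion",
    ifelse(map$region == inv$lg, paste0(inv$lg, "_collinear"),
           ifelse(map$region %in% lgs, map$region, "unplaced")))
  tibble(transcript_id = map$transcript_id, region_label = lab)
}

#' Cis enrichment of DE transcripts within a target region
#'
#' Builds the 2x2 table (DE/not-DE x inside/outside the target region),
#' reports the sample cross-product odds ratio (a d)/(b c) (`Inf` when
#' `b c = 0`), the conditional-MLE odds ratio, and the two-sided Fisher
#' exact p-value.
#'
#' @param de_flag Logical vector, one entry per tested transcript.
#' @param labels Region labels aligned with `de_flag` (vector or the
#'   `region_label` column of [assign_region()] output).
#' @param target_region Label counted as "inside" (default `"inversion"`).
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `odds_ratio_cmle`, `fisher_p`, `pct_de_inside` (percent of DE
#'   transcripts inside), `pct_tested_inside`, `pct_inside_de` (percent of
#'   inside transcripts that are DE), `pct_outside_de`.
#' @export
enrichment_test <- function(de_flag, labels, target_region = "inversion") {
  if (is.data.frame(labels)) labels <- labels$region_label
  stopifnot(length(de_flag) == length(labels))
  inside <- labels == target_region
  a <- sum(de_flag & inside); b <- sum(de_flag & !inside)
  c_ <- sum(!de_flag & inside); d <- sum(!de_flag & !inside)
  if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
    or <- NA_real_; or_cmle <- NA_real_; p <- 1
  } else {
    or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    or_cmle <- unname(ft$estimate)
    p <- ft$p.value
  }
  tibble(a = a, b = b, c = c_, d = d,
         odds_ratio = or, odds_ratio_cmle = or_cmle, fisher_p = p,
         pct_de_inside = 100 * a / max(a + b, 1),
         pct_tested_inside = 100 * (a + c_) / max(a + b + c_ + d, 1),
         pct_inside_de = 100 * a / max(a + c_, 1),
         pct_outside_de = 100 * b / max(b + d, 1))
}

#' Per-region percentage table for several transcript sets
#'
#' The classic localization summary: for each named set of transcripts
#' (e.g. all tested, karyotype-DE, sex-DE), the percentage located in each
#' region label. Each column sums to 100 up to rounding.
#'
#' @param labels Tibble from [assign_region()].
#' @param sets Named list of character vectors of transcript ids.
#' @return Tibble with `region_label` plus one percentage column per set and
#'   an attribute `"totals"` giving each set's size.
#' @export
localization_table <- function(labels, sets) {
  regs <- unique(labels$region_label)
  out <- tibble(region_label = regs)
  totals <- integer(0)
  for (nm in names(sets)) {
    ids <- sets[[nm]]
    lab <- labels$region_label[labels$transcript_id %in% ids]
    totals[nm] <- length(lab)
    out[[nm]] <- 100 * unname(vapply(regs, function(r) sum(lab == r), numeric(1))) /
      max(length(lab), 1)
  }
  attr(out, "totals") <- totals
  out
}

#' Distance of inversion transcripts to the nearest breakpoint
#'
#' For every transcript labelled `inversion`, the gap (bp) between its
#' interval and each of the two breakpoints (0 if the interval covers the
#' breakpoint), and the minimum of the two.
#'
#' @param map Transcript map tibble.
#' @param layout A [genome_layout()].
#' @param ids Optional subset of transcript ids (e.g. the DE set); default
#'   all inversion-overlapping transcripts.
#' @return Tibble `transcript_id`, `dist_start`, `dist_end`, `dist_nearest`,
#'   sorted by `dist_nearest`, with attribute `"nearest"`: a two-row tibble
#'   naming the closest transcript to each breakpoint.
#' @export
breakpoint_distances <- function(map, layout, ids = NULL) {
  labels <- assign_region(map, layout)
  keep <- labels$region_label == "inversion"
  if (!is.null(ids)) keep <- keep & map$transcript_id %in% ids
  sub <- map[keep, , drop = FALSE]
  gap_to_point <- function(s, e, b) ifelse(s <= b & b < e, 0, ifelse(b < s, s - b, b - (e - 1)))
  ds <- gap_to_point(sub$start, sub$end, layout$breakpoints["start"])
  de <- gap_to_point(sub$start, sub$end, layout$breakpoints["end"])
  out <- tibble(transcript_id = sub$transcript_id,
                dist_start = as.numeric(ds), dist_end = as.numeric(de),
                dist_nearest = pmin(as.numeric(ds), as.numeric(de)))
  out <- dplyr::arrange(out, .data$dist_nearest)
  nearest <- tibble(
    breakpoint = c("start", "end"),
    position = unname(layout$breakpoints),
    transcript_id = c(out$transcript_id[which.min(out$dist_start)] %||% NA_character_,
                      out$transcript_id[which.min(out$dist_end)] %||% NA_character_),
    distance = c(suppressWarnings(min(out$dist_start)), suppressWarnings(min(out$dist_end))))
  attr(out, "nearest") <- nearest
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical CDFs; the
#' p-value uses the asymptotic two-sided formula. With fewer than 2 points in
#' either sample, a warning is issued and `p = 1` returned.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble `statistic`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    rlang::warn("fewer than 2 points in a sample; KS p set to 1")
    d <- if (length(x) >= 1 && length(y) >= 1) {
      suppressWarnings(unname(stats::ks.test(x, y, exact = FALSE)$statistic))
    } else NA_real_
    return(tibble(statistic = d, p_value = 1, n_x = length(x), n_y = length(y)))
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_x = length(x), n_y = length(y))
}

#' Compare log2FC distributions genome-wide vs within the inversion
#'
#' For each named contrast-result group (e.g. female, male, larvae), the
#' within-inversion log2 fold changes are compared with the genome-wide set:
#' medians and interquartile widths per set, and the KS test between them.
#'
#' @param results_by_group Named list of contrast result tibbles.
#' @param labels Tibble from [assign_region()].
#' @return Tibble with two rows per group (`set` = `genome`/`inversion`):
#'   `group`, `set`, `n`, `median_lfc`, `iqr_lfc`, `ks_D`, `ks_p`.
#' @export
compare_lfc_distributions <- function(results_by_group, labels) {
  purrr::map_dfr(names(results_by_group), function(g) {
    res <- dplyr::left_join(results_by_group[[g]], labels, by = "transcript_id")
    all_lfc <- res$log2fc
    inv_lfc <- res$log2fc[!is.na(res$region_label) & res$region_label == "inversion"]
    ks <- ks_two_sample(inv_lfc, all_lfc)
    tibble(group = g, set = c("genome", "inversion"),
           n = c(length(all_lfc), length(inv_lfc)),
           median_lfc = c(stats::median(all_lfc), stats::median(inv_lfc)),
           iqr_lfc = c(stats::IQR(all_lfc), stats::IQR(inv_lfc)),
           ks_D = ks$statistic, ks_p = ks$p_value)
  })
}
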