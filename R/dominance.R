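# Dominance-pattern classification of heterokaryotype expression.
#
# Each transcript's pattern across the three larval karyotypes is reduced to
# two relations — the heterokaryotype (AB) against each homokaryotype (AA,
# BB) — taken from the unadjusted p-values and mean-difference signs of the
# AA-vs-AB and AB-vs-BB contrasts. The AA-vs-BB contrast is recorded for
# reporting but does not enter the decision table: the two
# heterokaryotype-vs-homokaryotype relations determine the class.

DOMINANCE_CLASSES <- c("additive", "underdominant", "overdominant",
                       "alpha_dominant", "beta_dominant", "unknown")

# relation of AB to a homokaryotype: "=", "<" or ">"
ab_relation <- function(p, m_ab, m_homo, sig_alpha) {
  ifelse(is.na(p) | p >= sig_alpha | m_ab == m_homo, "=",
         ifelse(m_ab < m_homo, "<", ">"))
}

dominance_from_relations <- function(rel_aa, rel_bb) {
  dplyr::case_when(
    (rel_aa == "<" & rel_bb == ">") | (rel_aa == ">" & rel_bb == "<") ~ "additive",
    rel_aa == "<" & rel_bb == "<" ~ "underdominant",
    rel_aa == ">" & rel_bb == ">" ~ "overdominant",
    rel_bb == "=" & rel_aa != "=" ~ "beta_dominant",
    rel_aa == "=" & rel_bb != "=" ~ "alpha_dominant",
    TRUE ~ "unknown"
  )
}

#' Classify dominance of heterokaryotype expression
#'
#' Relations use unadjusted p-values: relation(AB, X) is `"="` when
#' `p >= sig_alpha`, otherwise `"<"` or `">"` by the sign of the mean
#' difference. The decision table: AB strictly between the homokaryotypes
#' with both relations significant = additive; AB below both = underdominant;
#' above both = overdominant; AB equal to BB but not AA = β-dominant; equal
#' to AA but not BB = α-dominant; both equal = unknown.
#'
#' @param res_aa_ab Contrast result tibble for AA vs AB (unadjusted `p` used).
#' @param res_ab_bb Contrast result tibble for AB vs BB.
#' @param means Tibble from [karyotype_means()] (`m_AA`, `m_AB`, `m_BB`).
#' @param eligible_ids Transcripts to classify (typically those DE in at
#'   least one of the three larval contrasts); default: all shared ids.
#' @param sig_alpha Unadjusted-p cutoff separating "=" from a directional
#'   relation (default 0.05).
#' @return Tibble `transcript_id`, `rel_aa` (AB vs AA), `rel_bb` (AB vs BB),
#'   `p_aa_ab`, `p_ab_bb`, `m_AA`, `m_AB`, `m_BB`, `class`.
#' @export
classify_dominance <- function(res_aa_ab, res_ab_bb, means,
                               eligible_ids = NULL, sig_alpha = 0.05) {
  if (is.null(res_aa_ab) || is.null(res_ab_bb)) {
    rlang::abort("both the AA-vs-AB and AB-vs-BB contrasts are required")
  }
  d <- dplyr::inner_join(
    dplyr::select(res_aa_ab, "transcript_id", p_aa_ab = "p"),
    dplyr::select(res_ab_bb, "transcript_id", p_ab_bb = "p"),
    by = "transcript_id")
  d <- dplyr::inner_join(d, means, by = "transcript_id")
  if (!is.null(eligible_ids)) d <- d[d$transcript_id %in% eligible_ids, , drop = FALSE]
  d$rel_aa <- ab_relation(d$p_aa_ab, d$m_AB, d$m_AA, sig_alpha)
  d$rel_bb <- ab_relation(d$p_ab_bb, d$m_AB, d$m_BB, sig_alpha)
  d$class <- factor(dominance_from_relations(d$rel_aa, d$rel_bb),
                    levels = DOMINANCE_CLASSES)
  dplyr::select(d, "transcript_id", "rel_aa", "rel_bb",
                "p_aa_ab", "p_ab_bb", "m_AA", "m_AB", "m_BB", "class")
}

#' Tabulate dominance classes inside and outside the inversion
#'
#' @param calls Tibble from [classify_dominance()].
#' @param labels Tibble from [assign_region()] (`transcript_id`, `region_label`).
#' @return Tibble with one row per dominance class: counts `inside`,
#'   `outside` (of the inversion) and `total`.
#' @export
summarize_dominance <- function(calls, labels) {
  base <- tibble(class = factor(DOMINANCE_CLASSES, levels = DOMINANCE_CLASSES))
  if (nrow(calls) == 0) {
    return(dplyr::mutate(base, inside = 0L, outside = 0L, total = 0L))
  }
  d <- dplyr::left_join(calls, labels, by = "transcript_id")
  d$inside <- !is.na(d$region_label) & d$region_label == "inversion"
  tab <- d |>
    dplyr::count(.data$class, .data$inside) |>
    tidyr::pivot_wider(names_from = "inside", values_from = "n", values_fill = 0L)
  tab$inside <- if ("TRUE" %in% names(tab)) tab[["TRUE"]] else 0L
  tab$outside <- if ("FALSE" %in% names(tab)) tab[["FALSE"]] else 0L
  out <- dplyr::left_join(base, dplyr::select(tab, "class", "inside", "outside"),
                          by = "class")
  out$inside[is.na(out$inside)] <- 0L
  out$outside[is.na(out$outside)] <- 0L
  out$total <- out$inside + out$outside
  out
}
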