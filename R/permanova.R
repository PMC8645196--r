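# Distance-based PERMANOVA with sequential (Type-I) sums of squares via
# Gower centering of the squared distance matrix and nested design
# projectors; p-values by free permutation of sample labels.

#' Manhattan distance matrix between sample expression profiles
#'
#' d(i, j) = sum over transcripts of |x_gi - x_gj| on size-factor-normalized
#' counts (not log-transformed by default; pass a transformed table to
#' change that).
#'
#' @param expr Expression tibble (`transcript_id` + one column per sample),
#'   typically normalized counts.
#' @return A `dist` object over samples.
#' @export
manhattan_matrix <- function(expr) {
  m <- counts_to_matrix_loose(expr)
  if (anyNA(m)) {
    bad <- rownames(m)[which(rowSums(is.na(m)) > 0)[1]]
    rlang::abort(paste0("missing value in expression table at transcript ", bad))
  }
  stats::dist(t(m), method = "manhattan")
}

# like counts_to_matrix but allows non-integer (normalized) values
counts_to_matrix_loose <- function(expr) {
  expr <- as_tibble(expr)
  if (names(expr)[1] != "transcript_id") rlang::abort("first column must be 'transcript_id'")
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$transcript_id
  m
}

#' Size-factor-normalized expression table
#'
#' @param counts Count tibble.
#' @param log2_transform Apply log2(x + 1) after normalization (default
#'   FALSE).
#' @return Tibble of normalized expression values.
#' @export
normalize_counts <- function(counts, log2_transform = FALSE) {
  m <- counts_to_matrix(validate_counts(counts))
  sf <- compute_size_factors(counts)$size_factor
  norm <- sweep(m, 2, sf, "/")
  if (log2_transform) norm <- log2(norm + 1)
  matrix_to_counts(norm)
}

# trace of H %*% G for symmetric G (H symmetric projector)
tr_HG <- function(H, G) sum(H * G)

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Anderson's distance-based partitioning: the squared distance matrix is
#' Gower-centered; terms are added sequentially in the order given (put
#' karyotype first to attribute shared variance to it); each term's sum of
#' squares is the increment in projected trace; R² = SS_term / SS_total;
#' pseudo-F uses the residual mean square of the full model; p-values come
#' from free permutation of sample labels.
#'
#' @param dist A `dist` object or symmetric matrix of distances.
#' @param meta Metadata tibble with one row per sample, aligned with `dist`
#'   labels via `sample_id`.
#' @param terms Character vector of metadata columns, in the order they
#'   enter the model (first term absorbs shared variance).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return Object of class `invexpr_permanova`; see [tidy.invexpr_permanova()].
#' @export
permanova <- function(dist, meta, terms, n_permutations = 999, seed = 1) {
  D <- as.matrix(dist)
  n <- nrow(D)
  ids <- rownames(D) %||% meta$sample_id
  meta <- as_tibble(meta)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) rlang::abort("distance labels missing from metadata")
  for (tm in terms) {
    if (length(unique(meta[[tm]])) < 2) {
      rlang::abort(paste0("term '", tm, "' has fewer than 2 levels"))
    }
  }
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  # nested projectors: intercept, +term1, +term1+term2, ...
  hats <- list(matrix(1 / n, n, n))
  dfs <- numeric(length(terms))
  rank_prev <- 1
  for (k in seq_along(terms)) {
    dat <- as.data.frame(lapply(meta[terms[seq_len(k)]], factor))
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(k)]), dat)
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(Q)
    dfs[k] <- qrX$rank - rank_prev
    if (dfs[k] < 1) {
      rlang::abort(paste0("term '", terms[k], "' is confounded with earlier terms"))
    }
    rank_prev <- qrX$rank
  }
  H_full <- hats[[length(hats)]]
  df_res <- n - rank_prev
  ss_res <- ss_total - tr_HG(H_full, G)

  term_ss <- function(Gm) {
    vapply(seq_along(terms), function(k) tr_HG(hats[[k + 1]], Gm) - tr_HG(hats[[k]], Gm),
           numeric(1))
  }
  ss <- term_ss(G)
  f_obs <- (ss / dfs) / (ss_res / df_res)

  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_permutations)) {
    pidx <- sample.int(n)
    Gp <- G[pidx, pidx]
    ssp <- term_ss(Gp)
    ss_resp <- ss_total - tr_HG(H_full, Gp)
    fp <- (ssp / dfs) / (ss_resp / df_res)
    exceed <- exceed + (fp >= f_obs)
  }
  pvals <- (1 + exceed) / (1 + n_permutations)

  structure(list(
    terms = terms, df = dfs, ss = ss, r_squared = ss / ss_total,
    pseudo_f = f_obs, p = pvals,
    df_residual = df_res, ss_residual = ss_res, ss_total = ss_total,
    n_samples = n, n_permutations = n_permutations, seed = seed),
    class = "invexpr_permanova")
}

#' @export
print.invexpr_permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_permutations, "permutations)\n")
  print(as.data.frame(tidy.invexpr_permanova(x)), row.names = FALSE)
  invisible(x)
}

#' Tidy a PERMANOVA fit
#'
#' @param x An `invexpr_permanova` object.
#' @param ... Unused.
#' @return Tibble with one row per term plus `Residual` and `Total` rows:
#'   `term`, `df`, `ss`, `r_squared`, `pseudo_f`, `p_value`.
#' @method tidy invexpr_permanova
#' @export
tidy.invexpr_permanova <- function(x, ...) {
  tibble(
    term = c(x$terms, "Residual", "Total"),
    df = c(x$df, x$df_residual, x$n_samples - 1),
    ss = c(x$ss, x$ss_residual, x$ss_total),
    r_squared = c(x$r_squared, x$ss_residual / x$ss_total, 1),
    pseudo_f = c(x$pseudo_f, NA, NA),
    p_value = c(x$p, NA, NA))
}

#' @rdname tidy.invexpr_permanova
#' @method glance invexpr_permanova
#' @export
glance.invexpr_permanova <- function(x, ...) {
  tibble(n_samples = x$n_samples, n_permutations = x$n_permutations,
         seed = x$seed, ss_total = x$ss_total)
}
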