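# Small programmatic fixtures shared across test files.

# counts tibble from a matrix with default ids
make_counts <- function(m, tx = sprintf("tx%03d", seq_len(nrow(m))),
                        samples = sprintf("s%02d", seq_len(ncol(m)))) {
  rownames(m) <- tx
  colnames(m) <- samples
  tibble::as_tibble(m, rownames = "transcript_id")
}

# minimal single-factor metadata: first half AA, second half BB
make_meta <- function(samples, karyotype = rep(c("AA", "BB"), each = length(samples) / 2),
                      life_stage = "larva", sex = "unknown",
                      population = "pop1", pool_size = 3L) {
  tibble::tibble(sample_id = samples, life_stage = life_stage, sex = sex,
                 karyotype = karyotype, population = population,
                 pool_size = if (life_stage[1] == "adult") 1L else pool_size)
}

# random NB count tibble under the null (no group differences)
null_counts <- function(n_tx, samples, meanlog = 4, sdlog = 1.5, k = 10,
                        seed = 1) {
  set.seed(seed)
  mu <- stats::rlnorm(n_tx, meanlog, sdlog)
  m <- matrix(stats::rnbinom(n_tx * length(samples), size = k,
                             mu = rep(mu, length(samples))), nrow = n_tx)
  make_counts(m, samples = samples)
}

# simple six-linkage-group layout used by localization tests
toy_layout <- function(lg_len = 1e6, inv = c(2e5, 8e5)) {
  genome_layout(tibble::tibble(lg = paste0("LG", 1:6), length = lg_len),
                list(lg = "LG1", start = inv[1], end = inv[2]))
}
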