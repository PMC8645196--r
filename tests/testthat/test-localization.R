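test_that("region assignment uses the any-overlap rule and partitions transcripts", {
  layout <- toy_layout(lg_len = 1e6, inv = c(2e5, 8e5))
  map <- tibble::tibble(
    transcript_id = c("inside", "straddle", "collinear", "lg3", "orphan"),
    region = c("LG1", "LG1", "LG1", "LG3", "scaff12"),
    start = c(3e5, 199000, 1e5, 5e5, 10),
    end = c(3e5 + 1e3, 201000, 1.5e5, 5.01e5, 500),
    strand = "+")
  lab <- assign_region(map, layout)
  expect_equal(lab$region_label,
               c("inversion", "inversion", "LG1_collinear", "LG3", "unplaced"))
  expect_equal(sum(table(lab$region_label)), nrow(map))
})

test_that("enrichment odds ratio matches the 2x2 reconstruction and trivial cases", {
  # reconstructed localization table: 25,320 tested with 12.8% inside the
  # inversion; 293 DE with 80.5% inside
  a <- 236; b <- 57; c_ <- 3005; d <- 22022
  de <- c(rep(TRUE, a + b), rep(FALSE, c_ + d))
  lab <- c(rep("inversion", a), rep("LG2", b), rep("inversion", c_), rep("LG2", d))
  e <- enrichment_test(de, lab)
  expect_equal(round(e$odds_ratio, 1), 30.3)
  expect_equal(round(e$pct_outside_de, 1), 0.3)
  expect_equal(round(e$pct_de_inside, 1), 80.5)
  expect_equal(round(e$pct_tested_inside, 1), 12.8)

  flat <- enrichment_test(c(rep(TRUE, 20), rep(FALSE, 20)),
                          rep(c("inversion", "LG2"), 20))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$fisher_p, 1)
})

test_that("Fisher p equals exhaustive hypergeometric tail enumeration", {
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + c_; n_ <- b + d; k <- a + b
    supp <- max(0, k - n_):min(k, m)
    dens <- dhyper(supp, m, n_, k)
    sum(dens[dens <= dhyper(a, m, n_, k) * (1 + 1e-7)])
  }
  set.seed(61)
  for (i in 1:25) {
    tb <- rpois(4, lambda = c(5, 8, 10, 15)) + 1
    de <- c(rep(TRUE, tb[1] + tb[2]), rep(FALSE, tb[3] + tb[4]))
    lab <- c(rep("inversion", tb[1]), rep("out", tb[2]),
             rep("inversion", tb[3]), rep("out", tb[4]))
    e <- enrichment_test(de, lab)
    expect_equal(e$fisher_p, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
  }
})

test_that("odds ratio is invariant under double swaps and inverts under a row swap", {
  e1 <- enrichment_test(c(rep(TRUE, 30), rep(FALSE, 70)),
                        c(rep("inversion", 20), rep("o", 10),
                          rep("inversion", 25), rep("o", 45)))
  # swap rows (DE <-> not DE) and columns (inside <-> outside) together
  e2 <- enrichment_test(c(rep(FALSE, 30), rep(TRUE, 70)),
                        c(rep("o", 20), rep("inversion", 10),
                          rep("o", 25), rep("inversion", 45)))
  expect_equal(e1$odds_ratio, e2$odds_ratio, tolerance = 1e-12)
  # swap only rows: OR inverts
  e3 <- enrichment_test(c(rep(FALSE, 30), rep(TRUE, 70)),
                        c(rep("inversion", 20), rep("o", 10),
                          rep("inversion", 25), rep("o", 45)))
  expect_equal(e3$odds_ratio, 1 / e1$odds_ratio, tolerance = 1e-12)
})

test_that("localization percentage tables are complete and detect cis enrichment", {
  labels <- tibble::tibble(transcript_id = c("a", "b", "c"),
                           region_label = "LG2")
  tab <- localization_table(labels, list(tested = c("a", "b", "c")))
  expect_equal(tab$tested[tab$region_label == "LG2"], 100)

  sim <- simulate_dataset(sim_params(n_transcripts = 1500, cis_fraction = 0.8,
                                     frac_kar_de = 0.08, seed = 62))
  labels <- assign_region(sim$map, sim$layout)
  de_ids <- sim$truth$transcript_id[sim$truth$kar_de]
  tab2 <- localization_table(labels, list(tested = sim$truth$transcript_id,
                                          karyotype_de = de_ids))
  expect_true(all(abs(colSums(as.matrix(tab2[-1])) - 100) < 0.1))
  inv_row <- tab2[tab2$region_label == "inversion", ]
  expect_gt(inv_row$karyotype_de, inv_row$tested)
  # enrichment of true-DE flags inside the inversion is detectable
  e <- enrichment_test(sim$truth$kar_de, labels$region_label)
  expect_lt(e$fisher_p, 0.01)
})

test_that("breakpoint distances handle covering and offset intervals and look uniform", {
  layout <- toy_layout(lg_len = 1e6, inv = c(2e5, 8e5))
  b <- 2e5
  map <- tibble::tibble(
    transcript_id = c("covers", "offset"),
    region = "LG1", start = c(b - 50, b + 100), end = c(b + 50, b + 200),
    strand = "+")
  bd <- breakpoint_distances(map, layout)
  expect_equal(bd$dist_nearest[bd$transcript_id == "covers"], 0)
  expect_equal(bd$dist_start[bd$transcript_id == "offset"], 100)

  # uniformly placed transcripts: nearest-breakpoint distances ~ U(0, L/2)
  p <- sim_params(n_transcripts = 6000, seed = 63)
  lay <- simulate_layout(p)
  bd2 <- breakpoint_distances(lay$map, lay$layout)
  inv_len <- lay$layout$inversion$end - lay$layout$inversion$start
  ks <- suppressWarnings(ks.test(bd2$dist_nearest, "punif", 0, inv_len / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("the KS statistic matches a brute-force ECDF sweep", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  expect_warning(out <- ks_two_sample(1, c(2, 3)), "fewer than 2")
  expect_equal(out$p_value, 1)

  set.seed(64)
  x <- rnorm(40); y <- rnorm(25, 0.5)
  grid <- sort(c(x, y))
  d_oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(ks_two_sample(x, y)$statistic, d_oracle, tolerance = 1e-12)
})

test_that("log2FC distribution comparison reports one genome and one inversion row per group", {
  labels <- tibble::tibble(transcript_id = sprintf("t%03d", 1:200),
                           region_label = rep(c("inversion", "LG2"), each = 100))
  set.seed(65)
  res <- tibble::tibble(transcript_id = labels$transcript_id,
                        log2fc = rnorm(200) - ifelse(labels$region_label == "inversion", 2, 0))
  out <- compare_lfc_distributions(list(male = res, female = res), labels)
  expect_equal(nrow(out), 4)
  expect_lt(out$median_lfc[out$group == "male" & out$set == "inversion"],
            out$median_lfc[out$group == "male" & out$set == "genome"])
  expect_lt(out$ks_p[1], 1e-6)

  # all transcripts inside the inversion: the two sets coincide, D = 0
  lab_all <- tibble::tibble(transcript_id = labels$transcript_id,
                            region_label = "inversion")
  same <- compare_lfc_distributions(list(g = res), lab_all)
  expect_equal(same$ks_D[1], 0)
})
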