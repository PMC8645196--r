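#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows across n
#' @importFrom tibble tibble as_tibble
NULL

# ---- validators ------------------------------------------------------------

KARYOTYPES <- c("AA", "AB", "BB")
LIFE_STAGES <- c("adult", "larva")
SEXES <- c("male", "female", "unknown")

#' Validate a sample metadata table
#'
#' Checks the invariants the pipeline assumes: unique sample ids, known
#' factor levels, adults sequenced singly (`pool_size = 1`) and larvae as
#' pools. Larvae may have `sex = "unknown"`.
#'
#' @param meta A data frame with columns `sample_id`, `life_stage`, `sex`,
#'   `karyotype` (`AA`/`AB`/`BB`, i.e. the two inversion homokaryotypes and
#'   the heterokaryotype), `population`, `pool_size`.
#' @return The metadata as a tibble, invisibly validated.
#' @export
validate_sample_meta <- function(meta) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "life_stage", "sex", "karyotype", "population", "pool_size")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("metadata is missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")))
  }
  if (!all(meta$life_stage %in% LIFE_STAGES)) abort("life_stage must be 'adult' or 'larva'")
  if (!all(meta$sex %in% SEXES)) abort("sex must be 'male', 'female' or 'unknown'")
  if (!all(meta$karyotype %in% KARYOTYPES)) abort("karyotype must be one of AA, AB, BB")
  if (any(meta$pool_size < 1 | meta$pool_size != round(meta$pool_size))) {
    abort("pool_size must be a positive integer")
  }
  if (any(meta$life_stage == "adult" & meta$pool_size != 1)) {
    abort("adults must have pool_size = 1")
  }
  meta$pool_size <- as.integer(meta$pool_size)
  meta
}

validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  if (names(counts)[1] != "transcript_id") {
    abort("first column of a count table must be 'transcript_id'")
  }
  if (ncol(counts) < 2) abort("count table has no sample columns")
  if (anyDuplicated(counts$transcript_id)) {
    abort(paste0("duplicate transcript_id: ",
                 paste(unique(counts$transcript_id[duplicated(counts$transcript_id)]), collapse = ", ")))
  }
  if (anyDuplicated(names(counts))) abort("duplicate sample columns in count table")
  for (s in names(counts)[-1]) {
    v <- counts[[s]]
    if (!is.numeric(v)) abort(paste0("non-numeric counts in sample ", s))
    bad <- which(v < 0 | v != round(v) | is.na(v))
    if (length(bad)) {
      abort(paste0("invalid count at transcript ", counts$transcript_id[bad[1]],
                   ", sample ", s, ": ", v[bad[1]]))
    }
  }
  counts
}

# tibble (transcript_id + sample cols) <-> integer matrix
counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[-1])
  rownames(m) <- counts$transcript_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m, rownames = "transcript_id")
  out
}

# ---- readers / writers -----------------------------------------------------

#' Read a transcript-by-sample count matrix from TSV
#'
#' The file must have a header row of sample ids and a first column of
#' transcript ids. Counts are validated to be nonnegative integers; duplicate
#' transcript or sample ids are fatal.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with a `transcript_id` column and one integer column per
#'   sample.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(counts)[1] <- "transcript_id"
  counts$transcript_id <- as.character(counts$transcript_id)
  validate_counts(counts)
}

#' Write a count table to TSV
#' @param counts Count tibble as returned by [read_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(validate_counts(counts), path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path Path to a tab-separated file with the columns of
#'   [validate_sample_meta()].
#' @return A validated metadata tibble.
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read BED-style intervals (transcripts or SNP positions)
#'
#' Coordinates are 0-based, half-open throughout the package; SNPs are
#' length-1 intervals and are returned as point positions. Rows on regions
#' absent from `layout` (when given) are flagged `unplaced` with a warning
#' rather than dropped.
#'
#' @param path Tab-separated BED file: region, start, end, name, (strand).
#' @param kind `"transcripts"` for a transcript map, `"snps"` for point
#'   positions.
#' @param layout Optional [genome_layout()] used to flag unknown regions.
#' @return For `"transcripts"`, a tibble `transcript_id`, `region`, `start`,
#'   `end`, `strand`; for `"snps"`, a tibble `snp_id`, `region`, `pos`.
#' @export
read_intervals <- function(path, kind = c("transcripts", "snps"), layout = NULL) {
  kind <- match.arg(kind)
  raw <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns (region, start, end)")
  names(raw)[1:3] <- c("region", "start", "end")
  if (ncol(raw) >= 4) names(raw)[4] <- "name" else raw$name <- paste0("feature", seq_len(nrow(raw)))
  if (ncol(raw) >= 5) names(raw)[5] <- "strand" else raw$strand <- "."
  bad <- which(raw$end <= raw$start)
  if (length(bad)) {
    abort(paste0("interval with end <= start at line ", bad[1], ": ",
                 raw$region[bad[1]], " [", raw$start[bad[1]], ", ", raw$end[bad[1]], ")"))
  }
  if (any(raw$start < 0)) abort("negative start coordinate")
  if (!is.null(layout)) {
    unknown <- !(raw$region %in% layout$linkage_groups$lg)
    if (any(unknown)) {
      warn(paste0(sum(unknown), " interval(s) on regions absent from the genome layout; flagged unplaced"))
    }
  }
  if (kind == "snps") {
    tibble(snp_id = as.character(raw$name), region = raw$region, pos = as.integer(raw$start))
  } else {
    tibble(transcript_id = as.character(raw$name), region = raw$region,
           start = as.integer(raw$start), end = as.integer(raw$end),
           strand = ifelse(raw$strand %in% c("+", "-"), raw$strand, "."))
  }
}

#' Write a transcript map or SNP set as BED
#' @param x A transcript map (`transcript_id, region, start, end, strand`) or
#'   SNP tibble (`snp_id, region, pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  if ("pos" %in% names(x)) {
    bed <- data.frame(x$region, x$pos, x$pos + 1L, x$snp_id)
  } else {
    bed <- data.frame(x$region, x$start, x$end, x$transcript_id, x$strand %||% ".")
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- genome layout ---------------------------------------------------------

#' Construct a genome layout with one inversion
#'
#' @param linkage_groups Data frame or tibble with columns `lg` (name) and
#'   `length` (bp).
#' @param inversion List or tibble with `lg`, `start`, `end` (0-based,
#'   half-open) giving the inverted interval; its two breakpoints are
#'   `start` and `end`.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(linkage_groups, inversion) {
  lgs <- as_tibble(linkage_groups)
  stopifnot(all(c("lg", "length") %in% names(lgs)))
  if (anyDuplicated(lgs$lg)) abort("duplicate linkage group names")
  inv <- as.list(inversion)
  if (!inv$lg %in% lgs$lg) abort("inversion must lie on a named linkage group")
  len <- lgs$length[lgs$lg == inv$lg]
  if (!(inv$start >= 0 && inv$start < inv$end && inv$end <= len)) {
    abort("inversion interval must satisfy 0 <= start < end <= linkage-group length")
  }
  structure(
    list(linkage_groups = lgs,
         inversion = list(lg = inv$lg, start = as.numeric(inv$start), end = as.numeric(inv$end)),
         breakpoints = c(start = as.numeric(inv$start), end = as.numeric(inv$end))),
    class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", nrow(x$linkage_groups), "linkage groups,",
      format(sum(x$linkage_groups$length), big.mark = ","), "bp total\n")
  cat("Inversion on", x$inversion$lg, "[",
      format(x$inversion$start, big.mark = ","), ",",
      format(x$inversion$end, big.mark = ","), ") —",
      sprintf("%.1f%% of %s, %.1f%% of the genome\n",
              100 * (x$inversion$end - x$inversion$start) /
                x$linkage_groups$length[x$linkage_groups$lg == x$inversion$lg],
              x$inversion$lg,
              100 * (x$inversion$end - x$inversion$start) / sum(x$linkage_groups$length)))
  invisible(x)
}

# ---- PCA QC summary --------------------------------------------------------

#' Sample-level PCA on the most variable transcripts
#'
#' Counts are size-factor normalized, log2(x + 1) transformed, and the
#' `n_top` transcripts with the highest variance on that scale are retained;
#' transcripts are centered (not scaled) before the eigendecomposition.
#'
#' @param counts Count tibble.
#' @param n_top Number of top-variance transcripts to keep (default 500);
#'   if larger than the number of transcripts, all are used with a warning.
#' @param meta Optional metadata tibble joined onto the returned scores.
#' @return An object of class `invexpr_pca`: list with `scores` (tibble of
#'   per-sample coordinates on all components), `var_explained` (fractions of
#'   variance per component), `n_top`.
#' @export
pca_top_variance <- function(counts, n_top = 500, meta = NULL) {
  m <- counts_to_matrix(validate_counts(counts))
  if (ncol(m) < 3) abort("PCA summary needs at least 3 samples")
  sf <- compute_size_factors(counts)
  norm <- sweep(m, 2, sf$size_factor, "/")
  lg <- log2(norm + 1)
  if (n_top > nrow(lg)) {
    warn(sprintf("n_top = %d exceeds the %d transcripts available; using all", n_top, nrow(lg)))
    n_top <- nrow(lg)
  }
  v <- apply(lg, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(n_top)]
  pc <- stats::prcomp(t(lg[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  names(var_frac) <- colnames(pc$x)
  scores <- as_tibble(pc$x, rownames = "sample_id")
  if (!is.null(meta)) scores <- left_join(scores, as_tibble(meta), by = "sample_id")
  structure(list(scores = scores, var_explained = var_frac, n_top = n_top),
            class = "invexpr_pca")
}

#' @export
print.invexpr_pca <- function(x, ...) {
  cat(sprintf("PCA on top %d variable transcripts (%d samples)\n",
              x$n_top, nrow(x$scores)))
  cat(sprintf("PC1: %.1f%%  PC2: %.1f%% of variance\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' @rdname pca_top_variance
#' @param x An `invexpr_pca` object.
#' @param ... Unused.
#' @method tidy invexpr_pca
#' @export
tidy.invexpr_pca <- function(x, ...) x$scores

#' @rdname pca_top_variance
#' @method glance invexpr_pca
#' @export
glance.invexpr_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_top = x$n_top,
         pc1_var = unname(x$var_explained[1]), pc2_var = unname(x$var_explained[2]))
}
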