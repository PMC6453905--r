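#' Abundance input and unit computation
#'
#' Readers for the per-sample abundance TSV dialect emitted by pseudo-
#' alignment quantifiers (columns `target_id`, `length`, `eff_length`,
#' `est_counts`, `tpm`), the transcript-to-gene map and the sample sheet,
#' plus the standard effective-length-normalised TPM/FPKM definitions and
#' transcript-to-gene aggregation.
#'
#' @name expression_io
NULL

ABUNDANCE_COLS <- c("target_id", "length", "eff_length", "est_counts", "tpm")

#' Read a per-sample abundance table
#'
#' Strict reader for the abundance-TSV dialect: the header must be exactly
#' `target_id length eff_length est_counts tpm` and every numeric field must
#' parse; a malformed field is reported with its file line number.
#'
#' @param path abundance TSV path.
#' @return data.frame with one row per transcript and the five dialect
#'   columns, numerics parsed.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) {
    sm_stop_validation("abundance file not found: %s", path)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), ABUNDANCE_COLS)) {
    sm_stop_validation(
      "malformed abundance header in %s: expected {%s}, got {%s}",
      path, paste(ABUNDANCE_COLS, collapse = ", "),
      paste(names(df), collapse = ", "))
  }
  if (nrow(df) == 0L) {
    sm_stop_validation("abundance file has no data rows: %s", path)
  }
  for (col in ABUNDANCE_COLS[-1]) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num))
    if (length(bad)) {
      # +1 for the header line
      sm_stop_validation("non-numeric %s value %s at line %d of %s",
                         col, dQuote(df[[col]][bad[1]]), bad[1] + 1L, path)
    }
    df[[col]] <- num
  }
  df$length <- as.integer(df$length)
  if (any(df$eff_length <= 0)) {
    sm_stop_validation("non-positive eff_length in %s", path)
  }
  if (any(df$est_counts < 0) || any(df$tpm < 0)) {
    sm_stop_validation("negative est_counts or tpm in %s", path)
  }
  df
}

#' Write an abundance table in the dialect [read_abundance()] consumes
#'
#' @param df data.frame with the five dialect columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(df, path) {
  stopifnot(all(ABUNDANCE_COLS %in% names(df)))
  out <- df[, ABUNDANCE_COLS]
  out$eff_length <- format(out$eff_length, digits = 15, trim = TRUE,
                           scientific = FALSE)
  out$est_counts <- format(out$est_counts, digits = 15, trim = TRUE,
                           scientific = FALSE)
  out$tpm <- format(out$tpm, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcripts per million from estimated counts
#'
#' `tpm_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6` with `l` the effective
#' length; the output always sums to one million.
#'
#' @param est_counts non-negative estimated counts.
#' @param eff_length positive effective lengths, same length as `est_counts`.
#' @return TPM vector summing to 1e6.
#' @export
compute_tpm <- function(est_counts, eff_length) {
  check_abundance_vectors(est_counts, eff_length)
  if (all(est_counts == 0)) {
    sm_stop_validation("TPM undefined: all estimated counts are zero")
  }
  rate <- est_counts / eff_length
  rate / sum(rate) * 1e6
}

#' Fragments per kilobase per million mapped fragments
#'
#' `fpkm_i = c_i / (l_i / 1e3) / (sum_j c_j / 1e6)`.
#'
#' @inheritParams compute_tpm
#' @return FPKM vector.
#' @export
compute_fpkm <- function(est_counts, eff_length) {
  check_abundance_vectors(est_counts, eff_length)
  total <- sum(est_counts)
  if (total == 0) {
    sm_stop_validation("FPKM undefined: zero total counts")
  }
  est_counts / (eff_length / 1e3) / (total / 1e6)
}

check_abundance_vectors <- function(est_counts, eff_length) {
  if (length(est_counts) != length(eff_length)) {
    sm_stop_validation("est_counts and eff_length differ in length")
  }
  if (length(est_counts) == 0L) {
    sm_stop_validation("empty abundance vectors")
  }
  if (any(!is.finite(est_counts)) || any(est_counts < 0)) {
    sm_stop_validation("est_counts must be finite and non-negative")
  }
  if (any(!is.finite(eff_length)) || any(eff_length <= 0)) {
    sm_stop_validation("eff_length must be finite and positive")
  }
  invisible(TRUE)
}

#' Read a transcript-to-gene map
#'
#' Two-column TSV `transcript_id<TAB>gene_id`.
#'
#' @param path map TSV path.
#' @return data.frame with columns `transcript_id`, `gene_id`.
#' @export
read_t2g <- function(path) {
  if (!file.exists(path)) {
    sm_stop_validation("transcript-to-gene map not found: %s", path)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id")
  if (!all(need %in% names(df))) {
    sm_stop_validation("t2g map requires columns: %s",
                       paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$transcript_id)) {
    dup <- unique(df$transcript_id[duplicated(df$transcript_id)])
    sm_stop_validation("transcript mapped twice: %s",
                       paste(utils::head(dup, 5), collapse = ", "))
  }
  df[, need]
}

#' Sum transcript-level TPM to gene level
#'
#' TPM is an abundance share, so shares of the transcripts of one gene add.
#' Transcripts absent from the map are dropped and their count is reported
#' via `message()`.
#'
#' @param tpm named numeric vector of per-transcript TPM (names are
#'   transcript identifiers), or a data.frame from [read_abundance()].
#' @param t2g data.frame with columns `transcript_id`, `gene_id`.
#' @return named numeric vector of gene-level TPM, in first-appearance order
#'   of genes among the mapped transcripts.
#' @export
aggregate_to_genes <- function(tpm, t2g) {
  if (is.data.frame(tpm)) {
    tpm <- stats::setNames(tpm$tpm, tpm$target_id)
  }
  if (is.null(names(tpm))) {
    sm_stop_validation("per-transcript TPM vector must be named")
  }
  if (length(tpm) > 0L && nrow(t2g) == 0L) {
    sm_stop_validation("empty transcript-to-gene map for non-empty records")
  }
  gene <- t2g$gene_id[match(names(tpm), t2g$transcript_id)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    message(sprintf("aggregate_to_genes: dropped %d unmapped transcript(s)",
                    sum(unmapped)))
  }
  tpm <- tpm[!unmapped]
  gene <- gene[!unmapped]
  sums <- rowsum(tpm, group = gene, reorder = FALSE)
  stats::setNames(as.numeric(sums), rownames(sums))
}

#' Read a sample sheet
#'
#' TSV `sample_id<TAB>genotype<TAB>stage<TAB>replicate<TAB>path`; `path`
#' points at the per-sample abundance file, resolved relative to the sheet's
#' directory when not absolute.
#'
#' @param path sample sheet TSV path.
#' @return validated data.frame (columns sample_id, genotype, stage,
#'   replicate, path).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    sm_stop_validation("sample sheet not found: %s", path)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "stage", "replicate", "path")
  if (!all(need %in% names(df))) {
    sm_stop_validation("sample sheet requires columns: %s",
                       paste(need, collapse = ", "))
  }
  meta <- validate_sample_sheet(df[, c("sample_id", "genotype", "stage",
                                       "replicate")])
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  meta$path <- df$path
  meta
}

#' Assemble per-sample gene TPM vectors into an ExpressionMatrix
#'
#' Samples may disagree on their gene universe: genes are outer-joined in
#' first-appearance order and absences are zero-filled (absence of evidence
#' of expression) with a warning.
#'
#' @param gene_tpm named list (by sample_id) of named per-gene TPM vectors.
#' @param metas sample metadata data.frame (`sample_id`, `genotype`, `stage`,
#'   `replicate`); defines column order.
#' @param unit `"TPM"` (default) or `"FPKM"`.
#' @param species species tag for the matrix.
#' @return an `ExpressionMatrix`.
#' @export
assemble_matrix <- function(gene_tpm, metas, unit = "TPM",
                            species = "mouse") {
  metas <- validate_sample_sheet(metas)
  if (!setequal(names(gene_tpm), metas$sample_id) ||
      length(gene_tpm) != nrow(metas)) {
    sm_stop_validation("gene_tpm list names must match sample sheet ids")
  }
  gene_tpm <- gene_tpm[metas$sample_id]
  universe <- unique(unlist(lapply(gene_tpm, names), use.names = FALSE))
  values <- matrix(0, nrow = length(universe), ncol = nrow(metas),
                   dimnames = list(universe, metas$sample_id))
  n_missing <- 0L
  for (sid in metas$sample_id) {
    v <- gene_tpm[[sid]]
    n_missing <- n_missing + sum(!(universe %in% names(v)))
    values[names(v), sid] <- v
  }
  if (n_missing > 0L) {
    warning(sprintf("assemble_matrix: %d gene/sample cells absent, zero-filled",
                    n_missing))
  }
  expression_matrix(values, metas, unit = unit, species = species)
}

#' Mean expression over the replicates of one (genotype, stage) group
#'
#' @param matrix an `ExpressionMatrix`.
#' @param genotype `"transgenic"` or `"wildtype"`.
#' @param stage `"DN1"`..`"DN4"`.
#' @return named per-gene arithmetic mean vector.
#' @export
group_mean <- function(matrix, genotype, stage) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  sel <- matrix$samples$genotype == genotype & matrix$samples$stage == stage
  if (!any(sel)) {
    sm_stop_validation("no samples for genotype=%s stage=%s", genotype, stage)
  }
  rowMeans(matrix$values[, sel, drop = FALSE])
}

#' Per-gene group means for every (genotype, stage) cell
#'
#' Convenience used by tiling, the differential screen and candidate
#' selection: genes x 4 matrices of replicate-mean TPM for each genotype.
#'
#' @param matrix an `ExpressionMatrix` containing both genotypes at all four
#'   DN stages.
#' @return list with gene x stage matrices `tg` and `wt` (columns DN1..DN4).
#' @export
stage_means <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  mk <- function(genotype) {
    vapply(STAGES, function(st) group_mean(matrix, genotype, st),
           numeric(nrow(matrix$values)))
  }
  list(tg = mk("transgenic"), wt = mk("wildtype"))
}
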