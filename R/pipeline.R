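#' End-to-end analysis pipeline
#'
#' Orchestrates the full screen: read abundance tables, aggregate to genes,
#' assemble the annotated matrix, restrict to the surfaceome, build tile
#' matrices, run the stage-wise differential screen and its Venn partition,
#' select candidates, and compute the log/PCA/correlation diagnostics.
#' Every stage logs its row counts to stderr; all artifacts are written as
#' TSV/JSON under the output directory together with a machine-readable
#' `report.json` whose every count is re-derivable from the artifacts.
#'
#' @name pipeline
NULL

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis
#'
#' @param config analysis configuration list (see [read_run_config()]).
#' @param out_dir output directory for artifacts (created if absent).
#' @return invisibly, a list with the in-memory results: `matrix`,
#'   `surf_matrix`, `tiles`, `differential`, `venn`, `candidates`, `pca`,
#'   `separation`, `correlation`, `report`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sheet <- read_sample_sheet(config$samples)
  log_stage("read", "sample sheet: %d samples", nrow(sheet))
  t2g <- read_t2g(config$t2g)
  db <- load_surfaceome(config$surfaceome, species = config$species)
  log_stage("read", "surfaceome catalogue: %d entries", nrow(db$entries))

  gene_tpm <- lapply(stats::setNames(seq_len(nrow(sheet)), sheet$sample_id),
                     function(i) {
    ab <- read_abundance(sheet$path[i])
    aggregate_to_genes(stats::setNames(ab$tpm, ab$target_id), t2g)
  })
  log_stage("aggregate", "%d samples aggregated over %d transcripts",
            length(gene_tpm), nrow(t2g))

  mat <- assemble_matrix(gene_tpm,
                         sheet[, c("sample_id", "genotype", "stage",
                                   "replicate")],
                         unit = "TPM", species = config$species)
  log_stage("assemble", "matrix: %d genes x %d samples",
            nrow(mat$values), ncol(mat$values))
  write_expression_matrix(mat, file.path(out_dir, "gene_matrix.tsv"))

  surf <- filter_to_surfaceome(mat, db, by = config$match_by)
  log_stage("surfaceome", "restricted to %d surfaceome genes",
            nrow(surf$values))
  write_expression_matrix(surf, file.path(out_dir, "surfaceome_matrix.tsv"))

  tiles <- lapply(stats::setNames(STAGES, STAGES), function(st) {
    tile_matrix(surf, st)
  })
  for (st in STAGES) {
    write_tile_matrix(tiles[[st]],
                      file.path(out_dir, sprintf("tiles_%s.tsv", st)))
  }
  log_stage("tiles", "4 tile matrices over %d genes", tiles$DN1$n_genes)

  diff <- differential_by_stage(surf, min_mean = config$min_mean,
                                min_fold = config$min_fold)
  utils::write.table(diff$calls, file.path(out_dir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("differential", "%d up / %d down calls across stages",
            sum(diff$calls$direction == "up"),
            sum(diff$calls$direction == "down"))

  venn_up <- venn_partition(lapply(diff$stages, `[[`, "up"))
  venn_down <- venn_partition(lapply(diff$stages, `[[`, "down"))
  jsonlite::write_json(
    list(up = list(regions = venn_up$regions,
                   counts = as.list(venn_up$counts)),
         down = list(regions = venn_down$regions,
                     counts = as.list(venn_down$counts))),
    file.path(out_dir, "venn.json"), auto_unbox = TRUE, digits = NA)
  log_stage("venn", "all-four region: %d up, %d down",
            venn_up$all_four, venn_down$all_four)

  candidates <- select_candidates(surf,
                                  min_mean_tpm = config$candidate_min_tpm,
                                  min_fold = config$candidate_min_fold)
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("candidates", "%d selected of %d genes",
            sum(candidates$selected), nrow(candidates))

  logmat <- log_transform(surf, pseudocount = config$pseudocount,
                          base = config$log_base)
  n_comp <- min(config$n_components, nrow(surf$values),
                ncol(surf$values) - 1L)
  pca <- run_pca(logmat, n_components = n_comp)
  sep <- component_separation(pca)
  write_pca(pca, sep, out_dir)
  corr <- sample_correlation(logmat, method = config$cor_method)
  utils::write.table(
    data.frame(sample_id = rownames(corr$r), corr$r, check.names = FALSE),
    file.path(out_dir, "correlation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("structure", "PCA with %d components; correlation (%s)",
            n_comp, corr$method)

  report <- list(
    tool = "surfmine",
    version = as.character(utils::packageVersion("surfmine")),
    config = config,
    n_samples = ncol(mat$values),
    n_genes = nrow(mat$values),
    n_surfaceome_genes = nrow(surf$values),
    differential = lapply(diff$stages, function(s) {
      list(up = length(s$up), down = length(s$down))
    }),
    venn_up_counts = as.list(venn_up$counts),
    venn_down_counts = as.list(venn_down$counts),
    all_four_up = venn_up$all_four,
    all_four_down = venn_down$all_four,
    tile_totals = lapply(tiles, function(t) sum(t$counts)),
    n_candidates = sum(candidates$selected),
    explained_variance_ratio = pca$explained_variance_ratio,
    component_separation = sep,
    correlation_structure = correlation_structure(corr)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  log_stage("report", "written to %s", file.path(out_dir, "report.json"))

  invisible(list(matrix = mat, surf_matrix = surf, tiles = tiles,
                 differential = diff, venn = venn_up, venn_down = venn_down,
                 candidates = candidates, pca = pca, separation = sep,
                 correlation = corr, report = report))
}

write_tile_matrix <- function(tile, path) {
  counts <- tile$counts
  out <- data.frame(wildtype = rownames(counts), counts,
                    row_total = rowSums(counts), check.names = FALSE)
  total <- c("col_total", colSums(counts), sum(counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(paste(total, collapse = "\t"), "\n", sep = "", file = path,
      append = TRUE)
  invisible(path)
}

write_pca <- function(pca, sep, out_dir) {
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), pca$samples[-1],
               pca$scores, check.names = FALSE),
    file.path(out_dir, "pca_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(pca$loadings), pca$loadings,
               check.names = FALSE),
    file.path(out_dir, "pca_loadings.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sep, file.path(out_dir, "pca_explained.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
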