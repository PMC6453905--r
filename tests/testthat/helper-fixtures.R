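# In-code fixtures shared across the suite. All randomness is locally
# seeded with withr::with_seed-style wrappers kept base-only.

# full 2-genotype x 4-stage x n-replicate sample sheet
make_meta <- function(n_replicates = 1L) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      stage = c("DN1", "DN2", "DN3", "DN4"),
                      genotype = c("transgenic", "wildtype"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_r%d",
                        ifelse(grid$genotype == "transgenic", "tg", "wt"),
                        grid$stage, grid$replicate),
    genotype = grid$genotype, stage = grid$stage,
    replicate = grid$replicate, stringsAsFactors = FALSE)
}

# ExpressionMatrix from a gene x sample value matrix (defaults: full design)
make_matrix <- function(values, meta = NULL, unit = "TPM",
                        species = "mouse") {
  if (is.null(meta)) {
    n_rep <- ncol(values) / 8L
    meta <- make_meta(n_rep)
  }
  colnames(values) <- meta$sample_id
  expression_matrix(values, meta, unit = unit, species = species)
}

# matrix whose per-(genotype, stage) group means are given exactly:
# tg, wt are gene x 4 matrices (columns DN1..DN4); replicates are exact
# copies so replicate means equal the supplied values
make_matrix_from_means <- function(tg, wt, n_replicates = 2L,
                                   gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(nrow(tg)))
  meta <- make_meta(n_replicates)
  values <- base::matrix(0, nrow(tg), nrow(meta),
                         dimnames = list(gene_ids, meta$sample_id))
  for (i in seq_len(nrow(meta))) {
    src <- if (meta$genotype[i] == "transgenic") tg else wt
    values[, i] <- src[, meta$stage[i]]
  }
  expression_matrix(values, meta, unit = "TPM")
}

random_surfaceome_entries <- function(gene_ids) {
  if (length(gene_ids) == 0L) {
    return(data.frame(gene_id = character(), symbol = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  data.frame(gene_id = gene_ids,
             symbol = paste0("Sym", sub("^G", "", gene_ids)),
             category = sample(c("surface", "secreted",
                                 "presumptive_surface"),
                               length(gene_ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# load a generated dataset directory into the surfaceome-restricted matrix,
# exercising the real readers (no pipeline extras)
load_surfaceome_matrix <- function(dir, species = "mouse") {
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  t2g <- read_t2g(file.path(dir, "t2g.tsv"))
  db <- load_surfaceome(file.path(dir, "surfaceome.tsv"), species = species)
  gene_tpm <- lapply(stats::setNames(sheet$path, sheet$sample_id),
                     function(p) {
    ab <- read_abundance(p)
    suppressMessages(
      aggregate_to_genes(stats::setNames(ab$tpm, ab$target_id), t2g))
  })
  mat <- assemble_matrix(gene_tpm,
                         sheet[, c("sample_id", "genotype", "stage",
                                   "replicate")],
                         species = species)
  filter_to_surfaceome(mat, db)
}

# small-but-structured generator config for tests that need speed
small_config <- function(seed = 11, noise_sd = 0.2, planted_n = 6L,
                         n_genes = 400L, n_surfaceome = 100L) {
  synthetic_config(
    n_genes = n_genes, n_surfaceome = n_surfaceome,
    transcripts_per_gene = 2, n_replicates = 3,
    stage_effect_sd = 1.0, noise_sd = noise_sd,
    planted = list(list(n = planted_n,
                        stages = c("DN1", "DN2", "DN3", "DN4"),
                        log2_fc = 4.3, direction = "up")),
    library_size = 5e5, seed = seed)
}
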