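#' Synthetic study-shaped datasets with planted markers
#'
#' Generates everything the pipeline consumes — per-sample abundance
#' tables, a transcript-to-gene map, a surfaceome catalogue and a sample
#' sheet — from a seeded generative model of the 2-genotype x 4-stage x
#' replicate design, together with the planted ground truth for recovery
#' scoring.
#'
#' The model: per-gene log-normal baseline abundance, additive per-(gene,
#' stage) developmental programs, a genotype effect confined to a small
#' planted surfaceome gene set, and per-replicate log-normal noise.
#' Expected gene abundance is split over transcripts by fixed per-gene
#' proportions and realised as integer counts by deterministic
#' largest-remainder allocation of the library size proportional to
#' abundance times effective length (see [allocate_counts()]), so
#' [compute_tpm()] inverts the construction, counts sum to the library
#' size exactly, and replicate variation comes solely from the configured
#' noise.
#'
#' @name synthetic_data
NULL

#' Build and validate a synthetic-dataset configuration
#'
#' Defaults state the benchmark world: 2,000 genes of which 300 form the
#' surfaceome universe, two transcripts per gene, three replicates per
#' (genotype, stage), and 12 surfaceome genes planted up-regulated in all
#' four DN stages at log2 fold 4.3 (about 20-fold), against replicate noise
#' of 0.2 log2 units and stage programs of 1.0 log2 units.
#'
#' @param n_genes total genes.
#' @param n_surfaceome surfaceome universe size (<= n_genes).
#' @param transcripts_per_gene transcripts per gene (>= 1).
#' @param n_replicates replicates per (genotype, stage).
#' @param baseline_log2_mean,baseline_log2_sd baseline log2-abundance
#'   distribution.
#' @param stage_effect_sd sd of per-(gene, stage) programs (log2).
#' @param noise_sd replicate noise sd (log2).
#' @param planted list of planted effects; each element a list with fields
#'   `n` (genes to plant) or `genes` (explicit ids), `stages` (subset of
#'   DN1..DN4), `log2_fc` (> 0) and `direction` (`"up"` = higher in
#'   transgenic, `"down"` = higher in wild type).
#' @param library_size total counts per sample.
#' @param seed integer seed governing all randomness.
#' @return validated list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes = 2000, n_surfaceome = 300,
                             transcripts_per_gene = 2, n_replicates = 3,
                             baseline_log2_mean = 3, baseline_log2_sd = 2.5,
                             stage_effect_sd = 1.0, noise_sd = 0.2,
                             planted = list(list(n = 12, stages = STAGES,
                                                 log2_fc = 4.3,
                                                 direction = "up")),
                             library_size = 5e6, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_surfaceome = as.integer(n_surfaceome),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              n_replicates = as.integer(n_replicates),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              stage_effect_sd = stage_effect_sd,
              noise_sd = noise_sd,
              planted = planted,
              library_size = as.numeric(library_size),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_surfaceome < 0L ||
      cfg$n_surfaceome > cfg$n_genes) {
    sm_stop_validation("need 0 <= n_surfaceome <= n_genes, n_genes >= 1")
  }
  if (cfg$transcripts_per_gene < 1L || cfg$n_replicates < 1L) {
    sm_stop_validation("transcripts_per_gene and n_replicates must be >= 1")
  }
  if (cfg$baseline_log2_sd < 0 || cfg$stage_effect_sd < 0 ||
      cfg$noise_sd < 0) {
    sm_stop_validation("standard deviations must be non-negative")
  }
  if (cfg$library_size < 1) {
    sm_stop_validation("library_size must be positive")
  }
  for (p in cfg$planted) {
    if (is.null(p$stages) || !all(p$stages %in% STAGES)) {
      sm_stop_validation("planted stages must be a subset of DN1..DN4")
    }
    if (is.null(p$log2_fc) || !is.finite(p$log2_fc) || p$log2_fc <= 0) {
      sm_stop_validation("planted log2_fc must be positive and finite")
    }
    if (is.null(p$direction) || !p$direction %in% c("up", "down")) {
      sm_stop_validation("planted direction must be 'up' or 'down'")
    }
    if (is.null(p$genes) && is.null(p$n)) {
      sm_stop_validation("planted effect needs 'genes' or 'n'")
    }
  }
  structure(cfg, class = "SyntheticConfig")
}

#' Generate a synthetic dataset on disk
#'
#' Writes, under `out_dir`: `abundance/<sample_id>.tsv` per sample,
#' `t2g.tsv`, `surfaceome.tsv`, `samples.tsv` (with relative abundance
#' paths) and `truth.json`. Fully reproducible: the same configuration
#' (including seed) yields byte-identical files.
#'
#' @param config a `SyntheticConfig`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list: `dir`, `sample_sheet` path, `truth` (the
#'   in-memory `SyntheticTruth` list).
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dir.create(file.path(out_dir, "abundance"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(config$seed)

  n <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))
  # mouse-style symbols: capitalised first letter only
  symbols <- sprintf("Sgene%05d", seq_len(n))

  surf_idx <- sort(sample.int(n, config$n_surfaceome))
  surf_ids <- gene_ids[surf_idx]
  categories <- sample(SURFACEOME_CATEGORIES, config$n_surfaceome,
                       replace = TRUE, prob = c(0.7, 0.15, 0.15))

  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  stage_eff <- base::matrix(stats::rnorm(n * 4L, 0, config$stage_effect_sd),
                            nrow = n, dimnames = list(gene_ids, STAGES))

  # planted genotype effects (log2), kept separate per genotype
  shift_tg <- base::matrix(0, n, 4L, dimnames = list(gene_ids, STAGES))
  shift_wt <- shift_tg
  planted_rows <- list()
  taken <- character()
  names(baseline) <- gene_ids
  for (p in config$planted) {
    if (!is.null(p$genes)) {
      genes <- as.character(p$genes)
      if (!all(genes %in% surf_ids)) {
        sm_stop_validation("planted genes must lie in the surfaceome universe")
      }
    } else {
      # plant among moderately expressed surfaceome genes so a ~20-fold
      # effect clears both the TPM > 1 gate and the candidate TPM > 20 gate
      pool <- setdiff(surf_ids[baseline[surf_ids] >= 1 &
                               baseline[surf_ids] <= 5], taken)
      if (length(pool) < p$n) {
        sm_stop_validation("only %d eligible surfaceome genes for planting %d",
                           length(pool), p$n)
      }
      genes <- sort(sample(pool, p$n))
    }
    if (any(genes %in% taken)) {
      sm_stop_validation("planted gene sets must be disjoint")
    }
    taken <- c(taken, genes)
    if (p$direction == "up") {
      shift_tg[genes, p$stages] <- shift_tg[genes, p$stages] + p$log2_fc
    } else {
      shift_wt[genes, p$stages] <- shift_wt[genes, p$stages] + p$log2_fc
    }
    planted_rows[[length(planted_rows) + 1L]] <- data.frame(
      gene_id = genes,
      stages = paste(p$stages, collapse = "&"),
      log2_fc = p$log2_fc, direction = p$direction,
      stringsAsFactors = FALSE)
  }
  planted_df <- if (length(planted_rows)) {
    do.call(rbind, planted_rows)
  } else {
    data.frame(gene_id = character(), stages = character(),
               log2_fc = numeric(), direction = character())
  }

  # transcripts: fixed lengths and within-gene expression shares
  tpg <- config$transcripts_per_gene
  tx_gene <- rep(gene_ids, each = tpg)
  tx_ids <- paste0(rep(sub("^G", "T", gene_ids), each = tpg), ".",
                   rep(seq_len(tpg), times = n))
  tx_length <- sample(500:3000, n * tpg, replace = TRUE)
  tx_eff_length <- tx_length - 200
  share <- stats::rexp(n * tpg)
  share <- share / rep(rowsum(share, tx_gene, reorder = FALSE), each = tpg)

  # sample sheet in fixed order: genotype (tg, wt) x stage x replicate
  metas <- expand.grid(replicate = seq_len(config$n_replicates),
                       stage = STAGES,
                       genotype = c("transgenic", "wildtype"),
                       stringsAsFactors = FALSE)
  metas <- metas[, c("genotype", "stage", "replicate")]
  metas$sample_id <- sprintf("%s_%s_r%d",
                             ifelse(metas$genotype == "transgenic",
                                    "tg", "wt"),
                             metas$stage, metas$replicate)

  expected_log2 <- list()   # per (genotype, stage): expected log2 abundance
  for (g in c("transgenic", "wildtype")) {
    shift <- if (g == "transgenic") shift_tg else shift_wt
    for (st in STAGES) {
      expected_log2[[paste(g, st, sep = ".")]] <-
        baseline + stage_eff[, st] + shift[, st]
    }
  }

  paths <- character(nrow(metas))
  for (i in seq_len(nrow(metas))) {
    mu <- expected_log2[[paste(metas$genotype[i], metas$stage[i], sep = ".")]]
    log2_tpm <- mu + stats::rnorm(n, 0, config$noise_sd)
    gene_ab <- 2^log2_tpm
    tx_ab <- gene_ab[tx_gene] * share
    counts <- allocate_counts(config$library_size, tx_ab * tx_eff_length)
    ab <- data.frame(target_id = tx_ids, length = tx_length,
                     eff_length = tx_eff_length, est_counts = counts,
                     tpm = compute_tpm(counts, tx_eff_length),
                     stringsAsFactors = FALSE)
    rel <- file.path("abundance", paste0(metas$sample_id[i], ".tsv"))
    write_abundance(ab, file.path(out_dir, rel))
    paths[i] <- rel
  }

  utils::write.table(
    data.frame(transcript_id = tx_ids, gene_id = tx_gene),
    file.path(out_dir, "t2g.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = surf_ids, symbol = symbols[surf_idx],
               category = categories),
    file.path(out_dir, "surfaceome.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = metas$sample_id, genotype = metas$genotype,
                      stage = metas$stage, replicate = metas$replicate,
                      path = paths, stringsAsFactors = FALSE)
  utils::write.table(sheet, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    gene_ids = gene_ids,
    surfaceome = surf_ids,
    planted = planted_df,
    expected_log2_abundance = lapply(expected_log2, unname),
    config = unclass(config)
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir,
                 sample_sheet = file.path(out_dir, "samples.tsv"),
                 truth = truth))
}

#' Deterministic multinomial allocation by largest remainder
#'
#' Splits `n` counts over cells proportionally to `weights`: floor the
#' expected allocation, then hand the remaining units to the cells with the
#' largest fractional parts (ties broken by cell index). Counts sum to `n`
#' exactly and the allocation is a deterministic function of its inputs, so
#' replicate variation in generated data comes solely from the configured
#' noise, and zero noise yields identical replicates.
#'
#' @param n total count (library size).
#' @param weights non-negative allocation weights.
#' @return integer-valued numeric vector summing to `n`.
#' @export
allocate_counts <- function(n, weights) {
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    sm_stop_validation("allocation weights must be non-negative, some > 0")
  }
  expected <- n * weights / sum(weights)
  counts <- floor(expected)
  short <- round(n - sum(counts))
  if (short > 0) {
    frac <- expected - counts
    top <- order(-frac, seq_along(frac))[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  counts
}

#' Read a serialized SyntheticTruth
#'
#' @param path path to `truth.json`.
#' @return the truth list (planted table as data.frame).
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$planted <- as.data.frame(truth$planted, stringsAsFactors = FALSE)
  truth
}

#' Score differential calls against the planted truth
#'
#' Precision = |calls intersect planted| / |calls| (1 when no calls were
#' made); recall = |calls intersect planted| / |planted| (1 when nothing
#' was planted). Scored per stage — against the genes planted in the given
#' direction at that stage — and for the all-stage intersection against the
#' genes planted at all four stages.
#'
#' @param calls a `DifferentialResult`, or a named list (DN1..DN4) of
#'   per-stage gene-id vectors.
#' @param truth a truth list from [generate_dataset()] or [read_truth()].
#' @param direction `"up"` (default) or `"down"`.
#' @return data.frame (stage, n_called, n_planted, precision, recall) with
#'   rows DN1..DN4 and `"all"`.
#' @export
evaluate_recovery <- function(calls, truth, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (inherits(calls, "DifferentialResult")) {
    calls <- lapply(calls$stages, `[[`, direction)
  }
  if (!setequal(names(calls), STAGES)) {
    sm_stop_validation("calls must be named DN1..DN4")
  }
  pl <- truth$planted[truth$planted$direction == direction, , drop = FALSE]
  universe <- truth$gene_ids
  bad <- setdiff(unlist(calls, use.names = FALSE), universe)
  if (length(bad)) {
    sm_stop_validation("called gene(s) outside the truth universe: %s",
                       paste(utils::head(bad, 5), collapse = ", "))
  }
  planted_at <- function(st) {
    pl$gene_id[vapply(strsplit(pl$stages, "&", fixed = TRUE),
                      function(s) st %in% s, logical(1))]
  }
  score <- function(called, planted) {
    tp <- length(intersect(called, planted))
    c(precision = if (length(called)) tp / length(called) else 1,
      recall = if (length(planted)) tp / length(planted) else 1)
  }
  rows <- lapply(STAGES, function(st) {
    planted <- planted_at(st)
    s <- score(calls[[st]], planted)
    data.frame(stage = st, n_called = length(calls[[st]]),
               n_planted = length(planted),
               precision = s[["precision"]], recall = s[["recall"]],
               stringsAsFactors = FALSE)
  })
  all_called <- Reduce(intersect, calls[STAGES])
  all_planted <- Reduce(intersect, lapply(STAGES, planted_at))
  s <- score(all_called, all_planted)
  rows[[5L]] <- data.frame(stage = "all", n_called = length(all_called),
                           n_planted = length(all_planted),
                           precision = s[["precision"]],
                           recall = s[["recall"]], stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
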