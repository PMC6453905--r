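#' Threshold-based surfaceome screening
#'
#' The mining computations applied to a surfaceome-restricted expression
#' matrix: four-class TPM binning, 4x4 class-transition tiles per stage,
#' the fold-change differential screen, Venn partitioning of stage-wise hit
#' sets, candidate-marker selection and the binary expression call used on
#' FPKM cohorts.
#'
#' @name dbm_core
NULL

EXPRESSION_CLASSES <- c("ZERO", "LOW", "MED", "HIGH")

#' Bin TPM values into the four expression classes
#'
#' Classes partition `[0, Inf)`: ZERO `[0, 0.1)`, LOW `[0.1, 1)`,
#' MED `[1, 10]`, HIGH `(10, Inf)`. HIGH is strictly above 10; the inner
#' joints are resolved half-open (documented boundary convention).
#'
#' @param tpm non-negative finite TPM values (vectorised).
#' @return factor with levels `ZERO < LOW < MED < HIGH`.
#' @export
classify_expression <- function(tpm) {
  if (length(tpm) && (any(!is.finite(tpm)) || any(tpm < 0))) {
    sm_stop_validation("TPM values must be finite and non-negative")
  }
  lab <- ifelse(tpm < 0.1, "ZERO",
         ifelse(tpm < 1, "LOW",
         ifelse(tpm <= 10, "MED", "HIGH")))
  factor(lab, levels = EXPRESSION_CLASSES, ordered = TRUE)
}

#' 4x4 expression-class transition tile matrix for one stage
#'
#' Each gene contributes one count at (class of wild-type replicate mean,
#' class of transgenic replicate mean); the 16 cells therefore sum to the
#' number of genes tiled. The diagonal holds genes whose class is unchanged
#' between genotypes.
#'
#' @param matrix surfaceome-restricted `ExpressionMatrix` with both
#'   genotypes present at `stage`.
#' @param stage `"DN1"`..`"DN4"`.
#' @return object of class `TileMatrix`: `counts` (4x4 integer matrix, rows
#'   = wild-type class, columns = transgenic class), `stage`, `n_genes`.
#' @export
tile_matrix <- function(matrix, stage) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  stage <- match.arg(stage, STAGES)
  wt_class <- classify_expression(group_mean(matrix, "wildtype", stage))
  tg_class <- classify_expression(group_mean(matrix, "transgenic", stage))
  counts <- table(wildtype = wt_class, transgenic = tg_class)
  counts <- base::matrix(as.integer(counts), nrow = 4, ncol = 4,
                         dimnames = list(wildtype = EXPRESSION_CLASSES,
                                         transgenic = EXPRESSION_CLASSES))
  structure(list(counts = counts, stage = stage,
                 n_genes = nrow(matrix$values)),
            class = "TileMatrix")
}

#' @export
print.TileMatrix <- function(x, ...) {
  cat(sprintf("TileMatrix %s (%d genes; rows = wildtype, cols = transgenic)\n",
              x$stage, x$n_genes))
  print(x$counts)
  invisible(x)
}

#' Fold-change differential call between genotype means
#'
#' A gene is `up` when the transgenic replicate mean exceeds 1 TPM and is
#' more than 10-fold the wild-type mean; `down` is the genotype-mirrored
#' rule. The fold test is multiplicative (`mean_tg > fold * mean_wt`), so a
#' zero comparator needs no division, and all inequalities are strict.
#'
#' @param mean_tg,mean_wt non-negative replicate-mean TPM (vectorised).
#' @param min_mean expression gate on the higher genotype (default 1 TPM).
#' @param min_fold fold-change gate (default 10).
#' @return character vector in `{"up", "down", "none"}`.
#' @export
call_differential <- function(mean_tg, mean_wt, min_mean = 1, min_fold = 10) {
  if (any(!is.finite(mean_tg)) || any(!is.finite(mean_wt)) ||
      any(mean_tg < 0) || any(mean_wt < 0)) {
    sm_stop_validation("genotype means must be finite and non-negative")
  }
  up <- mean_tg > min_mean & mean_tg > min_fold * mean_wt
  down <- mean_wt > min_mean & mean_wt > min_fold * mean_tg
  ifelse(up, "up", ifelse(down, "down", "none"))
}

#' Stage-wise differential screen
#'
#' Applies [group_mean()] then [call_differential()] per gene at each DN
#' stage.
#'
#' @param matrix surfaceome-restricted `ExpressionMatrix` with both
#'   genotypes at all four stages.
#' @inheritParams call_differential
#' @return object of class `DifferentialResult`: `stages`, a per-stage list
#'   with character vectors `up` and `down`; `calls`, a tidy data.frame
#'   (gene_id, stage, direction, mean_tg, mean_wt) restricted to non-`none`
#'   calls.
#' @export
differential_by_stage <- function(matrix, min_mean = 1, min_fold = 10) {
  means <- stage_means(matrix)
  genes <- rownames(matrix$values)
  stages <- list()
  calls <- list()
  for (st in STAGES) {
    dir <- call_differential(means$tg[, st], means$wt[, st],
                             min_mean = min_mean, min_fold = min_fold)
    stages[[st]] <- list(up = genes[dir == "up"], down = genes[dir == "down"])
    hit <- dir != "none"
    calls[[st]] <- data.frame(gene_id = genes[hit],
                              stage = rep(st, sum(hit)),
                              direction = dir[hit],
                              mean_tg = means$tg[hit, st],
                              mean_wt = means$wt[hit, st],
                              stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  structure(list(stages = stages, calls = calls),
            class = "DifferentialResult")
}

#' @export
print.DifferentialResult <- function(x, ...) {
  for (st in names(x$stages)) {
    cat(sprintf("%s: %d up, %d down\n", st,
                length(x$stages[[st]]$up), length(x$stages[[st]]$down)))
  }
  invisible(x)
}

#' Partition four stage sets into their 15 Venn regions
#'
#' Every gene in the union of the four sets is assigned to exactly one
#' region according to its membership signature, so regions are pairwise
#' disjoint and exhaustive. Region labels join the member stages with
#' `"&"` (e.g. `"DN2&DN3"`); the `"DN1&DN2&DN3&DN4"` region is the
#' all-stage intersection.
#'
#' @param stage_sets named list of four character vectors, names
#'   `DN1`..`DN4`.
#' @return object of class `VennPartition`: `regions` (named list of gene
#'   vectors, all 15 labels always present), `counts` (named integer
#'   vector), `all_four` (size of the full intersection region).
#' @export
venn_partition <- function(stage_sets) {
  if (!setequal(names(stage_sets), STAGES)) {
    sm_stop_validation("stage_sets must be named DN1..DN4")
  }
  stage_sets <- lapply(stage_sets[STAGES], unique)
  universe <- sort(unique(unlist(stage_sets, use.names = FALSE)))
  membership <- base::matrix(FALSE, nrow = length(universe), ncol = 4L,
                             dimnames = list(universe, STAGES))
  for (st in STAGES) membership[stage_sets[[st]], st] <- TRUE
  labels <- venn_region_labels()
  regions <- stats::setNames(vector("list", length(labels)), labels)
  sig <- apply(membership, 1L, function(m) paste(STAGES[m], collapse = "&"))
  for (lab in labels) {
    regions[[lab]] <- universe[sig == lab]
  }
  counts <- vapply(regions, length, integer(1))
  structure(list(regions = regions, counts = counts,
                 all_four = counts[["DN1&DN2&DN3&DN4"]]),
            class = "VennPartition")
}

venn_region_labels <- function() {
  unlist(lapply(1:4, function(k) {
    apply(utils::combn(STAGES, k), 2L, paste, collapse = "&")
  }))
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition (15 regions):\n")
  print(x$counts)
  invisible(x)
}

#' Select candidate surface-marker genes
#'
#' A gene is a candidate when its transgenic replicate-mean TPM exceeds
#' `min_mean_tpm` at some stage and at some stage the transgenic mean is
#' more than `min_fold` times the wild-type mean ("large expression
#' difference"). Per-stage means are always reported so other aggregation
#' policies can be applied downstream.
#'
#' @param matrix surfaceome-restricted `ExpressionMatrix`.
#' @param min_mean_tpm TPM gate on the best transgenic stage mean
#'   (default 20).
#' @param min_fold fold gate (default 5).
#' @return data.frame, one row per gene: per-stage `tg_DN*` and `wt_DN*`
#'   means, `max_mean_tg`, `max_fold` (Inf when the wild-type mean is zero
#'   and the transgenic mean positive), `selected`; sorted with selected
#'   genes first, descending `max_mean_tg`.
#' @export
select_candidates <- function(matrix, min_mean_tpm = 20, min_fold = 5) {
  if (min_mean_tpm <= 0 || min_fold <= 0) {
    sm_stop_validation("candidate thresholds must be positive")
  }
  means <- stage_means(matrix)
  genes <- rownames(matrix$values)
  fold <- means$tg / means$wt           # Inf where wt = 0, tg > 0
  fold[means$tg == 0 & means$wt == 0] <- 1
  max_mean_tg <- apply(means$tg, 1L, max)
  fold_pass <- rowSums(means$tg > min_fold * means$wt) > 0
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (st in STAGES) out[[paste0("tg_", st)]] <- means$tg[, st]
  for (st in STAGES) out[[paste0("wt_", st)]] <- means$wt[, st]
  out$max_mean_tg <- max_mean_tg
  out$max_fold <- apply(fold, 1L, max)
  out$selected <- max_mean_tg > min_mean_tpm & fold_pass
  out <- out[order(-out$selected, -out$max_mean_tg), ]
  rownames(out) <- NULL
  out
}

#' Binary expression call on a length-normalised value
#'
#' `TRUE` when the value is strictly above the threshold; the cohort-level
#' convention used for calling a gene expressed from FPKM tables (default
#' threshold 4 FPKM).
#'
#' @param value non-negative expression value(s).
#' @param threshold strict lower bound (default 4).
#' @return logical vector.
#' @export
expression_call <- function(value, threshold = 4) {
  if (any(!is.finite(value)) || any(value < 0)) {
    sm_stop_validation("expression values must be finite and non-negative")
  }
  value > threshold
}

#' Per-gene marker summary across samples
#'
#' Extracts a tidy per-sample value table for a set of marker genes, plus
#' group means per (genotype, stage) and the fraction of samples in which
#' each marker is called expressed under [expression_call()].
#'
#' @param matrix an `ExpressionMatrix`.
#' @param genes character vector of gene identifiers; missing genes are
#'   reported with a warning, not an error.
#' @param threshold expression-call threshold (default 4).
#' @return list: `values` tidy data.frame (gene_id, sample_id, genotype,
#'   stage, replicate, value), `group_means` data.frame (gene_id, genotype,
#'   stage, mean), `expressed_fraction` named numeric vector over the found
#'   genes.
#' @export
marker_summary <- function(matrix, genes, threshold = 4) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  found <- genes[genes %in% rownames(matrix$values)]
  missing <- setdiff(genes, found)
  if (length(missing)) {
    warning(sprintf("marker_summary: gene(s) not in matrix: %s",
                    paste(missing, collapse = ", ")))
  }
  meta <- matrix$samples
  values <- do.call(rbind, lapply(found, function(g) {
    data.frame(gene_id = g, sample_id = meta$sample_id,
               genotype = meta$genotype, stage = meta$stage,
               replicate = meta$replicate,
               value = as.numeric(matrix$values[g, ]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(values)) {
    values <- data.frame(gene_id = character(), sample_id = character(),
                         genotype = character(), stage = character(),
                         replicate = integer(), value = numeric(),
                         stringsAsFactors = FALSE)
  }
  group_means <- if (nrow(values)) {
    agg <- stats::aggregate(value ~ gene_id + genotype + stage, data = values,
                            FUN = mean)
    names(agg)[names(agg) == "value"] <- "mean"
    agg[order(agg$gene_id, agg$genotype, agg$stage), ]
  } else {
    data.frame(gene_id = character(), genotype = character(),
               stage = character(), mean = numeric())
  }
  expressed_fraction <- vapply(found, function(g) {
    v <- values$value[values$gene_id == g]
    mean(expression_call(v, threshold))
  }, numeric(1))
  list(values = values, group_means = group_means,
       expressed_fraction = expressed_fraction)
}
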