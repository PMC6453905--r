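#' Sample-structure diagnostics
#'
#' Log transform, principal components of the sample cloud with a
#' deterministic sign convention, sorted per-gene loading weights, a
#' silhouette-style group-separation score per component, and sample-sample
#' correlation. In the study design these diagnostics show developmental
#' stage dominating the leading components while the genotype contrast,
#' carried by a handful of surfaceome genes, surfaces on a later component.
#'
#' @name stage_structure
NULL

#' Log-transform an expression matrix
#'
#' Entry-wise `log(x + pseudocount)` in the configured base (default
#' `log2(x + 1)`); strictly monotone in the input.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param pseudocount positive offset (default 1).
#' @param base logarithm base (default 2).
#' @return an `ExpressionMatrix` of transformed values; the transform is
#'   recorded in attributes `log_base` and `pseudocount`.
#' @export
log_transform <- function(matrix, pseudocount = 1, base = 2) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!is.finite(pseudocount) || pseudocount <= 0) {
    sm_stop_validation("pseudocount must be positive")
  }
  out <- matrix
  out$values <- log(matrix$values + pseudocount, base = base)
  attr(out, "log_base") <- base
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Principal components of the sample cloud
#'
#' Samples are points, genes are variables. Values are gene-wise
#' mean-centred without unit-variance scaling (expression convention) and
#' decomposed by singular values via [stats::prcomp()]. Sign convention:
#' within each component the largest-magnitude gene loading is positive, so
#' score plots and loading orders reproduce across platforms.
#'
#' @param matrix a log-transformed `ExpressionMatrix`.
#' @param n_components number of components to retain; default
#'   `min(genes, samples - 1)`.
#' @return object of class `PCAResult`: `scores` (sample x component),
#'   `loadings` (gene x component, orthonormal columns),
#'   `explained_variance_ratio`, `samples` (metadata), `pseudocount` and
#'   `log_base` echoed from the transform when present.
#' @export
run_pca <- function(matrix, n_components = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  n_samples <- ncol(matrix$values)
  n_genes <- nrow(matrix$values)
  if (n_samples < 2L) {
    sm_stop_validation("PCA requires at least 2 samples")
  }
  max_comp <- min(n_genes, n_samples - 1L)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components < 1L || n_components > max_comp) {
    sm_stop_validation("n_components must be in [1, %d]", max_comp)
  }
  x <- t(matrix$values)                  # samples x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  evr <- if (total_var > 0) pc$sdev^2 / total_var else rep(0, length(pc$sdev))
  k <- min(n_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| gene positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[seq_len(k)],
                 center = pc$center,
                 samples = matrix$samples,
                 log_base = attr(matrix, "log_base"),
                 pseudocount = attr(matrix, "pseudocount")),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: %d samples, %d genes, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Gene loadings of one component, sorted ascending
#'
#' The sorted-weight view of a component: most genes sit near zero weight
#' and the informative genes occupy the tails. Ties are broken by gene
#' identifier, lexicographically.
#'
#' @param pca a `PCAResult`.
#' @param component 1-based component index.
#' @return data.frame (gene_id, weight), ascending by weight; a permutation
#'   of all genes.
#' @export
sorted_loadings <- function(pca, component) {
  stopifnot(inherits(pca, "PCAResult"))
  if (component < 1L || component > ncol(pca$loadings)) {
    sm_stop_validation("component %d out of range [1, %d]",
                       component, ncol(pca$loadings))
  }
  w <- pca$loadings[, component]
  ord <- order(w, names(w))
  data.frame(gene_id = names(w)[ord], weight = unname(w[ord]),
             stringsAsFactors = FALSE)
}

#' Fraction of absolute loading mass carried by a gene set
#'
#' Concentration statistic for a component: `sum(|w[genes]|) / sum(|w|)`.
#' `genes` may be a character vector of identifiers or an integer `k`, in
#' which case the top-k genes by `|weight|` are used.
#'
#' @param pca a `PCAResult`.
#' @param component 1-based component index.
#' @param genes gene identifiers, or a single integer k for top-k.
#' @return fraction in `[0, 1]`.
#' @export
loading_concentration <- function(pca, component, genes) {
  w <- abs(pca$loadings[, component])
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- names(sort(w, decreasing = TRUE))[seq_len(genes)]
  }
  sum(w[names(w) %in% genes]) / sum(w)
}

#' Silhouette-style separation of sample groups on one score axis
#'
#' Mean silhouette width of the grouping on a single component's scores:
#' for each sample, `a` = mean |score difference| to its own group, `b` =
#' smallest mean distance to any other group, silhouette
#' `(b - a) / max(a, b)`. Positive means the axis separates the groups.
#'
#' @param scores numeric score vector (one PCA component).
#' @param groups grouping vector (genotype or stage), same length.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
group_separation <- function(scores, groups) {
  groups <- as.character(groups)
  if (length(scores) != length(groups)) {
    sm_stop_validation("scores and groups differ in length")
  }
  if (length(unique(groups)) < 2L) {
    sm_stop_validation("need at least 2 groups")
  }
  d <- abs(outer(scores, scores, "-"))
  sil <- vapply(seq_along(scores), function(i) {
    own <- groups == groups[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) return(0)          # singleton cluster convention
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g) {
      mean(d[i, groups == g])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' Per-component separation summary for genotype and stage
#'
#' Reports, for each retained component, the silhouette-style separation of
#' the genotype grouping and of the stage grouping, so the genotype-
#' separating component can be identified without eyeballing score plots.
#'
#' @param pca a `PCAResult` (carries sample metadata).
#' @return data.frame (component, explained_variance_ratio,
#'   stage_separation, genotype_separation).
#' @export
component_separation <- function(pca) {
  stopifnot(inherits(pca, "PCAResult"))
  k <- ncol(pca$scores)
  data.frame(
    component = seq_len(k),
    explained_variance_ratio = pca$explained_variance_ratio,
    stage_separation = vapply(seq_len(k), function(j) {
      group_separation(pca$scores[, j], pca$samples$stage)
    }, numeric(1)),
    genotype_separation = vapply(seq_len(k), function(j) {
      group_separation(pca$scores[, j], pca$samples$genotype)
    }, numeric(1))
  )
}

#' Sample-sample correlation matrix
#'
#' Pearson (default) or Spearman correlation between all sample pairs of a
#' log-transformed matrix. A zero-variance sample yields `NA` correlations
#' and a warning rather than an error.
#'
#' @param matrix a log-transformed `ExpressionMatrix` with >= 2 samples and
#'   >= 2 genes.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `CorrelationMatrix`: `r` (sample x sample),
#'   `method`, `samples`.
#' @export
sample_correlation <- function(matrix, method = c("pearson", "spearman")) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  method <- match.arg(method)
  if (ncol(matrix$values) < 2L || nrow(matrix$values) < 2L) {
    sm_stop_validation("correlation requires >= 2 samples and >= 2 genes")
  }
  sds <- apply(matrix$values, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance sample(s): %s (correlations set to NA)",
                    paste(colnames(matrix$values)[sds == 0], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(matrix$values, method = method))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  structure(list(r = r, method = method, samples = matrix$samples),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix (%s): %d samples\n", x$method, ncol(x$r)))
  invisible(x)
}

#' Compare within-stage versus within-genotype correlation
#'
#' Mean off-diagonal correlation of sample pairs sharing a stage but not a
#' genotype, versus pairs sharing a genotype but not a stage. In the study
#' design the former exceeds the latter: developmental stage moves the
#' transcriptome more than the transgene does.
#'
#' @param corr a `CorrelationMatrix`.
#' @return list with `within_stage_cross_genotype`,
#'   `within_genotype_cross_stage` mean correlations.
#' @export
correlation_structure <- function(corr) {
  stopifnot(inherits(corr, "CorrelationMatrix"))
  meta <- corr$samples
  n <- nrow(meta)
  same_stage <- outer(meta$stage, meta$stage, "==")
  same_geno <- outer(meta$genotype, meta$genotype, "==")
  off <- !diag(n)
  list(
    within_stage_cross_genotype =
      mean(corr$r[same_stage & !same_geno & off], na.rm = TRUE),
    within_genotype_cross_stage =
      mean(corr$r[!same_stage & same_geno & off], na.rm = TRUE)
  )
}
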