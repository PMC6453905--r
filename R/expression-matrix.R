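#' Gene-by-sample expression matrix with sample metadata
#'
#' The central container of the package: a non-negative numeric matrix of
#' length-normalised abundances (TPM or FPKM), genes as rows and samples as
#' columns, bound to a sample sheet describing the 2-genotype x 4-stage x
#' replicate study design.
#'
#' @param values numeric matrix, genes as rows (rownames = gene identifiers),
#'   samples as columns (colnames = sample identifiers). Entries must be
#'   finite and non-negative.
#' @param samples data.frame with columns `sample_id`, `genotype`
#'   (`"transgenic"` or `"wildtype"`), `stage` (`"DN1"`..`"DN4"`) and
#'   `replicate` (positive integer). Row order defines column order.
#' @param unit `"TPM"` or `"FPKM"`; downstream thresholds declare which unit
#'   they apply to.
#' @param species species tag carried for surfaceome-catalogue compatibility
#'   checks (default `"mouse"`).
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples, unit = c("TPM", "FPKM"),
                              species = "mouse") {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    sm_stop_validation("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) && nrow(values) > 0L) {
    sm_stop_validation("`values` must have gene identifiers as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    sm_stop_validation("duplicate gene_id in matrix: %s",
                       paste(dup, collapse = ", "))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    sm_stop_validation("expression values must be finite and non-negative")
  }
  samples <- validate_sample_sheet(samples)
  if (nrow(samples) != ncol(values)) {
    sm_stop_validation("sample sheet has %d rows but matrix has %d columns",
                       nrow(samples), ncol(values))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples$sample_id
  } else if (!identical(colnames(values), samples$sample_id)) {
    sm_stop_validation("matrix column names do not match sample sheet order")
  }
  structure(
    list(values = values, samples = samples, unit = unit, species = species),
    class = "ExpressionMatrix"
  )
}

GENOTYPES <- c("transgenic", "wildtype")
STAGES <- c("DN1", "DN2", "DN3", "DN4")

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "genotype", "stage", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    sm_stop_validation("sample sheet requires columns: %s",
                       paste(need, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$genotype <- as.character(samples$genotype)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    sm_stop_validation("duplicate sample_id: %s", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(samples$genotype), GENOTYPES)
  if (length(bad)) {
    sm_stop_validation("unknown genotype value(s): %s (expected %s)",
                       paste(bad, collapse = ", "),
                       paste(GENOTYPES, collapse = "/"))
  }
  bad <- setdiff(unique(samples$stage), STAGES)
  if (length(bad)) {
    sm_stop_validation("unknown stage value(s): %s (expected %s)",
                       paste(bad, collapse = ", "),
                       paste(STAGES, collapse = "/"))
  }
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L)) {
    sm_stop_validation("replicate must be a positive integer")
  }
  key <- paste(samples$genotype, samples$stage, samples$replicate)
  if (anyDuplicated(key)) {
    sm_stop_validation("duplicate (genotype, stage, replicate) triple: %s",
                       paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(samples) <- NULL
  samples
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$unit, x$species))
  tab <- table(genotype = x$samples$genotype, stage = x$samples$stage)
  print(tab)
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene identifiers
#'
#' Row order of `gene_ids` present in the matrix is kept as in the matrix
#' itself; metadata and unit are untouched.
#'
#' @param x an `ExpressionMatrix`.
#' @param gene_ids character vector of gene identifiers to keep.
#' @return an `ExpressionMatrix` restricted to the requested genes.
#' @export
subset_genes <- function(x, gene_ids) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep <- rownames(x$values) %in% gene_ids
  values <- x$values[keep, , drop = FALSE]
  expression_matrix(values, x$samples, unit = x$unit, species = x$species)
}

#' Write an ExpressionMatrix as TSV plus a JSON sidecar
#'
#' The TSV holds `gene_id` plus one column per sample; the sidecar records
#' the unit, species and the sample metadata so the matrix round-trips.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(unit = x$unit, species = x$species, samples = x$samples)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ExpressionMatrix written by [write_expression_matrix()]
#'
#' @param path TSV path with `<path>.json` sidecar alongside.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    sm_stop_validation("matrix file or sidecar missing: %s(.json)", path)
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  expression_matrix(values, as.data.frame(sidecar$samples),
                    unit = sidecar$unit, species = sidecar$species)
}

# Condition helpers: validation errors map to CLI exit code 2, runtime to 1.
sm_stop_validation <- function(fmt, ...) {
  stop(structure(
    class = c("surfmine_validation_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

sm_stop_runtime <- function(fmt, ...) {
  stop(structure(
    class = c("surfmine_runtime_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
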