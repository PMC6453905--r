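#' Surfaceome gene catalogues
#'
#' A surfaceome catalogue lists genes encoding proteins known (or presumed)
#' to reside on the cell surface or to be secreted. It defines the analysis
#' universe: expression matrices are intersected with the catalogue before
#' any screening, so every downstream hit encodes a potentially antibody-
#' accessible protein.
#'
#' @name surfaceome
NULL

SURFACEOME_CATEGORIES <- c("surface", "secreted", "presumptive_surface")

#' Load a surfaceome catalogue from TSV
#'
#' Expects a UTF-8 TSV with header `gene_id<TAB>symbol<TAB>category`, one
#' entry per line. `category` is a closed vocabulary: `surface`, `secreted`
#' or `presumptive_surface`.
#'
#' @param path path to the catalogue TSV.
#' @param species `"mouse"` or `"human"`; recorded on the catalogue and
#'   checked against matrices at filter time.
#' @return an object of class `SurfaceomeDB` with elements `entries`
#'   (data.frame gene_id/symbol/category) and `species`.
#' @export
load_surfaceome <- function(path, species = c("mouse", "human")) {
  species <- match.arg(species)
  if (!file.exists(path)) {
    sm_stop_validation("surfaceome catalogue not found: %s", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "symbol", "category")
  if (!identical(sort(names(df)), sort(need))) {
    sm_stop_validation(
      "catalogue header must be exactly {%s}; got {%s}",
      paste(need, collapse = ", "), paste(names(df), collapse = ", "))
  }
  df <- df[, need]
  surfaceome_db(df, species = species)
}

#' Construct a SurfaceomeDB from an entries data.frame
#'
#' @param entries data.frame with columns `gene_id`, `symbol`, `category`.
#' @param species `"mouse"` or `"human"`.
#' @return a `SurfaceomeDB`.
#' @export
surfaceome_db <- function(entries, species = c("mouse", "human")) {
  species <- match.arg(species)
  need <- c("gene_id", "symbol", "category")
  if (!is.data.frame(entries) || !all(need %in% names(entries))) {
    sm_stop_validation("entries require columns: %s",
                       paste(need, collapse = ", "))
  }
  entries <- as.data.frame(lapply(entries[need], as.character),
                           stringsAsFactors = FALSE)
  if (nrow(entries) > 0L && any(!nzchar(entries$gene_id))) {
    sm_stop_validation("empty gene_id in catalogue")
  }
  if (anyDuplicated(entries$gene_id)) {
    dup <- unique(entries$gene_id[duplicated(entries$gene_id)])
    sm_stop_validation("duplicate gene_id in catalogue: %s",
                       paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(entries$category), SURFACEOME_CATEGORIES)
  if (length(bad)) {
    sm_stop_validation("unknown category token(s): %s (allowed: %s)",
                       paste(bad, collapse = ", "),
                       paste(SURFACEOME_CATEGORIES, collapse = ", "))
  }
  rownames(entries) <- NULL
  structure(list(entries = entries, species = species),
            class = "SurfaceomeDB")
}

#' @export
print.SurfaceomeDB <- function(x, ...) {
  cat(sprintf("SurfaceomeDB (%s): %d entries\n", x$species,
              nrow(x$entries)))
  print(table(x$entries$category))
  invisible(x)
}

#' Restrict an expression matrix to surfaceome genes
#'
#' The database-mining subsetting step: keeps the rows of `matrix` whose
#' identifier is in the catalogue. Matching is on `gene_id` by default;
#' `by = "symbol"` matches matrix rownames against catalogue symbols after
#' uppercase normalisation (the cross-species bridge, since mouse `Cd53`
#' and human `CD53` casing conventions differ). Row order is preserved from
#' the input matrix and sample metadata is untouched.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param db a `SurfaceomeDB` of the same species as the matrix.
#' @param by match on `"gene_id"` (default) or on `"symbol"` with uppercase
#'   normalisation.
#' @return the row-subset `ExpressionMatrix`; zero overlap yields an empty
#'   matrix with a warning, not an error.
#' @export
filter_to_surfaceome <- function(matrix, db, by = c("gene_id", "symbol")) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), inherits(db, "SurfaceomeDB"))
  by <- match.arg(by)
  if (!identical(matrix$species, db$species)) {
    sm_stop_validation("species mismatch: matrix is %s, catalogue is %s",
                       matrix$species, db$species)
  }
  ids <- rownames(matrix$values)
  keep <- if (by == "gene_id") {
    ids %in% db$entries$gene_id
  } else {
    toupper(ids) %in% toupper(db$entries$symbol)
  }
  if (!any(keep) && length(ids) > 0L) {
    warning("no overlap between expression matrix and surfaceome catalogue")
  }
  expression_matrix(matrix$values[keep, , drop = FALSE], matrix$samples,
                    unit = matrix$unit, species = matrix$species)
}
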