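#' ansscore: gene signature scoring for single-cell RNA-seq
#'
#' Implements Adjusted Neighborhood Scoring (ANS) and the classic
#' control-gene-based (Tirosh-style) and rank-based (UCell, JASMINE) scoring
#' methods, score-based cell annotation, benchmark procedures, and a
#' synthetic scRNA-seq generator.
#'
#' Matrices are always oriented cells-as-rows, genes-as-columns, with unique
#' row (cell) and column (gene) names. Both base dense matrices and
#' \pkg{Matrix} sparse matrices are accepted everywhere and yield identical
#' results.
#'
#' @keywords internal
#' @aliases ansscore-package
"_PACKAGE"

#' @importFrom stats rlnorm rbinom runif sd var quantile wilcox.test p.adjust
#'   predict rnorm setNames aggregate plogis uniroot
#' @importFrom utils read.csv read.delim write.csv head tail
NULL

# Coerce any accepted matrix input (base matrix or Matrix sparse) to a dense
# base matrix. Used by per-cell rank scorers; linear operations stay sparse.
.dense <- function(x) {
  if (is.matrix(x)) x else as.matrix(x)
}

.is_matrix_like <- function(x) {
  is.matrix(x) || inherits(x, "Matrix")
}

#' Validate a cells-by-genes expression matrix
#'
#' Checks the invariants every scoring function relies on: a numeric
#' cells x genes matrix of finite, non-negative values (log-transformed
#' normalized expression) with unique, non-empty cell (row) and gene (column)
#' identifiers. Identifiers are treated as case-sensitive opaque strings;
#' no symbol aliasing is performed.
#'
#' @param x A base `matrix` or `Matrix` sparse matrix, cells as rows, genes
#'   as columns, with `dimnames`.
#' @param cell_metadata Optional `data.frame` with one row per cell
#'   (columns such as `sample_id`, `batch_id`, `label`). Row order must match
#'   the matrix rows.
#' @return `x`, invisibly unchanged (with `cell_metadata` attached as an
#'   attribute when supplied).
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2")))
#' validate_matrix(m)
#' @export
validate_matrix <- function(x, cell_metadata = NULL) {
  if (!.is_matrix_like(x)) {
    stop("expression matrix must be a base matrix or a Matrix sparse matrix")
  }
  cell_ids <- rownames(x)
  gene_ids <- colnames(x)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("expression matrix must have cell (row) and gene (column) names")
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicated cell identifier: ", cell_ids[duplicated(cell_ids)][1L])
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene identifier: ", gene_ids[duplicated(gene_ids)][1L])
  }
  vals <- if (is.matrix(x)) x else x@x
  bad <- which(!is.finite(vals) | vals < 0)
  if (length(bad)) {
    if (is.matrix(x)) {
      idx <- arrayInd(bad[1L], dim(x))
      stop(sprintf(
        "invalid expression value %g at cell '%s', gene '%s' (must be finite and >= 0)",
        x[bad[1L]], cell_ids[idx[1L]], gene_ids[idx[2L]]))
    }
    stop("invalid expression value (must be finite and >= 0) in sparse matrix")
  }
  if (!is.null(cell_metadata)) {
    if (nrow(cell_metadata) != nrow(x)) {
      stop("cell_metadata has ", nrow(cell_metadata), " rows but matrix has ",
           nrow(x), " cells")
    }
    attr(x, "cell_metadata") <- cell_metadata
  }
  invisible(x)
}

#' Construct a gene signature
#'
#' A signature is a named, ordered set of gene identifiers. Order is
#' meaningful when the signature was produced by marker ranking (most
#' important gene first).
#'
#' @param name Signature name (single string).
#' @param genes Character vector of gene identifiers, length >= 1.
#' @return An object of class `gene_signature` with fields `name`, `genes`.
#' @export
gene_signature <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (length(genes) < 1L) stop("signature '", name, "' is empty")
  if (anyDuplicated(genes)) {
    stop("signature '", name, "' contains duplicated genes: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

# Accept a gene_signature or a bare character vector (named by `name`).
.as_signature <- function(sig, name = "signature") {
  if (inherits(sig, "gene_signature")) return(sig)
  gene_signature(name, sig)
}

#' Intersect a signature with the genes of a matrix
#'
#' Genes absent from the matrix are dropped (with a warning), preserving the
#' original signature order. This mirrors the permissive behavior of the
#' standard single-cell toolkits; callers that need strictness can inspect
#' the `dropped` field.
#'
#' @param sig A `gene_signature` or character vector.
#' @param x Validated expression matrix.
#' @return List with `signature` (the restricted `gene_signature`) and
#'   `dropped` (character vector of absent genes).
#' @export
intersect_signature <- function(sig, x) {
  sig <- .as_signature(sig)
  present <- sig$genes %in% colnames(x)
  dropped <- sig$genes[!present]
  if (!any(present)) {
    stop("signature '", sig$name, "' has no genes in matrix")
  }
  if (length(dropped)) {
    warning("signature '", sig$name, "': ", length(dropped),
            " gene(s) absent from matrix: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  list(signature = gene_signature(sig$name, sig$genes[present]),
       dropped = dropped)
}
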