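#' Expression matrix container
#'
#' A lightweight container for a genes-by-samples expression matrix on the
#' log2(TPM+1) scale, together with a cohort label and a per-sample tissue
#' class (\code{"normal"} or \code{"tumor"}).
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   required and unique.
#' @param tissue_class character vector, one of \code{"normal"}/\code{"tumor"}
#'   per sample (recycled if length 1).
#' @param cohort_id single character cohort label.
#' @param log_scale logical; \code{TRUE} if values are log2(TPM+1).
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{tissue_class}, \code{cohort_id}, \code{log_scale}.
#' @export
expression_matrix <- function(values, tissue_class = "tumor",
                              cohort_id = "cohort", log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in rows")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in columns")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  tissue_class <- rep_len(as.character(tissue_class), ncol(values))
  if (!all(tissue_class %in% c("normal", "tumor")))
    stop("tissue_class entries must be 'normal' or 'tumor'")
  names(tissue_class) <- colnames(values)
  structure(
    list(values = values, tissue_class = tissue_class,
         cohort_id = as.character(cohort_id)[1], log_scale = isTRUE(log_scale)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d genes x %d samples (%d normal, %d tumor)%s\n",
              x$cohort_id, nrow(x$values), ncol(x$values),
              sum(x$tissue_class == "normal"), sum(x$tissue_class == "tumor"),
              if (x$log_scale) ", log2(TPM+1)" else ", raw"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x an \code{ExpressionMatrix}.
#' @param genes,samples character vectors of identifiers to keep (NULL keeps all).
#' @return a new \code{ExpressionMatrix}.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, x$tissue_class[colnames(v)], x$cohort_id, x$log_scale)
}

#' Combine two cohort matrices sharing a gene universe
#'
#' Binds samples column-wise on the intersection of genes; used to pool a
#' normal reference with a tumor cohort before perturbation analysis.
#'
#' @param a,b \code{ExpressionMatrix} objects with disjoint sample identifiers.
#' @param cohort_id cohort label for the combined object.
#' @return an \code{ExpressionMatrix}.
#' @export
bind_expression <- function(a, b, cohort_id = a$cohort_id) {
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  if (length(intersect(colnames(a$values), colnames(b$values))))
    stop("sample identifiers overlap between the two matrices")
  genes <- intersect(rownames(a$values), rownames(b$values))
  if (length(genes) < 2) stop("fewer than 2 shared genes")
  v <- cbind(a$values[genes, , drop = FALSE], b$values[genes, , drop = FALSE])
  expression_matrix(v, c(a$tissue_class, b$tissue_class), cohort_id,
                    a$log_scale && b$log_scale)
}

#' Per-gene z-score standardization within a cohort
#'
#' Standardizes each gene row to mean 0 and unit sample (n-1) standard
#' deviation. Cohorts are always processed independently: call once per
#' cohort object. Constant genes map to all-zero rows and are flagged in the
#' \code{constant_genes} attribute.
#'
#' @param x an \code{ExpressionMatrix} with at least 2 samples.
#' @return an \code{ExpressionMatrix} of z-scores, with attribute
#'   \code{constant_genes} (character vector) on the returned object.
#' @export
zscore <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2)
    stop("z-scaling requires >= 2 samples in the cohort")
  m <- rowMeans(x$values)
  s <- apply(x$values, 1, stats::sd)
  const <- s == 0 | !is.finite(s)
  z <- (x$values - m) / ifelse(const, 1, s)
  z[const, ] <- 0
  out <- expression_matrix(z, x$tissue_class, x$cohort_id, log_scale = FALSE)
  attr(out, "constant_genes") <- rownames(x$values)[const]
  out
}
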