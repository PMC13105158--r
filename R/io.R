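#' Read a bulk expression matrix from TSV
#'
#' Expects a tab-separated file with gene identifiers in the first column,
#' sample identifiers in the header, and a numeric body. Duplicate gene rows
#' are collapsed by per-sample maximum. Tissue classes come from a companion
#' metadata file (columns \code{sample}, \code{tissue_class}, optionally
#' \code{cohort}) or default to \code{"tumor"}.
#'
#' @param path expression TSV path.
#' @param raw_tpm if \code{TRUE} the body holds raw TPM and log2(x+1) is applied.
#' @param meta_path optional metadata TSV path.
#' @param cohort_id cohort label; overridden by a \code{cohort} metadata column.
#' @return an \code{ExpressionMatrix}.
#' @export
read_expression <- function(path, raw_tpm = FALSE, meta_path = NULL,
                            cohort_id = "cohort") {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("expression file is empty or has no sample columns: ", path)
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate sample column: ",
         colnames(df)[-1][duplicated(colnames(df)[-1])][1])
  genes <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(is.na(num) & !is.na(v)))
        stop(sprintf("non-numeric cell in column '%s', row %d",
                     colnames(body)[j], which(is.na(num) & !is.na(v))[1]))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    # collapse duplicate gene rows by per-sample maximum
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), genes), function(i) {
      apply(m[i, , drop = FALSE], 2, max)
    }))
  }
  if (raw_tpm) m <- log2(m + 1)
  tc <- rep("tumor", ncol(m))
  names(tc) <- colnames(m)
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!all(c("sample", "tissue_class") %in% colnames(meta)))
      stop("metadata file must have 'sample' and 'tissue_class' columns")
    hit <- match(colnames(m), meta$sample)
    if (anyNA(hit)) stop("metadata missing samples: ",
                         paste(colnames(m)[is.na(hit)][1:min(3, sum(is.na(hit)))],
                               collapse = ", "))
    tc[] <- meta$tissue_class[hit]
    if ("cohort" %in% colnames(meta)) cohort_id <- meta$cohort[hit][1]
  }
  expression_matrix(m, tc, cohort_id, log_scale = TRUE)
}

#' Write an expression matrix (and its metadata sidecar) to TSV
#'
#' @param x an \code{ExpressionMatrix}.
#' @param path output TSV path.
#' @param meta_path optional metadata sidecar path (sample, tissue_class, cohort).
#' @return invisibly, \code{path}.
#' @export
write_expression <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- data.frame(sample = colnames(x$values),
                       tissue_class = unname(x$tissue_class),
                       cohort = x$cohort_id)
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an interaction network edge list from TSV
#'
#' Expects two gene columns and a confidence column. STRING-style integer
#' scores in (1, 999] are divided by 1000. Edges with confidence strictly
#' below \code{min_confidence} are dropped; duplicates and self-loops are
#' removed with canonical edge ids.
#'
#' @param path edge-list TSV path.
#' @param min_confidence minimum retained confidence (default 0.8, the
#'   high-confidence STRING threshold).
#' @return an \code{InteractionNetwork}.
#' @export
read_network <- function(path, min_confidence = 0.8) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("network file needs two gene columns and a confidence column")
  conf <- as.numeric(df[[3]])
  if (anyNA(conf)) stop("non-numeric confidence values in ", path)
  if (any(conf > 1)) conf <- conf / 1000  # STRING combined scores in 0-999
  net <- interaction_network(df[[1]], df[[2]], conf)
  net[net$confidence >= min_confidence, , drop = FALSE]
}

#' Write an interaction network edge list to TSV
#' @param network an \code{InteractionNetwork}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_network <- function(network, path) {
  utils::write.table(network[, c("gene_a", "gene_b", "confidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a survival table
#'
#' A survival table is a data.frame with columns \code{sample}, \code{time}
#' (positive, consistent units within a cohort), \code{event} (0/1) and any
#' number of covariate columns (e.g. age, stage).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_survival(df)
  df
}

#' @rdname read_survival
#' @param surv a survival data.frame.
#' @export
write_survival <- function(surv, path) {
  validate_survival(surv)
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_survival <- function(surv) {
  req <- c("sample", "time", "event")
  if (!all(req %in% colnames(surv)))
    stop("survival table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(surv$sample)) stop("duplicate sample identifiers")
  if (any(surv$time <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event indicator must be 0/1")
  invisible(surv)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT path.
#' @return An object of class \code{GeneSetCollection}: a named list of
#'   character gene vectors with a \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields (name, description, >=1 gene)", i))
    nms[i] <- f[1]; desc[i] <- f[2]; sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nms)) stop("duplicate gene-set names in ", path)
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(desc, nms)
  class(sets) <- "GeneSetCollection"
  sets
}

#' @rdname read_gmt
#' @param sets a named list of gene vectors (or \code{GeneSetCollection}).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    d <- if (!is.null(desc)) desc[[names(sets)[i]]] else "na"
    paste(c(names(sets)[i], d, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Signature model constructor and plain-text round trip
#'
#' A signature is an ordered gene list with one linear coefficient per gene,
#' an optional risk cutoff, and the label of the cohort it was trained on.
#' Stored on disk as JSON.
#'
#' @param gene_ids character vector of unique genes.
#' @param coefficients numeric vector, same length as \code{gene_ids}; may be
#'   NA when only the gene list is known and coefficients must be retrained.
#' @param cutoff optional risk cutoff (NA when unset).
#' @param training_cohort cohort label.
#' @return an object of class \code{SignatureModel}.
#' @export
signature_model <- function(gene_ids, coefficients, cutoff = NA_real_,
                            training_cohort = "unspecified") {
  gene_ids <- as.character(gene_ids)
  coefficients <- as.numeric(coefficients)
  if (length(gene_ids) != length(coefficients))
    stop("gene_ids and coefficients must have equal length")
  if (anyDuplicated(gene_ids)) stop("duplicate signature genes")
  structure(list(gene_ids = gene_ids,
                 coefficients = stats::setNames(coefficients, gene_ids),
                 cutoff = as.numeric(cutoff)[1],
                 training_cohort = as.character(training_cohort)[1]),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %d genes (trained on %s)%s\n",
              length(x$gene_ids), x$training_cohort,
              if (is.na(x$cutoff)) "" else sprintf(", cutoff %.4g", x$cutoff)))
  invisible(x)
}

#' @rdname signature_model
#' @param path JSON path.
#' @export
write_signature <- function(x, path) {
  stopifnot(inherits(x, "SignatureModel"))
  jsonlite::write_json(
    list(gene_ids = x$gene_ids, coefficients = unname(x$coefficients),
         cutoff = x$cutoff, training_cohort = x$training_cohort),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname signature_model
#' @export
read_signature <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- if (is.list(j$coefficients)) {
    vapply(j$coefficients, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1))
  } else as.numeric(j$coefficients)
  signature_model(j$gene_ids, coefs,
                  cutoff = if (is.null(j$cutoff)) NA_real_ else j$cutoff,
                  training_cohort = j$training_cohort)
}
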