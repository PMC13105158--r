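#' Within-sample rank transform
#'
#' Converts expression values to relative ranks within each sample: rank 1 is
#' the lowest-expressed gene, average ranks for ties. Relative ranks are
#' robust to platform scaling and batch effects, which is why the
#' perturbation statistic works on ranks rather than absolute expression.
#'
#' Ranks are computed within whatever gene universe the matrix carries;
#' restrict to the network/cohort intersection first (see
#' \code{\link{restrict_universe}}).
#'
#' @param x an \code{ExpressionMatrix} with at least 2 genes.
#' @return numeric matrix of ranks, genes x samples, same dimnames; each
#'   column sums to G(G+1)/2.
#' @export
rank_transform <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (nrow(x$values) < 2) stop("rank transform requires >= 2 genes")
  apply(x$values, 2, rank, ties.method = "average")
}

#' Normal-reference rank benchmark
#'
#' Orders genes by their mean expression across normal reference samples;
#' the resulting integer ranks (1 = lowest mean) define the stable
#' coordination pattern that tumor samples are compared against. Ties in the
#' means are broken lexicographically by gene identifier so the reference is
#' deterministic.
#'
#' @param normals an \code{ExpressionMatrix} of normal samples (>= 2 samples).
#' @param network optional \code{InteractionNetwork}; when given, the
#'   reference is restricted to network genes present in the matrix (a
#'   message reports how many were dropped).
#' @return An object of class \code{ReferenceBenchmark}: list with
#'   \code{ref_rank} (named integer vector), \code{genes}, \code{source_cohort}.
#' @export
build_reference <- function(normals, network = NULL) {
  stopifnot(inherits(normals, "ExpressionMatrix"))
  if (ncol(normals$values) < 2) stop("reference requires >= 2 normal samples")
  genes <- rownames(normals$values)
  if (!is.null(network)) {
    ng <- network_genes(network)
    keep <- intersect(genes, ng)
    dropped <- length(ng) - length(keep)
    if (dropped > 0)
      message(sprintf("build_reference: %d network genes absent from reference, restricted", dropped))
    genes <- keep
  }
  if (length(genes) < 2) stop("fewer than 2 usable reference genes")
  m <- rowMeans(normals$values[genes, , drop = FALSE])
  ord <- order(m, genes)  # lexicographic tie-break on gene id
  ref_rank <- integer(length(genes))
  ref_rank[ord] <- seq_along(genes)
  names(ref_rank) <- genes
  structure(list(ref_rank = ref_rank, genes = genes,
                 source_cohort = normals$cohort_id),
            class = "ReferenceBenchmark")
}

#' @export
print.ReferenceBenchmark <- function(x, ...) {
  cat(sprintf("ReferenceBenchmark: %d genes ranked from cohort '%s'\n",
              length(x$genes), x$source_cohort))
  invisible(x)
}

#' Restrict a matrix and network to their common gene universe
#'
#' The analysis universe is the intersection of network genes with genes
#' present in the reference and in every analyzed cohort, so ranks are
#' comparable across cohorts. Edges falling outside are dropped with a
#' reported count.
#'
#' @param x an \code{ExpressionMatrix}.
#' @param network an \code{InteractionNetwork}.
#' @param reference optional \code{ReferenceBenchmark} whose genes also bound
#'   the universe.
#' @return list with elements \code{expr} (restricted matrix), \code{network}
#'   (restricted edges), \code{genes}.
#' @export
restrict_universe <- function(x, network, reference = NULL) {
  genes <- intersect(network_genes(network), rownames(x$values))
  if (!is.null(reference)) genes <- intersect(genes, reference$genes)
  genes <- sort(genes)
  keep <- network$gene_a %in% genes & network$gene_b %in% genes
  if (any(!keep))
    message(sprintf("restrict_universe: dropped %d edges outside the shared gene universe",
                    sum(!keep)))
  if (length(genes) < 2) stop("shared gene universe has fewer than 2 genes")
  list(expr = subset_expression(x, genes = genes),
       network = network[keep, , drop = FALSE], genes = genes)
}

#' Edge perturbation matrix
#'
#' For every network edge (i, j) and sample s, the perturbation is
#' \deqn{p_s(i,j) = [rank_s(i) - rank_s(j)] - [rank_{ref}(i) - rank_{ref}(j)],}
#' the deviation of the within-sample rank difference from the normal
#' reference rank difference. A sample whose expression ordering equals the
#' reference ordering yields an all-zero column; swapping an edge's endpoint
#' order flips the sign; entries are bounded by 2(G-1) in magnitude.
#'
#' Ranks are recomputed within the shared universe (network genes present in
#' both the reference and the cohort), not sliced from full-transcriptome
#' ranks.
#'
#' @param x an \code{ExpressionMatrix} (normal and/or tumor samples).
#' @param reference a \code{ReferenceBenchmark}.
#' @param network an \code{InteractionNetwork}.
#' @return An object of class \code{EdgePerturbationMatrix}: list with
#'   \code{values} (edges x samples numeric matrix, rownames = canonical edge
#'   ids), \code{tissue_class}, \code{edges} (the restricted network),
#'   \code{genes}.
#' @export
edge_perturbation <- function(x, reference, network) {
  stopifnot(inherits(reference, "ReferenceBenchmark"))
  u <- restrict_universe(x, network, reference)
  r <- rank_transform(u$expr)                      # genes x samples
  ref <- reference$ref_rank[rownames(r)]
  # ref ranks recomputed within the restricted universe to stay in 1..G
  ref <- rank(ref, ties.method = "first")
  ia <- match(u$network$gene_a, rownames(r))
  ib <- match(u$network$gene_b, rownames(r))
  d_s <- r[ia, , drop = FALSE] - r[ib, , drop = FALSE]
  d_ref <- ref[ia] - ref[ib]
  p <- d_s - d_ref
  rownames(p) <- u$network$edge_id
  structure(list(values = p, tissue_class = u$expr$tissue_class,
                 edges = u$network, genes = rownames(r)),
            class = "EdgePerturbationMatrix")
}

#' @export
print.EdgePerturbationMatrix <- function(x, ...) {
  cat(sprintf("EdgePerturbationMatrix: %d edges x %d samples (%d normal, %d tumor)\n",
              nrow(x$values), ncol(x$values),
              sum(x$tissue_class == "normal"), sum(x$tissue_class == "tumor")))
  invisible(x)
}

#' Write / read an edge perturbation matrix as TSV
#'
#' @param epm an \code{EdgePerturbationMatrix}.
#' @param path matrix TSV path (edge_id row key, sample columns).
#' @param meta_path optional sidecar with sample tissue classes.
#' @return invisibly, \code{path}.
#' @export
write_epm <- function(epm, path, meta_path = NULL) {
  df <- data.frame(edge_id = rownames(epm$values), epm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(
      data.frame(sample = colnames(epm$values),
                 tissue_class = unname(epm$tissue_class)),
      meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample network perturbation score
#'
#' The gene crosstalk perturbation mean on the log2 scale:
#' \code{score_s = log2(mean_e |p_s(e)| + 1)}. The +1 guards the
#' zero-perturbation case so a reference-identical sample scores exactly 0.
#'
#' @param epm an \code{EdgePerturbationMatrix} with >= 1 edge.
#' @return named numeric vector, one score per sample.
#' @export
sample_perturbation_score <- function(epm) {
  stopifnot(inherits(epm, "EdgePerturbationMatrix"))
  if (nrow(epm$values) < 1) stop("perturbation matrix has no edges")
  log2(colMeans(abs(epm$values)) + 1)
}

#' Differentially perturbed edges, tumor versus normal
#'
#' Per edge, a two-sided Wilcoxon rank-sum test compares |p_s(e)| between
#' tumor and normal samples; p-values are BH-adjusted across edges. Returns
#' every edge with its statistics, flagged by the q threshold, sorted by q
#' then effect magnitude.
#'
#' @param epm an \code{EdgePerturbationMatrix} with >= 3 samples per class.
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @return data.frame with columns \code{edge_id}, \code{gene_a},
#'   \code{gene_b}, \code{effect} (mean tumor |p| - mean normal |p|),
#'   \code{p}, \code{q}, \code{significant}.
#' @export
differential_edges <- function(epm, q_threshold = 0.05) {
  stopifnot(inherits(epm, "EdgePerturbationMatrix"))
  tum <- epm$tissue_class == "tumor"
  nor <- epm$tissue_class == "normal"
  if (sum(tum) < 3 || sum(nor) < 3)
    stop("differential edges need >= 3 samples in each tissue class")
  a <- abs(epm$values)
  p <- apply(a, 1, function(row)
    suppressWarnings(stats::wilcox.test(row[tum], row[nor])$p.value))
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  eff <- rowMeans(a[, tum, drop = FALSE]) - rowMeans(a[, nor, drop = FALSE])
  out <- data.frame(edge_id = rownames(a),
                    gene_a = epm$edges$gene_a, gene_b = epm$edges$gene_b,
                    effect = eff, p = p, q = q,
                    significant = q < q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, -abs(out$effect)), ]
}

#' Node genes of significant edges
#'
#' @param edges a data.frame as returned by \code{\link{differential_edges}}
#'   (uses rows with \code{significant == TRUE} if the column is present,
#'   otherwise all rows).
#' @return sorted, deduplicated character vector of endpoint genes.
#' @export
extract_node_genes <- function(edges) {
  if (!is.null(edges$significant)) edges <- edges[edges$significant, , drop = FALSE]
  if (nrow(edges) == 0) return(character(0))
  sort(unique(c(edges$gene_a, edges$gene_b)))
}
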