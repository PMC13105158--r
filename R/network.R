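#' Canonical edge identifier
#'
#' Undirected edges are keyed by \code{"min(a,b)|max(a,b)"} so storage is
#' order-free.
#'
#' @param a,b character vectors of gene identifiers.
#' @return character vector of canonical edge ids.
#' @export
edge_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Background interaction network
#'
#' An undirected simple graph over gene identifiers with per-edge confidence
#' scores in [0,1]. Self-loops are rejected; duplicate edges (in either gene
#' order) are collapsed keeping the maximum confidence, the STRING convention.
#'
#' @param gene_a,gene_b character vectors of endpoint genes.
#' @param confidence numeric vector of confidence scores in [0,1].
#' @return An object of class \code{InteractionNetwork}: a data.frame with
#'   columns \code{gene_a}, \code{gene_b} (lexicographically ordered within
#'   each edge), \code{confidence}, \code{edge_id}.
#' @export
interaction_network <- function(gene_a, gene_b, confidence = 1) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  confidence <- rep_len(as.numeric(confidence), length(gene_a))
  keep <- gene_a != gene_b
  gene_a <- gene_a[keep]; gene_b <- gene_b[keep]; confidence <- confidence[keep]
  if (any(confidence < 0 | confidence > 1))
    stop("confidence scores must lie in [0, 1]")
  lo <- pmin(gene_a, gene_b); hi <- pmax(gene_a, gene_b)
  id <- paste(lo, hi, sep = "|")
  # duplicate resolution: keep max confidence per canonical id
  ord <- order(id, -confidence)
  first <- !duplicated(id[ord])
  df <- data.frame(gene_a = lo[ord][first], gene_b = hi[ord][first],
                   confidence = confidence[ord][first],
                   edge_id = id[ord][first], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("InteractionNetwork", "data.frame")
  df
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  genes <- network_genes(x)
  cat(sprintf("InteractionNetwork: %d edges over %d genes (mean degree %.2f)\n",
              nrow(x), length(genes), 2 * nrow(x) / max(1L, length(genes))))
  invisible(x)
}

#' Genes appearing in a network
#' @param network an \code{InteractionNetwork}.
#' @return sorted character vector of unique endpoint genes.
#' @export
network_genes <- function(network) {
  sort(unique(c(network$gene_a, network$gene_b)))
}

#' Average node degree 2E/N
#' @param network an \code{InteractionNetwork}.
#' @return a single number.
#' @export
average_degree <- function(network) {
  2 * nrow(network) / length(network_genes(network))
}
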