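#' Single-cell QC thresholds
#'
#' Defaults are the standard droplet QC bounds used for the epithelial
#' analysis: 200-6000 detected genes, 500-40000 total counts, and at most
#' 20 percent mitochondrial counts. All bounds are inclusive.
#'
#' @param min_features,max_features bounds on detected genes per cell.
#' @param min_counts,max_counts bounds on total counts per cell.
#' @param max_percent_mt maximum mitochondrial percentage (0-100).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return a \code{QCThresholds} list.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 6000,
                          min_counts = 500, max_counts = 40000,
                          max_percent_mt = 20, mito_prefix = "MT-") {
  if (min_features >= max_features) stop("min_features must be < max_features")
  if (min_counts >= max_counts) stop("min_counts must be < max_counts")
  if (max_percent_mt < 0 || max_percent_mt > 100)
    stop("max_percent_mt must lie in [0, 100]")
  structure(list(min_features = min_features, max_features = max_features,
                 min_counts = min_counts, max_counts = max_counts,
                 max_percent_mt = max_percent_mt, mito_prefix = mito_prefix),
            class = "QCThresholds")
}

#' Filter low-quality cells
#'
#' Keeps cells with detected-gene and total-count values inside the inclusive
#' threshold bounds and mitochondrial percentage at or below the maximum.
#' The report lists every removed cell with its failure reasons.
#'
#' @param counts cells x genes matrix of nonnegative integer counts
#'   (cell rownames, gene colnames).
#' @param thresholds a \code{QCThresholds} object.
#' @return list with \code{counts} (filtered matrix) and \code{report}
#'   (data.frame: cell, n_features, n_counts, percent_mt, kept, reasons).
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  n_feat <- rowSums(counts > 0)
  n_cnt <- rowSums(counts)
  is_mt <- startsWith(colnames(counts), thresholds$mito_prefix)
  pct_mt <- 100 * rowSums(counts[, is_mt, drop = FALSE]) / pmax(n_cnt, 1)
  reasons <- vapply(seq_len(nrow(counts)), function(i) {
    r <- character(0)
    if (n_feat[i] < thresholds$min_features) r <- c(r, "min_features")
    if (n_feat[i] > thresholds$max_features) r <- c(r, "max_features")
    if (n_cnt[i] < thresholds$min_counts) r <- c(r, "min_counts")
    if (n_cnt[i] > thresholds$max_counts) r <- c(r, "max_counts")
    if (pct_mt[i] > thresholds$max_percent_mt) r <- c(r, "max_percent_mt")
    paste(r, collapse = ";")
  }, character(1))
  kept <- !nzchar(reasons)
  if (!any(kept)) stop("no cells pass QC filtering")
  report <- data.frame(cell = rownames(counts), n_features = n_feat,
                       n_counts = n_cnt, percent_mt = pct_mt, kept = kept,
                       reasons = reasons, stringsAsFactors = FALSE,
                       row.names = NULL)
  list(counts = counts[kept, , drop = FALSE], report = report)
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a total of \code{scale_factor} and applies
#' log1p, the conventional default normalization of droplet toolchains.
#'
#' @param counts QC-passed cells x genes count matrix.
#' @param scale_factor per-cell target total (default 10000).
#' @return cells x genes matrix of log-normalized expression.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("all-zero cell encountered: ",
                          rownames(counts)[tot == 0][1])
  log1p(counts / tot * scale_factor)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene, a two-sided rank-sum test between the two groups on
#' log-normalized expression. The fold change compares de-logged group means:
#' \code{log2fc = log2((mean(expm1 a) + pc) / (mean(expm1 b) + pc))} with
#' pseudocount \code{pc = 1e-9}. P-values are BH-adjusted across all tested
#' genes; rows are flagged significant at \code{|log2fc| > lfc_threshold}
#' and \code{q < q_threshold}.
#'
#' @param expr cells x genes log-normalized matrix.
#' @param group_a,group_b disjoint character vectors of cell ids (>= 3 each);
#'   \code{group_a} is the condition of interest (direction "up" means higher
#'   in \code{group_a}).
#' @param lfc_threshold log2 fold-change threshold (default 0.25).
#' @param q_threshold BH-adjusted p threshold (default 0.05).
#' @return data.frame: gene, log2fc, p, q, direction, significant; sorted by q.
#' @export
wilcoxon_de <- function(expr, group_a, group_b, lfc_threshold = 0.25,
                        q_threshold = 0.05) {
  if (length(intersect(group_a, group_b)))
    stop("cell groups must be disjoint")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs >= 3 cells")
  a <- expr[group_a, , drop = FALSE]
  b <- expr[group_b, , drop = FALSE]
  pc <- 1e-9
  lfc <- log2((colMeans(expm1(a)) + pc) / (colMeans(expm1(b)) + pc))
  p <- vapply(seq_len(ncol(expr)), function(g) {
    suppressWarnings(stats::wilcox.test(a[, g], b[, g])$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = colnames(expr), log2fc = lfc, p = p, q = q,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    significant = abs(lfc) > lfc_threshold & q < q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, -abs(out$log2fc)), ]
}

#' Bulk tumor-versus-normal differential expression
#'
#' Per gene, a two-sided rank-sum test of tumor versus normal samples on the
#' log2 expression values; the fold change is the difference of class means
#' on the log2 scale. BH adjustment across genes. Direction "up" means
#' higher in tumors.
#'
#' @param x an \code{ExpressionMatrix} with >= 3 samples in each tissue class.
#' @param lfc_threshold log2 fold-change threshold (default 0.5).
#' @param q_threshold BH-adjusted p threshold (default 0.05).
#' @return data.frame: gene, log2fc, p, q, direction, significant; sorted by q.
#' @export
bulk_de <- function(x, lfc_threshold = 0.5, q_threshold = 0.05) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tum <- x$tissue_class == "tumor"; nor <- x$tissue_class == "normal"
  if (sum(tum) < 3 || sum(nor) < 3)
    stop("bulk DE needs >= 3 samples in each tissue class")
  lfc <- rowMeans(x$values[, tum, drop = FALSE]) -
    rowMeans(x$values[, nor, drop = FALSE])
  p <- apply(x$values, 1, function(v)
    suppressWarnings(stats::wilcox.test(v[tum], v[nor])$p.value))
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(x$values), log2fc = lfc, p = p, q = q,
                    direction = ifelse(lfc >= 0, "up", "down"),
                    significant = abs(lfc) > lfc_threshold & q < q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, -abs(out$log2fc)), ]
}

#' Intersect single-cell and bulk DE results
#'
#' Returns genes significant in both analyses with concordant direction —
#' the consistently dysregulated set that seeds the interaction network.
#'
#' @param sc,bulk data.frames from \code{\link{wilcoxon_de}} /
#'   \code{\link{bulk_de}} (rows with \code{significant == TRUE} are used
#'   when the column is present).
#' @return sorted character vector of concordant genes.
#' @export
intersect_sc_bulk <- function(sc, bulk) {
  pick <- function(d) if (!is.null(d$significant)) d[d$significant, ] else d
  sc <- pick(sc); bulk <- pick(bulk)
  if (nrow(sc) == 0 || nrow(bulk) == 0) return(character(0))
  m <- merge(sc[, c("gene", "direction")], bulk[, c("gene", "direction")],
             by = "gene", suffixes = c("_sc", "_bulk"))
  sort(m$gene[m$direction_sc == m$direction_bulk])
}
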