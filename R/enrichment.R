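#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (average ties) and walked in
#' descending rank order; the enrichment score is the sum over the walk of
#' the difference between the rank-weighted in-set ECDF (weights
#' \code{rank^alpha}) and the unweighted out-of-set ECDF. With
#' \code{normalize = TRUE} the whole score matrix is min-max scaled to [0,1].
#'
#' @param x an \code{ExpressionMatrix}.
#' @param sets a \code{GeneSetCollection} (or named list of gene vectors);
#'   genes absent from the matrix are dropped per set with a warning; sets
#'   left with fewer than 2 present genes are skipped with a message; a set
#'   covering every gene is degenerate (no out-of-set ECDF) and scores 0 in
#'   every sample.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize min-max normalize the score matrix (default TRUE).
#' @return An object of class \code{SsgseaScores}: list with \code{scores}
#'   (sets x samples matrix) and \code{normalized}.
#' @export
ssgsea <- function(x, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- rownames(x$values)
  usable <- list()
  for (nm in names(sets)) {
    present <- intersect(sets[[nm]], genes)
    if (length(present) < length(sets[[nm]]))
      warning(sprintf("set '%s': %d genes absent from the matrix, dropped",
                      nm, length(sets[[nm]]) - length(present)))
    if (length(present) < 2) {
      message(sprintf("set '%s' skipped: fewer than 2 present genes", nm))
      next
    }
    usable[[nm]] <- present
  }
  if (!length(usable)) stop("no usable gene sets")
  G <- length(genes)
  ranks <- apply(x$values, 2, rank, ties.method = "average")
  scores <- matrix(NA_real_, length(usable), ncol(x$values),
                   dimnames = list(names(usable), colnames(x$values)))
  for (j in seq_len(ncol(ranks))) {
    r <- ranks[, j]
    ord <- order(r, decreasing = TRUE)   # walk from highest expression down
    r_ord <- r[ord]
    for (nm in names(usable)) {
      inset <- genes[ord] %in% usable[[nm]]
      n_out <- G - sum(inset)
      if (n_out == 0) {          # degenerate: no out-of-set genes
        scores[nm, j] <- 0
        next
      }
      w <- abs(r_ord)^alpha * inset
      ecdf_in <- cumsum(w) / sum(w)
      ecdf_out <- cumsum(!inset) / n_out
      scores[nm, j] <- sum(ecdf_in - ecdf_out)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  structure(list(scores = scores, normalized = normalize),
            class = "SsgseaScores")
}

#' @export
print.SsgseaScores <- function(x, ...) {
  cat(sprintf("SsgseaScores: %d sets x %d samples%s\n", nrow(x$scores),
              ncol(x$scores), if (x$normalized) " (min-max normalized)" else ""))
  invisible(x)
}

#' Spearman association of enrichment scores with a risk index
#'
#' Per set, Spearman correlation (tie-corrected ranks) between the set's
#' sample scores and the risk index, with BH adjustment across sets. Sets
#' with a constant score vector get NA.
#'
#' @param scores an \code{SsgseaScores}.
#' @param index named numeric vector (e.g. the perturbation-network risk
#'   score); >= 5 samples must be shared.
#' @return data.frame: set, rho, p, q; sorted by q.
#' @export
associate_scores <- function(scores, index) {
  stopifnot(inherits(scores, "SsgseaScores"))
  shared <- intersect(colnames(scores$scores), names(index))
  if (length(shared) < 5) stop("fewer than 5 shared samples")
  g <- index[shared]
  res <- t(apply(scores$scores[, shared, drop = FALSE], 1, function(v) {
    if (stats::sd(v) == 0 || stats::sd(g) == 0) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(v, g, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }))
  out <- data.frame(set = rownames(scores$scores), rho = res[, 1], p = res[, 2],
                    q = stats::p.adjust(res[, 2], method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q), ]
}

#' Compare one enrichment score between risk groups
#'
#' Two-sided rank-sum test of a score vector between the "high" and "low"
#' risk groups, with the median difference giving the direction.
#'
#' @param score named numeric vector of one set's sample scores.
#' @param groups named character vector of "high"/"low" labels (>= 3 samples
#'   per group).
#' @return list with \code{p}, \code{median_diff} (high minus low),
#'   \code{direction} ("up" = higher in the high-risk group).
#' @export
group_compare <- function(score, groups) {
  shared <- intersect(names(score), names(groups))
  hi <- score[shared][groups[shared] == "high"]
  lo <- score[shared][groups[shared] == "low"]
  if (length(hi) < 3 || length(lo) < 3)
    stop("each risk group needs >= 3 samples")
  p <- suppressWarnings(stats::wilcox.test(hi, lo)$p.value)
  md <- stats::median(hi) - stats::median(lo)
  list(p = p, median_diff = md, direction = if (md >= 0) "up" else "down")
}
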