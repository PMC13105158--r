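#' Consensus clustering of tumor samples on the edge perturbation matrix
#'
#' Monti-style consensus clustering: for each candidate k, samples are
#' repeatedly subsampled without replacement, partitioned around medoids on a
#' 1 - Spearman-correlation distance over edge features, and co-assignment
#' frequencies (normalized by co-sampling frequency) are accumulated into a
#' consensus matrix. Consensus CDFs and the relative gain in area under the
#' CDF select the cluster number: the optimal k is the last one whose
#' successor adds less than \code{elbow_threshold} relative area. Final
#' labels come from average-linkage hierarchical clustering of
#' 1 - consensus.
#'
#' @param epm an \code{EdgePerturbationMatrix}; by default only tumor samples
#'   are clustered.
#' @param k_range candidate cluster numbers (default 2:6); bounded by n/3.
#' @param n_resamples subsampling iterations per k (default 200).
#' @param subsample_frac fraction of samples per resample (default 0.8).
#' @param elbow_threshold relative delta-area gain below which adding a
#'   cluster is considered uninformative (default 0.1).
#' @param top_edges optionally restrict to the N most variable edges
#'   (default NULL = all edges).
#' @param samples optional character vector of sample ids to cluster
#'   (default: tumor samples).
#' @param seed integer seed.
#' @return An object of class \code{ConsensusResult}: list with
#'   \code{k_range}, \code{consensus} (list of sample x sample matrices),
#'   \code{cdf} (list of functions), \code{area}, \code{delta_area},
#'   \code{optimal_k}, \code{labels} (list of named integer vectors, one per
#'   k).
#' @export
consensus_cluster <- function(epm, k_range = 2:6, n_resamples = 200,
                              subsample_frac = 0.8, elbow_threshold = 0.1,
                              top_edges = NULL, samples = NULL, seed = 17) {
  stopifnot(inherits(epm, "EdgePerturbationMatrix"))
  if (is.null(samples)) {
    samples <- colnames(epm$values)[epm$tissue_class == "tumor"]
    if (!length(samples)) samples <- colnames(epm$values)
  }
  m <- epm$values[, samples, drop = FALSE]
  n <- ncol(m)
  if (any(k_range < 2) || max(k_range) > n / 3)
    stop("k_range must lie within [2, n_samples/3]")
  if (!is.null(top_edges) && top_edges < nrow(m)) {
    v <- apply(m, 1, stats::var)
    m <- m[order(v, decreasing = TRUE)[seq_len(top_edges)], , drop = FALSE]
  }
  set.seed(seed)
  # Spearman correlation distance between sample columns over edge features
  rk <- apply(m, 2, rank)
  d_full <- as.matrix(1 - stats::cor(rk))
  n_sub <- max(2, round(subsample_frac * n))

  consensus <- list(); labels <- list()
  for (k in k_range) {
    co <- matrix(0, n, n); tog <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, n_sub))
      cl <- cluster::pam(stats::as.dist(d_full[idx, idx]), k = k,
                         cluster.only = TRUE, pamonce = 5)
      tog[idx, idx] <- tog[idx, idx] + 1
      same <- outer(cl, cl, "==")
      co[idx, idx] <- co[idx, idx] + same
    }
    cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(samples, samples)
    consensus[[as.character(k)]] <- cons
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    labels[[as.character(k)]] <- stats::setNames(stats::cutree(hc, k = k),
                                                 samples)
  }

  # CDFs over the upper-triangle consensus entries and area under each CDF
  upper <- function(cm) cm[upper.tri(cm)]
  cdf <- lapply(consensus, function(cm) stats::ecdf(upper(cm)))
  area <- vapply(consensus, function(cm) {
    x <- sort(upper(cm))
    f <- stats::ecdf(x)
    grid <- seq(0, 1, length.out = 201)
    sum(f(grid[-length(grid)]) * diff(grid))
  }, numeric(1))
  delta_area <- numeric(length(k_range))
  delta_area[1] <- area[1]
  if (length(k_range) > 1)
    delta_area[-1] <- diff(area) / utils::head(area, -1)
  delta_area <- pmax(delta_area, 0)
  names(delta_area) <- names(area)

  # optimal k: the last k whose successor's relative gain is below threshold;
  # i.e. the smallest k in range such that all later gains are uninformative
  optimal_k <- max(k_range)
  for (i in seq_along(k_range)) {
    if (i < length(k_range) && all(delta_area[(i + 1):length(k_range)] <
                                   elbow_threshold)) {
      optimal_k <- k_range[i]
      break
    }
  }
  structure(list(k_range = k_range, consensus = consensus, cdf = cdf,
                 area = area, delta_area = delta_area, optimal_k = optimal_k,
                 labels = labels),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: k in {%s}, optimal k = %d\n",
              paste(x$k_range, collapse = ","), x$optimal_k))
  invisible(x)
}

#' K-group log-rank test of survival by cluster label
#'
#' Standard log-rank chi-square test across the label groups, with the
#' hypergeometric variance handling of tied event times.
#'
#' @param surv a survival data.frame (columns sample, time, event).
#' @param labels named vector of group labels covering the survival samples.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
logrank_by_label <- function(surv, labels) {
  validate_survival(surv)
  lab <- labels[surv$sample]
  if (anyNA(lab)) stop("labels missing for some survival samples")
  if (length(unique(lab)) < 2) stop("need >= 2 label groups")
  tab <- table(lab, surv$event)
  if (any(rowSums(tab) == 0)) stop("empty label group")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ factor(lab))
  df <- length(unique(lab)) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length (matched by names when both are
#'   named).
#' @return a single number in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b), !anyNA(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
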