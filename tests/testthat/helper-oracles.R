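# Independent brute-force oracles used to validate the package implementations.
# Each is written as directly as possible from the defining formula and stays
# independent of the code path it checks.

# BH adjustment: sort ascending, q_i = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- cummin(rev(p[ord] * m / seq_len(m)))
  q <- numeric(m)
  q[ord] <- rev(q_sorted)
  pmin(q, 1)
}

# Harrell C by O(n^2) enumeration of ordered pairs
harrell_oracle <- function(scores, time, event) {
  conc <- 0; usable <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # i must have the earlier observed event; ties in time with a censored j
    # are usable (j outlived i)
    ok <- (event[i] == 1) && (time[i] < time[j] ||
                                (time[i] == time[j] && event[j] == 0))
    if (!ok) next
    usable <- usable + 1
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] == scores[j]) conc <- conc + 0.5
  }
  conc / usable
}

# k-group log-rank chi-square via the risk-table loop with hypergeometric
# variance at each distinct event time
logrank_oracle <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_g <- tabulate(group[at_risk], k)
    d_g <- tabulate(group[time == t & event == 1], k)
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      mult <- d_t * (n_t - d_t) / (n_t - 1)
      for (a in seq_len(k)) for (b in seq_len(k)) {
        V[a, b] <- V[a, b] +
          mult * (n_g[a] / n_t) * ((a == b) - n_g[b] / n_t)
      }
    }
  }
  u <- (O - E)[-k]
  chisq <- drop(t(u) %*% solve(V[-k, -k]) %*% u)
  list(chisq = chisq, df = k - 1,
       p = pchisq(chisq, k - 1, lower.tail = FALSE))
}

# edge perturbation by naive double loop over edges and samples
epm_oracle <- function(values, ref_rank, edges_a, edges_b) {
  out <- matrix(NA_real_, length(edges_a), ncol(values))
  for (s in seq_len(ncol(values))) {
    r <- rank(values[, s], ties.method = "average")
    names(r) <- rownames(values)
    for (e in seq_along(edges_a)) {
      d_s <- r[edges_a[e]] - r[edges_b[e]]
      d_ref <- ref_rank[edges_a[e]] - ref_rank[edges_b[e]]
      out[e, s] <- d_s - d_ref
    }
  }
  out
}

# ssGSEA walk for one sample: explicit loop over descending-rank positions
ssgsea_oracle_sample <- function(expr_values, set_genes, alpha) {
  genes <- names(expr_values)
  r <- rank(expr_values, ties.method = "average")
  ord <- names(sort(r, decreasing = TRUE))
  inset <- ord %in% set_genes
  denom_in <- sum(r[ord][inset]^alpha)
  n_out <- sum(!inset)
  score <- 0; cum_in <- 0; cum_out <- 0
  for (i in seq_along(ord)) {
    if (inset[i]) cum_in <- cum_in + r[ord[i]]^alpha else cum_out <- cum_out + 1
    score <- score + (cum_in / denom_in - cum_out / n_out)
  }
  unname(score)
}

# rank-based AUROC of a score that should be LOW for positives (p-values)
auroc_lowscore <- function(p, positive) {
  r <- rank(p)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[!positive]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

# small deterministic survival fixture with mixed censoring
mixed_surv_fixture <- function() {
  data.frame(sample = paste0("S", 1:8),
             time = c(2, 5, 5, 7, 8, 8, 11, 14),
             event = c(1, 1, 0, 1, 0, 1, 1, 0),
             stringsAsFactors = FALSE)
}
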