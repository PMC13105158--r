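#' Simulation configuration
#'
#' Bundles the parameters of the synthetic cohort generator. Defaults define
#' the package's reference study conditions: two tumor cohorts of 50 samples
#' each plus 50 matched normals, a 200-gene / 600-edge background network,
#' 10% of edges sampled as perturbation anchors, a rank-shift magnitude of 3
#' (about 60 rank positions at the default gene spacing), three planted
#' perturbation subtypes, a log-hazard of 1.5 per standard deviation of
#' perturbation burden, and 30% censoring.
#'
#' @param n_genes number of genes in the universe.
#' @param n_edges number of background network edges.
#' @param n_normal normal samples per cohort (also the reference cohort size).
#' @param n_tumor tumor samples per cohort.
#' @param n_cohorts number of independent tumor cohorts.
#' @param frac_perturbed_edges fraction of edges sampled as perturbation
#'   anchors, in [0,1].
#' @param perturb_shift latent-mean shift applied to one endpoint of each
#'   anchor edge (rank-coordination disruption magnitude; >= 0).
#' @param hazard_beta log-hazard per standard deviation of perturbation burden.
#' @param censor_rate target fraction of censored tumor samples, in [0,1].
#' @param n_subtypes number of planted perturbation subtypes (>= 1).
#' @param sigma standard deviation of the i.i.d. expression noise.
#' @param n_prognostic number of burden-coupled prognostic genes (their shift
#'   scales with the per-sample severity factor, in a common direction).
#' @param seed integer seed; identical seed + config gives bit-identical output.
#' @return a \code{SimulationConfig} list.
#' @export
simulation_config <- function(n_genes = 200, n_edges = 600, n_normal = 50,
                              n_tumor = 50, n_cohorts = 2,
                              frac_perturbed_edges = 0.1, perturb_shift = 3,
                              hazard_beta = 1.5, censor_rate = 0.3,
                              n_subtypes = 3, sigma = 1, n_prognostic = 10,
                              seed = 17) {
  cfg <- list(n_genes = n_genes, n_edges = n_edges, n_normal = n_normal,
              n_tumor = n_tumor, n_cohorts = n_cohorts,
              frac_perturbed_edges = frac_perturbed_edges,
              perturb_shift = perturb_shift, hazard_beta = hazard_beta,
              censor_rate = censor_rate, n_subtypes = n_subtypes,
              sigma = sigma, n_prognostic = n_prognostic, seed = seed)
  counts <- c("n_genes", "n_edges", "n_normal", "n_tumor", "n_cohorts",
              "n_subtypes")
  for (f in counts)
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop(sprintf("%s must be a count >= 1", f))
  if (cfg$frac_perturbed_edges < 0 || cfg$frac_perturbed_edges > 1)
    stop("frac_perturbed_edges must lie in [0, 1]")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    stop("censor_rate must lie in [0, 1]")
  if (cfg$perturb_shift < 0) stop("perturb_shift must be >= 0")
  if (cfg$sigma <= 0) stop("sigma must be > 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Random background interaction network
#'
#' Draws a simple undirected graph (no self-loops, no duplicate edges in
#' either gene order) uniformly over gene pairs, with confidence scores in
#' [0.8, 1], emulating a high-confidence interaction prior.
#'
#' @param n_genes number of genes (ids \code{G0001}, ...).
#' @param n_edges number of edges; must not exceed n_genes(n_genes-1)/2.
#' @param seed integer seed.
#' @return an \code{InteractionNetwork}.
#' @export
make_toy_network <- function(n_genes, n_edges, seed = 17) {
  max_edges <- n_genes * (n_genes - 1) / 2
  if (n_edges > max_edges)
    stop(sprintf("n_edges = %d exceeds the %d pairs available on %d genes",
                 n_edges, max_edges, n_genes))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  pair_index <- function(i, j) {      # linear upper-triangle index, i < j
    (j - 1) * (j - 2) / 2 + i
  }
  # when feasible, cover every gene first (a node list implies no isolates):
  # chain consecutive genes of a random permutation into ceiling(n/2) edges
  cover <- integer(0)
  n_cover <- ceiling(n_genes / 2)
  if (n_edges >= n_cover && n_genes >= 2) {
    perm <- sample.int(n_genes)
    a <- perm[seq(1, n_genes - 1, by = 2)]
    b <- perm[seq(2, n_genes, by = 2)]
    if (n_genes %% 2 == 1) { a <- c(a, perm[n_genes]); b <- c(b, perm[1]) }
    cover <- pair_index(pmin(a, b), pmax(a, b))
  }
  pool <- setdiff(seq_len(max_edges), cover)
  idx <- c(cover, pool[sample.int(length(pool), n_edges - length(cover))])
  # map linear upper-triangle index (column-major, i < j) to (i, j)
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  j <- j - (idx <= (j - 1) * (j - 2) / 2)   # guard float error at boundaries
  j <- j + (idx > j * (j - 1) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  conf <- stats::runif(n_edges, 0.8, 1.0)
  interaction_network(genes[i], genes[j], conf)
}

#' Simulate bulk cohorts with planted edge perturbations and survival
#'
#' The latent model: gene g has mean \eqn{\mu_g} from a fixed decreasing
#' sequence; a sample's value is \eqn{\mu_g + N(0, \sigma^2)}, so the normal
#' rank ordering is stable in expectation. Tumor samples receive two kinds of
#' latent shifts: (i) subtype shifts — for each anchor edge one endpoint is
#' moved by \code{perturb_shift} with a subtype-specific sign, giving the
#' subtypes recoverable structure; (ii) prognostic shifts — a small set of
#' genes is moved by \code{perturb_shift} times a per-sample severity factor
#' (Uniform(0.5, 1.5)) in a gene-fixed direction. Every network edge incident
#' to a shifted gene is thereby perturbed; the truth records that full set.
#' Survival times are exponential with hazard proportional to
#' \code{exp(hazard_beta * standardized severity)}; censoring times are
#' uniform on (0, tau) with tau calibrated to the target censor rate.
#'
#' @param config a \code{SimulationConfig}.
#' @param network an \code{InteractionNetwork} over the config's gene universe.
#' @return list with \code{reference} (normal \code{ExpressionMatrix}),
#'   \code{cohorts} (list of per-cohort \code{ExpressionMatrix}, each holding
#'   its tumors plus matched normals), \code{survival} (data.frame over all
#'   tumor samples with a \code{cohort} column), and \code{truth} (list:
#'   \code{anchor_edge_ids}, \code{perturbed_edge_ids}, \code{moved_genes},
#'   \code{prognostic_genes}, \code{prognostic_direction}, \code{subtype},
#'   \code{burden}).
#' @export
simulate_bulk <- function(config, network) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(network, "InteractionNetwork"))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  if (!all(network_genes(network) %in% genes))
    stop("network genes must lie inside the simulated gene universe")
  set.seed(config$seed)
  mu <- stats::setNames(seq(12, 2, length.out = config$n_genes), genes)

  # --- plant anchors: one moved endpoint per anchor edge, endpoints distinct
  n_anchor <- round(config$frac_perturbed_edges * nrow(network))
  ord <- sample.int(nrow(network))
  moved <- character(0); anchors <- integer(0)
  for (e in ord) {
    if (length(anchors) >= n_anchor) break
    cand <- setdiff(c(network$gene_a[e], network$gene_b[e]), moved)
    if (length(cand)) {
      moved <- c(moved, sample(cand, 1))
      anchors <- c(anchors, e)
    }
  }
  if (length(anchors) < n_anchor)
    warning("could not place all anchors on distinct genes; planted ",
            length(anchors))
  anchor_ids <- network$edge_id[anchors]
  # subtype-specific sign per moved gene
  signs <- matrix(sample(c(-1, 1), length(moved) * config$n_subtypes,
                         replace = TRUE),
                  nrow = length(moved), ncol = config$n_subtypes,
                  dimnames = list(moved, NULL))

  # --- prognostic genes: burden-coupled, common direction, not already moved
  free <- setdiff(genes, moved)
  prog <- sample(free, min(config$n_prognostic, length(free)))
  prog_dir <- stats::setNames(sample(c(-1, 1), length(prog), replace = TRUE),
                              prog)

  shifted <- c(moved, prog)
  perturbed_ids <- network$edge_id[network$gene_a %in% shifted |
                                     network$gene_b %in% shifted]

  draw_cohort <- function(cid) {
    n_t <- config$n_tumor; n_n <- config$n_normal
    subtype <- sample(rep_len(seq_len(config$n_subtypes), n_t))
    severity <- stats::runif(n_t, 0.5, 1.5)
    lat <- matrix(mu, nrow = config$n_genes, ncol = n_t + n_n,
                  dimnames = list(genes, c(sprintf("%s_T%03d", cid, seq_len(n_t)),
                                           sprintf("%s_N%03d", cid, seq_len(n_n)))))
    for (s in seq_len(n_t)) {
      lat[moved, s] <- lat[moved, s] +
        config$perturb_shift * signs[, subtype[s]]
      lat[prog, s] <- lat[prog, s] +
        config$perturb_shift * severity[s] * prog_dir
    }
    vals <- lat + matrix(stats::rnorm(length(lat), 0, config$sigma),
                         nrow = nrow(lat))
    vals <- pmax(vals, 0)  # log2(TPM+1) scale is nonnegative
    expr <- expression_matrix(vals, c(rep("tumor", n_t), rep("normal", n_n)),
                              cohort_id = cid)
    list(expr = expr, subtype = stats::setNames(subtype, colnames(vals)[seq_len(n_t)]),
         severity = stats::setNames(severity, colnames(vals)[seq_len(n_t)]))
  }

  cohorts <- list(); subtype <- integer(0); burden <- numeric(0)
  surv_rows <- list()
  for (k in seq_len(config$n_cohorts)) {
    cid <- sprintf("C%d", k)
    ch <- draw_cohort(cid)
    cohorts[[cid]] <- ch$expr
    subtype <- c(subtype, ch$subtype)
    burden <- c(burden, ch$severity)
    # survival for tumor samples: exponential hazard in standardized severity
    z <- if (stats::sd(ch$severity) > 0)
      (ch$severity - mean(ch$severity)) / stats::sd(ch$severity) else
        rep(0, length(ch$severity))
    rate <- 0.02 * exp(config$hazard_beta * z)
    t_event <- stats::rexp(length(rate), rate)
    u <- stats::runif(length(rate))
    cens_frac <- function(tau) mean(u * tau < t_event)
    if (config$censor_rate == 0) {
      time <- t_event; event <- rep(1L, length(rate))
    } else {
      # bisection on tau for the realized censor fraction
      lo <- 1e-6; hi <- max(t_event) * 2
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (cens_frac(mid) > config$censor_rate) lo <- mid else hi <- mid
      }
      cens <- u * ((lo + hi) / 2)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    }
    surv_rows[[cid]] <- data.frame(
      sample = names(ch$severity), time = pmax(time, 1e-6), event = event,
      age = round(stats::rnorm(length(rate), 60, 8)),
      stage = sample(1:3, length(rate), replace = TRUE),
      cohort = cid, stringsAsFactors = FALSE)
  }
  # independent normal reference cohort
  ref_vals <- matrix(mu, nrow = config$n_genes, ncol = config$n_normal,
                     dimnames = list(genes, sprintf("REF_N%03d", seq_len(config$n_normal)))) +
    matrix(stats::rnorm(config$n_genes * config$n_normal, 0, config$sigma),
           nrow = config$n_genes)
  ref_vals <- pmax(ref_vals, 0)
  reference <- expression_matrix(ref_vals, "normal", cohort_id = "REF")

  survival <- do.call(rbind, surv_rows)
  rownames(survival) <- NULL
  list(reference = reference, cohorts = cohorts, survival = survival,
       truth = list(anchor_edge_ids = anchor_ids,
                    perturbed_edge_ids = perturbed_ids,
                    moved_genes = moved,
                    prognostic_genes = prog, prognostic_direction = prog_dir,
                    subtype = subtype, burden = burden))
}

#' Simulate a toy single-cell count matrix with planted markers
#'
#' Negative-binomial counts over three clusters (\code{malignant},
#' \code{benign}, \code{other}). Genes named with the mitochondrial prefix
#' contribute a per-cell mito fraction; planted DEGs receive the given
#' log2 fold change in malignant cells (alternating sign). A fraction of
#' cells is modified to violate QC bounds (low features, low counts, high
#' counts, high mito) so filters are exercised; the truth lists them.
#'
#' @param config a \code{SimulationConfig} (used for the seed).
#' @param planted_deg_ids character vector of genes to perturb between the
#'   malignant and benign clusters (subset of the generated gene names; pass
#'   e.g. \code{sprintf("GENE%04d", 1:50)}).
#' @param n_genes single-cell gene universe size (default 1000).
#' @param n_cells_per_cluster cells in each epithelial cluster (default 500).
#' @param n_other cells in the background cluster (default 100).
#' @param lfc planted log2 fold change magnitude (default 2).
#' @param mito_prefix prefix of mitochondrial gene names (default "MT-").
#' @param n_mito number of mitochondrial genes (default 50).
#' @param frac_violators fraction of cells converted to QC violators
#'   (default 0.1, split across violation types).
#' @return list with \code{counts} (cells x genes integer matrix),
#'   \code{metadata} (data.frame: cell, cluster), and \code{truth} (list:
#'   \code{planted_deg_ids}, \code{planted_lfc} (signed, named),
#'   \code{violators} (named character vector cell -> reason)).
#' @export
simulate_single_cell <- function(config, planted_deg_ids = character(0),
                                 n_genes = 1000, n_cells_per_cluster = 500,
                                 n_other = 100, lfc = 2, mito_prefix = "MT-",
                                 n_mito = 50, frac_violators = 0.1) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  n_reg <- n_genes - n_mito
  genes <- c(sprintf("GENE%04d", seq_len(n_reg)),
             sprintf("%sG%02d", mito_prefix, seq_len(n_mito)))
  if (!all(planted_deg_ids %in% genes))
    stop("planted_deg_ids must be a subset of the generated gene universe")
  if (any(startsWith(planted_deg_ids, mito_prefix)))
    stop("planted DEGs must not be mitochondrial")

  # base means: lognormal, scaled so the expected library is ~3000 counts,
  # with ~8% of it mitochondrial
  base <- exp(stats::rnorm(n_genes, 0, 1))
  is_mt <- startsWith(genes, mito_prefix)
  base[!is_mt] <- base[!is_mt] / sum(base[!is_mt]) * 2760
  base[is_mt] <- base[is_mt] / sum(base[is_mt]) * 240
  names(base) <- genes

  n_cells <- 2 * n_cells_per_cluster + n_other
  cluster <- c(rep("malignant", n_cells_per_cluster),
               rep("benign", n_cells_per_cluster), rep("other", n_other))
  cells <- sprintf("CELL%05d", seq_len(n_cells))

  planted_lfc <- stats::setNames(
    lfc * rep_len(c(1, -1), length(planted_deg_ids)), planted_deg_ids)

  counts <- matrix(0L, nrow = n_cells, ncol = n_genes,
                   dimnames = list(cells, genes))
  for (cl in unique(cluster)) {
    m <- base
    if (cl == "malignant" && length(planted_deg_ids))
      m[planted_deg_ids] <- m[planted_deg_ids] * 2^planted_lfc
    rows <- which(cluster == cl)
    counts[rows, ] <- matrix(
      stats::rnbinom(length(rows) * n_genes, mu = rep(m, each = length(rows)),
                     size = 2),
      nrow = length(rows))
  }

  # plant QC violators
  n_viol <- round(frac_violators * n_cells)
  viol_cells <- sample(cells, n_viol)
  types <- rep_len(c("low_features", "low_counts", "high_counts", "high_mito"),
                   n_viol)
  for (i in seq_len(n_viol)) {
    r <- viol_cells[i]
    row <- counts[r, ]
    switch(types[i],
      low_features = {        # keep only 150 genes detected
        keep <- sample(which(row > 0), min(150, sum(row > 0)))
        row[-keep] <- 0L
        row[keep] <- pmax(row[keep], 1L) * 5L  # keep totals >= 500
      },
      low_counts = {          # downsample the library to ~300 counts
        row <- as.integer(stats::rbinom(n_genes, row,
                                        min(1, 300 / max(1, sum(row)))))
        # ensure features stay above the floor
        if (sum(row > 0) < 250) {
          add <- sample(which(row == 0), 250 - sum(row > 0))
          row[add] <- 1L
        }
      },
      high_counts = row <- row * 20L,
      high_mito = row[is_mt] <- row[is_mt] * 30L)
    counts[r, ] <- row
  }
  list(counts = counts,
       metadata = data.frame(cell = cells, cluster = cluster,
                             stringsAsFactors = FALSE),
       truth = list(planted_deg_ids = planted_deg_ids,
                    planted_lfc = planted_lfc,
                    violators = stats::setNames(types, viol_cells)))
}

#' Simulate a z-scaled cohort with gene-level hazard effects
#'
#' A direct generator for survival-model testing: independent standard
#' normal expression for \code{n_genes} genes, with survival hazard
#' \code{exp(sum(beta_g * x_g))} over the named \code{betas}. Used to test
#' coefficient recovery of the signature fitters.
#'
#' @param n_samples number of samples.
#' @param n_genes total genes (the first \code{length(betas)} carry effects).
#' @param betas named numeric vector of log-hazard coefficients; names must
#'   be gene ids of the form \code{G0001}, ... (or will be assigned).
#' @param censor_rate target censor fraction.
#' @param seed integer seed.
#' @param cohort_id cohort label.
#' @return list with \code{expr} (an \code{ExpressionMatrix} of z-scale
#'   values), \code{survival} (data.frame), \code{betas} (the planted vector,
#'   named over all genes with zeros elsewhere).
#' @export
simulate_prognostic <- function(n_samples, n_genes, betas,
                                censor_rate = 0.3, seed = 17,
                                cohort_id = "SIM") {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(names(betas))) names(betas) <- genes[seq_along(betas)]
  if (!all(names(betas) %in% genes)) stop("beta names outside gene universe")
  full_beta <- stats::setNames(numeric(n_genes), genes)
  full_beta[names(betas)] <- betas
  x <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(genes, sprintf("%s_S%04d", cohort_id,
                                             seq_len(n_samples))))
  lp <- drop(crossprod(x, full_beta))
  rate <- 0.02 * exp(lp)
  t_event <- stats::rexp(n_samples, rate)
  u <- stats::runif(n_samples)
  if (censor_rate == 0) {
    time <- t_event; event <- rep(1L, n_samples)
  } else {
    lo <- 1e-6; hi <- max(t_event) * 2
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (mean(u * mid < t_event) > censor_rate) lo <- mid else hi <- mid
    }
    cens <- u * ((lo + hi) / 2)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  }
  expr <- expression_matrix(x, "tumor", cohort_id, log_scale = FALSE)
  list(expr = expr,
       survival = data.frame(sample = colnames(x), time = pmax(time, 1e-6),
                             event = event, stringsAsFactors = FALSE),
       betas = full_beta)
}
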