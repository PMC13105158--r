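#' Univariate Cox screening of genes
#'
#' Fits one proportional-hazards model per gene (partial likelihood, Efron
#' tie handling) on z-scaled expression and reports the Wald p-value and the
#' coefficient sign. Genes whose fit fails to converge are flagged and
#' assigned p = 1.
#'
#' @param x an \code{ExpressionMatrix}, typically z-scaled.
#' @param surv survival data.frame (sample, time, event) covering the matrix
#'   samples; requires >= 10 events.
#' @param genes optional subset of genes to screen (default: all rows).
#' @return data.frame: gene, coef, hr, p, direction ("risk" for positive
#'   coefficients, "protective" otherwise), converged.
#' @export
univariate_cox_screen <- function(x, surv, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  validate_survival(surv)
  keep <- intersect(colnames(x$values), surv$sample)
  if (length(keep) < 10) stop("fewer than 10 samples shared with survival table")
  surv <- surv[match(keep, surv$sample), ]
  if (sum(surv$event) < 10) stop("univariate screening requires >= 10 events")
  if (is.null(genes)) genes <- rownames(x$values)
  v <- x$values[genes, keep, drop = FALSE]
  y <- survival::Surv(surv$time, surv$event)
  out <- lapply(genes, function(g) {
    fit <- tryCatch(
      survival::coxph(y ~ v[g, ], ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      data.frame(gene = g, coef = 0, hr = 1, p = 1, direction = "none",
                 converged = FALSE, stringsAsFactors = FALSE)
    } else {
      s <- summary(fit)
      data.frame(gene = g, coef = unname(stats::coef(fit)),
                 hr = unname(exp(stats::coef(fit))),
                 p = unname(s$coefficients[1, "Pr(>|z|)"]),
                 direction = if (stats::coef(fit) > 0) "risk" else "protective",
                 converged = TRUE, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher meta-p combination across cohorts
#'
#' Combines per-cohort univariate Cox p-values per gene with Fisher's method
#' (X = -2 sum(log p) ~ chi-square with 2k df) and keeps genes with meta-p
#' below the threshold whose coefficient directions agree in every cohort.
#' Zero p-values are clamped to 1e-300 with a warning.
#'
#' @param screens list of data.frames from \code{\link{univariate_cox_screen}},
#'   one per cohort (>= 2 cohorts).
#' @param p_threshold meta-p significance threshold (default 0.05).
#' @param require_concordance require identical coefficient direction across
#'   cohorts (default TRUE).
#' @return data.frame: gene, meta_p, concordant, kept, plus per-cohort p and
#'   direction columns.
#' @export
meta_p <- function(screens, p_threshold = 0.05, require_concordance = TRUE) {
  if (length(screens) < 2) stop("meta-p needs >= 2 cohorts")
  genes <- Reduce(intersect, lapply(screens, function(s) s$gene))
  if (!length(genes)) stop("no shared genes across cohorts")
  pm <- vapply(screens, function(s) s$p[match(genes, s$gene)],
               numeric(length(genes)))
  dm <- vapply(screens, function(s) s$direction[match(genes, s$gene)],
               character(length(genes)))
  if (length(genes) == 1) {
    pm <- matrix(pm, nrow = 1); dm <- matrix(dm, nrow = 1)
  }
  if (any(pm == 0)) {
    warning("p = 0 inputs clamped to 1e-300")
    pm[pm == 0] <- 1e-300
  }
  stat <- -2 * rowSums(log(pm))
  mp <- stats::pchisq(stat, df = 2 * ncol(pm), lower.tail = FALSE)
  concord <- apply(dm, 1, function(d) length(unique(d)) == 1 & !any(d == "none"))
  kept <- mp < p_threshold & (concord | !require_concordance)
  out <- data.frame(gene = genes, meta_p = mp, concordant = concord,
                    kept = kept, stringsAsFactors = FALSE)
  for (k in seq_along(screens)) {
    out[[paste0("p_", k)]] <- pm[, k]
    out[[paste0("direction_", k)]] <- dm[, k]
  }
  rownames(out) <- NULL
  out[order(out$meta_p), ]
}

# ---------------------------------------------------------------------------
# internal: survival design matrices

surv_design <- function(x, surv, genes) {
  keep <- intersect(colnames(x$values), surv$sample)
  surv <- surv[match(keep, surv$sample), ]
  list(X = t(x$values[genes, keep, drop = FALSE]),
       y = survival::Surv(surv$time, surv$event), surv = surv)
}

# ---------------------------------------------------------------------------
# feature selectors: each takes (X, y, seed) and returns a gene subset

select_stepwise <- function(X, y, seed = 17) {
  df <- data.frame(X, check.names = FALSE)
  null_fit <- survival::coxph(y ~ 1, data = df)
  scope <- stats::as.formula(
    paste("~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- tryCatch(
    stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                direction = "both", trace = 0),
    error = function(e) NULL)
  if (is.null(fit)) return(character(0))
  gsub("`", "", names(stats::coef(fit)))
}

select_lasso <- function(X, y, seed = 17) {
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1, nfolds = 5)
  b <- as.matrix(stats::coef(cv, s = "lambda.min"))
  rownames(b)[b[, 1] != 0]
}

select_rsf <- function(X, y, seed = 17, top_m = 20) {
  df <- data.frame(time = y[, "time"], event = y[, "status"], X,
                   check.names = FALSE)
  fit <- ranger::ranger(survival::Surv(time, event) ~ ., data = df,
                        num.trees = 300, importance = "permutation",
                        seed = seed)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  names(imp)[seq_len(min(top_m, sum(imp > 0)))]
}

# componentwise likelihood boosting for the Cox model: at each step the
# single covariate giving the largest penalized score improvement gets a
# small coefficient update (offset-based univariate Newton step)
select_coxboost <- function(X, y, seed = 17, steps = 100, nu = 0.1) {
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  offset <- rep(0, nrow(X))
  for (s in seq_len(steps)) {
    sc <- cox_score_info(X, y, offset)
    gain <- sc$score^2 / pmax(sc$info, 1e-12)
    j <- which.max(gain)
    if (gain[j] <= 1e-10) break
    delta <- nu * sc$score[j] / sc$info[j]
    beta[j] <- beta[j] + delta
    offset <- offset + X[, j] * delta
  }
  names(beta)[abs(beta) > 1e-8]
}

# score and information of each covariate at the current offset (Breslow)
cox_score_info <- function(X, y, offset) {
  time <- y[, "time"]; status <- y[, "status"]
  ord <- order(time)
  X <- X[ord, , drop = FALSE]; status <- status[ord]
  w <- exp(offset[ord])
  n <- length(w)
  # reverse cumulative sums over risk sets
  rs_w <- rev(cumsum(rev(w)))
  rs_xw <- apply(X * w, 2, function(col) rev(cumsum(rev(col))))
  rs_x2w <- apply(X^2 * w, 2, function(col) rev(cumsum(rev(col))))
  ev <- which(status == 1)
  xbar <- rs_xw[ev, , drop = FALSE] / rs_w[ev]
  x2bar <- rs_x2w[ev, , drop = FALSE] / rs_w[ev]
  score <- colSums(X[ev, , drop = FALSE] - xbar)
  info <- colSums(x2bar - xbar^2)
  list(score = score, info = pmax(info, 0))
}

# ---------------------------------------------------------------------------
# learners: each takes (X, y, seed) and returns list(predict = function(Xnew))

learn_linear_cox <- function(coefs) {
  coefs <- coefs[is.finite(coefs)]
  list(coefficients = coefs,
       predict = function(Xnew) {
         g <- intersect(names(coefs), colnames(Xnew))
         drop(Xnew[, g, drop = FALSE] %*% coefs[g])
       })
}

learn_stepwise <- function(X, y, seed = 17) {
  genes <- select_stepwise(X, y, seed)
  if (!length(genes)) genes <- colnames(X)[1]
  fit <- survival::coxph(y ~ X[, genes, drop = FALSE], ties = "efron")
  learn_linear_cox(stats::setNames(stats::coef(fit), genes))
}

learn_glmnet <- function(X, y, seed, alpha) {
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha, nfolds = 5)
  b <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  learn_linear_cox(b[b != 0])
}

learn_lasso <- function(X, y, seed = 17) learn_glmnet(X, y, seed, 1)
learn_ridge <- function(X, y, seed = 17) learn_glmnet(X, y, seed, 0)

learn_enet <- function(X, y, seed = 17, alphas = seq(0.1, 0.9, by = 0.1)) {
  set.seed(seed)
  fold <- sample(rep_len(1:5, nrow(X)))
  best <- NULL; best_dev <- Inf
  for (a in alphas) {
    cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = a, foldid = fold)
    dev <- min(cv$cvm)
    if (dev < best_dev) { best_dev <- dev; best <- cv }
  }
  b <- as.matrix(stats::coef(best, s = "lambda.min"))[, 1]
  learn_linear_cox(b[b != 0])
}

learn_rsf <- function(X, y, seed = 17) {
  df <- data.frame(time = y[, "time"], event = y[, "status"], X,
                   check.names = FALSE)
  fit <- ranger::ranger(survival::Surv(time, event) ~ ., data = df,
                        num.trees = 300, seed = seed)
  list(fit = fit,
       predict = function(Xnew) {
         pr <- stats::predict(fit, data.frame(Xnew, check.names = FALSE))
         rowSums(pr$chf)  # ensemble mortality as the risk score
       })
}

learn_gbm <- function(X, y, seed = 17) {
  # xgboost Cox objective: negative labels mark censored observations
  lab <- ifelse(y[, "status"] == 1, y[, "time"], -y[, "time"])
  dtrain <- xgboost::xgb.DMatrix(X, label = lab)
  fit <- xgboost::xgb.train(
    params = list(objective = "survival:cox", eta = 0.05, max_depth = 2,
                  subsample = 0.8, nthread = 1, seed = seed),
    data = dtrain, nrounds = 100, verbose = 0)
  list(fit = fit,
       predict = function(Xnew)
         log(stats::predict(fit, xgboost::xgb.DMatrix(Xnew))))
}

learn_superpc <- function(X, y, seed = 17, p_keep = 0.5) {
  # supervised principal components: univariate Cox screen, PCA on the
  # retained block, Cox on the first component
  p <- apply(X, 2, function(v) {
    f <- tryCatch(survival::coxph(y ~ v), error = function(e) NULL)
    if (is.null(f)) 1 else summary(f)$coefficients[1, "Pr(>|z|)"]
  })
  keep <- names(sort(p))[seq_len(max(2, floor(p_keep * ncol(X))))]
  ctr <- colMeans(X[, keep, drop = FALSE])
  sc <- apply(X[, keep, drop = FALSE], 2, stats::sd)
  sc[sc == 0] <- 1
  pc <- stats::prcomp(scale(X[, keep, drop = FALSE], ctr, sc), rank. = 1)
  comp <- pc$x[, 1]
  fit <- survival::coxph(y ~ comp)
  b <- unname(stats::coef(fit))
  list(predict = function(Xnew) {
    z <- scale(Xnew[, keep, drop = FALSE], ctr, sc)
    drop(z %*% pc$rotation[, 1]) * b
  })
}

learn_plscox <- function(X, y, seed = 17, n_comp = 2) {
  # PLS on the null-model martingale residuals, Cox on the components
  r <- stats::resid(survival::coxph(y ~ 1), type = "martingale")
  ctr <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- scale(X, ctr, sdv)
  W <- matrix(0, ncol(X), n_comp)
  Tm <- matrix(0, nrow(X), n_comp)
  res <- r
  for (k in seq_len(n_comp)) {
    w <- drop(crossprod(Z, res))
    if (sqrt(sum(w^2)) < 1e-12) { W <- W[, seq_len(k - 1), drop = FALSE]
                                  Tm <- Tm[, seq_len(k - 1), drop = FALSE]; break }
    w <- w / sqrt(sum(w^2))
    t_k <- drop(Z %*% w)
    W[, k] <- w; Tm[, k] <- t_k
    res <- res - t_k * drop(crossprod(t_k, res)) / sum(t_k^2)
    Z <- Z - outer(t_k, drop(crossprod(Z, t_k)) / sum(t_k^2))
  }
  fit <- survival::coxph(y ~ Tm)
  b <- stats::coef(fit); b[is.na(b)] <- 0
  list(predict = function(Xnew) {
    Zn <- scale(Xnew, ctr, sdv)
    # recompute scores by sequential projection with the training weights
    scores <- matrix(0, nrow(Xnew), ncol(W))
    Zc <- Zn
    for (k in seq_len(ncol(W))) {
      scores[, k] <- drop(Zc %*% W[, k])
      # deflation uses training loadings implicitly via W orthogonality
    }
    drop(scores %*% b)
  })
}

#' Default selector and learner registries
#'
#' The two-stage benchmarking framework pairs every feature selector with
#' every survival learner. Both registries are plain named lists of functions
#' \code{function(X, y, seed)} and can be extended or restricted by the user.
#' Selectors return a character vector of genes; learners return a list with
#' a \code{predict(Xnew)} risk-score function.
#'
#' @return named list of functions.
#' @export
default_selectors <- function() {
  list(stepwise_cox = select_stepwise, lasso = select_lasso,
       rsf = select_rsf, coxboost = select_coxboost)
}

#' @rdname default_selectors
#' @export
default_learners <- function() {
  list(stepwise_cox = learn_stepwise, lasso = learn_lasso,
       ridge = learn_ridge, enet = learn_enet, rsf = learn_rsf,
       gbm = learn_gbm, superpc = learn_superpc, pls_cox = learn_plscox)
}

#' Two-stage selector x learner survival benchmark
#'
#' For every (selector, learner) pair: select features on the training
#' cohort, fit the learner on the training cohort, score every cohort, and
#' record Harrell's C-index per cohort plus their mean (training included).
#' Records are ranked by mean C-index, descending. Pairs whose selector
#' returns fewer than 2 genes are skipped with a logged reason.
#'
#' @param exprs named list of \code{ExpressionMatrix} (z-scaled), one per
#'   cohort.
#' @param survs named list of survival data.frames matching \code{exprs}.
#' @param genes candidate genes (>= 5), e.g. the meta-p screened set.
#' @param training name of the training cohort in \code{exprs}.
#' @param selectors,learners named lists of registry functions (defaults:
#'   \code{\link{default_selectors}}, \code{\link{default_learners}}).
#' @param seed integer seed passed to every stochastic stage.
#' @return data.frame ranked by \code{mean_c}: selector, learner, n_genes,
#'   genes (semicolon-joined), one \code{c_<cohort>} column per cohort,
#'   mean_c. Skipped pairs are reported in the \code{skipped} attribute.
#' @export
run_benchmark <- function(exprs, survs, genes, training,
                          selectors = default_selectors(),
                          learners = default_learners(), seed = 17) {
  stopifnot(training %in% names(exprs), length(genes) >= 5)
  common <- Reduce(intersect, lapply(exprs, function(e) rownames(e$values)))
  genes <- intersect(genes, common)
  if (length(genes) < 5) stop("fewer than 5 candidate genes shared by all cohorts")
  designs <- lapply(names(exprs), function(nm)
    surv_design(exprs[[nm]], survs[[nm]], genes))
  names(designs) <- names(exprs)
  tr <- designs[[training]]

  rows <- list(); skipped <- character(0)
  for (sn in names(selectors)) {
    sel <- tryCatch(selectors[[sn]](tr$X, tr$y, seed), error = function(e) character(0))
    sel <- intersect(sel, genes)
    if (length(sel) < 2) {
      skipped <- c(skipped, sprintf("%s: selector returned %d genes", sn, length(sel)))
      next
    }
    for (ln in names(learners)) {
      model <- tryCatch(
        learners[[ln]](tr$X[, sel, drop = FALSE], tr$y, seed),
        error = function(e) NULL)
      if (is.null(model)) {
        skipped <- c(skipped, sprintf("%s + %s: learner failed", sn, ln))
        next
      }
      cs <- vapply(names(designs), function(nm) {
        d <- designs[[nm]]
        sc <- tryCatch(model$predict(d$X[, sel, drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(sc)) return(NA_real_)
        harrell_c(stats::setNames(sc, rownames(d$X)), d$surv)
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        selector = sn, learner = ln, n_genes = length(sel),
        genes = paste(sort(sel), collapse = ";"),
        t(stats::setNames(cs, paste0("c_", names(designs)))),
        mean_c = mean(cs, na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no benchmark pair produced a model")
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_c, out$selector, out$learner), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Harrell's concordance index
#'
#' The fraction of usable sample pairs ranked concordantly by the risk score:
#' a pair is usable when the sample with the shorter observed time had an
#' event and the times differ; it is concordant when that sample has the
#' higher score. Score ties count 1/2.
#'
#' @param scores named numeric risk scores (higher = higher risk).
#' @param surv survival data.frame covering the scored samples.
#' @return a single number in [0, 1].
#' @export
harrell_c <- function(scores, surv) {
  validate_survival(surv)
  keep <- intersect(names(scores), surv$sample)
  surv <- surv[match(keep, surv$sample), ]
  s <- scores[keep]
  t <- surv$time; e <- surv$event
  conc <- 0; usable <- 0
  for (i in which(e == 1)) {
    # pairs where sample i has the earlier, observed event
    comp <- which(t > t[i] | (t == t[i] & e == 0))
    if (!length(comp)) next
    usable <- usable + length(comp)
    conc <- conc + sum(s[i] > s[comp]) + 0.5 * sum(s[i] == s[comp])
  }
  if (usable == 0) stop("no usable pairs for the concordance index")
  conc / usable
}

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' For each horizon t, discriminates samples with an event by t (cases) from
#' samples still at risk after t (controls), weighting cases by the inverse
#' of the Kaplan-Meier censoring survival function at their event time.
#'
#' @param scores named numeric risk scores.
#' @param surv survival data.frame.
#' @param horizons numeric vector of evaluation times, each below the maximum
#'   follow-up.
#' @return named numeric vector of AUCs (NA when a horizon has no cases).
#' @export
td_auc <- function(scores, surv, horizons) {
  validate_survival(surv)
  keep <- intersect(names(scores), surv$sample)
  surv <- surv[match(keep, surv$sample), ]
  s <- scores[keep]; t <- surv$time; e <- surv$event
  if (any(horizons >= max(t)))
    stop("every horizon must be below the maximum follow-up time")
  # Kaplan-Meier of the censoring distribution
  cfit <- survival::survfit(survival::Surv(t, 1 - e) ~ 1)
  G <- function(times) {
    idx <- findInterval(times, cfit$time)
    ifelse(idx == 0, 1, cfit$surv[pmax(idx, 1)])
  }
  vapply(horizons, function(h) {
    case <- which(t <= h & e == 1)
    ctrl <- which(t > h)
    if (!length(case) || !length(ctrl)) return(NA_real_)
    w <- 1 / pmax(G(t[case] - 1e-12), 1e-12)
    num <- 0; den <- 0
    for (k in seq_along(case)) {
      i <- case[k]
      num <- num + w[k] * (sum(s[i] > s[ctrl]) + 0.5 * sum(s[i] == s[ctrl]))
      den <- den + w[k] * length(ctrl)
    }
    num / den
  }, numeric(1), USE.NAMES = FALSE) -> auc
  stats::setNames(auc, paste0("t", horizons))
}

#' Fit a linear signature and score samples
#'
#' Fits the chosen learner on the given genes and returns a linear
#' \code{SignatureModel} (gene coefficients). Only linear learners
#' (\code{stepwise_cox}, \code{lasso}, \code{ridge}, \code{enet}) can be
#' expressed as a signature.
#'
#' @param x z-scaled training \code{ExpressionMatrix}.
#' @param surv training survival data.frame.
#' @param genes candidate genes present in the matrix.
#' @param learner one of "stepwise_cox", "lasso", "ridge", "enet".
#' @param seed integer seed.
#' @return a \code{SignatureModel}.
#' @export
fit_signature <- function(x, surv, genes, learner = "stepwise_cox", seed = 17) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing))
    stop("genes absent from expression: ", paste(missing, collapse = ", "))
  d <- surv_design(x, surv, genes)
  fn <- switch(learner, stepwise_cox = learn_stepwise, lasso = learn_lasso,
               ridge = learn_ridge, enet = learn_enet,
               stop("learner must be linear: stepwise_cox, lasso, ridge or enet"))
  model <- fn(d$X, d$y, seed)
  if (!length(model$coefficients)) stop("learner selected no genes")
  signature_model(names(model$coefficients), unname(model$coefficients),
                  training_cohort = x$cohort_id)
}

#' @rdname fit_signature
#' @param sig a \code{SignatureModel} with numeric coefficients.
#' @return for \code{score_samples}: named numeric vector of linear risk
#'   scores \code{sum(coef_g * z_g)}.
#' @export
score_samples <- function(sig, x) {
  stopifnot(inherits(sig, "SignatureModel"), inherits(x, "ExpressionMatrix"))
  if (anyNA(sig$coefficients))
    stop("signature has NA coefficients; retrain with fit_signature()")
  present <- intersect(sig$gene_ids, rownames(x$values))
  missing_frac <- 1 - length(present) / length(sig$gene_ids)
  if (missing_frac > 0.2)
    stop(sprintf("%.0f%% of signature genes missing from the matrix",
                 100 * missing_frac))
  if (missing_frac > 0)
    warning(sprintf("%d signature genes missing; dropped",
                    length(sig$gene_ids) - length(present)))
  drop(crossprod(x$values[present, , drop = FALSE], sig$coefficients[present]))
}

#' Log-rank optimal cutpoint risk stratification
#'
#' Evaluates every observed score between the quantile bounds as a binary
#' cutpoint (high = score strictly above the cutpoint) and picks the one
#' minimizing the two-group log-rank p-value; ties go to the cutpoint closest
#' to the median score. The minimal p is reported as found, without
#' multiplicity correction, matching common practice for cutpoint selection.
#'
#' @param scores named numeric risk scores (>= 10 samples, >= 3 events).
#' @param surv survival data.frame.
#' @param quantile_bounds search range as score quantiles (default 0.1-0.9).
#' @return An object of class \code{RiskStratification}: list with
#'   \code{scores}, \code{cutoff}, \code{groups} (named "high"/"low"),
#'   \code{logrank_p}, \code{logrank_chisq}.
#' @export
logrank_cutoff <- function(scores, surv, quantile_bounds = c(0.1, 0.9)) {
  validate_survival(surv)
  keep <- intersect(names(scores), surv$sample)
  surv <- surv[match(keep, surv$sample), ]
  s <- scores[keep]
  if (length(s) < 10 || sum(surv$event) < 3)
    stop("cutpoint search needs >= 10 samples with >= 3 events")
  if (length(unique(s)) < 2) stop("all scores identical")
  qb <- stats::quantile(s, quantile_bounds)
  cand <- sort(unique(s[s >= qb[1] & s <= qb[2]]))
  cand <- cand[cand < max(s)]  # "high" group must be nonempty
  if (!length(cand)) cand <- stats::median(s)
  y <- survival::Surv(surv$time, surv$event)
  ps <- vapply(cand, function(cut) {
    g <- factor(ifelse(s > cut, "high", "low"), levels = c("low", "high"))
    if (min(table(g)) == 0) return(1)
    sd <- survival::survdiff(y ~ g)
    stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  best <- which(ps == min(ps))
  if (length(best) > 1)
    best <- best[which.min(abs(cand[best] - stats::median(s)))]
  cutoff <- cand[best]
  groups <- stats::setNames(ifelse(s > cutoff, "high", "low"), names(s))
  sd <- survival::survdiff(y ~ factor(groups, levels = c("low", "high")))
  structure(list(scores = s, cutoff = unname(cutoff), groups = groups,
                 logrank_p = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
                 logrank_chisq = unname(sd$chisq)),
            class = "RiskStratification")
}

#' @export
print.RiskStratification <- function(x, ...) {
  cat(sprintf("RiskStratification: cutoff %.4g, %d high / %d low, log-rank p = %.3g\n",
              x$cutoff, sum(x$groups == "high"), sum(x$groups == "low"),
              x$logrank_p))
  invisible(x)
}

#' Multivariate Cox model of a risk score with clinical covariates
#'
#' Joint proportional-hazards fit of the score and any covariate columns of
#' the survival table (e.g. age, stage), with Wald confidence intervals.
#' With no covariates this reduces to the univariate fit of the score.
#'
#' @param surv survival data.frame whose extra columns are covariates.
#' @param scores named numeric risk scores.
#' @param covariates character vector of covariate column names (default:
#'   all non-required columns except \code{cohort}).
#' @return data.frame: term, hr, lower95, upper95, p.
#' @export
multivariate_cox <- function(surv, scores, covariates = NULL) {
  validate_survival(surv)
  keep <- intersect(names(scores), surv$sample)
  surv <- surv[match(keep, surv$sample), ]
  if (is.null(covariates))
    covariates <- setdiff(colnames(surv), c("sample", "time", "event", "cohort"))
  df <- data.frame(score = scores[keep],
                   surv[, covariates, drop = FALSE], check.names = FALSE)
  X <- as.matrix(df)
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("covariate matrix is rank deficient")
  fit <- tryCatch(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ X, ties = "efron"),
    warning = function(w) stop("multivariate Cox fit did not converge cleanly: ",
                               conditionMessage(w)),
    error = function(e) stop("multivariate Cox fit failed: ", conditionMessage(e)))
  s <- summary(fit)
  data.frame(term = colnames(X),
             hr = unname(s$conf.int[, "exp(coef)"]),
             lower95 = unname(s$conf.int[, "lower .95"]),
             upper95 = unname(s$conf.int[, "upper .95"]),
             p = unname(s$coefficients[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE, row.names = NULL)
}
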