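test_that("univariate screening: sign convention and null uniformity", {
  # constructed fixture: high expression of g1 accompanies early events
  set.seed(3)
  n <- 80
  x1 <- rnorm(n)
  time <- rexp(n, 0.05 * exp(1.5 * x1))
  surv <- data.frame(sample = sprintf("s%03d", 1:n), time = time, event = 1)
  m <- rbind(g1 = x1, g2 = rnorm(n))
  colnames(m) <- surv$sample
  scr <- univariate_cox_screen(expression_matrix(m, log_scale = FALSE), surv)
  expect_identical(scr$direction[scr$gene == "g1"], "risk")
  expect_lt(scr$p[scr$gene == "g1"], 1e-6)
  # null calibration: p-values approximately uniform over 1000 genes
  sim <- simulate_prognostic(150, 1000, betas = c(G0001 = 0), seed = 17)
  scr0 <- univariate_cox_screen(sim$expr, sim$survival)
  expect_gt(ks.test(scr0$p, "punif")$p.value, 0.01)
})

test_that("a planted hazard gene screens below p = 0.01", {
  sim <- simulate_prognostic(150, 50, betas = c(G0001 = 1), seed = 17)
  scr <- univariate_cox_screen(sim$expr, sim$survival)
  expect_lt(scr$p[scr$gene == "G0001"], 0.01)
})

test_that("Fisher meta-p matches the chi-square oracle and applies rules", {
  mk <- function(p, dir) data.frame(gene = "g", coef = 1, hr = exp(1), p = p,
                                    direction = dir, converged = TRUE)
  res <- meta_p(list(mk(0.5, "risk"), mk(0.5, "risk")), p_threshold = 0.05)
  expect_equal(res$meta_p, pchisq(-2 * (log(0.5) + log(0.5)), 4,
                                  lower.tail = FALSE))
  expect_equal(round(res$meta_p, 3), 0.597)
  res1 <- meta_p(list(mk(1, "risk"), mk(1, "risk")))
  expect_equal(res1$meta_p, 1)
  # discordant directions are never kept, however small the p-values
  res2 <- meta_p(list(mk(1e-10, "risk"), mk(1e-10, "protective")))
  expect_false(res2$kept)
  expect_lt(res2$meta_p, 1e-10)
  expect_warning(meta_p(list(mk(0, "risk"), mk(0.1, "risk"))), "clamped")
})

test_that("Harrell C: perfect ranking, null, and the pair-enumeration oracle", {
  surv <- data.frame(sample = paste0("s", 1:6), time = c(1, 2, 3, 4, 5, 6),
                     event = 1)
  perfect <- setNames(6:1, surv$sample)   # higher risk = earlier event
  expect_equal(harrell_c(perfect, surv), 1)
  set.seed(10)
  big <- data.frame(sample = sprintf("s%04d", 1:600),
                    time = rexp(600), event = 1)
  rand <- setNames(rnorm(600), big$sample)
  expect_lt(abs(harrell_c(rand, big) - 0.5), 0.05)
  # 8-sample mixed-censoring fixture vs O(n^2) enumeration, exactly
  surv8 <- mixed_surv_fixture()
  sc <- setNames(c(3.2, 1.5, 1.5, 2.5, 0.3, 2.5, 1.1, -0.7), surv8$sample)
  expect_identical(harrell_c(sc, surv8),
                   harrell_oracle(sc, surv8$time, surv8$event))
  # and agrees with the survival package on the same fixture
  cf <- survival::concordance(survival::Surv(surv8$time, surv8$event) ~ sc,
                              reverse = TRUE)
  expect_equal(harrell_c(sc, surv8), unname(cf$concordance))
  expect_error(harrell_c(setNames(1, "s1"),
                         data.frame(sample = "s1", time = 1, event = 0)),
               "usable")
})

test_that("time-dependent AUC: perfect, null, and hand-computed fixture", {
  surv <- data.frame(sample = paste0("s", 1:10), time = 1:10, event = 1)
  perfect <- setNames(10:1, surv$sample)
  expect_equal(unname(td_auc(perfect, surv, c(3.5, 7.5))), c(1, 1))
  set.seed(11)
  big <- data.frame(sample = sprintf("s%04d", 1:500), time = rexp(500, 0.1),
                    event = 1)
  rand <- setNames(rnorm(500), big$sample)
  expect_lt(max(abs(td_auc(rand, big, c(5, 10)) - 0.5)), 0.07)
  # 10-sample fixture with censoring: weighted pair count done by hand
  s10 <- data.frame(sample = paste0("s", 1:10),
                    time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                    event = c(1, 0, 1, 1, 0, 1, 0, 1, 1, 1))
  sc <- setNames(c(5, 4, 6, 1, 2, 3, 1.5, 0.5, 2.5, 0), s10$sample)
  h <- 6.5
  # censoring KM: censored at t = 2 (9 at risk) and t = 5 (6 at risk), so
  # G(t) = 8/9 on [2,5) and 8/9 * 5/6 on [5,7); no case falls beyond 7
  G <- function(t) ifelse(t < 2, 1, ifelse(t < 5, 8 / 9, 8 / 9 * 5 / 6))
  cases <- which(s10$time <= h & s10$event == 1)
  ctrls <- which(s10$time > h)
  num <- 0; den <- 0
  for (i in cases) {
    w <- 1 / G(s10$time[i] - 1e-12)
    num <- num + w * sum(sc[i] > sc[ctrls])
    den <- den + w * length(ctrls)
  }
  expect_equal(unname(td_auc(sc, s10, h)), num / den)
  expect_error(td_auc(sc, s10, 20), "below the maximum")
  expect_true(is.na(td_auc(sc, s10, 0.5)))   # no events before the horizon
})

test_that("signature fitting, linear scoring, and missing-gene handling", {
  sim <- simulate_prognostic(200, 20,
                             betas = c(G0001 = 1.5, G0002 = -1.5, G0003 = 1),
                             seed = 17)
  sig <- fit_signature(sim$expr, sim$survival, sprintf("G%04d", 1:10),
                       learner = "stepwise_cox", seed = 17)
  expect_true(all(c("G0001", "G0002", "G0003") %in% sig$gene_ids))
  sc <- score_samples(sig, sim$expr)
  # linearity: doubling one coefficient doubles that gene's contribution
  sig2 <- sig
  sig2$coefficients[1] <- 2 * sig$coefficients[1]
  g1 <- sig$gene_ids[1]
  expect_equal(score_samples(sig2, sim$expr) - sc,
               sig$coefficients[g1] * sim$expr$values[g1, ],
               ignore_attr = TRUE)
  # all-zero coefficients give all-zero scores
  sig0 <- signature_model(sig$gene_ids, rep(0, length(sig$gene_ids)))
  expect_true(all(score_samples(sig0, sim$expr) == 0))
  # missing-gene rules: <= 20% dropped with warning, > 20% is an error
  sig5 <- signature_model(sprintf("G%04d", 1:5), rep(1, 5))
  expr_small <- subset_expression(sim$expr, genes = sprintf("G%04d", 2:20))
  expect_warning(score_samples(sig5, expr_small), "missing")
  expr_tiny <- subset_expression(sim$expr, genes = sprintf("G%04d", 4:20))
  expect_error(score_samples(sig5, expr_tiny), "missing")
  expect_error(score_samples(gipni_signature(), sim$expr), "NA coefficients")
})

test_that("retrained coefficients recover planted effects across seeds", {
  betas <- setNames(c(1.5, -1.5, 1.5, -1.5, 1.5), sprintf("G%04d", 1:5))
  for (seed in 1:3) {
    sim <- simulate_prognostic(300, 5, betas = betas, seed = seed)
    sig <- fit_signature(sim$expr, sim$survival, names(betas),
                         learner = "stepwise_cox", seed = seed)
    fitted <- setNames(numeric(5), names(betas))
    fitted[sig$gene_ids] <- sig$coefficients
    expect_gt(cor(fitted, betas), 0.8)
  }
})

test_that("benchmark plumbing: restricted registry, ranking, order invariance", {
  sim1 <- simulate_prognostic(120, 12, betas = c(G0001 = 2), seed = 1,
                              cohort_id = "A")
  sim2 <- simulate_prognostic(120, 12, betas = c(G0001 = 2), seed = 2,
                              cohort_id = "B")
  exprs <- list(A = sim1$expr, B = sim2$expr)
  survs <- list(A = sim1$survival, B = sim2$survival)
  genes <- sprintf("G%04d", 1:12)
  one <- run_benchmark(exprs, survs, genes, training = "A",
                       selectors = default_selectors()["stepwise_cox"],
                       learners = default_learners()["stepwise_cox"],
                       seed = 17)
  expect_equal(nrow(one), 1)
  expect_gt(one$c_A, 0.7)   # single strongly prognostic gene, training C-index
  expect_equal(one$mean_c, mean(c(one$c_A, one$c_B)))
  sel <- default_selectors()[c("lasso", "stepwise_cox")]
  lrn <- default_learners()[c("ridge", "lasso")]
  fwd <- run_benchmark(exprs, survs, genes, "A", sel, lrn, seed = 17)
  rev <- run_benchmark(exprs, survs, genes, "A", rev(sel), rev(lrn), seed = 17)
  key <- function(d) d[order(d$selector, d$learner),
                       c("selector", "learner", "mean_c")]
  expect_equal(key(fwd), key(rev), ignore_attr = TRUE)
  expect_identical(fwd$mean_c, sort(fwd$mean_c, decreasing = TRUE))
})

test_that("permuted survival pushes every benchmark pair to a null C-index", {
  sim1 <- simulate_prognostic(150, 10, betas = c(G0001 = 2), seed = 3,
                              cohort_id = "A")
  set.seed(4)
  s_perm <- sim1$survival
  shuffle <- sample(nrow(s_perm))
  s_perm$time <- s_perm$time[shuffle]
  s_perm$event <- s_perm$event[shuffle]
  # passthrough selector: under the null a sparse selector may legitimately
  # return nothing, which would skip the pair rather than score it
  bm <- run_benchmark(list(A = sim1$expr), list(A = s_perm),
                      sprintf("G%04d", 1:10), "A",
                      selectors = list(all = function(X, y, seed) colnames(X)),
                      learners = default_learners()[c("ridge", "pls_cox")],
                      seed = 17)
  expect_true(all(bm$mean_c > 0.40 & bm$mean_c < 0.60))
})

test_that("log-rank cutpoint finds a bimodal gap and stratifies the generator", {
  # bimodal scores with survival separation across the gap
  set.seed(6)
  n <- 40
  scores <- setNames(c(rnorm(20, 0, 0.3), rnorm(20, 5, 0.3)),
                     sprintf("s%02d", 1:n))
  # survival separates perfectly across the score gap; within the high
  # cluster, lower scores get earlier times so no boundary sample is
  # ambiguous for the log-rank search
  surv <- data.frame(sample = names(scores),
                     time = c(100:119, 1:20)[c(1:20, 20 + order(order(scores[21:40])))],
                     event = 1)
  rs <- logrank_cutoff(scores, surv)
  # the chosen cutpoint separates the two score modes exactly
  expect_gte(rs$cutoff, max(scores[1:20])); expect_lt(rs$cutoff, min(scores[21:40]))
  expect_setequal(names(rs$groups[rs$groups == "high"]), names(scores)[21:40])
  expect_true(all(table(rs$groups) > 0))
  expect_error(logrank_cutoff(setNames(rep(1, n), names(scores)), surv),
               "identical")
  # generator risk scores: high group has worse survival, p < 0.001
  sim <- simulate_prognostic(200, 10, betas = c(G0001 = 1.5, G0002 = -1.5),
                             seed = 17)
  sig <- fit_signature(sim$expr, sim$survival, sprintf("G%04d", 1:10),
                       seed = 17)
  rs2 <- logrank_cutoff(score_samples(sig, sim$expr), sim$survival)
  expect_lt(rs2$logrank_p, 0.001)
  km <- survival::survfit(
    survival::Surv(sim$survival$time, sim$survival$event) ~
      rs2$groups[sim$survival$sample])
  med <- summary(km)$table[, "median"]
  expect_lt(med["rs2$groups[sim$survival$sample]=high"],
            med["rs2$groups[sim$survival$sample]=low"])
})

test_that("multivariate Cox: rank deficiency, covariate-free consistency, HR", {
  sim <- simulate_prognostic(200, 5, betas = c(G0001 = 1), seed = 17)
  surv <- sim$survival
  sc <- setNames(sim$expr$values["G0001", ], surv$sample)
  surv$dup <- sc[surv$sample]   # duplicate of the score column
  expect_error(multivariate_cox(surv, sc, covariates = "dup"),
               "rank deficient")
  surv$dup <- NULL
  uni <- multivariate_cox(surv, sc, covariates = character(0))
  expect_equal(nrow(uni), 1)
  # confounder-free covariates leave the score HR essentially unchanged
  set.seed(8)
  surv$age <- rnorm(nrow(surv), 60, 8)
  multi <- multivariate_cox(surv, sc, covariates = "age")
  hr_uni <- uni$hr[uni$term == "score"]
  hr_multi <- multi$hr[multi$term == "score"]
  expect_gt(hr_multi, uni$lower95[uni$term == "score"])
  expect_lt(hr_multi, uni$upper95[uni$term == "score"])
  expect_gt(hr_uni, 1.5)
})

test_that("the packaged published signature carries exactly its 11 genes", {
  sig <- gipni_signature()
  expect_length(sig$gene_ids, 11)
  expect_setequal(sig$gene_ids,
                  c("SPRR2A", "SPRR2B", "SPRR2E", "SEC11A", "PPFIA1", "CROT",
                    "RAP1B", "HPRT1", "MRPL41", "S100A7", "SNRPD2"))
  expect_true(all(is.na(sig$coefficients)))
})
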