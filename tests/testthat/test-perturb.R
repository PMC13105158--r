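tiny_expr <- function(values, genes, samples, tissue = "tumor") {
  expression_matrix(matrix(values, nrow = length(genes),
                           dimnames = list(genes, samples)), tissue)
}

test_that("rank transform uses ascending average ranks within each sample", {
  x <- tiny_expr(c(2, 1, 3, 1, 1, 3), c("A", "B", "C"), c("s1", "s2"))
  r <- rank_transform(x)
  expect_equal(unname(r[, "s1"]), c(2, 1, 3))
  expect_equal(unname(r[, "s2"]), c(1.5, 1.5, 3))
  expect_error(rank_transform(tiny_expr(1, "A", "s1")), ">= 2 genes")
})

test_that("per-sample rank sums equal G(G+1)/2", {
  set.seed(4)
  m <- matrix(rnorm(100 * 30), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:30)))
  r <- rank_transform(expression_matrix(m))
  expect_true(all(colSums(r) == 5050))
})

test_that("reference ordering follows normal means with lexicographic ties", {
  m <- matrix(c(5, 5, 2, 2, 9, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("n1", "n2")))
  ref <- build_reference(expression_matrix(m, "normal"))
  expect_equal(ref$ref_rank, c(A = 2L, B = 1L, C = 3L))
  # tie between two genes decided by identifier order
  m2 <- matrix(c(5, 5, 5, 5, 1, 1), nrow = 3, byrow = TRUE,
               dimnames = list(c("Zeta", "Alpha", "Mid"), c("n1", "n2")))
  ref2 <- build_reference(expression_matrix(m2, "normal"))
  expect_lt(ref2$ref_rank["Alpha"], ref2$ref_rank["Zeta"])
  expect_error(build_reference(expression_matrix(m[, 1, drop = FALSE], "normal")),
               ">= 2 normal samples")
})

test_that("low-noise generator reference recovers the latent ordering", {
  net <- make_toy_network(100, 250, seed = 17)
  cfg <- simulation_config(n_genes = 100, n_edges = 250, n_normal = 20,
                           n_tumor = 4, n_cohorts = 1, sigma = 0.01, seed = 17)
  sim <- simulate_bulk(cfg, net)
  ref <- build_reference(sim$reference)
  # latent means decrease with gene index, so ranks must too
  expect_identical(unname(ref$ref_rank), rev(seq_len(100)))
})

test_that("edge perturbation reproduces hand-checkable arithmetic", {
  # G=3; sample ranks A=2, C=3; ref ranks A=3, C=1 -> p = (2-3) - (3-1) = -3
  samp <- tiny_expr(c(5, 1, 9), c("A", "B", "C"), "s1")
  # normal means A=9.25, B=5.25, C=1.25 -> ref ranks C=1, B=2, A=3
  norm <- tiny_expr(c(9, 5, 1, 9.5, 5.5, 1.5), c("A", "B", "C"), c("n1", "n2"),
                    "normal")
  # B enters the network through a second edge so the rank universe is G=3
  net <- interaction_network(c("A", "A"), c("C", "B"), 0.9)
  ref <- build_reference(norm)
  epm <- edge_perturbation(samp, ref, net)
  expect_equal(unname(epm$values["A|C", "s1"]), -3)
})

test_that("a reference-identical sample yields an all-zero column", {
  set.seed(8)
  net <- make_toy_network(20, 60, seed = 8)
  normal_vals <- matrix(rnorm(20 * 5, seq(10, 1, length.out = 20), 0.2),
                        nrow = 20,
                        dimnames = list(sprintf("G%04d", 1:20),
                                        sprintf("n%d", 1:5)))
  normals <- expression_matrix(normal_vals, "normal")
  ref <- build_reference(normals)
  # construct a sample whose expression order equals the reference order
  v <- matrix(ref$ref_rank + 0.5, ncol = 1,
              dimnames = list(names(ref$ref_rank), "ident"))
  epm <- edge_perturbation(expression_matrix(v), ref, net)
  expect_true(all(epm$values[, "ident"] == 0))
})

test_that("perturbation is antisymmetric and bounded by 2(G-1)", {
  set.seed(12)
  G <- 15
  m <- matrix(rnorm(G * 6), nrow = G,
              dimnames = list(sprintf("G%04d", 1:G), sprintf("s%d", 1:6)))
  normals <- expression_matrix(matrix(rnorm(G * 4), nrow = G,
                                      dimnames = list(rownames(m),
                                                      paste0("n", 1:4))),
                               "normal")
  ref <- build_reference(normals)
  net <- make_toy_network(G, 30, seed = 12)
  epm <- edge_perturbation(expression_matrix(m), ref, net)
  expect_true(all(abs(epm$values) <= 2 * (G - 1)))
  # antisymmetry: recompute each edge with endpoints swapped
  r <- rank_transform(expression_matrix(m))
  for (e in seq_len(nrow(net))) {
    a <- net$gene_a[e]; b <- net$gene_b[e]
    swapped <- (r[b, ] - r[a, ]) - (ref$ref_rank[b] - ref$ref_rank[a])
    expect_equal(unname(swapped), -unname(epm$values[net$edge_id[e], ]))
  }
})

test_that("edge perturbation equals the naive double-loop oracle bit-exactly", {
  set.seed(23)
  genes <- sprintf("G%04d", 1:10)
  m <- matrix(rnorm(10 * 6, 5), nrow = 10,
              dimnames = list(genes, sprintf("s%d", 1:6)))
  normals <- expression_matrix(
    matrix(rnorm(10 * 4, 5), nrow = 10, dimnames = list(genes, paste0("n", 1:4))),
    "normal")
  ref <- build_reference(normals)
  net <- make_toy_network(10, 15, seed = 23)
  epm <- edge_perturbation(expression_matrix(m), ref, net)
  oracle <- epm_oracle(m, ref$ref_rank, net$gene_a, net$gene_b)
  dimnames(oracle) <- dimnames(epm$values)
  expect_identical(epm$values, oracle)
})

test_that("sample order permutation permutes score columns identically", {
  net <- make_toy_network(30, 80, seed = 2)
  genes <- sprintf("G%04d", 1:30)
  m <- matrix(rnorm(30 * 8, 5), nrow = 30,
              dimnames = list(genes, sprintf("s%d", 1:8)))
  normals <- expression_matrix(
    matrix(rnorm(30 * 4, 5), nrow = 30, dimnames = list(genes, paste0("n", 1:4))),
    "normal")
  ref <- build_reference(normals)
  a <- edge_perturbation(expression_matrix(m), ref, net)
  b <- edge_perturbation(expression_matrix(m[, 8:1]), ref, net)
  expect_identical(b$values[, colnames(a$values)], a$values)
})

test_that("perturbation scores follow the log2(mean|p|+1) definition", {
  epm <- structure(list(
    values = matrix(c(0, 0, 0, 1, -1, 1), nrow = 3,
                    dimnames = list(c("A|B", "B|C", "A|C"), c("s0", "s1"))),
    tissue_class = c(s0 = "normal", s1 = "tumor")),
    class = "EdgePerturbationMatrix")
  sc <- sample_perturbation_score(epm)
  expect_equal(unname(sc), c(0, 1))   # log2(0+1)=0, log2(1+1)=1
})

test_that("differential edges: null labels stay within binomial bounds and
           tumor shift is detected", {
  net <- make_toy_network(100, 250, seed = 17)
  cfg <- simulation_config(n_genes = 100, n_edges = 250, n_normal = 20,
                           n_tumor = 20, n_cohorts = 1, seed = 17)
  sim <- simulate_bulk(cfg, net)
  ref <- build_reference(sim$reference, net)
  epm <- suppressMessages(edge_perturbation(sim$cohorts$C1, ref, net))
  # permute labels: significant count within binomial(E, 0.05) 99.9% bounds
  set.seed(1)
  epm_null <- epm
  epm_null$tissue_class[] <- sample(epm$tissue_class)
  de_null <- differential_edges(epm_null)
  expect_lte(sum(de_null$significant),
             qbinom(0.999, nrow(epm$values), 0.05))
  de <- differential_edges(epm)
  expect_gt(sum(de$significant), 10)
  # reversed duplicate of an edge yields the identical statistic on |p|
  row <- abs(epm$values[1, ])
  tum <- epm$tissue_class == "tumor"
  expect_equal(suppressWarnings(wilcox.test(row[tum], row[!tum])$p.value),
               suppressWarnings(wilcox.test(abs(-epm$values[1, tum]),
                                            abs(-epm$values[1, !tum]))$p.value))
})

test_that("node gene extraction deduplicates, sorts, handles empty input", {
  edges <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                      significant = c(TRUE, TRUE))
  expect_identical(extract_node_genes(edges), c("A", "B", "C"))
  expect_identical(extract_node_genes(edges[0, ]), character(0))
})

test_that("node genes cover the endpoints of >= 90% of perturbed edges", {
  net <- make_toy_network(200, 600, seed = 17)
  sim <- simulate_bulk(simulation_config(seed = 17), net)
  ref <- build_reference(sim$reference, net)
  epm <- suppressMessages(edge_perturbation(sim$cohorts$C1, ref, net))
  nodes <- extract_node_genes(differential_edges(epm))
  covered <- vapply(sim$truth$anchor_edge_ids, function(id) {
    gs <- strsplit(id, "|", fixed = TRUE)[[1]]
    all(gs %in% nodes)
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
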