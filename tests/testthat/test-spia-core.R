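deg_df <- function(genes, lfc, label = "A") {
  out <- data.frame(gene = genes, lfc = lfc, best_ES = abs(lfc),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("deg_set", "data.frame")
  out
}

test_that("delta_e places fold-changes only on pathway DEGs", {
  g <- chain_graph(c(1, 1))
  de <- delta_e(deg_df("A", 2), g)
  expect_equal(unname(de$dE), c(2, 0, 0))
  expect_identical(de$NDE, 1L)

  empty <- delta_e(deg_df("Z", 5), g)
  expect_true(all(empty$dE == 0))
  expect_identical(empty$NDE, 0L)

  mixed <- delta_e(deg_df(c("A", "Z"), c(2, 5)), g)
  expect_equal(unname(mixed$dE), c(2, 0, 0))
  expect_identical(mixed$NDE, 1L)
})

test_that("net perturbation matches hand-solved chains and cycles", {
  g <- chain_graph(c(1, 1))
  r <- net_perturbation(build_beta_matrix(g), c(A = 1, B = 0, C = 0))
  expect_equal(unname(r$PF), c(1, 1, 1))
  expect_equal(unname(r$Acc), c(0, 1, 1))
  expect_equal(r$tA, 2)

  gi <- chain_graph(c(-1, 1))  # A -| B -> C
  ri <- net_perturbation(build_beta_matrix(gi), c(A = 1, B = 0, C = 0))
  expect_equal(unname(ri$PF), c(1, -1, -1))
  expect_equal(ri$tA, -2)

  # 2-cycle A -> B (+1), B -> A (-1): PF solves the 2x2 system by hand
  cyc <- pathway_graph("cyc", "cyc", c("A", "B"),
                       data.frame(src = c("A", "B"), dst = c("B", "A"),
                                  beta = c(1, -1)))
  rc <- net_perturbation(build_beta_matrix(cyc), c(A = 1, B = 0))
  expect_equal(unname(rc$PF), c(0.5, 0.5))
  expect_equal(unname(rc$Acc), c(-0.5, 0.5))
  expect_equal(rc$tA, 0)
})

test_that("singular I - B is flagged as not computable", {
  # A -> B and B -> A both +1 with Nds 1: det(I - B) = 0
  g <- pathway_graph("sing", "sing", c("A", "B"),
                     data.frame(src = c("A", "B"), dst = c("B", "A"),
                                beta = c(1, 1)))
  expect_error(net_perturbation(build_beta_matrix(g), c(A = 1, B = 0)),
               class = "kopb_singular")
})

test_that("linear solve equals path enumeration on random DAGs", {
  set.seed(2024)
  for (i in 1:50) {
    g <- random_dag_graph(sample(3:8, 1), id = paste0("d", i))
    dE <- stats::setNames(rnorm(g$pSize) * rbinom(g$pSize, 1, 0.5), g$nodes)
    r <- net_perturbation(build_beta_matrix(g), dE)
    expect_equal(r$PF, oracle_pf_paths(g, dE), tolerance = 1e-12)
  }
})

test_that("linear solve equals the iterative fixed point; tA is linear", {
  set.seed(8)
  g <- random_dag_graph(7, id = "fx")
  B <- build_beta_matrix(g)
  dE <- stats::setNames(rnorm(7), g$nodes)
  r <- net_perturbation(B, dE)
  pf <- dE
  for (k in 1:200) pf <- dE + as.numeric(B %*% pf)
  expect_equal(unname(r$PF), unname(pf), tolerance = 1e-10)
  # scaling dE by k scales tA by k
  expect_equal(net_perturbation(B, 3.7 * dE)$tA, 3.7 * r$tA,
               tolerance = 1e-12)
})

test_that("hypergeometric pNDE matches exhaustive enumeration", {
  expect_equal(p_nde(3, 5, 4, 20), 155 / 4845, tolerance = 1e-12)
  expect_equal(p_nde(0, 5, 4, 20), 1)
  expect_equal(p_nde(3, 3, 3, 3), 1)  # certain event
  set.seed(6)
  for (i in 1:25) {
    N <- sample(10:40, 1)
    K <- sample(2:(N - 2), 1)
    draws <- sample(1:(N - 1), 1)
    nde <- sample(0:min(K, draws), 1)
    expect_equal(p_nde(nde, K, draws, N), oracle_pnde(nde, K, draws, N),
                 tolerance = 1e-12)
  }
  expect_error(p_nde(6, 5, 4, 20), "inconsistent")
})

test_that("pPERT: degenerate, deterministic and enumeration-consistent", {
  lone <- pathway_graph("lone", "lone", c("A", "B", "C"))
  degs <- deg_df("A", 3)
  r <- p_pert(lone, degs, n_boot = 300, seed = 1)
  expect_equal(r$pPERT, 1)  # no propagation: every tA is 0

  g <- chain_graph(c(1, 1, 1, 1))  # 5-node chain
  r1 <- p_pert(g, deg_df("A", 3), n_boot = 500, seed = 42)
  r2 <- p_pert(g, deg_df("A", 3), n_boot = 500, seed = 42)
  expect_identical(r1$pPERT, r2$pPERT)

  # single-value pool, NDE = 1: the null places 3 on one of 5 genes,
  # so tA_null enumerates 5 equiprobable values; compare against the
  # exhaustive two-sided probability around the true null median
  coefs <- vapply(g$nodes, function(nd) {
    dE <- stats::setNames(numeric(5), g$nodes); dE[nd] <- 3
    net_perturbation(build_beta_matrix(g), dE)$tA
  }, numeric(1))
  med <- median(coefs)
  tA_obs <- coefs[["A"]]
  p_exact <- mean(abs(coefs - med) >= abs(tA_obs - med))
  rb <- p_pert(g, deg_df("A", 3), n_boot = 4000, seed = 7)
  expect_lt(abs(rb$pPERT - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
  expect_identical(rb$status, "Activated")
})

test_that("pG combination matches its closed form and is monotone", {
  expect_equal(combine_pg(1, 1), 1)
  expect_equal(combine_pg(0.5, 0.5), 0.25 - 0.25 * log(0.25),
               tolerance = 1e-12)
  expect_error(combine_pg(0, 0.5), "0, 1")
  cc <- seq(0.01, 0.99, by = 0.01)
  pg <- combine_pg(cc, 1)
  expect_true(all(diff(pg) > 0))   # monotone in each argument
  expect_true(all(pg >= cc))       # -c log c >= 0
})

test_that("BH adjustment equals the hand-applied step-up rule", {
  expect_equal(fdr_bh(c(0.005, 0.01, 0.03, 0.8)), c(0.02, 0.02, 0.04, 0.8))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(rep(0.2, 6)), rep(0.2, 6))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("run_spia produces the per-pathway record, sorted by pGFdr", {
  p <- small_sim_params(seed = 19)
  sim <- simulate_pathway_collection(p)
  em <- simulate_expression(p, sim$collection, sim$truth)
  st <- compute_gene_stats(em, default_contrasts()$A)
  net <- suppressWarnings(merge_global_network(sim$collection))
  degs <- select_degs(score_edges(st, net),
                      find_hes_threshold(score_edges(st, net)), st)
  res <- run_spia(sim$collection, st, degs, n_boot = 300, seed = 19)
  expect_identical(names(res),
                   c("ID", "Name", "Status", "pSize", "NDE", "DEG_pct",
                     "tA", "pNDE", "pPERT", "pG", "pGFdr"))
  expect_true(all(diff(res$pGFdr) >= 0))
  expect_true(all(res$NDE >= 0 & res$NDE <= res$pSize))
  expect_true(all(res$pG > 0 & res$pG <= 1))
  # planted positives must outrank the negatives' median
  pos <- res$pGFdr[res$ID %in% sim$truth$positive_pathway_ids]
  neg <- res$pGFdr[!res$ID %in% sim$truth$positive_pathway_ids]
  expect_true(all(pos < median(neg)))
})

test_that("an empty DEG set degenerates every p-value to one", {
  p <- small_sim_params(seed = 23)
  sim <- simulate_pathway_collection(p)
  em <- simulate_expression(p, sim$collection, sim$truth)
  st <- compute_gene_stats(em, default_contrasts()$A)
  degs <- deg_df(character(0), numeric(0))
  res <- run_spia(sim$collection, st, degs, n_boot = 300, seed = 1)
  expect_true(all(res$pNDE == 1))
  expect_true(all(res$pPERT == 1))
  expect_true(all(res$pGFdr == 1))
  expect_true(all(is.na(res$Status)))
})
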