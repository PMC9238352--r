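test_that("invalid simulation parameters are rejected by field name", {
  expect_error(simulation_params(n_pathways = 4, n_positive_pathways = 5),
               "n_positive_pathways")
  expect_error(simulation_params(pathway_size_range = c(2, 10)),
               "pathway_size_range")
  expect_error(simulation_params(noise_sd = 0), "noise_sd")
  expect_error(simulation_params(n_replicates = 1), "n_replicates")
  expect_error(simulation_params(ko_gene = "nope"), "ko_gene")
})

test_that("pathway collection honors counts, membership and determinism", {
  p <- simulation_params(n_pathways = 30, n_positive_pathways = 5, seed = 7)
  sim <- simulate_pathway_collection(p)
  expect_length(sim$collection$graphs, 30)
  has_ko <- vapply(sim$collection$graphs,
                   function(g) p$ko_gene %in% g$nodes, logical(1))
  expect_identical(sum(has_ko), 5L)
  expect_setequal(names(which(has_ko)), sim$truth$positive_pathway_ids)
  # planted label counts conserved
  expect_identical(sum(has_ko) + sum(!has_ko), 30L)

  sim2 <- simulate_pathway_collection(p)
  expect_identical(lapply(sim$collection$graphs, `[[`, "edges"),
                   lapply(sim2$collection$graphs, `[[`, "edges"))
  sim3 <- simulate_pathway_collection(
    simulation_params(n_pathways = 30, n_positive_pathways = 5, seed = 8))
  expect_false(identical(lapply(sim$collection$graphs, `[[`, "edges"),
                         lapply(sim3$collection$graphs, `[[`, "edges")))
})

test_that("degenerate size range yields fixed-size connected DAGs", {
  p <- simulation_params(n_pathways = 8, n_positive_pathways = 2,
                         pathway_size_range = c(5, 5), seed = 3)
  sim <- simulate_pathway_collection(p)
  for (g in sim$collection$graphs) {
    expect_identical(g$pSize, 5L)
    # DAG by construction: every edge goes forward in stored node order
    pos <- match(g$nodes, g$nodes)
    expect_true(all(match(g$edges$src, g$nodes) < match(g$edges$dst, g$nodes)))
    # weak connectivity: every non-root node has an incoming edge
    expect_setequal(setdiff(g$nodes, g$edges$dst), g$nodes[1])
  }
})

test_that("truth records downstream genes with propagated signs", {
  p <- small_sim_params(seed = 5)
  sim <- simulate_pathway_collection(p)
  for (pid in sim$truth$positive_pathway_ids) {
    g <- sim$collection$graphs[[pid]]
    down <- sim$truth$perturbed_genes[[pid]]
    expect_true(all(down %in% g$nodes))
    expect_false(p$ko_gene %in% down)
    expect_true(all(sim$truth$perturbed_signs[[pid]] %in% c(-1, 1)))
    # ko gene heads the topological order, so everything with an
    # incoming path is downstream; spot-check direct targets
    direct <- g$edges$dst[g$edges$src == p$ko_gene]
    expect_true(all(direct %in% down))
  }
})

test_that("expression simulation is seed-deterministic and plants the KO shift", {
  p <- simulation_params(n_genes = 500, n_pathways = 6,
                         pathway_size_range = c(8, 15),
                         n_positive_pathways = 2, delta_ko = 3,
                         noise_sd = 0.25, n_replicates = 5, seed = 21)
  sim <- simulate_pathway_collection(p)
  em1 <- simulate_expression(p, sim$collection, sim$truth)
  em2 <- simulate_expression(p, sim$collection, sim$truth)
  expect_identical(em1$values, em2$values)

  ko_cols <- em1$metadata$genotype == "KO"
  swt <- em1$metadata$genotype == "WT" & em1$metadata$treatment == "septic"
  diff <- mean(em1$values[p$ko_gene, ko_cols]) -
    mean(em1$values[p$ko_gene, swt])
  # planted -delta_ko, tolerance 3 * SE per the direct-sampling oracle
  expect_lt(abs(diff - (-3)), 0.4)
})

test_that("null simulation yields uniform Welch p-values", {
  p <- simulation_params(delta_treatment = 0, delta_ko = 0, seed = 2)
  sim <- simulate_pathway_collection(p)
  em <- simulate_expression(p, sim$collection, sim$truth)
  st <- compute_gene_stats(em, default_contrasts()$C)
  expect_identical(nrow(st), 2000L)
  frac <- mean(st$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("mismatched truth and collection are refused", {
  p <- small_sim_params(seed = 9)
  sim <- simulate_pathway_collection(p)
  other <- simulate_pathway_collection(small_sim_params(seed = 10))
  bad_truth <- sim$truth
  bad_truth$positive_pathway_ids <- c("nonexistent")
  expect_error(simulate_expression(p, sim$collection, bad_truth), "mismatch")
  # positives of one run need not contain ko gene in another run's graphs
  expect_error(
    simulate_expression(p, other$collection, sim$truth), "mismatch")
})

test_that("KGML fixtures round-trip through the parser", {
  g <- chain_graph(c(1, -1))
  coll <- pathway_collection(list(g))
  dir <- withr::local_tempdir()
  paths <- write_kgml_fixtures(coll, dir)
  expect_named(paths, "chain")
  doc <- xml2::read_xml(paths[["chain"]])
  expect_length(xml2::xml_find_all(doc, "//entry"), 3)
  expect_length(xml2::xml_find_all(doc, "//relation"), 2)

  back <- parse_kgml(paths[["chain"]])
  expect_setequal(back$nodes, g$nodes)
  expect_identical(
    back$edges[order(back$edges$src), c("src", "dst", "beta")],
    g$edges[order(g$edges$src), c("src", "dst", "beta")])
})

test_that("a full generated collection round-trips file for file", {
  p <- small_sim_params(seed = 13)
  sim <- simulate_pathway_collection(p)
  dir <- withr::local_tempdir()
  paths <- write_kgml_fixtures(sim$collection, dir)
  expect_length(paths, 12)
  expect_setequal(names(paths), names(sim$collection$graphs))
  for (pid in names(paths)) {
    orig <- sim$collection$graphs[[pid]]
    back <- parse_kgml(paths[[pid]])
    key <- function(e) sort(paste(e$src, e$dst, e$beta))
    expect_identical(key(back$edges), key(orig$edges))
    expect_setequal(back$nodes, orig$nodes)
  }
})
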