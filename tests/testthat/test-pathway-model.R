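kgml_text <- function(entries, relations, title = "Test pathway") {
  ent <- paste(vapply(seq_along(entries), function(i) {
    sprintf('<entry id="%d" name="%s" type="%s"/>',
            i, entries[[i]]$name, entries[[i]]$type %||% "gene")
  }, character(1)), collapse = "\n")
  rel <- paste(vapply(relations, function(r) {
    sprintf('<relation entry1="%d" entry2="%d" type="PPrel"><subtype name="%s" value="x"/></relation>',
            r$e1, r$e2, r$subtype)
  }, character(1)), collapse = "\n")
  sprintf('<?xml version="1.0"?>\n<pathway name="path:test01" org="mmu" title="%s">\n%s\n%s\n</pathway>',
          title, ent, rel)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

write_kgml_tmp <- function(text) {
  f <- withr::local_tempfile(fileext = ".xml",
                             .local_envir = parent.frame())
  writeLines(text, f)
  f
}

test_that("parse_kgml maps entries and signed relations directly", {
  f <- write_kgml_tmp(kgml_text(
    list(list(name = "A"), list(name = "B"), list(name = "C")),
    list(list(e1 = 1, e2 = 2, subtype = "activation"),
         list(e1 = 2, e2 = 3, subtype = "inhibition"))))
  g <- parse_kgml(f)
  expect_setequal(g$nodes, c("A", "B", "C"))
  expect_identical(g$pSize, 3L)
  e <- g$edges[order(g$edges$src), ]
  expect_identical(e$src, c("A", "B"))
  expect_identical(e$dst, c("B", "C"))
  expect_identical(e$beta, c(1, -1))
  expect_identical(unname(g$Nds[c("A", "B", "C")]), c(1L, 1L, 0L))
})

test_that("unknown subtypes are dropped but nodes kept; prefixes stripped", {
  f <- write_kgml_tmp(kgml_text(
    list(list(name = "mmu:11"), list(name = "mmu:22")),
    list(list(e1 = 1, e2 = 2, subtype = "binding/association"))))
  g <- parse_kgml(f)
  expect_setequal(g$nodes, c("11", "22"))
  expect_identical(nrow(g$edges), 0L)
  g2 <- parse_kgml(f, strip_prefix = FALSE)
  expect_setequal(g2$nodes, c("mmu:11", "mmu:22"))
})

test_that("multi-gene entries expand to Cartesian edge products", {
  f <- write_kgml_tmp(kgml_text(
    list(list(name = "A1 A2"), list(name = "B")),
    list(list(e1 = 1, e2 = 2, subtype = "activation"))))
  g <- parse_kgml(f)
  expect_setequal(g$nodes, c("A1", "A2", "B"))
  # oracle: manual expansion -> exactly (A1,B,+1) and (A2,B,+1)
  expect_identical(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$src, g$edges$dst, g$edges$beta),
                  c("A1 B 1", "A2 B 1"))
})

test_that("relations touching non-gene entries are ignored", {
  f <- write_kgml_tmp(kgml_text(
    list(list(name = "A"), list(name = "cpd:C00001", type = "compound")),
    list(list(e1 = 1, e2 = 2, subtype = "activation"))))
  g <- parse_kgml(f)
  expect_setequal(g$nodes, "A")
  expect_identical(nrow(g$edges), 0L)
})

test_that("parse errors carry the file name; empty pathways are refused", {
  f <- write_kgml_tmp("<pathway><entry")
  expect_error(parse_kgml(f), basename(f), fixed = TRUE)
  f2 <- write_kgml_tmp(kgml_text(
    list(list(name = "X", type = "map")), list()))
  expect_error(parse_kgml(f2), "empty pathway")
})

test_that("build_beta_matrix matches hand constructions", {
  g <- chain_graph(c(1, 1))
  B <- build_beta_matrix(g)
  expect_equal(B["B", "A"], 1)
  expect_equal(B["C", "B"], 1)
  expect_equal(sum(B != 0), 2)

  fan <- pathway_graph("fan", "fan", c("A", "B", "C"),
                       data.frame(src = "A", dst = c("B", "C"), beta = 1))
  Bf <- build_beta_matrix(fan)
  expect_equal(Bf["B", "A"], 0.5)
  expect_equal(Bf["C", "A"], 0.5)

  lone <- pathway_graph("lone", "lone", c("A", "B"))
  expect_true(all(build_beta_matrix(lone) == 0))
})

test_that("columns of |B| sum to one (or zero) for generated graphs", {
  set.seed(42)
  for (i in 1:20) {
    g <- random_dag_graph(sample(3:9, 1), id = paste0("g", i))
    B <- build_beta_matrix(g)
    cs <- colSums(abs(B))
    expect_true(all(abs(cs) < 1e-12 | abs(cs - 1) < 1e-12))
  }
})

test_that("global network merge deduplicates with provenance", {
  g1 <- pathway_graph("p1", "p1", c("A", "B"),
                      data.frame(src = "A", dst = "B", beta = 1))
  g2 <- pathway_graph("p2", "p2", c("A", "B", "C"),
                      data.frame(src = c("A", "B"), dst = c("B", "C"),
                                 beta = c(1, -1)))
  net <- merge_global_network(pathway_collection(list(g1, g2)))
  expect_identical(nrow(net), 2L)
  ab <- which(net$src == "A" & net$dst == "B")
  expect_setequal(net$pathways[[ab]], c("p1", "p2"))

  # disjoint pathways: edge count adds up
  g3 <- pathway_graph("p3", "p3", c("X", "Y"),
                      data.frame(src = "X", dst = "Y", beta = 1))
  net2 <- merge_global_network(pathway_collection(list(g1, g3)))
  expect_identical(nrow(net2), 2L)
})

test_that("sign conflicts keep the first pathway's sign with one warning", {
  g1 <- pathway_graph("p1", "p1", c("A", "B"),
                      data.frame(src = "A", dst = "B", beta = 1))
  g2 <- pathway_graph("p2", "p2", c("A", "B"),
                      data.frame(src = "A", dst = "B", beta = -1))
  warns <- testthat::capture_warnings(
    net <- merge_global_network(pathway_collection(list(g1, g2))))
  expect_length(warns, 1)
  expect_match(warns, "sign conflict")
  expect_identical(nrow(net), 1L)
  expect_identical(net$beta, 1)
  expect_setequal(net$pathways[[1]], c("p1", "p2"))
})

test_that("edge counts never exceed the per-pathway sum", {
  p <- small_sim_params(seed = 31)
  sim <- simulate_pathway_collection(p)
  net <- suppressWarnings(merge_global_network(sim$collection))
  total <- sum(vapply(sim$collection$graphs,
                      function(g) nrow(g$edges), integer(1)))
  expect_lte(nrow(net), total)
  expect_true(all(lengths(net$pathways) >= 1))
})
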