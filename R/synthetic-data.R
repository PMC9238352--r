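#' Parameters of the synthetic knockout study
#'
#' The generator emulates the structure of a spleen microarray knockout
#' experiment: three sample groups (untreated wildtype, septic wildtype,
#' septic knockout), a knockout gene planted on a known subset of pathways,
#' and log-normal-like expression (Gaussian on the log2 scale) with group
#' effects. Defaults describe a small study: 2000 measured genes, 30
#' pathways of 20-60 genes, 5 knockout-positive pathways, a 1.5 log2-unit
#' treatment/knockout effect over 0.25 log2 units of replicate noise, and
#' 3 replicates per group (a typical small microarray design).
#'
#' @param n_genes size of the measured gene universe.
#' @param n_pathways number of pathways to generate.
#' @param pathway_size_range inclusive (min, max) gene counts per pathway;
#'   min must be >= 3.
#' @param ko_gene id of the knockout gene; must belong to the generated
#'   universe `g0001 ... g<n_genes>`.
#' @param n_positive_pathways how many pathways contain `ko_gene`
#'   (<= `n_pathways`).
#' @param delta_treatment log2 mean shift applied in septic samples to
#'   genes downstream of `ko_gene` on positive pathways (sign follows the
#'   cumulative edge sign from `ko_gene`).
#' @param delta_ko log2 downward shift of `ko_gene` (and, with propagated
#'   sign, its downstream genes on positive pathways) in knockout samples.
#' @param noise_sd i.i.d. replicate noise, log2 units (> 0).
#' @param baseline_mean,baseline_sd per-gene baseline means are drawn from
#'   Normal(baseline_mean, baseline_sd^2), log2 units.
#' @param n_replicates samples per group (>= 2).
#' @param seed integer RNG seed; seeded runs are bit-reproducible.
#' @param inhibition_fraction probability an edge is inhibitory (beta -1).
#' @param allow_cycles add a few back-edges; by default graphs are DAGs so
#'   the perturbation linear system is always solvable.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 2000L, n_pathways = 30L,
                              pathway_size_range = c(20L, 60L),
                              ko_gene = "g0001",
                              n_positive_pathways = 5L,
                              delta_treatment = 1.5, delta_ko = 1.5,
                              noise_sd = 0.25,
                              baseline_mean = 8, baseline_sd = 1.5,
                              n_replicates = 3L, seed = 1L,
                              inhibition_fraction = 0.25,
                              allow_cycles = FALSE) {
  p <- list(n_genes = as.integer(n_genes),
            n_pathways = as.integer(n_pathways),
            pathway_size_range = as.integer(pathway_size_range),
            ko_gene = as.character(ko_gene),
            n_positive_pathways = as.integer(n_positive_pathways),
            delta_treatment = delta_treatment, delta_ko = delta_ko,
            noise_sd = noise_sd, baseline_mean = baseline_mean,
            baseline_sd = baseline_sd,
            n_replicates = as.integer(n_replicates),
            seed = as.integer(seed),
            inhibition_fraction = inhibition_fraction,
            allow_cycles = isTRUE(allow_cycles))
  fail <- function(field, why) {
    stop(sprintf("invalid simulation parameter '%s': %s", field, why),
         call. = FALSE)
  }
  if (p$n_positive_pathways > p$n_pathways)
    fail("n_positive_pathways", "must be <= n_pathways")
  if (p$n_positive_pathways < 1L)
    fail("n_positive_pathways", "must be >= 1")
  if (length(p$pathway_size_range) != 2L ||
      p$pathway_size_range[1] > p$pathway_size_range[2])
    fail("pathway_size_range", "must be (min, max) with min <= max")
  if (p$pathway_size_range[1] < 3L)
    fail("pathway_size_range", "min must be >= 3")
  if (!is.finite(p$noise_sd) || p$noise_sd <= 0)
    fail("noise_sd", "must be > 0")
  if (p$n_replicates < 2L)
    fail("n_replicates", "must be >= 2")
  if (p$pathway_size_range[2] > p$n_genes)
    fail("pathway_size_range", "max exceeds n_genes")
  if (!p$ko_gene %in% gene_universe_ids(p$n_genes))
    fail("ko_gene", "not in the generated gene universe")
  if (is.na(p$seed) || abs(p$seed) > 2^30)
    fail("seed", "must be an integer with |seed| <= 2^30")
  structure(p, class = "simulation_params")
}

gene_universe_ids <- function(n_genes) {
  sprintf("g%04d", seq_len(n_genes))
}

# Random DAG on `genes` (given in topological order): every node after the
# first gets one parent among its predecessors (weak connectivity), then
# each node gains extra forward edges, out-degree increment ~ Poisson(2).
random_pathway_dag <- function(genes, inhibition_fraction, allow_cycles) {
  s <- length(genes)
  src_i <- vapply(2:s, function(j) sample.int(j - 1L, 1L), integer(1))
  dst_i <- 2:s
  for (j in seq_len(s - 1L)) {
    d <- stats::rpois(1L, 2)
    if (d > 0L) {
      cand <- setdiff((j + 1L):s, dst_i[src_i == j])
      if (length(cand)) {
        pick <- cand[sample.int(length(cand), min(d, length(cand)))]
        src_i <- c(src_i, rep(j, length(pick)))
        dst_i <- c(dst_i, pick)
      }
    }
  }
  if (allow_cycles && s >= 3L) {
    n_back <- max(1L, stats::rpois(1L, 1))
    for (k in seq_len(n_back)) {
      j <- sample(2:s, 1L)
      i <- sample.int(j - 1L, 1L)
      src_i <- c(src_i, j); dst_i <- c(dst_i, i)
    }
    keep <- !duplicated(cbind(src_i, dst_i))
    src_i <- src_i[keep]; dst_i <- dst_i[keep]
  }
  beta <- ifelse(stats::runif(length(src_i)) < inhibition_fraction, -1, 1)
  data.frame(src = genes[src_i], dst = genes[dst_i], beta = beta,
             subtype = ifelse(beta > 0, "activation", "inhibition"),
             stringsAsFactors = FALSE)
}

# First-path propagated signs: sign(v) = sign(u) * beta(u -> v) along the
# first path from the knockout gene encountered in topological order.
propagated_signs <- function(graph, from) {
  sgn <- stats::setNames(rep(NA_real_, graph$pSize), graph$nodes)
  sgn[from] <- 1
  e <- graph$edges
  for (u in graph$nodes) {          # nodes are stored in topological order
    if (is.na(sgn[u])) next
    out <- e[e$src == u, , drop = FALSE]
    for (k in seq_len(nrow(out))) {
      v <- out$dst[k]
      if (is.na(sgn[v])) sgn[v] <- sgn[u] * out$beta[k]
    }
  }
  sgn[!is.na(sgn)]
}

#' Simulate a pathway collection with planted knockout membership
#'
#' Generates `n_pathways` connected signed DAGs over a shared gene
#' universe (so pathways overlap). Exactly `n_positive_pathways` of them
#' contain the knockout gene, placed at the top of the topological order
#' so it has downstream targets -- the position a receptor-proximal
#' adaptor occupies on a real signaling pathway. The returned truth
#' records, per positive pathway, the genes downstream of the knockout
#' gene and their propagated signs.
#'
#' @param params a [simulation_params()].
#' @return A list with elements `collection` (a [pathway_collection()])
#'   and `truth` (class `planted_truth`: `positive_pathway_ids`,
#'   `ko_gene`, `perturbed_genes`, `perturbed_signs`, `params`).
#' @export
simulate_pathway_collection <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  universe <- gene_universe_ids(params$n_genes)
  others <- setdiff(universe, params$ko_gene)
  ids <- sprintf("path%02d", seq_len(params$n_pathways))
  positive <- sort(sample(ids, params$n_positive_pathways))
  lo <- params$pathway_size_range[1]; hi <- params$pathway_size_range[2]

  graphs <- vector("list", params$n_pathways)
  perturbed_genes <- list()
  perturbed_signs <- list()
  for (i in seq_len(params$n_pathways)) {
    s <- if (lo == hi) lo else sample(lo:hi, 1L)
    is_pos <- ids[i] %in% positive
    genes <- if (is_pos) {
      c(params$ko_gene, sample(others, s - 1L))
    } else {
      sample(others, s)
    }
    edges <- random_pathway_dag(genes, params$inhibition_fraction,
                                params$allow_cycles)
    g <- pathway_graph(ids[i], sprintf("Synthetic pathway %02d", i),
                       genes, edges)
    graphs[[i]] <- g
    if (is_pos) {
      sgn <- propagated_signs(g, params$ko_gene)
      down <- setdiff(names(sgn), params$ko_gene)
      perturbed_genes[[ids[i]]] <- down
      perturbed_signs[[ids[i]]] <- sgn[down]
    }
  }
  truth <- structure(
    list(positive_pathway_ids = positive, ko_gene = params$ko_gene,
         perturbed_genes = perturbed_genes,
         perturbed_signs = perturbed_signs, params = params),
    class = "planted_truth")
  list(collection = pathway_collection(graphs, gene_universe = universe),
       truth = truth)
}

#' Simulate three-group expression with planted effects
#'
#' Produces a log2 expression matrix for three groups of `n_replicates`
#' samples each -- untreated wildtype (`uWT`), septic wildtype (`sWT`)
#' and septic knockout (`sKO`) -- supporting the three standard contrasts
#' A (sKO vs sWT), B (sKO vs uWT) and C (sWT vs uWT). Per-gene baselines
#' are Normal(baseline_mean, baseline_sd^2); replicate noise is i.i.d.
#' Normal(0, noise_sd^2). In septic samples, downstream genes of the
#' knockout gene on positive pathways shift by `sign * delta_treatment`;
#' in knockout samples the knockout gene shifts by `-delta_ko` and its
#' downstream genes by `-sign * delta_ko` (the knocked-out signal no
#' longer reaches them).
#'
#' @param params the same [simulation_params()] used for the collection.
#' @param collection,truth output of [simulate_pathway_collection()].
#' @return An `expression_matrix` object (see [read_expression()]).
#' @export
simulate_expression <- function(params, collection, truth) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(collection, "pathway_collection"),
            inherits(truth, "planted_truth"))
  if (!all(truth$positive_pathway_ids %in% names(collection$graphs)))
    stop("truth/collection mismatch: positive pathway ids absent from collection")
  if (!identical(truth$ko_gene, params$ko_gene))
    stop("truth/collection mismatch: ko_gene differs from params")
  for (pid in truth$positive_pathway_ids) {
    if (!params$ko_gene %in% collection$graphs[[pid]]$nodes)
      stop("truth/collection mismatch: ", pid, " does not contain ko_gene")
  }
  set.seed(params$seed + 1L)  # distinct, derived stream for expression
  genes <- collection$gene_universe
  n_rep <- params$n_replicates
  groups <- c("uWT", "sWT", "sKO")
  samples <- as.vector(vapply(groups, function(g)
    sprintf("%s_%d", g, seq_len(n_rep)), character(n_rep)))
  meta <- data.frame(
    sample = samples,
    genotype = rep(c("WT", "WT", "KO"), each = n_rep),
    treatment = rep(c("untreated", "septic", "septic"), each = n_rep),
    stringsAsFactors = FALSE)

  mu <- stats::rnorm(length(genes), params$baseline_mean, params$baseline_sd)
  X <- matrix(mu, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  X <- X + matrix(stats::rnorm(length(X), 0, params$noise_sd), nrow(X))

  # first-pathway sign wins for genes perturbed on several positive pathways
  sgn <- unlist(truth$perturbed_signs, use.names = FALSE)
  nm <- unlist(lapply(truth$perturbed_signs, names), use.names = FALSE)
  keep <- !duplicated(nm)
  eff <- stats::setNames(sgn[keep], nm[keep])
  eff <- eff[names(eff) %in% genes]

  septic <- meta$treatment == "septic"
  ko <- meta$genotype == "KO"
  if (length(eff)) {
    X[names(eff), septic] <- X[names(eff), septic] +
      eff * params$delta_treatment
    X[names(eff), ko] <- X[names(eff), ko] - eff * params$delta_ko
  }
  X[params$ko_gene, ko] <- X[params$ko_gene, ko] - params$delta_ko
  expression_matrix(X, meta)
}

#' Write a pathway collection as KGML fixture files
#'
#' One well-formed KGML document per pathway, with one `entry` element of
#' type "gene" per node and one `relation` element per signed edge
#' (subtype `activation` or `inhibition`). Files round-trip through
#' [parse_kgml()] to graphs with identical signed edge sets.
#'
#' @param collection a [pathway_collection()].
#' @param directory output directory (created if needed).
#' @return Character vector of file paths, named by pathway id.
#' @export
write_kgml_fixtures <- function(collection, directory) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  paths <- character(0)
  for (g in collection$graphs) {
    doc <- xml2::xml_new_root("pathway",
                              name = paste0("path:", g$pathway_id),
                              org = "syn", number = g$pathway_id,
                              title = g$name)
    node_id <- stats::setNames(seq_along(g$nodes), g$nodes)
    for (gene in g$nodes) {
      xml2::xml_add_child(doc, "entry", id = as.character(node_id[[gene]]),
                          name = gene, type = "gene")
    }
    for (k in seq_len(nrow(g$edges))) {
      rel <- xml2::xml_add_child(
        doc, "relation",
        entry1 = as.character(node_id[[g$edges$src[k]]]),
        entry2 = as.character(node_id[[g$edges$dst[k]]]),
        type = "PPrel")
      xml2::xml_add_child(rel, "subtype", name = g$edges$subtype[k],
                          value = if (g$edges$beta[k] > 0) "-->" else "--|")
    }
    path <- file.path(directory, paste0(g$pathway_id, ".xml"))
    xml2::write_xml(doc, path)
    paths[g$pathway_id] <- path
  }
  paths
}

#' Write the planted truth as JSON
#'
#' @param truth a `planted_truth` from [simulate_pathway_collection()].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(
    list(positive_pathway_ids = truth$positive_pathway_ids,
         ko_gene = truth$ko_gene,
         perturbed_genes = truth$perturbed_genes,
         seed = truth$params$seed,
         params = unclass(truth$params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
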