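#' Signed pathway graphs and the global regulatory network
#'
#' A `pathway_graph` is the package's representation of one signaling
#' pathway: a directed gene graph whose edges carry a sign
#' (beta = +1 activation, -1 inhibition) taken from the KGML relation
#' subtype via a configurable weight table. `pSize` is the number of genes
#' on the pathway and `Nds(g)` the number of outgoing signed edges of gene
#' `g`; both feed the perturbation model in [run_spia()].
#'
#' @param pathway_id single string, unique within a collection.
#' @param name human-readable pathway title.
#' @param nodes character vector of gene ids.
#' @param edges data.frame with columns `src`, `dst`, `beta` (+1/-1) and
#'   `subtype` (relation subtype the sign came from).
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, name, nodes, edges = NULL) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  nodes <- unique(as.character(nodes))
  if (is.null(edges)) {
    edges <- data.frame(src = character(), dst = character(),
                        beta = numeric(), subtype = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("src", "dst", "beta") %in% names(edges)))
  if (!"subtype" %in% names(edges)) {
    edges$subtype <- ifelse(edges$beta >= 0, "activation", "inhibition")
  }
  edges <- edges[, c("src", "dst", "beta", "subtype")]
  if (nrow(edges)) {
    bad <- setdiff(c(edges$src, edges$dst), nodes)
    if (length(bad)) {
      stop("edge endpoints not in node set: ", paste(bad, collapse = ", "))
    }
    key <- paste(edges$src, edges$dst, edges$subtype, sep = "\r")
    if (anyDuplicated(key)) {
      edges <- edges[!duplicated(key), , drop = FALSE]
    }
    if (!all(edges$beta %in% c(-1, 1))) {
      stop("edge beta must be +1 or -1")
    }
  }
  nds <- integer(length(nodes))
  names(nds) <- nodes
  if (nrow(edges)) {
    tab <- table(factor(edges$src, levels = nodes))
    nds[names(tab)] <- as.integer(tab)
  }
  structure(
    list(pathway_id = pathway_id, name = name, nodes = nodes,
         edges = edges, pSize = length(nodes), Nds = nds),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph %s '%s': %d genes, %d signed edges>\n",
              x$pathway_id, x$name, x$pSize, nrow(x$edges)))
  invisible(x)
}

#' Bundle pathway graphs into a collection
#'
#' @param graphs list of [pathway_graph()] objects with unique ids.
#' @param gene_universe optional character vector of all measurable gene
#'   ids; defaults to the union of pathway node sets.
#' @return An object of class `pathway_collection` (a list with elements
#'   `graphs` and `gene_universe`; graphs are named by pathway id).
#' @export
pathway_collection <- function(graphs, gene_universe = NULL) {
  stopifnot(is.list(graphs), length(graphs) >= 1L)
  ok <- vapply(graphs, inherits, logical(1), "pathway_graph")
  if (!all(ok)) stop("all elements must be pathway_graph objects")
  ids <- vapply(graphs, function(g) g$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(graphs) <- ids
  if (is.null(gene_universe)) {
    gene_universe <- sort(unique(unlist(lapply(graphs, `[[`, "nodes"))))
  }
  structure(list(graphs = graphs, gene_universe = unique(gene_universe)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection: %d pathways, %d genes in universe>\n",
              length(x$graphs), length(x$gene_universe)))
  invisible(x)
}

#' Default relation-subtype sign table
#'
#' KGML relation subtypes mapped to edge signs. Subtypes absent from the
#' table (e.g. "binding/association", "indirect effect") are dropped at
#' parse time: their regulatory direction is not defined.
#'
#' @return Named numeric vector mapping subtype name to beta.
#' @export
default_relation_weights <- function() {
  c(activation = 1, expression = 1, inhibition = -1, repression = -1)
}

#' Parse a KGML (KEGG XML) pathway file into a signed graph
#'
#' Entries of type `"gene"` become nodes; an entry listing k gene ids in
#' its `name` attribute expands to k nodes. A relation between two entries
#' expands to the Cartesian product of their gene sets (no intra-entry
#' edges). Group, compound and map entries are ignored. Each relation
#' subtype found in `weight_table` contributes one signed edge per gene
#' pair; unknown subtypes are dropped.
#'
#' @param path KGML file path.
#' @param weight_table named numeric vector, subtype -> beta
#'   (default [default_relation_weights()]).
#' @param strip_prefix drop KEGG organism prefixes such as `"mmu:"` from
#'   gene ids (default `TRUE`).
#' @return A [pathway_graph()].
#' @export
parse_kgml <- function(path, weight_table = default_relation_weights(),
                       strip_prefix = TRUE) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed KGML in '%s': %s", path, conditionMessage(e)))
  })
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop(sprintf("'%s' is not a KGML pathway document", path))
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- tools::file_path_sans_ext(basename(path))
  pid <- sub("^path:", "", pid)
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- pid

  norm <- function(ids) {
    if (strip_prefix) ids <- sub("^[a-zA-Z]+:", "", ids)
    ids
  }
  entries <- xml2::xml_find_all(doc, "/pathway/entry[@type='gene']")
  if (length(entries) == 0L) {
    stop(sprintf("empty pathway: no gene entries in '%s'", path))
  }
  entry_genes <- lapply(entries, function(e) {
    norm(strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1]])
  })
  names(entry_genes) <- xml2::xml_attr(entries, "id")
  nodes <- unique(unlist(entry_genes))

  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  src <- dst <- subtype <- character(0)
  beta <- numeric(0)
  for (r in rels) {
    e1 <- xml2::xml_attr(r, "entry1")
    e2 <- xml2::xml_attr(r, "entry2")
    g1 <- entry_genes[[e1]]
    g2 <- entry_genes[[e2]]
    if (is.null(g1) || is.null(g2)) next  # relation touches a non-gene entry
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "subtype"), "name")
    for (s in subs) {
      if (!s %in% names(weight_table)) next
      pairs <- expand.grid(src = g1, dst = g2,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      src <- c(src, pairs$src)
      dst <- c(dst, pairs$dst)
      beta <- c(beta, rep(unname(weight_table[[s]]), nrow(pairs)))
      subtype <- c(subtype, rep(s, nrow(pairs)))
    }
  }
  pathway_graph(pid, title, nodes,
                data.frame(src = src, dst = dst, beta = beta,
                           subtype = subtype, stringsAsFactors = FALSE))
}

#' Normalized signed influence matrix of a pathway
#'
#' `B[i, j] = beta(j -> i) / Nds(j)`: the influence of gene j on gene i,
#' normalized by j's out-degree so that each column of |B| sums to 1 (or 0
#' for sink genes). This is the propagation operator of the perturbation
#' model: `PF = dE + B %*% PF`.
#'
#' @param p a [pathway_graph()].
#' @return Square numeric matrix with dimnames `p$nodes` x `p$nodes`.
#' @export
build_beta_matrix <- function(p) {
  stopifnot(inherits(p, "pathway_graph"))
  n <- p$pSize
  B <- matrix(0, n, n, dimnames = list(p$nodes, p$nodes))
  if (nrow(p$edges)) {
    w <- p$edges$beta / p$Nds[p$edges$src]
    B[cbind(p$edges$dst, p$edges$src)] <- w
  }
  B
}

#' Merge a pathway collection into one global network
#'
#' Edges are deduplicated on (src, dst); each retained edge remembers the
#' pathways it came from. When two pathways disagree on the sign of the
#' same (src, dst) pair, the sign of the first-listed pathway wins and a
#' warning is emitted (the provenance still lists both pathways).
#'
#' @param collection a [pathway_collection()].
#' @return An object of class `global_network`: a data.frame with columns
#'   `src`, `dst`, `beta` and a list-column `pathways`.
#' @export
merge_global_network <- function(collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  parts <- lapply(collection$graphs, function(g) {
    if (!nrow(g$edges)) return(NULL)
    cbind(g$edges[, c("src", "dst", "beta")],
          pathway = g$pathway_id, stringsAsFactors = FALSE)
  })
  all_e <- do.call(rbind, parts)
  if (is.null(all_e) || !nrow(all_e)) {
    net <- data.frame(src = character(), dst = character(), beta = numeric())
    net$pathways <- list()
    class(net) <- c("global_network", "data.frame")
    return(net)
  }
  key <- paste(all_e$src, all_e$dst, sep = "\r")
  first <- !duplicated(key)
  net <- all_e[first, c("src", "dst", "beta")]
  rownames(net) <- NULL
  km <- split(seq_len(nrow(all_e)), factor(key, levels = key[first]))
  net$pathways <- lapply(km, function(ix) unique(all_e$pathway[ix]))
  conflicts <- vapply(km, function(ix) length(unique(all_e$beta[ix])) > 1L,
                      logical(1))
  if (any(conflicts)) {
    for (ix in which(conflicts)) {
      warning(sprintf(
        "sign conflict on edge %s -> %s; keeping beta = %+d from pathway %s",
        net$src[ix], net$dst[ix], as.integer(net$beta[ix]),
        net$pathways[[ix]][1]), call. = FALSE)
    }
  }
  class(net) <- c("global_network", "data.frame")
  net
}

#' Write pathway collection summaries as TSV
#'
#' @param collection a [pathway_collection()].
#' @param summary_path,edges_path output TSV paths (either may be `NULL`
#'   to skip that file).
#' @return Invisibly, the written paths.
#' @export
write_pathway_tables <- function(collection, summary_path = NULL,
                                 edges_path = NULL) {
  stopifnot(inherits(collection, "pathway_collection"))
  written <- character(0)
  if (!is.null(summary_path)) {
    s <- data.frame(
      pathway_id = vapply(collection$graphs, `[[`, character(1), "pathway_id"),
      name = vapply(collection$graphs, `[[`, character(1), "name"),
      pSize = vapply(collection$graphs, `[[`, integer(1), "pSize"),
      n_edges = vapply(collection$graphs, function(g) nrow(g$edges), integer(1))
    )
    utils::write.table(s, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, summary_path)
  }
  if (!is.null(edges_path)) {
    net <- merge_global_network(collection)
    e <- data.frame(src = net$src, dst = net$dst, beta = net$beta,
                    pathways = vapply(net$pathways, paste,
                                      character(1), collapse = ","))
    utils::write.table(e, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edges_path)
  }
  invisible(written)
}
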