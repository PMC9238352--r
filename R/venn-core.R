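#' Partition three DEG sets into the seven Venn regions
#'
#' @param degsA,degsB,degsC `deg_set` objects (or character vectors of
#'   gene ids) for the three contrasts.
#' @return A `venn_partition`: named list of the seven disjoint regions
#'   `A_only`, `B_only`, `C_only`, `AB_only`, `AC_only`, `BC_only`,
#'   `ABC`, each a sorted character vector.
#' @export
venn_partition <- function(degsA, degsB, degsC) {
  g <- function(x) if (is.data.frame(x)) unique(x$gene) else unique(as.character(x))
  A <- g(degsA); B <- g(degsB); C <- g(degsC)
  all_genes <- union(union(A, B), C)
  inA <- all_genes %in% A; inB <- all_genes %in% B; inC <- all_genes %in% C
  region <- function(keep) sort(all_genes[keep])
  structure(list(
    A_only = region(inA & !inB & !inC),
    B_only = region(!inA & inB & !inC),
    C_only = region(!inA & !inB & inC),
    AB_only = region(inA & inB & !inC),
    AC_only = region(inA & !inB & inC),
    BC_only = region(!inA & inB & inC),
    ABC = region(inA & inB & inC)),
    class = "venn_partition")
}

#' The seven Venn region labels
#' @return Character vector of region labels in canonical order.
#' @export
venn_region_labels <- function() {
  c("A_only", "B_only", "C_only", "AB_only", "AC_only", "BC_only", "ABC")
}

#' Rank the genes of one Venn region
#'
#' The ranking key is, by default, the maximum best-edge-score a gene
#' attains across the contrasts in which it appears (the pipeline's own
#' evidence measure); `key = "min_p"` ranks by smallest p-value instead
#' (then internally negated so larger key = stronger). Ties are broken
#' lexicographically by gene id.
#'
#' @param region character vector of gene ids (one element of
#'   [venn_partition()]).
#' @param deg_sets named list of the contributing `deg_set`s
#'   (e.g. `list(A = ..., B = ..., C = ...)`).
#' @param k how many genes to return (default 50).
#' @param key `"max_best_es"` or `"min_p"`.
#' @param stats_list named list of `contrast_result`s, required for
#'   `key = "min_p"`.
#' @return A `ranked_region` data.frame (`rank`, `gene`, `key`).
#' @export
rank_region <- function(region, deg_sets, k = 50L,
                        key = c("max_best_es", "min_p"),
                        stats_list = NULL) {
  key <- match.arg(key)
  region <- as.character(region)
  if (!length(region)) {
    out <- data.frame(rank = integer(), gene = character(), key = numeric())
    class(out) <- c("ranked_region", "data.frame")
    return(out)
  }
  kv <- vapply(region, function(gene) {
    if (key == "max_best_es") {
      vals <- vapply(deg_sets, function(d) {
        i <- match(gene, d$gene)
        if (is.na(i)) -Inf else d$best_ES[i]
      }, numeric(1))
      max(vals)
    } else {
      if (is.null(stats_list)) stop("key = 'min_p' needs stats_list")
      vals <- vapply(stats_list, function(s) {
        i <- match(gene, s$gene)
        if (is.na(i)) Inf else s$p[i]
      }, numeric(1))
      -min(vals)
    }
  }, numeric(1))
  o <- order(-kv, region)
  top <- utils::head(o, k)
  out <- data.frame(rank = seq_along(top), gene = region[top],
                    key = unname(kv[top]), stringsAsFactors = FALSE)
  class(out) <- c("ranked_region", "data.frame")
  out
}

#' Count distinct genes in a union of Venn regions
#'
#' @param partition a [venn_partition()].
#' @param selection character vector of region labels (subset of
#'   `A_only`, ..., `ABC`).
#' @return Number of distinct genes in the selected regions.
#' @export
core_union_count <- function(partition, selection) {
  stopifnot(inherits(partition, "venn_partition"))
  bad <- setdiff(selection, venn_region_labels())
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  length(unique(unlist(partition[selection], use.names = FALSE)))
}

#' Write the ranked Venn regions as one TSV
#'
#' Columns `region`, `rank`, `gene`, `key` for every non-empty region.
#'
#' @param partition a [venn_partition()].
#' @param deg_sets named list of the three `deg_set`s.
#' @param path output TSV path.
#' @param k top-k per region (default 50).
#' @return Invisibly, `path`.
#' @export
write_venn_table <- function(partition, deg_sets, path, k = 50L) {
  rows <- lapply(venn_region_labels(), function(lbl) {
    contrasts <- strsplit(sub("_only$", "", sub("^ABC$", "ABC", lbl)), "")[[1]]
    r <- rank_region(partition[[lbl]], deg_sets[contrasts], k = k)
    if (!nrow(r)) return(NULL)
    cbind(region = lbl, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(), rank = integer(),
                      gene = character(), key = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
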