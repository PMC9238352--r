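#' Score global-network edges from gene statistics
#'
#' Each measured gene gets a weight `w_g = |lfc_g| * (-log10 p_g)`, the
#' product of effect size and evidence; the score of edge (u, v) is the
#' geometric mean `ES = sqrt(w_u * w_v)`. ES is symmetric in the
#' endpoints and zero exactly when either endpoint carries no evidence
#' (p = 1 or lfc = 0). Edges with an unmeasured endpoint are skipped and
#' counted in attribute `n_skipped`.
#'
#' @param stats a `contrast_result` from [compute_gene_stats()].
#' @param net a `global_network` from [merge_global_network()].
#' @return An `edge_score_table`: data.frame with columns `src`, `dst`,
#'   `w_src`, `w_dst`, `ES`.
#' @export
score_edges <- function(stats, net) {
  stopifnot(inherits(net, "global_network"))
  w <- abs(stats$lfc) * (-log10(stats$p))
  names(w) <- stats$gene
  measured <- !is.na(match(net$src, stats$gene)) &
    !is.na(match(net$dst, stats$gene))
  if (!any(measured))
    stop("no network edge has both endpoints measured")
  n_skipped <- sum(!measured)
  if (n_skipped)
    message(n_skipped, " edge(s) skipped: unmeasured endpoint")
  e <- net[measured, c("src", "dst"), drop = FALSE]
  out <- data.frame(src = e$src, dst = e$dst,
                    w_src = unname(w[e$src]), w_dst = unname(w[e$dst]),
                    stringsAsFactors = FALSE)
  out$ES <- sqrt(out$w_src * out$w_dst)
  rownames(out) <- NULL
  attr(out, "label") <- attr(stats, "label")
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("edge_score_table", "data.frame")
  out
}

# Two-segment Gaussian cost of the descending-sorted sequence x split
# after position k: k*log(var1) + (n-k)*log(var2), variances MLE with a
# small floor. Used both by the detector and (independently, in tests)
# by the exhaustive oracle.
amoc_cost <- function(x, k) {
  n <- length(x)
  v1 <- stats::var(x[1:k]) * (k - 1) / k
  v2 <- stats::var(x[(k + 1):n]) * (n - k - 1) / (n - k)
  k * log(max(v1, 1e-12)) + (n - k) * log(max(v2, 1e-12))
}

#' Find the HES1 threshold by at-most-one-change detection
#'
#' Edge scores are sorted descending and a single change point in mean
#' and variance is located by minimizing the two-segment Gaussian cost
#' (equivalently, maximizing the two-segment log-likelihood) over all
#' admissible splits. The HES1 ("high edge score") threshold is the score
#' at the change-point index; edges scoring at or above it define the
#' High-Edges subnetwork and hence the DEG set. An MBIC-style comparison
#' against the one-segment model is reported as diagnostic flag
#' `mbic_supported`; detection itself is deterministic.
#'
#' @param table an `edge_score_table`, or a bare numeric vector of scores.
#' @param min_segment smallest admissible segment length (default 2).
#' @return A `hes_threshold`: list with `hes1_value`,
#'   `changepoint_index` (rank in the descending-sorted scores),
#'   `n_edges_retained`, and `mbic_supported`.
#' @export
find_hes_threshold <- function(table, min_segment = 2L) {
  scores <- if (is.numeric(table)) table else table$ES
  n <- length(scores)
  if (n < 20L)
    stop("need >= 20 scored edges to locate a threshold (got ", n,
         "); pass an explicit cutoff instead")
  if (diff(range(scores)) == 0)
    stop("all edge scores are equal; no change point exists")
  x <- sort(scores, decreasing = TRUE)
  ks <- min_segment:(n - min_segment)
  # O(n) segment variances via cumulative sums
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  v1 <- pmax(cs2[ks] / ks - (cs[ks] / ks)^2, 1e-12)
  n2 <- n - ks
  v2 <- pmax((cs2[n] - cs2[ks]) / n2 - ((cs[n] - cs[ks]) / n2)^2, 1e-12)
  cost <- ks * log(v1) + n2 * log(v2)
  k <- ks[which.min(cost)]
  null_cost <- n * log(max(stats::var(x) * (n - 1) / n, 1e-12))
  # MBIC penalty for adding one change (3 extra params) plus segment terms
  penalty <- 4 * log(n) + log(k) + log(n - k)
  hes1 <- x[k]
  structure(list(hes1_value = hes1, changepoint_index = k,
                 n_edges_retained = sum(scores >= hes1),
                 mbic_supported = (null_cost - min(cost)) > penalty),
            class = "hes_threshold")
}

#' @export
print.hes_threshold <- function(x, ...) {
  cat(sprintf("<hes_threshold: HES1 = %.4g at rank %d, %d edges retained%s>\n",
              x$hes1_value, x$changepoint_index, x$n_edges_retained,
              if (isTRUE(x$mbic_supported)) "" else " (weak MBIC support)"))
  invisible(x)
}

#' Select DEGs incident to retained high-score edges
#'
#' A gene is a DEG when it touches at least one edge with
#' `ES >= hes1_value`. Each DEG carries its log2 fold-change from `stats`
#' and its best (maximum) incident edge score, the ranking key used by
#' the Venn stage.
#'
#' @param table an `edge_score_table`.
#' @param threshold a `hes_threshold`, or a single numeric cutoff.
#' @param stats the `contrast_result` the table was scored from.
#' @return A `deg_set`: data.frame with columns `gene`, `lfc`, `best_ES`.
#' @export
select_degs <- function(table, threshold, stats) {
  cut <- if (inherits(threshold, "hes_threshold")) threshold$hes1_value
         else as.numeric(threshold)
  kept <- table[table$ES >= cut, , drop = FALSE]
  if (nrow(kept) == 0L) {
    out <- data.frame(gene = character(), lfc = numeric(),
                      best_ES = numeric(), stringsAsFactors = FALSE)
  } else {
    long <- data.frame(gene = c(kept$src, kept$dst),
                       ES = rep(kept$ES, 2), stringsAsFactors = FALSE)
    best <- tapply(long$ES, long$gene, max)
    genes <- sort(names(best))
    lfc <- stats$lfc[match(genes, stats$gene)]
    out <- data.frame(gene = genes, lfc = lfc,
                      best_ES = as.numeric(best[genes]),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "label") <- attr(table, "label")
  attr(out, "hes1_value") <- cut
  class(out) <- c("deg_set", "data.frame")
  out
}

#' Export the High-Edges subnetwork and edge-score histogram
#'
#' The data behind the two standard diagnostic panels: a table of edges
#' at or above the threshold, and a histogram of all edge scores.
#'
#' @param table an `edge_score_table`.
#' @param threshold a `hes_threshold` or numeric cutoff.
#' @param n_bins suggested histogram bin count.
#' @param edges_path optional TSV path for the retained edges.
#' @return List with `edges` (data.frame) and `histogram`
#'   (list of `breaks`, `counts`).
#' @export
high_edges_export <- function(table, threshold, n_bins = 50L,
                              edges_path = NULL) {
  cut <- if (inherits(threshold, "hes_threshold")) threshold$hes1_value
         else as.numeric(threshold)
  kept <- as.data.frame(table)[table$ES >= cut, , drop = FALSE]
  rownames(kept) <- NULL
  h <- graphics::hist(table$ES, breaks = n_bins, plot = FALSE)
  if (!is.null(edges_path)) {
    utils::write.table(kept, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(edges = kept, histogram = list(breaks = h$breaks, counts = h$counts))
}
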