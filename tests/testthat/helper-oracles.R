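# Brute-force oracles, kept deliberately independent of the package's
# implementation paths, plus tiny graph builders shared across test files.

# chain pathway A -> B -> C -> ... with given edge signs
chain_graph <- function(betas, id = "chain") {
  n <- length(betas) + 1L
  nodes <- LETTERS[seq_len(n)]
  pathway_graph(id, id, nodes,
                data.frame(src = nodes[-n], dst = nodes[-1], beta = betas,
                           stringsAsFactors = FALSE))
}

# small random DAG pathway for property tests
random_dag_graph <- function(n_nodes, id = "dag", p_edge = 0.5,
                             p_inhib = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  src <- dst <- character(0)
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) {
        src <- c(src, nodes[i]); dst <- c(dst, nodes[j])
      }
    }
  }
  beta <- ifelse(stats::runif(length(src)) < p_inhib, -1, 1)
  pathway_graph(id, id, nodes,
                if (length(src)) data.frame(src = src, dst = dst, beta = beta,
                                            stringsAsFactors = FALSE)
                else NULL)
}

# PF by explicit enumeration of all directed paths:
# PF(i) = dE(i) + sum_paths j~>i dE(j) * prod(beta/Nds) along the path
oracle_pf_paths <- function(g, dE) {
  e <- g$edges
  w <- if (nrow(e)) e$beta / g$Nds[e$src] else numeric(0)
  PF <- stats::setNames(as.numeric(dE[g$nodes]), g$nodes)
  walk <- function(u, wt, source_dE) {
    out <- which(e$src == u)
    for (k in out) {
      v <- e$dst[k]
      wv <- wt * w[k]
      PF[v] <<- PF[v] + source_dE * wv
      walk(v, wv, source_dE)
    }
  }
  for (j in g$nodes) {
    if (dE[j] != 0) walk(j, 1, dE[j])
  }
  PF
}

# exhaustive two-segment Gaussian log-likelihood scan on the
# descending-sorted sequence; returns the maximizing split index
oracle_amoc_split <- function(scores, min_seg = 2L) {
  x <- sort(scores, decreasing = TRUE)
  n <- length(x)
  ks <- min_seg:(n - min_seg)
  ll <- vapply(ks, function(k) {
    a <- x[1:k]; b <- x[(k + 1):n]
    v1 <- mean((a - mean(a))^2); v2 <- mean((b - mean(b))^2)
    -(k * log(max(v1, 1e-12)) + (n - k) * log(max(v2, 1e-12)))
  }, numeric(1))
  ks[which.max(ll)]
}

# concordant-pair AUC (orientation: lower score = positive call)
oracle_auc_pairs <- function(pos_scores, neg_scores) {
  s <- 0
  for (a in pos_scores) for (b in neg_scores)
    s <- s + (a < b) + 0.5 * (a == b)
  s / (length(pos_scores) * length(neg_scores))
}

# hand-applied Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive hypergeometric upper tail
oracle_pnde <- function(nde, K, draws, N) {
  if (nde == 0) return(1)
  ks <- nde:min(K, draws)
  sum(choose(K, ks) * choose(N - K, draws - ks)) / choose(N, draws)
}

# tiny benchmark constructor from raw vectors
make_benchmark <- function(pos_scores, neg_scores) {
  ids <- sprintf("p%03d", seq_len(length(pos_scores) + length(neg_scores)))
  labels <- data.frame(
    pathway_id = ids,
    label = rep(c("positive", "negative"),
                c(length(pos_scores), length(neg_scores))),
    stringsAsFactors = FALSE)
  ko_benchmark(labels, stats::setNames(c(pos_scores, neg_scores), ids))
}

# small simulation used by several files; cheap but non-trivial
small_sim_params <- function(seed = 11L, ...) {
  simulation_params(n_genes = 600L, n_pathways = 12L,
                    pathway_size_range = c(10L, 20L),
                    n_positive_pathways = 3L, seed = seed, ...)
}
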