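#' Per-pathway signed perturbation input
#'
#' `dE(g)` equals the DEG's log2 fold-change for genes in the DEG set
#' that lie on the pathway, and 0 elsewhere; `NDE` counts the DEGs on
#' the pathway.
#'
#' @param degs a `deg_set` from [select_degs()] (or any data.frame with
#'   `gene` and `lfc`).
#' @param p a [pathway_graph()].
#' @return List with `dE` (named numeric over `p$nodes`) and `NDE`.
#' @export
delta_e <- function(degs, p) {
  stopifnot(inherits(p, "pathway_graph"))
  dE <- stats::setNames(numeric(p$pSize), p$nodes)
  hit <- intersect(degs$gene, p$nodes)
  dE[hit] <- degs$lfc[match(hit, degs$gene)]
  list(dE = dE, NDE = length(hit))
}

#' Propagate perturbation through the signed topology
#'
#' Solves the perturbation fixed point `PF = dE + B PF`, i.e.
#' `PF = (I - B)^{-1} dE`: each gene's net perturbation factor is its own
#' input plus the normalized signed influence of its upstream genes. The
#' accumulated perturbation is `Acc = PF - dE` and the pathway's total
#' accumulation `tA = sum(Acc)`.
#'
#' @param B influence matrix from [build_beta_matrix()].
#' @param dE named perturbation input over the same genes.
#' @return List with `PF`, `Acc`, `tA`.
#' @export
net_perturbation <- function(B, dE) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B), length(dE) == nrow(B))
  A <- diag(nrow(B)) - B
  d <- det(A)
  if (!is.finite(d) || abs(d) <= 1e-12) {
    stop(errorCondition("pathway not computable: I - B is singular",
                        class = "kopb_singular"))
  }
  PF <- as.numeric(solve(A, dE))
  names(PF) <- names(dE)
  Acc <- PF - dE
  list(PF = PF, Acc = Acc, tA = sum(Acc))
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least `NDE` DEGs on a pathway
#' of `pSize_measured` measured genes, when `n_deg_total` DEGs were drawn
#' from a universe of `n_universe` genes. `NDE = 0` returns 1.
#'
#' @param NDE DEGs on the pathway.
#' @param pSize_measured measured pathway genes.
#' @param n_deg_total total DEGs in the universe.
#' @param n_universe universe size.
#' @return The p-value P(X >= NDE), in (0, 1].
#' @export
p_nde <- function(NDE, pSize_measured, n_deg_total, n_universe) {
  if (NDE > min(pSize_measured, n_deg_total) ||
      pSize_measured > n_universe || n_deg_total > n_universe || NDE < 0)
    stop(sprintf(
      "inconsistent counts: NDE=%d pathway=%d degs=%d universe=%d",
      NDE, pSize_measured, n_deg_total, n_universe))
  if (NDE == 0L) return(1)
  p <- stats::phyper(NDE - 1, pSize_measured, n_universe - pSize_measured,
                     n_deg_total, lower.tail = FALSE)
  min(max(p, 1e-300), 1)
}

# tA is linear in dE: tA = sum_g coef[g] * dE[g] with
# coef = colSums((I - B)^{-1} - I). Precomputing coef makes the bootstrap
# a pure sampling exercise.
ta_coefficients <- function(B) {
  A <- diag(nrow(B)) - B
  d <- det(A)
  if (!is.finite(d) || abs(d) <= 1e-12) return(NULL)
  M <- solve(A)
  stats::setNames(colSums(M - diag(nrow(B))), colnames(B))
}

#' Bootstrap p-value of the total accumulated perturbation
#'
#' The null distribution of `tA` is built by `n_boot` resamples, each
#' placing `NDE` fold-changes (drawn with replacement from the full DEG
#' fold-change pool) on `NDE` uniformly chosen distinct pathway genes and
#' recomputing `tA`. The two-sided p-value uses the add-one estimator
#' around the null median, so it is never 0:
#' `pPERT = (1 + #(|tA_null - med| >= |tA_obs - med|)) / (n_boot + 1)`.
#' Status is `Activated` when `tA_obs` exceeds the null median,
#' `Inhibited` otherwise.
#'
#' @param p a [pathway_graph()].
#' @param degs a `deg_set`; its `lfc` column is the resampling pool.
#' @param n_boot number of resamples (>= 200; default 2000).
#' @param seed integer seed for the resampling stream.
#' @return List with `pPERT`, `status` (`NA` when `NDE = 0`), `tA_obs`,
#'   `tA_null_median`, `NDE`.
#' @export
p_pert <- function(p, degs, n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(p, "pathway_graph"))
  if (n_boot < 200L) stop("n_boot must be >= 200")
  de <- delta_e(degs, p)
  if (de$NDE == 0L) {
    return(list(pPERT = 1, status = NA_character_, tA_obs = 0,
                tA_null_median = 0, NDE = 0L))
  }
  B <- build_beta_matrix(p)
  coef <- ta_coefficients(B)
  if (is.null(coef)) {
    stop(errorCondition("pathway not computable: I - B is singular",
                        class = "kopb_singular"))
  }
  tA_obs <- sum(coef * de$dE)
  pool <- degs$lfc
  set.seed(seed)
  nde <- de$NDE
  tA_null <- vapply(seq_len(n_boot), function(b) {
    genes <- sample.int(p$pSize, nde)
    sum(coef[genes] * pool[sample.int(length(pool), nde, replace = TRUE)])
  }, numeric(1))
  med <- stats::median(tA_null)
  pPERT <- (1 + sum(abs(tA_null - med) >= abs(tA_obs - med))) / (n_boot + 1)
  list(pPERT = pPERT,
       status = if (tA_obs > med) "Activated" else "Inhibited",
       tA_obs = tA_obs, tA_null_median = med, NDE = nde)
}

#' Combine over-representation and perturbation evidence
#'
#' With `c = pNDE * pPERT`, the combined p-value is
#' `pG = c - c * log(c)`: the probability that the product of two
#' independent Uniform(0,1) variables falls at or below `c`. Monotone in
#' both inputs and continuous at `c = 1`.
#'
#' @param pNDE,pPERT p-values in (0, 1] (vectorized).
#' @return `pG` in (0, 1].
#' @export
combine_pg <- function(pNDE, pPERT) {
  if (any(pNDE <= 0 | pNDE > 1) || any(pPERT <= 0 | pPERT > 1))
    stop("pNDE and pPERT must lie in (0, 1]")
  cc <- pNDE * pPERT
  pmin(cc - cc * log(cc), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Step-up adjusted values, capped at 1.
#' @export
fdr_bh <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score every pathway of a collection (the per-pathway results table)
#'
#' For each computable pathway: `NDE` and hypergeometric `pNDE`
#' (universe = measured genes mapping to at least one pathway, unless
#' overridden), bootstrap `pPERT` with total accumulation `tA` and
#' Activated/Inhibited status, combined `pG` and BH-adjusted `pGFdr`.
#' Pathways whose `I - B` is singular are excluded and listed in
#' attribute `excluded`. Rows are sorted ascending by `pGFdr`.
#'
#' @param collection a [pathway_collection()].
#' @param stats the `contrast_result` (defines the measured genes).
#' @param degs the `deg_set` for the same contrast.
#' @param universe optional explicit universe of gene ids.
#' @param n_boot,seed bootstrap controls; each pathway uses the derived
#'   seed `seed + <pathway position>` so results are order- and
#'   parallelization-independent.
#' @return A `spia_result` data.frame with columns `ID`, `Name`,
#'   `Status`, `pSize`, `NDE`, `DEG_pct`, `tA`, `pNDE`, `pPERT`, `pG`,
#'   `pGFdr`.
#' @export
run_spia <- function(collection, stats, degs, universe = NULL,
                     n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(collection, "pathway_collection"))
  measured <- stats$gene
  if (is.null(universe)) {
    on_pathway <- unique(unlist(lapply(collection$graphs, `[[`, "nodes")))
    universe <- intersect(measured, on_pathway)
  }
  n_universe <- length(universe)
  deg_in_universe <- intersect(degs$gene, universe)
  n_deg_total <- length(deg_in_universe)

  rows <- list(); excluded <- character(0)
  for (i in seq_along(collection$graphs)) {
    g <- collection$graphs[[i]]
    pert <- tryCatch(p_pert(g, degs, n_boot = n_boot, seed = seed + i),
                     kopb_singular = function(e) NULL)
    if (is.null(pert)) {
      excluded <- c(excluded, g$pathway_id)
      message("pathway ", g$pathway_id, " excluded: I - B singular")
      next
    }
    pSize_measured <- length(intersect(g$nodes, universe))
    nde <- length(intersect(degs$gene, intersect(g$nodes, universe)))
    pnde <- p_nde(nde, pSize_measured, n_deg_total, n_universe)
    rows[[g$pathway_id]] <- data.frame(
      ID = g$pathway_id, Name = g$name, Status = pert$status,
      pSize = g$pSize, NDE = pert$NDE,
      DEG_pct = round_half_away(100 * pert$NDE / g$pSize, 1),
      tA = pert$tA_obs, pNDE = pnde, pPERT = pert$pPERT,
      pG = combine_pg(pnde, pert$pPERT),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no computable pathway in collection")
  out$pGFdr <- fdr_bh(out$pG)
  out <- out[order(out$pGFdr, out$pG, out$ID), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "label") <- attr(degs, "label")
  attr(out, "n_universe") <- n_universe
  attr(out, "n_deg_total") <- n_deg_total
  class(out) <- c("spia_result", "data.frame")
  out
}

#' Write a pathway scoring table as TSV
#'
#' @param res a `spia_result` from [run_spia()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_spia_results <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
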