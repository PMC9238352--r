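#' Label pathways by knockout-gene membership
#'
#' Ground truth for benchmarking: a pathway is a positive exactly when it
#' contains the knockout gene. Labels depend only on topology, never on
#' scores.
#'
#' @param collection a [pathway_collection()].
#' @param ko_gene knockout gene id.
#' @return data.frame with columns `pathway_id`, `label`
#'   (`"positive"`/`"negative"`).
#' @export
label_pathways_by_ko_gene <- function(collection, ko_gene) {
  stopifnot(inherits(collection, "pathway_collection"),
            is.character(ko_gene), nzchar(ko_gene))
  pos <- vapply(collection$graphs, function(g) ko_gene %in% g$nodes,
                logical(1))
  if (!any(pos))
    stop("knockout gene '", ko_gene, "' absent from every pathway")
  if (all(pos))
    stop("knockout gene '", ko_gene, "' present on every pathway; ",
         "ROC is undefined without negatives")
  data.frame(pathway_id = names(collection$graphs),
             label = ifelse(pos, "positive", "negative"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble a knockout benchmark
#'
#' Pairs ground-truth labels with per-pathway p-values. Orientation is
#' fixed: smaller score = stronger positive call.
#'
#' @param labels data.frame from [label_pathways_by_ko_gene()].
#' @param scores named numeric vector of p-values (names = pathway ids),
#'   or a data.frame with columns `pathway_id` and `p`.
#' @return A `ko_benchmark` data.frame (`pathway_id`, `label`, `score`).
#'   Pathways without a score (e.g. flagged not computable) are dropped
#'   and counted in attribute `n_excluded`.
#' @export
ko_benchmark <- function(labels, scores) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$p, scores$pathway_id)
  }
  stray <- setdiff(names(scores), labels$pathway_id)
  if (length(stray))
    stop("scored pathway id(s) not in collection: ",
         paste(stray, collapse = ", "))
  s <- scores[match(labels$pathway_id, names(scores))]
  keep <- !is.na(s)
  out <- data.frame(pathway_id = labels$pathway_id[keep],
                    label = labels$label[keep], score = as.numeric(s[keep]),
                    stringsAsFactors = FALSE)
  if (!any(out$label == "positive") || !any(out$label == "negative"))
    stop("benchmark needs at least one positive and one negative pathway")
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("ko_benchmark", "data.frame")
  out
}

# midpoint thresholds between adjacent distinct scores, plus sentinels
# below the minimum (call nothing) and at the maximum (call everything)
candidate_thresholds <- function(scores) {
  d <- sort(unique(scores))
  mids <- if (length(d) > 1) (d[-length(d)] + d[-1]) / 2 else numeric(0)
  gap <- if (length(d) > 1) (d[2] - d[1]) / 2 else max(abs(d[1]) / 2, 0.5)
  c(d[1] - gap, mids, d[length(d)])
}

sens_spec_at <- function(bm, thr) {
  pos <- bm$label == "positive"
  call_pos <- bm$score <= thr
  c(sens = sum(call_pos & pos) / sum(pos),
    spec = sum(!call_pos & !pos) / sum(!pos))
}

#' ROC curve over all distinct p-value thresholds
#'
#' A pathway is called positive when its p-value is at or below the
#' threshold; the curve is traced over midpoints between adjacent
#' distinct scores plus the two trivial endpoints.
#'
#' @param bm a [ko_benchmark()].
#' @return A `roc_curve` data.frame (`threshold`, `sensitivity`,
#'   `specificity`) ordered from (0, 1) to (1, 0).
#' @export
roc_curve <- function(bm) {
  stopifnot(inherits(bm, "ko_benchmark"))
  thr <- candidate_thresholds(bm$score)
  ss <- t(vapply(thr, function(t) sens_spec_at(bm, t), numeric(2)))
  out <- data.frame(threshold = thr, sensitivity = ss[, "sens"],
                    specificity = ss[, "spec"])
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve with a DeLong confidence interval
#'
#' The AUC is the Mann-Whitney statistic (probability a random positive
#' scores below a random negative, ties counted 0.5), identical to the
#' trapezoidal area under [roc_curve()]. The confidence interval uses
#' DeLong's asymptotic variance of the placement values; with perfect
#' separation the variance is zero and the interval degenerates to
#' `[auc, auc]` (flagged by `degenerate`).
#'
#' @param bm a [ko_benchmark()].
#' @param level confidence level (default 0.95).
#' @return List with `auc`, `ci_low`, `ci_high`, `se`, `degenerate`.
#' @export
auc_delong <- function(bm, level = 0.95) {
  stopifnot(inherits(bm, "ko_benchmark"))
  x <- -bm$score[bm$label == "positive"]  # higher = stronger positive
  y <- -bm$score[bm$label == "negative"]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # placement of each positive among negatives
  v01 <- colMeans(psi)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  varhat <- s10 / m + s01 / n
  if (varhat <= 0) {
    return(list(auc = auc, ci_low = auc, ci_high = auc, se = 0,
                degenerate = TRUE))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(varhat)
  list(auc = auc, ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se), se = se, degenerate = FALSE)
}

# integral of y dx over a polyline clipped to x in [x0, x1], with linear
# interpolation at the clip boundaries; vertices must be sorted by x
polyline_area <- function(x, y, x0, x1) {
  area <- 0
  for (k in seq_len(length(x) - 1)) {
    xa <- x[k]; xb <- x[k + 1]
    if (xb <= x0 || xa >= x1 || xa == xb) next
    lo <- max(xa, x0); hi <- min(xb, x1)
    ya <- y[k] + (y[k + 1] - y[k]) * (lo - xa) / (xb - xa)
    yb <- y[k] + (y[k + 1] - y[k]) * (hi - xa) / (xb - xa)
    area <- area + (hi - lo) * (ya + yb) / 2
  }
  area
}

#' Partial AUC over a high-specificity or high-sensitivity region
#'
#' Restricts the area to specificity (or sensitivity) within `bounds`
#' (default the 90-100% region), interpolating the curve linearly at the
#' region boundary. The corrected form is the McClish standardization
#' `(1 + (pA - pA_min) / (pA_max - pA_min)) / 2`, mapping chance to 0.5
#' and a perfect classifier to 1, with `pA_max` the region width and
#' `pA_min = width^2 / 2`.
#'
#' @param bm a [ko_benchmark()].
#' @param region `"specificity"` or `"sensitivity"`.
#' @param bounds region bounds, default `c(0.9, 1)`.
#' @param corrected apply the McClish standardization.
#' @return The (possibly corrected) partial area.
#' @export
partial_auc <- function(bm, region = c("specificity", "sensitivity"),
                        bounds = c(0.9, 1), corrected = FALSE) {
  region <- match.arg(region)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2],
            bounds[1] >= 0, bounds[2] <= 1)
  if (bounds[1] == bounds[2]) stop("empty partial-AUC region")
  rc <- roc_curve(bm)
  if (region == "specificity") {
    # area under sens vs (1 - spec), for FPR in [1 - b2, 1 - b1]
    x <- 1 - rc$specificity; y <- rc$sensitivity
    o <- order(x, y)
    pa <- polyline_area(x[o], y[o], 1 - bounds[2], 1 - bounds[1])
  } else {
    # area under spec vs sens, for sens in [b1, b2]
    x <- rc$sensitivity; y <- rc$specificity
    o <- order(x, -y)
    pa <- polyline_area(x[o], y[o], bounds[1], bounds[2])
  }
  if (!corrected) return(pa)
  width <- bounds[2] - bounds[1]
  pa_max <- width
  pa_min <- width^2 / 2
  (1 + (pa - pa_min) / (pa_max - pa_min)) / 2
}

#' Youden's optimal operating point
#'
#' Maximizes `J = sensitivity + specificity - 1` over the candidate
#' thresholds (midpoints between adjacent distinct scores plus the
#' trivial endpoints). Ties on J are broken by higher specificity, then
#' by lower threshold.
#'
#' @param bm a [ko_benchmark()].
#' @return List with `threshold`, `sens`, `spec`, `J`.
#' @export
youden_best <- function(bm) {
  stopifnot(inherits(bm, "ko_benchmark"))
  thr <- candidate_thresholds(bm$score)
  ss <- t(vapply(thr, function(t) sens_spec_at(bm, t), numeric(2)))
  J <- ss[, "sens"] + ss[, "spec"] - 1
  o <- order(-J, -ss[, "spec"], thr)
  best <- o[1]
  list(threshold = thr[best], sens = unname(ss[best, "sens"]),
       spec = unname(ss[best, "spec"]), J = unname(J[best]))
}

#' Full ROC metric panel for one method's p-value table
#'
#' The benchmarking harness: given any per-pathway p-value table (this
#' package's `pG` column, or an external method's output), computes AUC
#' with DeLong 95% CI, partial AUCs over the 90-100% specificity and
#' sensitivity regions in original and corrected formats, and Youden's
#' best operating point, against knockout-gene ground truth.
#'
#' @param collection a [pathway_collection()].
#' @param ko_gene knockout gene id defining the positives.
#' @param score_table named numeric p-values or data.frame
#'   (`pathway_id`, `p`); ids must belong to the collection.
#' @param level confidence level for the AUC interval.
#' @return A `roc_summary` list: `auc`, `ci_low`, `ci_high`, `pauc_sp`,
#'   `pauc_se`, `pauc_sp_corrected`, `pauc_se_corrected`,
#'   `youden_threshold`, `youden_sens`, `youden_spec`, `n_positive`,
#'   `n_negative`, `n_excluded`.
#' @export
evaluate_method_scores <- function(collection, ko_gene, score_table,
                                   level = 0.95) {
  labels <- label_pathways_by_ko_gene(collection, ko_gene)
  bm <- ko_benchmark(labels, score_table)
  summarize_benchmark(bm, level = level)
}

#' @rdname evaluate_method_scores
#' @param bm a prebuilt [ko_benchmark()].
#' @export
summarize_benchmark <- function(bm, level = 0.95) {
  a <- auc_delong(bm, level = level)
  yb <- youden_best(bm)
  structure(list(
    auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
    pauc_sp = partial_auc(bm, "specificity"),
    pauc_se = partial_auc(bm, "sensitivity"),
    pauc_sp_corrected = partial_auc(bm, "specificity", corrected = TRUE),
    pauc_se_corrected = partial_auc(bm, "sensitivity", corrected = TRUE),
    youden_threshold = yb$threshold, youden_sens = yb$sens,
    youden_spec = yb$spec,
    n_positive = sum(bm$label == "positive"),
    n_negative = sum(bm$label == "negative"),
    n_excluded = attr(bm, "n_excluded") %||% 0L),
    class = "roc_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(
    "<roc_summary: AUC %.3f [%.3f, %.3f], pAUC_SP %.4f (corr %.3f), pAUC_SE %.4f (corr %.3f), Youden p* = %.3g (sens %.2f, spec %.2f)>\n",
    x$auc, x$ci_low, x$ci_high, x$pauc_sp, x$pauc_sp_corrected,
    x$pauc_se, x$pauc_se_corrected, x$youden_threshold,
    x$youden_sens, x$youden_spec))
  invisible(x)
}

#' Write ROC outputs
#'
#' @param summary a `roc_summary`.
#' @param bm the underlying [ko_benchmark()].
#' @param summary_path JSON path for the metric panel.
#' @param points_path TSV path for the ROC points.
#' @return Invisibly, the written paths.
#' @export
write_roc_outputs <- function(summary, bm, summary_path = NULL,
                              points_path = NULL) {
  written <- character(0)
  if (!is.null(summary_path)) {
    jsonlite::write_json(unclass(summary), summary_path,
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, summary_path)
  }
  if (!is.null(points_path)) {
    utils::write.table(as.data.frame(roc_curve(bm)), points_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, points_path)
  }
  invisible(written)
}
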