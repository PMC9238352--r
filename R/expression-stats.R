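#' Annotated log2 expression matrix
#'
#' Thin container pairing a numeric log2 intensity matrix (rows = genes,
#' columns = samples) with sample annotations (`genotype`, `treatment`).
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param metadata data.frame with columns `sample`, `genotype`,
#'   `treatment` covering every column of `values`.
#' @param allow_duplicates permit duplicate gene ids (probe-level data);
#'   downstream statistics refuse such a matrix until probes are
#'   collapsed with [collapse_probes()].
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata, allow_duplicates = FALSE) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!allow_duplicates && anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene ids (collapse must be explicit, see collapse_probes): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "genotype", "treatment") %in% names(metadata)))
  missing <- setdiff(colnames(values), metadata$sample)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(metadata$sample, colnames(values))
  if (length(unknown))
    stop("unknown sample(s) in metadata: ", paste(unknown, collapse = ", "))
  metadata <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d samples (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s/%s", x$metadata$genotype, x$metadata$treatment),
                    collapse = ", ")))
  invisible(x)
}

#' Read expression and sample-metadata TSV files
#'
#' The expression TSV has a first column `gene` followed by one numeric
#' column per sample; the metadata TSV has columns `sample`, `genotype`,
#' `treatment`. Row order is preserved. Non-numeric cells and samples
#' missing from the metadata are reported by name.
#'
#' @param expr_path,meta_path input TSV paths.
#' @param allow_duplicates see [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expr_path, meta_path, allow_duplicates = FALSE) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene")
    stop("expression TSV must start with a 'gene' column, got '",
         names(df)[1], "'")
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric expression value at row %d, column '%s'",
                     bad[1], names(vals)[j]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_matrix(m, meta, allow_duplicates = allow_duplicates)
}

#' Write an expression matrix and its metadata as TSV
#'
#' @param em an [expression_matrix()].
#' @param expr_path,meta_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(em, expr_path, meta_path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, meta_path))
}

#' Collapse duplicate probe rows to one row per gene
#'
#' @param em an [expression_matrix()] built with `allow_duplicates = TRUE`.
#' @param rule `"max_mean"` keeps, per gene, the probe row with the
#'   highest mean intensity; `"median"` takes the per-sample median across
#'   that gene's probes.
#' @return An [expression_matrix()] with unique gene rows.
#' @export
collapse_probes <- function(em, rule = c("max_mean", "median")) {
  stopifnot(inherits(em, "expression_matrix"))
  rule <- match.arg(rule)
  v <- em$values
  if (!anyDuplicated(rownames(v)))
    return(expression_matrix(v, em$metadata))
  genes <- rownames(v)
  keep_order <- unique(genes)
  rows <- lapply(keep_order, function(g) {
    ix <- which(genes == g)
    if (length(ix) == 1L) return(v[ix, ])
    block <- v[ix, , drop = FALSE]
    if (rule == "max_mean") {
      block[which.max(rowMeans(block)), ]
    } else {
      apply(block, 2, stats::median)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- keep_order
  expression_matrix(out, em$metadata)
}

#' Specify a two-group contrast
#'
#' @param label contrast label, conventionally `"A"`, `"B"` or `"C"`.
#' @param case,reference lists with elements `genotype` and `treatment`.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(label, case, reference) {
  stopifnot(is.list(case), is.list(reference),
            all(c("genotype", "treatment") %in% names(case)),
            all(c("genotype", "treatment") %in% names(reference)))
  if (identical(case[c("genotype", "treatment")],
                reference[c("genotype", "treatment")]))
    stop("case and reference groups must differ")
  structure(list(label = label, case = case, reference = reference),
            class = "contrast_spec")
}

#' The three standard knockout-study contrasts
#'
#' A: septic KO vs septic WT; B: septic KO vs untreated WT;
#' C: septic WT vs untreated WT.
#'
#' @return Named list of three [contrast_spec()] objects.
#' @export
default_contrasts <- function() {
  g <- function(genotype, treatment) list(genotype = genotype,
                                          treatment = treatment)
  list(A = contrast_spec("A", g("KO", "septic"), g("WT", "septic")),
       B = contrast_spec("B", g("KO", "septic"), g("WT", "untreated")),
       C = contrast_spec("C", g("WT", "septic"), g("WT", "untreated")))
}

group_columns <- function(em, grp) {
  which(em$metadata$genotype == grp$genotype &
          em$metadata$treatment == grp$treatment)
}

#' Per-gene two-group statistics (Welch t-test)
#'
#' Computes, for every gene, the log2 fold-change (case mean minus
#' reference mean) and a two-sided Welch unequal-variance t-test p-value.
#' A variance floor of 1e-8 on the squared standard error keeps constant
#' genes testable (degrees of freedom then fall back to the pooled
#' n1 + n2 - 2); p-values are floored at 1e-300 so -log10(p) is finite.
#'
#' @param em an [expression_matrix()] with unique gene rows.
#' @param contrast a [contrast_spec()].
#' @return A `contrast_result`: data.frame with columns `gene`, `lfc`,
#'   `p` and attribute `label`.
#' @export
compute_gene_stats <- function(em, contrast) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(contrast, "contrast_spec"))
  if (anyDuplicated(rownames(em$values)))
    stop("duplicate gene ids; collapse probes first")
  i1 <- group_columns(em, contrast$case)
  i2 <- group_columns(em, contrast$reference)
  if (length(i1) < 2L || length(i2) < 2L)
    stop(sprintf("contrast %s needs >= 2 samples per group (case %d, reference %d)",
                 contrast$label, length(i1), length(i2)))
  x1 <- em$values[, i1, drop = FALSE]
  x2 <- em$values[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  floored <- se2 < 1e-8
  se2[floored] <- 1e-8
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[floored | !is.finite(df)] <- n1 + n2 - 2
  tstat <- lfc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmin(pmax(p, 1e-300), 1)
  res <- data.frame(gene = rownames(em$values), lfc = lfc, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "label") <- contrast$label
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Write per-contrast gene statistics as TSV
#'
#' @param stats a `contrast_result` from [compute_gene_stats()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_gene_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats)[, c("gene", "lfc", "p")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
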