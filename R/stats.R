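#' Pooled-variance Student's t test
#'
#' Classical equal-variance two-sample t test (two-sided).  Welch's
#' unequal-variance variant is available behind `var_equal = FALSE`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance statistic (default `TRUE`).
#' @return List with `t`, `df` and two-sided `p`.
#' @export
students_t <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs n >= 2")
  }
  fit <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Point-biserial effect size with banding
#'
#' Pearson correlation between the pooled values and a 0/1 group
#' indicator, reported as an absolute value and banded: `r > 0.5` strong,
#' `0.3 < r <= 0.5` moderate, `r <= 0.3` negligible (boundary values fall
#' in the lower band).
#'
#' @param group_a,group_b Numeric vectors with combined length >= 3.
#' @return List with `r` (in `[0, 1]`) and `band`.
#' @export
point_biserial_r <- function(group_a, group_b) {
  values <- c(group_a, group_b)
  if (length(values) < 3L) stop("combined n must be >= 3")
  if (stats::var(values) == 0) stop("zero total variance")
  indicator <- rep(c(0, 1), c(length(group_a), length(group_b)))
  r <- abs(stats::cor(values, indicator))
  list(r = r, band = effect_band(r))
}

#' Band an effect size r at the 0.3 / 0.5 cut points
#' @param r Absolute correlation in `[0, 1]`.
#' @return `"strong"` (r > 0.5), `"moderate"` (0.3 < r <= 0.5) or
#'   `"negligible"` (r <= 0.3).
#' @export
effect_band <- function(r) {
  if (r > 0.5) "strong" else if (r > 0.3) "moderate" else "negligible"
}

#' Compare two groups of values: t test plus effect size
#'
#' Bundles [students_t()] and [point_biserial_r()] for a
#' cluster-vs-cluster or sample-vs-sample comparison.  Groups may be
#' given directly as numeric vectors, or extracted from a matrix with
#' gene and/or sample selections.
#'
#' @param a,b Numeric vectors, or lists `list(genes = , samples = )`
#'   selecting from `matrix`.
#' @param matrix Optional gene-by-sample matrix for selection-based
#'   calls.
#' @param var_equal Passed to [students_t()].
#' @return List with `t`, `df`, `p`, `r`, `band`.
#' @export
compare_groups <- function(a, b, matrix = NULL, var_equal = TRUE) {
  pick <- function(sel) {
    if (is.numeric(sel)) return(sel)
    if (is.null(matrix)) stop("matrix required for selection-based groups")
    rows <- if (is.null(sel$genes)) seq_len(nrow(matrix)) else sel$genes
    cols <- if (is.null(sel$samples)) seq_len(ncol(matrix)) else sel$samples
    as.vector(matrix[rows, cols, drop = FALSE])
  }
  va <- pick(a); vb <- pick(b)
  tt <- students_t(va, vb, var_equal = var_equal)
  es <- point_biserial_r(va, vb)
  c(tt, es)
}

#' Per-cluster category fraction
#'
#' For each cluster, the fraction of its genes annotated with the queried
#' category label (default `"transcription regulator"`); unannotated
#' genes count as non-category and are tallied.
#'
#' @param partition A `cluster_partition`.
#' @param annotation Named character vector, gene id -> category label.
#' @param label Category label to query.
#' @return Data frame with `cluster`, `n_genes`, `n_category`, `fraction`
#'   and `n_unannotated`; attribute `global_fraction` holds the
#'   partition-wide fraction.
#' @export
category_fraction <- function(partition, annotation,
                              label = "transcription regulator") {
  genes <- names(partition$assignment)
  if (length(genes) == 0L) stop("empty partition")
  labels <- sort(unique(partition$assignment))
  rows <- lapply(labels, function(lab) {
    g <- genes[partition$assignment == lab]
    cat_hit <- !is.na(annotation[g]) & annotation[g] == label
    data.frame(cluster = lab, n_genes = length(g),
               n_category = sum(cat_hit),
               fraction = sum(cat_hit) / length(g),
               n_unannotated = sum(!g %in% names(annotation)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "global_fraction") <- sum(out$n_category) / sum(out$n_genes)
  out
}
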