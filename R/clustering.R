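#' Seeded k-means clustering of log expression
#'
#' Rows are transformed to `log2(FPKM + 1)` and partitioned with Lloyd's
#' algorithm from a seeded, k-means++-style initialization.  Candidate
#' points are scanned in canonical (lexicographic) row order during
#' initialization, so permuting the input rows cannot change the result.
#' Cluster labels `0 .. k-1` are assigned in order of descending cluster
#' mean (label 0 = highest overall mean).
#'
#' @param expr Gene-by-sample FPKM matrix.
#' @param k Number of clusters (>= 1).
#' @param seed Integer seed for the initialization.
#' @param transform Row transform applied before clustering.
#' @param iter_max Lloyd iteration cap.
#' @return A `cluster_partition`: list with `method`, `k`, `seed`,
#'   `assignment` (named integer vector, labels `0 .. k-1`) and `objective`
#'   (total within-cluster sum of squares).
#' @export
kmeans_expression <- function(expr, k = 4L, seed = 1L,
                              transform = function(x) log2(x + 1),
                              iter_max = 300L) {
  x <- transform(expr)
  if (k < 1L) stop("k must be >= 1")
  n_distinct <- nrow(unique(as.data.frame(x)))
  if (n_distinct < k) stop("fewer distinct rows (", n_distinct, ") than k = ", k)
  if (k == 1L) {
    assignment <- stats::setNames(rep(0L, nrow(x)), rownames(x))
    centers <- matrix(colMeans(x), nrow = 1L)
    obj <- sum(sweep(x, 2L, centers[1L, ])^2)
  } else {
    centers <- kmeanspp_init(x, k, seed)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max, algorithm = "Lloyd")
    )
    # relabel by descending cluster mean for reproducible identities
    ord <- order(rowMeans(fit$centers), decreasing = TRUE)
    relabel <- integer(k)
    relabel[ord] <- seq_len(k) - 1L
    assignment <- stats::setNames(relabel[fit$cluster], rownames(x))
    obj <- fit$tot.withinss
  }
  structure(list(method = "kmeans", k = as.integer(k), seed = as.integer(seed),
                 assignment = assignment, objective = obj),
            class = "cluster_partition")
}

# Seeded k-means++-style initialization, invariant to input row order:
# rows are ranked lexicographically and all randomness is drawn against
# that canonical order.
kmeanspp_init <- function(x, k, seed) {
  ord <- do.call(order, as.data.frame(x))
  xs <- x[ord, , drop = FALSE]
  n <- nrow(xs)
  centers <- matrix(0, nrow = k, ncol = ncol(xs))
  picked <- integer(k)
  rng <- local_rng(seed)
  picked[1L] <- floor(rng(1L) * n) + 1L
  centers[1L, ] <- xs[picked[1L], ]
  d2 <- rowSums(sweep(xs, 2L, centers[1L, ])^2)
  for (i in seq_len(k)[-1L]) {
    if (all(d2 == 0)) stop("fewer distinct rows than k")
    cum <- cumsum(d2 / sum(d2))
    picked[i] <- findInterval(rng(1L) * (1 - 1e-12), cum) + 1L
    centers[i, ] <- xs[picked[i], ]
    d2 <- pmin(d2, rowSums(sweep(xs, 2L, centers[i, ])^2))
  }
  centers
}

# Private uniform RNG stream so clustering does not disturb the caller's
# .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
}

#' Per-iteration k-means objective trace
#'
#' Reruns Lloyd's algorithm from the same seeded initialization with an
#' increasing iteration cap and records the total within-cluster sum of
#' squares after each iteration; the sequence is non-increasing.
#'
#' @inheritParams kmeans_expression
#' @param n_iter Number of iterations to trace.
#' @return Numeric vector of objective values after 1 .. `n_iter`
#'   iterations.
#' @export
kmeans_objective_trace <- function(expr, k = 4L, seed = 1L,
                                   transform = function(x) log2(x + 1),
                                   n_iter = 10L) {
  x <- transform(expr)
  centers <- kmeanspp_init(x, k, seed)
  vapply(seq_len(n_iter), function(i) {
    suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = i, algorithm = "Lloyd")
    )$tot.withinss
  }, numeric(1L))
}

#' Hierarchical clustering of genes on promoter histone values
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage) of a gene
#' set on its concatenated H3K4me3/H3K27me3 promoter scores, with the
#' tree cut at `k` clusters.  Labels `C1 .. Ck` are assigned in order of
#' descending cluster mean over the `order_samples` columns (by default
#' all columns), so C1 is the highest-signal cluster.
#'
#' @param matrix Gene-by-sample score matrix (a `tss_signal_matrix` or a
#'   plain matrix), already restricted to the gene set of interest.
#' @param k Number of clusters (`1 <= k <=` number of genes).
#' @param order_samples Columns used for the label-ordering mean
#'   (e.g. the H3K27me3 columns); default all.
#' @param linkage `stats::hclust` method; `"ward.D2"` implements the Ward
#'   criterion on Euclidean distances.
#' @return A `cluster_partition` with labels `"C1" .. "Ck"`.
#' @export
hierarchical_histone <- function(matrix, k, order_samples = NULL,
                                 linkage = "ward.D2") {
  x <- if (inherits(matrix, "tss_signal_matrix")) matrix$scores else matrix
  if (k > nrow(x)) stop("k = ", k, " exceeds number of genes (", nrow(x), ")")
  if (k < 1L) stop("k must be >= 1")
  # hclust is order-sensitive under distance ties; canonicalize row order
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]
  cut <- if (nrow(x) == 1L) stats::setNames(1L, rownames(x)) else {
    tree <- stats::hclust(stats::dist(x, method = "euclidean"), method = linkage)
    stats::cutree(tree, k = k)
  }
  ref_cols <- if (is.null(order_samples)) seq_len(ncol(x)) else order_samples
  cluster_means <- vapply(seq_len(k), function(ci) {
    mean(x[cut == ci, ref_cols, drop = FALSE])
  }, numeric(1L))
  relabel <- character(k)
  relabel[order(cluster_means, decreasing = TRUE)] <- paste0("C", seq_len(k))
  structure(list(method = "hierarchical", k = as.integer(k), linkage = linkage,
                 assignment = stats::setNames(relabel[cut], rownames(x))),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition (", x$method, ", k = ", x$k, "): ",
      length(x$assignment), " genes\n", sep = "")
  print(table(x$assignment))
  invisible(x)
}

#' Per-cluster, per-sample summary statistics
#'
#' The numbers behind a box-plot panel: median, quartiles, mean and size
#' for every cluster-by-sample cell.
#'
#' @param partition A `cluster_partition`.
#' @param values Gene-by-sample matrix covering all assigned genes.
#' @return Data frame with columns `cluster`, `sample`, `n`, `mean`,
#'   `median`, `q1`, `q3`.
#' @export
cluster_summary <- function(partition, values) {
  genes <- names(partition$assignment)
  if (!all(genes %in% rownames(values))) {
    stop("values matrix does not cover all assigned genes")
  }
  labels <- sort(unique(partition$assignment))
  if (length(labels) < partition$k) stop("empty cluster in partition")
  rows <- lapply(labels, function(lab) {
    sub <- values[genes[partition$assignment == lab], , drop = FALSE]
    data.frame(
      cluster = lab, sample = colnames(values), n = nrow(sub),
      mean = colMeans(sub),
      median = apply(sub, 2L, stats::median),
      q1 = apply(sub, 2L, stats::quantile, probs = 0.25),
      q3 = apply(sub, 2L, stats::quantile, probs = 0.75),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
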