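#' Fold-change gating of fraction-specific genes
#'
#' A gene is specific to the EGFP-positive fraction (EPG) at a timepoint
#' when its expression there exceeds the opposing fraction by strictly
#' more than `fold` (default 2); the reciprocal rule defines the
#' negative-fraction set (ENG).  A pseudocount keeps zero-FPKM
#' denominators finite.
#'
#' @param expr Gene-by-sample FPKM matrix.
#' @param pos_sample,neg_sample Column names of the opposing fractions.
#' @param fold Fold threshold (> 1), strict inequality.
#' @param pseudocount Added to both numerator and denominator (>= 0,
#'   default 0.1 FPKM).
#' @param min_fpkm Optional expression floor: genes below it in both
#'   samples are excluded from either set (default 0 = off).
#' @return A `gate_result`: list with `epg` and `eng` gene-id character
#'   vectors (always disjoint) and the gate parameters.
#' @export
fold_change_gate <- function(expr, pos_sample, neg_sample, fold = 2,
                             pseudocount = 0.1, min_fpkm = 0) {
  if (identical(pos_sample, neg_sample)) stop("pos_sample and neg_sample must differ")
  if (!all(c(pos_sample, neg_sample) %in% colnames(expr))) {
    stop("sample(s) not in expression matrix: ",
         paste(setdiff(c(pos_sample, neg_sample), colnames(expr)), collapse = ", "))
  }
  if (fold <= 1) stop("fold must be > 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  p <- expr[, pos_sample]
  n <- expr[, neg_sample]
  expressed <- p >= min_fpkm | n >= min_fpkm
  ratio <- (p + pseudocount) / (n + pseudocount)
  structure(
    list(epg = rownames(expr)[which(expressed & ratio > fold)],
         eng = rownames(expr)[which(expressed & 1 / ratio > fold)],
         pos_sample = pos_sample, neg_sample = neg_sample,
         fold_threshold = fold, pseudocount = pseudocount, min_fpkm = min_fpkm),
    class = "gate_result"
  )
}

#' @export
print.gate_result <- function(x, ...) {
  cat("gate_result ", x$pos_sample, " vs ", x$neg_sample, " (>", x$fold_threshold,
      "-fold): |EPG| = ", length(x$epg), ", |ENG| = ", length(x$eng), "\n", sep = "")
  invisible(x)
}

#' Set algebra on two gene sets
#'
#' Standard intersection/union/difference with sizes; the
#' inclusion-exclusion identity `|union| = |a| + |b| - |intersection|` is
#' asserted on every call.
#'
#' @param a,b Character vectors of gene ids (duplicates removed).
#' @return List with `intersection`, `union`, `a_only`, `b_only` and a
#'   `sizes` named integer vector.
#' @export
set_algebra <- function(a, b) {
  a <- unique(a); b <- unique(b)
  res <- list(intersection = intersect(a, b), union = union(a, b),
              a_only = setdiff(a, b), b_only = setdiff(b, a))
  sizes <- c(a = length(a), b = length(b),
             intersection = length(res$intersection), union = length(res$union),
             a_only = length(res$a_only), b_only = length(res$b_only))
  stopifnot(sizes[["union"]] == sizes[["a"]] + sizes[["b"]] - sizes[["intersection"]])
  res$sizes <- sizes
  res
}

#' Restrict a gene set to genes covered by a histone-signal matrix
#'
#' @param genes Character vector of gene ids.
#' @param matrix A `tss_signal_matrix`, or a matrix with gene-id rownames.
#' @return Character vector of retained genes, with attribute `dropped`
#'   listing those without histone coverage.
#' @export
restrict_to_measured <- function(genes, matrix) {
  covered <- if (inherits(matrix, "tss_signal_matrix")) rownames(matrix$scores)
             else rownames(matrix)
  kept <- genes[genes %in% covered]
  attr(kept, "dropped") <- setdiff(genes, covered)
  kept
}
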