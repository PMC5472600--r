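#' Sliding-window tag counting, input subtraction and TSS signal averaging
#'
#' The promoter histone-modification score of a gene is computed from a
#' genome-wide sliding-window track: tags are counted in 1050-bp windows
#' sliding by 50 bp, divided by the library size, the matched input track
#' is subtracted window-wise, values are moved to log2 scale, and the
#' windows whose centers fall within TSS +/- 5 kb are averaged per gene.
#' Gene-by-sample score matrices are then quantile normalized across
#' samples.
#'
#' @name histone_signal
NULL

new_window_track <- function(chrom, values, width, step) {
  structure(list(chrom = chrom, width = as.integer(width),
                 step = as.integer(step), values = as.numeric(values)),
            class = "window_track")
}

#' Window start positions of a track
#' @param track A `window_track`.
#' @return Integer vector of 0-based window starts (step apart).
#' @export
window_starts <- function(track) {
  (seq_along(track$values) - 1L) * track$step
}

#' Window center positions of a track
#' @param track A `window_track`.
#' @return Numeric vector of window centers (`start + width / 2`).
#' @export
window_centers <- function(track) {
  window_starts(track) + track$width / 2
}

#' Count tags in sliding windows along each chromosome
#'
#' Window `[s, s + width)` holds the number of tags with
#' `s <= pos < s + width`; window starts tile `[0, chrom_length)` at the
#' given step, so the last windows may extend past the chromosome end
#' (tags cannot).  A tag at position `p >= width - step` is counted by
#' exactly `width / step` windows (21 at the defaults).
#'
#' @param library A `tag_library` with `total_tags > 0`.
#' @param chrom_lengths Named integer vector covering every tag chromosome.
#' @param width Window width in bp.
#' @param step Slide in bp; must divide evenly into the window grid.
#' @return Named list of `window_track`, one per chromosome in
#'   `chrom_lengths`.
#' @export
count_window_tags <- function(library, chrom_lengths, width = 1050L, step = 50L) {
  if (library$total_tags <= 0L) stop("empty tag library")
  width <- as.integer(width); step <- as.integer(step)
  stopifnot(width > 0L, step > 0L)
  missing_chrom <- setdiff(unique(library$chrom), names(chrom_lengths))
  if (length(missing_chrom) > 0L) {
    stop("tag chromosome(s) absent from chrom_lengths: ",
         paste(missing_chrom, collapse = ", "))
  }
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    n <- as.integer(ceiling(len / step))
    pos <- library$pos[library$chrom == cn]
    if (any(pos >= len)) stop("tag position beyond chromosome end on ", cn)
    if (length(pos) == 0L) return(new_window_track(cn, numeric(n), width, step))
    # window j covers tag p iff j*step <= p < j*step + width
    j_hi <- pos %/% step
    j_lo <- pmax((pos - width) %/% step + 1L, 0L)
    inc <- tabulate(j_lo + 1L, nbins = n)
    dec <- tabulate(j_hi + 2L, nbins = n + 1L)[seq_len(n)]
    new_window_track(cn, cumsum(inc - dec), width, step)
  })
  names(out) <- names(chrom_lengths)
  out
}

#' Divide a window track by the library size
#'
#' @param track A `window_track` of raw counts.
#' @param total_tags Library size (> 0).
#' @return The track with every value divided by `total_tags`.
#' @export
normalize_by_library <- function(track, total_tags) {
  if (total_tags <= 0L) stop("total_tags must be positive")
  track$values <- track$values / total_tags
  track
}

#' Subtract an input track from a test track, window-wise
#'
#' @param test,input `window_track`s on the identical window grid.
#' @return `test - input` per window; values may be negative.
#' @export
subtract_input <- function(test, input) {
  if (!identical(test$chrom, input$chrom) ||
      test$width != input$width || test$step != input$step ||
      length(test$values) != length(input$values)) {
    stop("window grid mismatch between test and input tracks")
  }
  test$values <- test$values - input$values
  test
}

#' Move a window track to log2 scale
#'
#' Values are floored at zero (input subtraction can leave depleted
#' windows negative) and offset by a small `epsilon` before taking log2,
#' so the transform is monotone non-decreasing and defined everywhere:
#' `v -> log2(max(v, 0) + epsilon)`.
#'
#' @param track A `window_track`.
#' @param epsilon Positive offset (default `1e-9`).
#' @return The transformed track.
#' @export
log2_transform <- function(track, epsilon = 1e-9) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  track$values <- log2(pmax(track$values, 0) + epsilon)
  track
}

#' Average window values in TSS +/- flank per gene
#'
#' A window contributes to a gene when its center `c` satisfies
#' `TSS - flank <= c <= TSS + flank`.  Genes on a chromosome absent from
#' the tracks, or whose interval captures no window center, are flagged
#' missing (`NA` score) and reported via the `"missing"` attribute.
#'
#' @param tracks Named per-chromosome list of `window_track`.
#' @param genes A `gene_annotation` data frame (small RNAs already
#'   excluded upstream).
#' @param flank Flank size in bp around the TSS (default 5000).
#' @return Named numeric vector of per-gene scores with attribute
#'   `missing` (character vector of flagged gene ids).
#' @export
average_tss_window <- function(tracks, genes, flank = 5000L) {
  tss <- gene_tss(genes)
  scores <- rep(NA_real_, nrow(genes))
  names(scores) <- genes$gene_id
  for (cn in unique(genes$chrom)) {
    if (!cn %in% names(tracks)) next
    tr <- tracks[[cn]]
    half <- tr$width / 2
    n <- length(tr$values)
    idx <- which(genes$chrom == cn)
    # center c = j*step + half in [tss - flank, tss + flank]
    j_lo <- pmax(ceiling((tss[idx] - flank - half) / tr$step), 0)
    j_hi <- pmin(floor((tss[idx] + flank - half) / tr$step), n - 1)
    ok <- j_lo <= j_hi
    scores[idx[ok]] <- vapply(which(ok), function(k) {
      mean(tr$values[(j_lo[k] + 1):(j_hi[k] + 1)])
    }, numeric(1L))
  }
  attr(scores, "missing") <- names(scores)[is.na(scores)]
  scores
}

#' Quantile normalize a gene-by-sample matrix
#'
#' Standard quantile normalization: the value of rank *i* in each column
#' is replaced by the mean over columns of their rank-*i* values; tied
#' values within a column receive the mean of the tied ranks' reference
#' values.  Afterwards every column holds the same value multiset and
#' within-column rank order is preserved; the transform is idempotent.
#'
#' @param matrix Numeric matrix, >= 2 columns, no missing values.
#' @return The normalized matrix (same dimnames).
#' @export
quantile_normalize <- function(matrix) {
  if (anyNA(matrix)) stop("missing values not allowed")
  if (ncol(matrix) < 2L) {
    warning("single column: quantile normalization is the identity")
    return(matrix)
  }
  if (nrow(matrix) == 0L) return(matrix)
  if (nrow(matrix) == 1L) {
    matrix[] <- mean(matrix)
    return(matrix)
  }
  reference <- rowMeans(apply(matrix, 2L, sort))
  out <- apply(matrix, 2L, function(col) {
    assigned <- numeric(length(col))
    assigned[order(col)] <- reference
    # tied values share the mean of their tied ranks' reference values
    stats::ave(assigned, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(matrix)
  out
}

#' Compute the TSS histone-signal matrix for matched test/input libraries
#'
#' Runs the full promoter scoring chain for each (test, input) pair —
#' window counting, library normalization, input subtraction, log2
#' transform, TSS +/- flank averaging — then quantile normalizes the
#' per-gene scores across test samples.  Genes flagged missing in any
#' sample are dropped from both matrices and reported.
#'
#' @param pairs List of `list(test = , input = )` pairs of `tag_library`.
#' @param genes A `gene_annotation` data frame.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width,step,flank,epsilon Scoring parameters (see the individual
#'   steps).
#' @return A `tss_signal_matrix`: list with `scores` (quantile-normalized
#'   gene x sample matrix), `raw` (pre-normalization matrix), `missing`
#'   (dropped gene ids), and `params`.
#' @export
compute_histone_matrix <- function(pairs, genes, chrom_lengths,
                                   width = 1050L, step = 50L,
                                   flank = 5000L, epsilon = 1e-9) {
  if (length(pairs) == 0L) stop("no test/input pairs")
  bad <- vapply(pairs, function(p) is.null(p$test) || is.null(p$input), logical(1L))
  if (any(bad)) stop("unmatched test/input pair at position ", which(bad)[1L])
  cols <- lapply(pairs, function(p) {
    test_tr <- count_window_tags(p$test, chrom_lengths, width, step)
    input_tr <- count_window_tags(p$input, chrom_lengths, width, step)
    tracks <- lapply(names(test_tr), function(cn) {
      tr <- subtract_input(
        normalize_by_library(test_tr[[cn]], p$test$total_tags),
        normalize_by_library(input_tr[[cn]], p$input$total_tags)
      )
      log2_transform(tr, epsilon)
    })
    names(tracks) <- names(test_tr)
    average_tss_window(tracks, genes, flank)
  })
  sample_ids <- vapply(pairs, function(p) p$test$sample_id, character(1L))
  if (anyDuplicated(sample_ids)) stop("duplicated test sample_id")
  raw <- do.call(cbind, cols)
  colnames(raw) <- sample_ids
  missing <- rownames(raw)[apply(is.na(raw), 1L, any)]
  raw <- raw[!rownames(raw) %in% missing, , drop = FALSE]
  scores <- if (ncol(raw) >= 2L) quantile_normalize(raw) else raw
  structure(
    list(scores = scores, raw = raw, missing = missing, normalized = ncol(raw) >= 2L,
         params = list(width = width, step = step, flank = flank, epsilon = epsilon)),
    class = "tss_signal_matrix"
  )
}

#' @export
print.tss_signal_matrix <- function(x, ...) {
  cat("tss_signal_matrix:", nrow(x$scores), "genes x", ncol(x$scores),
      "samples;", length(x$missing), "gene(s) without coverage\n")
  invisible(x)
}
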