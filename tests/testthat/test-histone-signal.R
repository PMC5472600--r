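test_that("sliding-window counts match direct interval membership", {
  lib <- make_library(c(100L, 600L, 1100L))
  tr <- count_window_tags(lib, c(chr1 = 2000L))$chr1
  starts <- window_starts(tr)
  expect_equal(tr$values[starts == 0], 2)     # [0, 1050) holds 100, 600
  expect_equal(tr$values[starts == 100], 3)   # [100, 1150) holds all three
  brute <- vapply(starts, function(s) sum(lib$pos >= s & lib$pos < s + 1050),
                  numeric(1))
  expect_equal(tr$values, brute)
})

test_that("a tag at position >= 1000 falls in exactly width/step windows", {
  set.seed(7)
  for (p in sample(1000:49000, 25)) {
    tr <- count_window_tags(make_library(p), c(chr1 = 50000L))$chr1
    expect_equal(sum(tr$values), 21)
    expect_true(all(tr$values %in% c(0, 1)))
  }
  # fewer windows near the chromosome start
  tr <- count_window_tags(make_library(100L), c(chr1 = 50000L))$chr1
  expect_equal(sum(tr$values), 3)
})

test_that("tagless chromosomes give all-zero tracks", {
  tr <- count_window_tags(make_library(10L), c(chr1 = 1000L, chr2 = 1000L))
  expect_true(all(tr$chr2$values == 0))
  expect_equal(length(tr$chr2$values), 20L)
})

test_that("library normalization divides by total tags and is scale-invariant", {
  tr <- count_window_tags(make_library(c(5L, 60L)), c(chr1 = 500L))$chr1
  norm <- normalize_by_library(tr, 10L)
  expect_equal(norm$values, tr$values / 10)
  expect_error(normalize_by_library(tr, 0L), "positive")

  # duplicating every tag k times leaves the normalized track bit-identical
  pos <- sample(0:9999, 300, replace = TRUE)
  for (k in c(2L, 5L)) {
    a <- count_window_tags(make_library(pos), c(chr1 = 10000L))$chr1
    b <- count_window_tags(make_library(rep(pos, k)), c(chr1 = 10000L))$chr1
    expect_identical(normalize_by_library(a, length(pos))$values,
                     normalize_by_library(b, k * length(pos))$values)
  }
})

test_that("input subtraction is window-wise and invertible", {
  lens <- c(chr1 = 3000L)
  test <- count_window_tags(make_library(c(10L, 500L, 2500L)), lens)$chr1
  input <- count_window_tags(make_library(c(480L, 2500L, 2600L)), lens)$chr1
  diff <- subtract_input(test, input)
  expect_equal(diff$values, test$values - input$values)
  expect_true(any(diff$values < 0))
  back <- diff; back$values <- back$values + input$values
  expect_equal(back$values, test$values)
  expect_equal(subtract_input(test, test)$values, rep(0, length(test$values)))
  short <- input; short$values <- short$values[-1]
  expect_error(subtract_input(test, short), "grid mismatch")
})

test_that("log2 transform floors at zero, offsets by epsilon, stays monotone", {
  tr <- new_track_for_test(c(1 - 1e-9, -0.5, 0, 0.25))
  out <- log2_transform(tr, epsilon = 1e-9)
  expect_equal(out$values[1], 0)
  expect_equal(out$values[2], log2(1e-9))
  expect_equal(out$values[3], log2(1e-9))
  expect_equal(out$values[4], log2(0.25 + 1e-9))
  expect_error(log2_transform(tr, epsilon = 0), "epsilon")

  set.seed(11)
  v <- sort(stats::rnorm(200))
  tr$values <- v
  expect_true(all(diff(log2_transform(tr, 1e-6)$values) >= 0))
})

test_that("TSS averaging selects windows by center, boundaries inclusive", {
  # value 1 at center 4975, 2 at center 5025, 4 at center 5075; only the
  # first two centers lie within TSS = 50 +/- 5000 (91 candidate centers)
  n <- 120L
  values <- numeric(n)
  values[(4450 / 50) + 1] <- 1
  values[(4500 / 50) + 1] <- 2
  values[(4550 / 50) + 1] <- 4
  tracks <- list(chr1 = new_track_for_test(values))
  genes <- make_genes(50L)
  expect_equal(average_tss_window(tracks, genes), 3 / 91,
               ignore_attr = TRUE)
  # TSS = 25 puts center 5025 exactly on the boundary: included ("<=")
  expect_equal(average_tss_window(tracks, make_genes(25L)), 3 / 91,
               ignore_attr = TRUE)
  # TSS = 24 pushes it just outside: 90 candidate centers, only value 1 left
  expect_equal(average_tss_window(tracks, make_genes(24L)), 1 / 90,
               ignore_attr = TRUE)

  # constant track: every gene scores the constant
  tracks$chr1$values <- rep(1.7, n)
  many <- make_genes(c(500L, 3000L, 5900L))
  expect_equal(average_tss_window(tracks, many), rep(1.7, 3),
               ignore_attr = TRUE)
})

test_that("genes without coverage are flagged missing", {
  tracks <- list(chr1 = new_track_for_test(rep(1, 50)))
  genes <- make_genes(c(1000L, 1000L), chrom = c("chr1", "chr9"),
                      ids = c("a", "b"))
  scores <- average_tss_window(tracks, genes)
  expect_equal(attr(scores, "missing"), "b")
  expect_true(is.na(scores["b"]))
})

test_that("minus-strand scoring is invariant under genome mirroring", {
  set.seed(23)
  len <- 100000L
  pos <- sample(0:(len - 1L), 4000L, replace = TRUE)
  tss <- 51000L  # multiple of 50 so no window center sits on the boundary
  fwd_genes <- make_genes(tss, ids = "g")
  rev_genes <- make_genes(len - tss - 1L, strand = "-", ids = "g")
  expect_equal(rev_genes$tx_end - 1L, len - 1L - tss)
  score <- function(genes, p) {
    tr <- count_window_tags(make_library(p), c(chr1 = len))
    unname(average_tss_window(tr, genes))
  }
  expect_equal(score(fwd_genes, pos), score(rev_genes, len - 1L - pos))
})

test_that("quantile normalization matches the hand-computed example", {
  m <- cbind(A = c(5, 3), B = c(2, 4))
  out <- quantile_normalize(m)
  expect_equal(out, cbind(A = c(4.5, 2.5), B = c(2.5, 4.5)))
  same <- cbind(A = c(1, 5, 2), B = c(1, 5, 2))
  expect_equal(quantile_normalize(same), same)
  expect_warning(one <- quantile_normalize(m[, 1, drop = FALSE]), "single column")
  expect_equal(one, m[, 1, drop = FALSE])
  m[1, 1] <- NA
  expect_error(quantile_normalize(m), "missing values")
})

test_that("quantile normalization ties take the mean of tied reference values", {
  m <- cbind(A = c(1, 1, 1, 10), B = c(4, 3, 2, 1))
  ref <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  out <- quantile_normalize(m)
  expect_equal(unname(out[1:3, "A"]), rep(mean(ref[1:3]), 3))
  expect_equal(unname(out[4, "A"]), ref[4])
  expect_equal(unname(out[, "B"]), rev(ref))
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(stats::rnorm(40 * 4), 40, 4,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:4)))
    expect_equal(unname(quantile_normalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
  }
})

test_that("the assembled histone matrix equals step-by-step composition", {
  set.seed(31)
  lens <- c(chr1 = 60000L)
  genes <- make_genes(c(10000L, 30000L, 50000L), ids = c("a", "b", "c"))
  libs <- lapply(1:4, function(i) {
    make_library(sample(0:59999, 800L, replace = TRUE),
                 sample_id = c("t1", "i1", "t2", "i2")[i])
  })
  pairs <- list(list(test = libs[[1]], input = libs[[2]]),
                list(test = libs[[3]], input = libs[[4]]))
  hm <- compute_histone_matrix(pairs, genes, lens)

  manual <- vapply(pairs, function(p) {
    tr <- subtract_input(
      normalize_by_library(count_window_tags(p$test, lens)$chr1, p$test$total_tags),
      normalize_by_library(count_window_tags(p$input, lens)$chr1, p$input$total_tags)
    )
    average_tss_window(list(chr1 = log2_transform(tr)), genes)
  }, numeric(3))
  colnames(manual) <- c("t1", "t2")
  expect_equal(hm$raw, manual)
  expect_equal(hm$scores, quantile_normalize(manual))
  expect_true(hm$normalized)

  expect_error(compute_histone_matrix(list(list(test = libs[[1]])), genes, lens),
               "unmatched")
})

test_that("identical test and input collapse to a constant matrix", {
  lib1 <- make_library(c(100L, 900L, 4000L), sample_id = "s1")
  lib2 <- make_library(c(200L, 500L, 3000L), sample_id = "s2")
  genes <- make_genes(2500L)
  hm <- compute_histone_matrix(
    list(list(test = lib1, input = lib1), list(test = lib2, input = lib2)),
    genes, c(chr1 = 10000L)
  )
  expect_equal(unname(hm$raw[1, ]), rep(log2(1e-9), 2))
  expect_equal(unname(hm$scores[1, ]), rep(log2(1e-9), 2))
})
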