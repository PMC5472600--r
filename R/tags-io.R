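#' Construct a ChIP tag library
#'
#' A tag library holds the reduced 1-bp tag positions of one aligned ChIP
#' (or input) sample together with its library size, which is the
#' denominator of the per-window library normalization.
#'
#' @param chrom Character vector of tag chromosomes.
#' @param pos Integer vector of 0-based tag positions (the 5' end of each
#'   read on its strand).
#' @param sample_id Sample identifier.
#' @param antibody `"H3K4me3"`, `"H3K27me3"` or `"input"`.
#' @param fraction Sorted cell fraction (e.g. `"Cd73_P"`).
#' @param stage Developmental stage (e.g. `"P2"`).
#' @return A `tag_library` object.
#' @export
tag_library <- function(chrom, pos, sample_id = NA_character_,
                        antibody = NA_character_, fraction = NA_character_,
                        stage = NA_character_) {
  stopifnot(length(chrom) == length(pos))
  if (length(pos) && any(pos < 0)) stop("negative tag position")
  structure(
    list(sample_id = sample_id, antibody = antibody, fraction = fraction,
         stage = stage, chrom = as.character(chrom), pos = as.integer(pos),
         total_tags = length(pos)),
    class = "tag_library"
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library", x$sample_id, "-", x$total_tags, "tags on",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read aligned ChIP tags from a BED file
#'
#' Each interval is reduced to a single tag at the 5' end of the read on
#' its strand: the interval start for plus-strand (or strandless, BED3)
#' records, `end - 1` for minus-strand records.  The library size is the
#' number of data lines; duplicate tags are retained.
#'
#' @param path Path to a BED3+ file.
#' @param ... Passed to [tag_library()] (sample metadata).
#' @return A `tag_library`.  An empty file yields a valid library with
#'   `total_tags = 0`; downstream scoring rejects it.
#' @export
read_tag_bed <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(tag_library(character(0), integer(0), ...))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) stop("malformed BED line ", which(n < 3L)[1L], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, character(1L), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1L), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1L), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinate on line ", which(is.na(start) | is.na(end))[1L])
  }
  if (any(start < 0L)) stop("negative coordinate on line ", which(start < 0L)[1L])
  strand <- rep("+", length(lines))
  has6 <- n >= 6L
  strand[has6] <- vapply(fields[has6], `[`, character(1L), 6L)
  pos <- ifelse(strand == "-", end - 1L, start)
  tag_library(chrom, pos, ...)
}

#' Write a tag library as BED6 (1-bp intervals at the tag positions)
#'
#' @param library A `tag_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_bed <- function(library, path) {
  lines <- paste(library$chrom, library$pos, library$pos + 1L, ".", 0L, "+",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
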