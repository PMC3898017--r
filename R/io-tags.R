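#' Tag library container
#'
#' Strand-separated 5'-end tag positions per replicon for one sequencing
#' library (ChIP or input).  Positions are 1-based; the forward list holds
#' 5' ends of plus-strand tags, the reverse list 5' ends of minus-strand
#' tags (which sit at the right-hand end of the sequenced fragment).
#'
#' @param sample `"chip"` or `"input"`.
#' @param tags named list, one entry per replicon, each a list with sorted
#'   integer vectors `fwd` and `rev`.
#' @return an object of class `TagLibrary` with elements `sample`, `tags`
#'   and `library_size`.
#' @export
tag_library <- function(sample = c("chip", "input"), tags) {
  sample <- match.arg(sample)
  if (is.null(names(tags)) || any(names(tags) == ""))
    stop("tag list entries must be named by replicon")
  tags <- lapply(tags, function(tr) {
    fwd <- as.integer(sort(tr$fwd))
    rev <- as.integer(sort(tr$rev))
    if (length(fwd) && fwd[1] < 1 || length(rev) && rev[1] < 1)
      stop("tag position below 1")
    list(fwd = fwd, rev = rev)
  })
  n <- sum(vapply(tags, function(tr) length(tr$fwd) + length(tr$rev),
                  integer(1)))
  structure(list(sample = sample, tags = tags, library_size = n),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary (%s): %d tags on %d replicon(s)\n",
              x$sample, x$library_size, length(x$tags)))
  invisible(x)
}

#' Read a tag library from BED
#'
#' BED intervals are 0-based half-open; each interval is one aligned tag
#' (or fragment) whose 5' end is taken as `chromStart + 1` on the plus
#' strand and `chromEnd` on the minus strand, both expressed 1-based.
#' Output position lists are sorted regardless of input order.
#'
#' @param path BED6 file (strand column required).
#' @param sample `"chip"` or `"input"`.
#' @return a [tag_library()] object.
#' @export
read_tags_bed <- function(path, sample = c("chip", "input")) {
  sample <- match.arg(sample)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  str <- as.character(GenomicRanges::strand(gr))
  if (any(str == "*")) stop("BED tag record without strand in ", path)
  rep <- as.character(GenomicRanges::seqnames(gr))
  # rtracklayer already converts to 1-based inclusive: start = chromStart+1
  pos <- ifelse(str == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  tags <- lapply(split(data.frame(pos = pos, str = str), rep), function(d)
    list(fwd = sort(d$pos[d$str == "+"]), rev = sort(d$pos[d$str == "-"])))
  tag_library(sample, tags)
}

#' Write a tag library as BED6
#'
#' Each tag is written as a 1-bp interval at its 5' end, so that
#' [read_tags_bed()] recovers the library exactly.
#'
#' @param lib a [tag_library()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_tags_bed <- function(lib, path) {
  stopifnot(inherits(lib, "TagLibrary"))
  rows <- lapply(names(lib$tags), function(rep) {
    tr <- lib$tags[[rep]]
    data.frame(chrom = rep,
               start = c(tr$fwd, tr$rev) - 1L,
               end = c(tr$fwd, tr$rev),
               name = ".",
               score = 0L,
               strand = c(rep("+", length(tr$fwd)), rep("-", length(tr$rev))),
               stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
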