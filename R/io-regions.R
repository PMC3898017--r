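#' Region midpoint
#'
#' Integer midpoint of a 1-based inclusive interval: the floor of the
#' arithmetic mean, so an even-span region gets the left-of-center base.
#' The midpoint is the single most likely binding position within a
#' double-strand ChIP peak region.
#'
#' @param start,end integer vectors, 1-based inclusive.
#' @return integer vector.
#' @export
#' @examples
#' region_midpoint(3561438, 3561710)  # 3561574
region_midpoint <- function(start, end) {
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Convert 1-based inclusive intervals to BED (0-based half-open) and back
#'
#' @param start,end interval bounds.
#' @return two-column data.frame.
#' @export
to_bed_coords <- function(start, end) {
  stopifnot(all(start >= 1), all(start <= end))
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_bed_coords
#' @export
from_bed_coords <- function(start, end) {
  stopifnot(all(start >= 0), all(start < end))
  data.frame(start = start + 1L, end = end)
}

#' Write the binding-region report table
#'
#' One row per called region: identifier, coordinates (1-based inclusive),
#' midpoint, Q and NLQ, assigned gene(s) with positional class, and the
#' best binding-site sequence found in the region.  A Q value that
#' underflows double precision (below ~1e-308) is printed as `"0"` while
#' NLQ stays finite — NLQ, not Q, is the ranking statistic.  A BED6
#' companion file (same path with extension `.bed`) is written in 0-based
#' half-open coordinates.
#'
#' @param regions region data.frame from [call_binding_regions()]
#'   (columns `id`, `replicon`, `start`, `end`, `midpoint`, `log10_q`,
#'   `nlq`).
#' @param assignments optional assignment data.frame from
#'   [assign_regions()] (columns `region_id`, `gene_id`, `position_class`).
#' @param sites optional per-region best-site data.frame (columns
#'   `region_id`, `sequence`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, assignments = NULL, sites = NULL,
                               path) {
  tab <- data.frame(
    id = regions$id,
    replicon = regions$replicon,
    start = regions$start,
    end = regions$end,
    midpoint = region_midpoint(regions$start, regions$end),
    Q = ifelse(regions$log10_q < -308, "0",
               sprintf("%.6g", 10^regions$log10_q)),
    NLQ = sprintf("%.4f", regions$nlq),
    genes = character(nrow(regions)),
    position_class = character(nrow(regions)),
    site = character(nrow(regions)),
    stringsAsFactors = FALSE)
  if (nrow(tab)) {
    if (!is.null(assignments) && nrow(assignments)) {
      if (!all(assignments$region_id %in% regions$id))
        stop("assignment region_id not present in regions table")
      sp <- split(assignments, assignments$region_id)
      i <- match(names(sp), tab$id)
      tab$genes[i] <- vapply(sp, function(d)
        paste(d$gene_id, collapse = ","), character(1))
      tab$position_class[i] <- vapply(sp, function(d)
        paste(d$position_class, collapse = ","), character(1))
    }
    if (!is.null(sites) && nrow(sites)) {
      if (!all(sites$region_id %in% regions$id))
        stop("site region_id not present in regions table")
      i <- match(sites$region_id, tab$id)
      tab$site[i] <- sites$sequence
    }
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = regions$replicon,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = regions$id,
                    score = pmin(1000L, as.integer(round(regions$nlq))),
                    strand = rep(".", nrow(regions)))
  write.table(bed, sub("\\.[^.]*$", ".bed", path), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a binding-region report table
#'
#' @param path TSV written by [write_region_table()].
#' @return data.frame with numeric `Q` and `NLQ` columns.
#' @export
read_region_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(Q = "character"))
  tab$Q <- as.numeric(tab$Q)
  tab
}
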