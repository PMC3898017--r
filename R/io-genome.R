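#' Genome container
#'
#' A light S3 container for a (multi-replicon) nucleotide genome: an ordered
#' set of named sequences over the A/C/G/T/N alphabet, as found in a
#' bacterial chromosome plus plasmids.  All pipeline coordinates are 1-based
#' inclusive in this frame.
#'
#' @param replicons named character vector of uppercase sequences.
#' @return an object of class `Genome` with elements `replicons` (named
#'   character) and `lengths` (named integer).
#' @export
Genome <- function(replicons) {
  if (length(replicons) == 0) stop("genome has no sequences")
  if (is.null(names(replicons)) || anyNA(names(replicons)) ||
      any(names(replicons) == ""))
    stop("all replicons must be named")
  if (anyDuplicated(names(replicons)))
    stop("duplicate replicon names: ",
         paste(unique(names(replicons)[duplicated(names(replicons))]),
               collapse = ", "))
  replicons <- toupper(replicons)
  replicons <- gsub("U", "T", replicons, fixed = TRUE)
  if (any(nchar(replicons) == 0)) stop("empty sequence in genome")
  bad <- grepl("[^ACGTN]", replicons)
  if (any(bad))
    stop("non-ACGTN characters in replicon(s): ",
         paste(names(replicons)[bad], collapse = ", "))
  structure(list(replicons = replicons,
                 lengths = vapply(replicons, nchar, integer(1))),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x$replicons), "replicon(s):\n")
  for (nm in names(x$replicons))
    cat(sprintf("  %s  %d bp\n", nm, x$lengths[[nm]]))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' One `Genome` replicon per FASTA record, in file order.  Sequences are
#' uppercased and RNA `U` is mapped to `T`.
#'
#' @param path FASTA file.
#' @return a [Genome] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  seqs <- as.character(ss)
  # record names: strip description after first whitespace
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record names in ", path)
  Genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a [Genome].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "Genome"))
  ss <- Biostrings::DNAStringSet(genome$replicons)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract a subsequence from a genome (1-based inclusive)
#'
#' @param genome a [Genome].
#' @param replicon replicon name.
#' @param start,end 1-based inclusive bounds.
#' @param strand `"+"` returns the top strand, `"-"` its reverse complement.
#' @return character scalar.
#' @export
genome_subseq <- function(genome, replicon, start, end, strand = "+") {
  stopifnot(inherits(genome, "Genome"))
  if (!replicon %in% names(genome$replicons))
    stop("unknown replicon: ", replicon)
  L <- genome$lengths[[replicon]]
  if (start < 1 || end > L || start > end)
    stop("subsequence out of bounds: ", replicon, ":", start, "-", end)
  s <- substr(genome$replicons[[replicon]], start, end)
  if (identical(strand, "-")) s <- revcomp(s)
  s
}
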