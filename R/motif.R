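#' Scan a sequence for GTAN8TAC-like 14-mer sites
#'
#' A dimeric CRP-family binding site is modeled as a 14-mer with six
#' constrained positions — `G1 T2 A3 ... T12 A13 C14` — and a free 8-nt
#' spacer.  The score of a window is the number of constrained positions
#' that match (0-6); `N` never matches.  Because the constrained positions
#' are reverse-complement palindromic, a strict (score 6) hit is found at
#' the same genomic interval on both strands; a minus-strand record that
#' would duplicate a plus-strand record exactly (perfectly palindromic
#' 14-mer) is reported once.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param min_score minimum score to report (default 5, which admits the
#'   single-mismatch sites accepted in curated regions).
#' @param both_strands scan the reverse strand too (reported with the
#'   reverse-complement 14-mer as `sequence`).
#' @param require_g1 require the constrained `G` at position 1 of the
#'   oriented site (used for relaxed exploratory scans at `min_score = 4`).
#' @return data.frame with columns `start` (1-based leftmost position of
#'   the window), `strand`, `sequence` (oriented 14-mer), `score`.
#' @export
#' @examples
#' scan_sites("GTAACATACACTAC")  # one perfect site
scan_sites <- function(sequence, min_score = 5, both_strands = TRUE,
                       require_g1 = FALSE) {
  n <- nchar(sequence)
  if (n < 14) stop("sequence shorter than 14 nt")
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  i <- seq_len(n - 13L)
  # oriented constrained positions: plus reads the window left-to-right,
  # minus reads its reverse complement
  plus <- (s[i] == "G") + (s[i + 1] == "T") + (s[i + 2] == "A") +
          (s[i + 11] == "T") + (s[i + 12] == "A") + (s[i + 13] == "C")
  minus <- (s[i + 13] == "C") + (s[i + 12] == "A") + (s[i + 11] == "T") +
           (s[i + 2] == "A") + (s[i + 1] == "T") + (s[i] == "G")
  keep_p <- plus >= min_score & (!require_g1 | s[i] == "G")
  res <- data.frame(start = i[keep_p],
                    strand = rep("+", sum(keep_p)),
                    sequence = if (any(keep_p))
                      substring(sequence, i[keep_p], i[keep_p] + 13L)
                    else character(0),
                    score = plus[keep_p], stringsAsFactors = FALSE)
  if (both_strands) {
    keep_m <- minus >= min_score & (!require_g1 | s[i + 13] == "C")
    if (any(keep_m)) {
      win <- substring(sequence, i[keep_m], i[keep_m] + 13L)
      rc <- revcomp(win)
      m <- data.frame(start = i[keep_m], strand = "-", sequence = rc,
                      score = minus[keep_m], stringsAsFactors = FALSE)
      # the constrained consensus is a reverse-complement palindrome, so a
      # window reported on both strands with the same score is one site;
      # keep the plus-strand record only
      j <- match(m$start, res$start)
      dup <- !is.na(j) & res$score[j] == m$score
      res <- rbind(res, m[!dup, , drop = FALSE])
    }
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Best binding site within a region sequence
#'
#' Highest-scoring 14-mer window; ties are broken by proximity of the
#' site center to the region midpoint (sites cluster around the midpoint
#' of real double-strand peak regions), then leftmost, then plus strand.
#'
#' @param sequence region sequence.
#' @param min_score minimum acceptable score.
#' @param require_g1 passed to [scan_sites()].
#' @return one-row data.frame as in [scan_sites()], or `NULL` when no
#'   window reaches `min_score`.
#' @export
best_site_in_region <- function(sequence, min_score = 5,
                                require_g1 = FALSE) {
  hits <- scan_sites(sequence, min_score, both_strands = TRUE,
                     require_g1 = require_g1)
  if (nrow(hits) == 0) return(NULL)
  mid <- (nchar(sequence) + 1) / 2
  d <- abs(hits$start + 6.5 - mid)
  ord <- order(-hits$score, d, hits$start, hits$strand)
  hits[ord[1], , drop = FALSE]
}

#' Motif enrichment in regions versus random control subsequences
#'
#' Density of strict-consensus (score 6) sites in the region set, divided
#' by the mean density over `n_controls` sets of randomly located,
#' length-matched subsequences drawn from the same replicons.  The
#' empirical p-value is the fraction of control sets whose density reaches
#' the observed one.  With no strict site anywhere the ratio is defined
#' as 0 with p = 1.
#'
#' @param regions data.frame with `replicon`, `start`, `end`.
#' @param genome a [Genome].
#' @param n_controls number of control sets (>= 1).
#' @param seed RNG seed for control placement.
#' @return list with `ratio`, `p_value`, `observed_density`,
#'   `control_densities`.
#' @export
motif_enrichment <- function(regions, genome, n_controls = 200L,
                             seed = 7L) {
  if (n_controls < 1) stop("n_controls must be >= 1")
  strict_count <- function(reps, starts, ends) {
    sum(vapply(seq_along(starts), function(i) {
      s <- genome_subseq(genome, reps[i], starts[i], ends[i])
      if (nchar(s) < 14) return(0L)
      nrow(scan_sites(s, min_score = 6, both_strands = FALSE))
    }, integer(1)))
  }
  lens <- regions$end - regions$start + 1L
  total_len <- sum(lens)
  obs <- strict_count(regions$replicon, regions$start, regions$end) /
    total_len
  ctrl <- with_local_seed(seed, {
    vapply(seq_len(n_controls), function(k) {
      starts <- vapply(seq_len(nrow(regions)), function(i) {
        L <- genome$lengths[[regions$replicon[i]]]
        sample.int(L - lens[i] + 1L, 1)
      }, integer(1))
      strict_count(regions$replicon, starts, starts + lens - 1L) / total_len
    }, numeric(1))
  })
  if (obs == 0 && all(ctrl == 0))
    return(list(ratio = 0, p_value = 1, observed_density = 0,
                control_densities = ctrl))
  list(ratio = obs / mean(ctrl), p_value = mean(ctrl >= obs),
       observed_density = obs, control_densities = ctrl)
}

#' Position-frequency matrix with per-column information content
#'
#' Counts, frequencies and information content (in bits) per column of a
#' set of aligned equal-length sequences, as displayed by a sequence logo:
#' `I_j = 2 + sum_b f_bj log2 f_bj` with `0 log 0 = 0` and no small-sample
#' correction.
#'
#' @param sequences character vector of aligned equal-length sequences
#'   over A/C/G/T (e.g. oriented 14-mer sites, optionally extended by
#'   flanking context via [extract_site_context()]).
#' @return object of class `PFMatrix`: list with `counts` (4 x L),
#'   `n`, `freq`, `information`.
#' @export
build_pfm <- function(sequences) {
  if (length(sequences) == 0) stop("empty sequence set")
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  counts <- vapply(seq_len(L), function(j)
    c(A = sum(mat[, j] == "A"), C = sum(mat[, j] == "C"),
      G = sum(mat[, j] == "G"), T = sum(mat[, j] == "T")),
    numeric(4))
  freq <- counts / length(sequences)
  info <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  structure(list(counts = counts, n = length(sequences), freq = freq,
                 information = info),
            class = "PFMatrix")
}

#' @export
print.PFMatrix <- function(x, ...) {
  cat(sprintf("PFMatrix: %d sequences x %d columns, total information %.2f bits\n",
              x$n, ncol(x$counts), sum(x$information)))
  invisible(x)
}

#' Extract oriented site sequences with flanking context
#'
#' Returns the 14-mer of each site extended by `extend` bp on both sides,
#' oriented by site strand (minus-strand sites are reverse-complemented),
#' for extended-consensus logos.  Sites too close to a replicon edge are
#' dropped.
#'
#' @param genome a [Genome].
#' @param sites data.frame with `replicon`, `start`, `strand`.
#' @param extend flank width in bp (default 0: the bare 14-mer).
#' @return character vector of sequences of length `14 + 2 * extend`.
#' @export
extract_site_context <- function(genome, sites, extend = 0L) {
  out <- character(0)
  for (i in seq_len(nrow(sites))) {
    lo <- sites$start[i] - extend
    hi <- sites$start[i] + 13L + extend
    L <- genome$lengths[[sites$replicon[i]]]
    if (lo < 1 || hi > L) next
    out <- c(out, genome_subseq(genome, sites$replicon[i], lo, hi,
                                sites$strand[i]))
  }
  out
}
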