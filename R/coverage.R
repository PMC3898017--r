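#' Strand-specific moving-sum coverage track
#'
#' The coverage substrate for double-strand peak calling:
#' `C(x) = number of same-strand 5'-end tags within [x - w, x + w]`.
#' The track stores the sorted tag positions and evaluates `C` lazily at
#' arbitrary positions via [coverage_at()], which keeps a 500-kb replicon
#' cheap to analyze.
#'
#' @param lib a [tag_library()].
#' @param replicon replicon name.
#' @param strand `"+"` (forward) or `"-"` (reverse).
#' @param w window half-width in bp (> 0).
#' @return an object of class `CoverageTrack`.
#' @export
strand_coverage <- function(lib, replicon, strand = c("+", "-"), w = 100L) {
  stopifnot(inherits(lib, "TagLibrary"))
  strand <- match.arg(strand)
  if (w <= 0) stop("window half-width w must be positive")
  if (!replicon %in% names(lib$tags))
    stop("replicon not in library: ", replicon)
  tags <- if (strand == "+") lib$tags[[replicon]]$fwd
          else lib$tags[[replicon]]$rev
  structure(list(replicon = replicon, strand = strand, w = as.integer(w),
                 tags = tags, n_tags = length(tags),
                 library_size = lib$library_size),
            class = "CoverageTrack")
}

#' Evaluate a coverage track at positions
#'
#' @param track a [strand_coverage()] object.
#' @param x integer positions.
#' @return integer vector `C(x)`.
#' @export
coverage_at <- function(track, x) {
  stopifnot(inherits(track, "CoverageTrack"))
  findInterval(x + track$w, track$tags) -
    findInterval(x - track$w - 1L, track$tags)
}

#' Candidate single-strand peaks
#'
#' Finds local maxima of the ChIP coverage and keeps those whose
#' continuity-corrected one-sided score
#' `z = (a - b - 1) / sqrt(a + b)` reaches `z_min`, where `a` is the ChIP
#' coverage at the maximum and the background expectation `b` is the larger
#' of (i) the mean ChIP coverage on the two flanks at +/- 2w and (ii) the
#' input coverage at the maximum scaled by the ratio of library sizes.
#' Maxima closer than `w` are merged, keeping the higher-coverage one, and
#' the merged peak is re-centered on the median tag position within
#' `+/-w` (see the source note on moving-sum plateaus).
#'
#' @param chip ChIP [strand_coverage()] track.
#' @param input matched input track (same replicon and strand).
#' @param z_min minimum z score for a candidate (default 4, a genome-scale
#'   pre-filter).
#' @return data.frame with columns `strand`, `location`, `a`, `b`, `z`.
#' @export
candidate_peaks <- function(chip, input, z_min = 4) {
  stopifnot(inherits(chip, "CoverageTrack"),
            inherits(input, "CoverageTrack"),
            chip$replicon == input$replicon, chip$strand == input$strand)
  if (input$library_size == 0) stop("input library has zero tags")
  empty <- data.frame(strand = character(0), location = integer(0),
                      a = numeric(0), b = numeric(0), z = numeric(0))
  pos <- unique(chip$tags)
  if (length(pos) == 0) return(empty)
  w <- chip$w
  a <- coverage_at(chip, pos)
  lo <- findInterval(pos - w - 1L, pos) + 1L
  hi <- findInterval(pos + w, pos)
  is_max <- vapply(seq_along(pos),
                   function(i) a[i] >= max(a[lo[i]:hi[i]]), logical(1))
  pos <- pos[is_max]; a <- a[is_max]
  # merge maxima closer than w into clusters, keeping the higher count.
  # the top of a moving sum is a near-flat plateau whose single highest
  # position can be set by one stray tag, so the reported location is the
  # median same-strand tag position within +/-w of the plateau center —
  # the maximum-density estimate of the fragment-end pileup
  cl <- cumsum(c(1L, as.integer(diff(pos) >= w)))
  pos <- vapply(split(seq_along(pos), cl), function(idx) {
    amax <- max(a[idx])
    plateau <- pos[idx][a[idx] == amax]
    p0 <- plateau[ceiling(length(plateau) / 2)]
    near <- chip$tags[chip$tags >= p0 - w & chip$tags <= p0 + w]
    as.integer(round(median(near)))
  }, integer(1))
  a <- coverage_at(chip, pos)
  flank <- (coverage_at(chip, pos - 2L * w) +
            coverage_at(chip, pos + 2L * w)) / 2
  scaled_input <- coverage_at(input, pos) *
    chip$library_size / input$library_size
  b <- pmax(flank, scaled_input)
  z <- (a - b - 1) / sqrt(a + b)
  ok <- z >= z_min
  data.frame(strand = rep(chip$strand, sum(ok)), location = pos[ok],
             a = a[ok], b = b[ok], z = z[ok])
}

#' Pair forward and reverse peaks into double-strand binding regions
#'
#' Greedy pairing by descending forward-peak z: each forward peak takes the
#' nearest not-yet-used downstream reverse peak whose lag (reverse minus
#' forward location) lies in `[min_lag, max_lag]`.  The region spans the
#' two peak locations; the reported binding location is the floor of their
#' mean.  Unmatched peaks are dropped.
#'
#' @param fwd,rev candidate data.frames from [candidate_peaks()] for the
#'   forward and reverse strand of one replicon.
#' @param min_lag,max_lag allowed lag window in bp (brackets the fragment
#'   length; defaults 50-400 for ~200-bp fragments).
#' @param replicon replicon name attached to the output.
#' @return unscored region data.frame with columns `replicon`, `start`,
#'   `end`, `location`, `midpoint`, `a_pair`, `b_pair`.
#' @export
pair_peaks <- function(fwd, rev, min_lag = 50L, max_lag = 400L,
                       replicon = "chr") {
  if (min_lag >= max_lag) stop("min_lag must be smaller than max_lag")
  empty <- data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), location = integer(0),
                      midpoint = integer(0), a_pair = numeric(0),
                      b_pair = numeric(0))
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(empty)
  used <- logical(nrow(rev))
  out <- vector("list", nrow(fwd))
  for (i in order(-fwd$z, fwd$location)) {
    lag <- rev$location - fwd$location[i]
    cand <- which(lag >= min_lag & lag <= max_lag & !used)
    if (length(cand) == 0) next
    j <- cand[which.min(lag[cand])]
    used[j] <- TRUE
    out[[i]] <- data.frame(
      replicon = replicon,
      start = fwd$location[i], end = rev$location[j],
      location = as.integer((fwd$location[i] + rev$location[j]) %/% 2),
      midpoint = region_midpoint(fwd$location[i], rev$location[j]),
      a_pair = fwd$a[i] + rev$a[j],
      b_pair = fwd$b[i] + rev$b[j])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a paired double-strand region
#'
#' The paired statistic replaces the single-strand coverage with the sum of
#' the coverages at the forward and reverse peak locations:
#' `a_pair = C_fwd(start) + C_rev(end)`, with the summed background
#' expectation `b_pair`, giving
#' `z_pair = (a_pair - b_pair - 1) / sqrt(a_pair + b_pair)`.  The one-sided
#' p-value is the upper normal tail of `z_pair`, computed entirely in log10
#' space so that astronomically significant peaks keep a finite
#' `-log10(p)` (NLQ values in the thousands are routine for deeply
#' sequenced bacterial ChIP data).
#'
#' Also computes `log10_minp`, the smallest attainable p-value for the
#' region's discreteness-aware FDR adjustment: the tail probability of the
#' most extreme outcome in which the whole observed total `a_pair + b_pair`
#' falls in the peak.
#'
#' @param regions unscored region data.frame from [pair_peaks()].
#' @return the data.frame with `z_pair`, `log10_p`, `log10_minp` added.
#' @export
score_regions <- function(regions) {
  if (nrow(regions) == 0) {
    regions$z_pair <- numeric(0)
    regions$log10_p <- numeric(0)
    regions$log10_minp <- numeric(0)
    return(regions)
  }
  tot <- regions$a_pair + regions$b_pair
  if (any(tot == 0)) stop("region with zero total coverage")
  regions$z_pair <- (regions$a_pair - regions$b_pair - 1) / sqrt(tot)
  regions$log10_p <- log10_normal_tail(regions$z_pair)
  regions$log10_minp <- log10_normal_tail((tot - 1) / sqrt(tot))
  regions
}

#' Upper normal tail probability in log10 space
#'
#' `log10 P(Z >= z)` for a standard normal `Z`, finite for arbitrarily
#' large `z` (R's `pnorm(log.p = TRUE)` switches to an asymptotic
#' expansion internally).
#'
#' @param z numeric vector.
#' @return numeric vector of log10 tail probabilities.
#' @export
log10_normal_tail <- function(z) {
  pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
}
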