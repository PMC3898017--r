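#' Promoter-architecture parameters
#'
#' Canonical bacterial Class II activator geometry for a dimeric
#' CRP-family site: the 14-nt site is separated from a TAN3T -10 box by a
#' ~22-nt spacer and its 3' end lies ~35 nt from the transcription start
#' point (TSP base counted), putting the site center ~41.5 nt upstream of
#' the TSP.  Windows allow ~2 nt of slack on each element.  The
#' repressor-like window is the promoter footprint around the TSP
#' (from the -35 element through just past the TSP) that an operator
#' overlapping site would occlude.
#'
#' @param spacer_min,spacer_max accepted exclusive site-to-box spacer (nt).
#' @param tsp_min,tsp_max accepted site 3'-end-to-TSP distance (nt).
#' @param repressor_window numeric length-2 offset window around the TSP,
#'   `c(-35, 15)` by default: a site overlapping `[TSP-35, TSP+15]` (same
#'   strand) without Class II geometry is repressor-like.
#' @return an `arch_params` list.
#' @export
arch_params <- function(spacer_min = 20L, spacer_max = 24L,
                        tsp_min = 30L, tsp_max = 40L,
                        repressor_window = c(-35, 15)) {
  stopifnot(spacer_min <= spacer_max, tsp_min <= tsp_max,
            length(repressor_window) == 2,
            repressor_window[1] <= repressor_window[2])
  structure(list(spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 tsp_min = as.integer(tsp_min),
                 tsp_max = as.integer(tsp_max),
                 repressor_window = repressor_window),
            class = "arch_params")
}

#' Find a -10 box (TAN3T) downstream of a binding site
#'
#' Scans the sequence immediately downstream of the site 3' end for the
#' first `TAN3T` hexamer whose exclusive spacer (number of intervening
#' nucleotides between site 3' end and box start) lies within the window.
#' A TAN3T match closer than `spacer_min` is ignored, not rejected.
#'
#' @param downstream sequence starting at the first base after the site
#'   3' end.
#' @param spacer_min,spacer_max accepted spacer window (nt).
#' @return list with `spacer`, `box` (6-mer) and `box_start` (1-based
#'   offset of the box within `downstream`), or `NULL` if no box in
#'   window.
#' @export
#' @examples
#' find_minus10("AATACTTTTAAGATGACTGTTATATGCTTTCTAAG")  # TATGCT, spacer 22
find_minus10 <- function(downstream, spacer_min = 20L, spacer_max = 24L) {
  s <- strsplit(toupper(downstream), "", fixed = TRUE)[[1]]
  for (spacer in seq.int(spacer_min, spacer_max)) {
    j <- spacer + 1L           # box start offset
    if (j + 5L > length(s)) break
    if (s[j] == "T" && s[j + 1L] == "A" && s[j + 5L] == "T")
      return(list(spacer = spacer,
                  box = paste(s[j:(j + 5L)], collapse = ""),
                  box_start = j))
  }
  NULL
}

#' Site-to-TSP distance
#'
#' Strand-aware distance from the 3' end of a 14-nt site to a
#' transcription start point, counting the intervening bases plus the TSP
#' base itself (so a TSP immediately after the site end is at distance 1).
#' Also returns the half-integer site-center-to-TSP distance
#' (`tsp_distance + 6.5` for a 14-nt site).  A TSP upstream of the site
#' 3' end yields a negative distance, not an error.
#'
#' @param site_start 1-based leftmost genomic position of the 14-mer.
#' @param strand site strand (`"+"` or `"-"`).
#' @param tsp_pos 1-based genomic position of the TSP (+1) base.
#' @return list with `tsp_distance` and `center_to_tsp`.
#' @export
site_tsp_distance <- function(site_start, strand, tsp_pos) {
  d <- if (strand == "+") tsp_pos - (site_start + 13L)
       else site_start - tsp_pos
  list(tsp_distance = d, center_to_tsp = d + 6.5)
}

#' Classify the promoter architecture around a binding site
#'
#' Decision rule, applied in the site's own strand frame:
#'
#' * `CLASS_II_ACTIVATOR` — a TAN3T -10 box lies in the spacer window
#'   downstream of the site, and either no TSP information is available or
#'   a same-strand TSP sits at a 3'-end distance within the TSP window.
#' * `REPRESSOR_LIKE` — no Class II geometry, but the site interval
#'   overlaps the promoter footprint `[TSP + repressor_window]` of a
#'   same-strand TSP (an operator position occluding the promoter).
#' * `SITE_ONLY` — neither; a binding site with no recognizable promoter
#'   context.
#'
#' @param context the sequence of the replicon (or region) containing the
#'   site, top strand.
#' @param site_start 1-based leftmost position of the 14-mer in `context`.
#' @param strand site strand.
#' @param tsps optional data.frame of TSP records (`position`, `strand`,
#'   optionally `regulation`) in `context` coordinates; `NULL` or
#'   zero rows means no TSP information.
#' @param params an [arch_params()].
#' @return list with `class`, `minus10`, `box_start` (oriented-frame
#'   offset of the box from the site 3' end), `spacer`, `tsp_distance`,
#'   `center_to_tsp`, `tsp_position`.
#' @export
classify_promoter <- function(context, site_start, strand = "+",
                              tsps = NULL, params = arch_params()) {
  L <- nchar(context)
  if (site_start < 1 || site_start + 13L > L)
    stop("site outside the supplied sequence context")
  # mirror a minus-strand problem onto the plus strand
  flipped <- identical(strand, "-")
  if (flipped) {
    context <- revcomp(context)
    site_start <- L - (site_start + 13L) + 1L
    if (!is.null(tsps) && nrow(tsps)) {
      tsps$position <- L - tsps$position + 1L
      tsps$strand <- ifelse(tsps$strand == "+", "-", "+")
    }
    strand <- "+"
  }
  site_end <- site_start + 13L
  down <- if (site_end < L)
    substr(context, site_end + 1L, min(L, site_end + params$spacer_max + 6L))
  else ""
  box <- if (nchar(down) >= params$spacer_min + 6L)
    find_minus10(down, params$spacer_min, params$spacer_max) else NULL
  same <- if (!is.null(tsps) && nrow(tsps))
    tsps[tsps$strand == "+", , drop = FALSE] else NULL
  have_tsps <- !is.null(tsps) && nrow(tsps) > 0
  call <- list(class = "SITE_ONLY", minus10 = NA_character_,
               box_start = NA_integer_, spacer = NA_integer_,
               tsp_distance = NA_integer_, center_to_tsp = NA_real_,
               tsp_position = NA_integer_)
  if (!is.null(box)) {
    call$minus10 <- box$box
    call$box_start <- box$box_start
    call$spacer <- box$spacer
  }
  done <- FALSE
  if (!is.null(box)) {
    if (!have_tsps) {
      call$class <- "CLASS_II_ACTIVATOR"
      done <- TRUE
    } else if (!is.null(same) && nrow(same)) {
      d <- same$position - site_end
      ok <- d >= params$tsp_min & d <= params$tsp_max
      if (any(ok)) {
        j <- which(ok)[which.min(abs(d[ok] - 35))]
        call$class <- "CLASS_II_ACTIVATOR"
        call$tsp_distance <- d[j]
        call$center_to_tsp <- d[j] + 6.5
        call$tsp_position <- same$position[j]
        done <- TRUE
      }
    }
  }
  if (!done && !is.null(same) && nrow(same)) {
    lo <- same$position + params$repressor_window[1]
    hi <- same$position + params$repressor_window[2]
    ov <- site_start <= hi & site_end >= lo
    if (any(ov)) {
      j <- which(ov)[1]
      d <- same$position[j] - site_end
      call$class <- "REPRESSOR_LIKE"
      call$tsp_distance <- d
      call$center_to_tsp <- d + 6.5
      call$tsp_position <- same$position[j]
    }
  }
  # report the TSP in the caller's coordinate frame
  if (flipped && !is.na(call$tsp_position))
    call$tsp_position <- L - call$tsp_position + 1L
  call
}
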