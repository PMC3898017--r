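#' Peak-calling parameters
#'
#' @param w coverage window half-width in bp.
#' @param z_min per-strand candidate z threshold.
#' @param min_lag,max_lag forward-to-reverse peak lag window in bp
#'   (brackets the sonication fragment length).
#' @param fdr Q-value cutoff for reported regions.
#' @return a `peak_params` list.
#' @export
peak_params <- function(w = 100L, z_min = 4, min_lag = 50L, max_lag = 400L,
                        fdr = 0.05) {
  stopifnot(w > 0, min_lag < max_lag, fdr > 0, fdr <= 1)
  structure(list(w = as.integer(w), z_min = z_min,
                 min_lag = as.integer(min_lag),
                 max_lag = as.integer(max_lag), fdr = fdr),
            class = "peak_params")
}

#' Call double-strand binding regions
#'
#' Full peak-calling pipeline over all replicons of a ChIP / input library
#' pair: strand-specific moving-sum coverage, per-strand candidate maxima,
#' forward/reverse pairing into double-strand regions, paired z scoring
#' with log-space p-values, Tarone-modified Benjamini-Yekutieli Q values,
#' and the NLQ (`-log10 Q`) ranking statistic.  Regions with `Q <= fdr`
#' are returned sorted by NLQ descending; identifiers are assigned in
#' genome order.
#'
#' @param chip ChIP [tag_library()].
#' @param input matched input [tag_library()].
#' @param params a [peak_params()].
#' @return data.frame with columns `id`, `replicon`, `start`, `end`,
#'   `location`, `midpoint`, `a_pair`, `b_pair`, `z_pair`, `log10_p`,
#'   `log10_q`, `Q`, `nlq`.
#' @export
call_binding_regions <- function(chip, input, params = peak_params()) {
  stopifnot(inherits(chip, "TagLibrary"), inherits(input, "TagLibrary"))
  regions <- lapply(names(chip$tags), function(rep) {
    if (!rep %in% names(input$tags))
      stop("replicon missing from input library: ", rep)
    fwd <- candidate_peaks(strand_coverage(chip, rep, "+", params$w),
                           strand_coverage(input, rep, "+", params$w),
                           params$z_min)
    rev <- candidate_peaks(strand_coverage(chip, rep, "-", params$w),
                           strand_coverage(input, rep, "-", params$w),
                           params$z_min)
    score_regions(pair_peaks(fwd, rev, params$min_lag, params$max_lag, rep))
  })
  regions <- do.call(rbind, regions)
  if (is.null(regions) || nrow(regions) == 0) return(empty_regions())
  regions$log10_q <- tarone_by_log10q(regions$log10_p, regions$log10_minp)
  regions <- regions[regions$log10_q <= log10(params$fdr), , drop = FALSE]
  if (nrow(regions) == 0) return(empty_regions())
  # ids in genome order (replicon order of the library, then coordinate)
  regions <- regions[order(match(regions$replicon, names(chip$tags)),
                           regions$start), , drop = FALSE]
  regions$id <- seq_len(nrow(regions))
  regions$Q <- 10^regions$log10_q
  regions$nlq <- -regions$log10_q
  regions <- regions[order(-regions$nlq, regions$id), , drop = FALSE]
  rownames(regions) <- NULL
  regions[c("id", "replicon", "start", "end", "location", "midpoint",
            "a_pair", "b_pair", "z_pair", "log10_p", "log10_q", "Q", "nlq")]
}

empty_regions <- function() {
  data.frame(id = integer(0), replicon = character(0), start = integer(0),
             end = integer(0), location = integer(0), midpoint = integer(0),
             a_pair = numeric(0), b_pair = numeric(0), z_pair = numeric(0),
             log10_p = numeric(0), log10_q = numeric(0), Q = numeric(0),
             nlq = numeric(0))
}
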