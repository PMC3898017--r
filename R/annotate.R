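#' Region-to-gene assignment parameters
#'
#' Bacterial 5'-UTRs — particularly in cyanobacteria — are frequently very
#' long, so a binding region may regulate a gene whose start codon is far
#' downstream.  These windows bound the search; none of them is dictated
#' by the underlying biology, so all are configurable.
#'
#' @param u_close maximum gap (bp) for the UPSTREAM_CLOSE class.
#' @param d_up maximum anchor-to-gene-start gap (bp) for any upstream
#'   assignment (long 5'-UTR allowance).
#' @param d_down maximum gene-end-to-anchor gap (bp) for a downstream
#'   assignment.
#' @param tie_tol two candidates whose distances differ by at most this
#'   many bp are treated as tied.
#' @return an `assign_params` list.
#' @export
assign_params <- function(u_close = 200L, d_up = 1500L, d_down = 300L,
                          tie_tol = 10L) {
  stopifnot(u_close > 0, d_up >= u_close, d_down > 0, tie_tol >= 0)
  structure(list(u_close = as.integer(u_close), d_up = as.integer(d_up),
                 d_down = as.integer(d_down), tie_tol = as.integer(tie_tol)),
            class = "assign_params")
}

#' Classify a binding position relative to a gene
#'
#' Strand-aware positional classes: upstream of the gene's 5' end
#' (`UPSTREAM_CLOSE` within `u_close`, else `UPSTREAM_FAR` within `d_up`),
#' inside the gene (`INTERNAL_5` in the 5'-most half, `INTERNAL_3`
#' otherwise; a dead-center anchor goes 5'), or past the 3' end within
#' `d_down` (`DOWNSTREAM`).
#'
#' @param anchor integer position (a region midpoint).
#' @param gene one-row gene data.frame (`start`, `end`, `strand`).
#' @param params an [assign_params()].
#' @return one of `"UPSTREAM_FAR"`, `"UPSTREAM_CLOSE"`, `"INTERNAL_5"`,
#'   `"INTERNAL_3"`, `"DOWNSTREAM"`.
#' @export
classify_position <- function(anchor, gene, params = assign_params()) {
  start <- gene$start; end <- gene$end
  if (anchor >= start && anchor <= end) {
    # offset from the 5' end in transcription direction
    off <- if (gene$strand == "+") anchor - start else end - anchor
    len <- end - start + 1L
    return(if (off <= (len - 1) / 2) "INTERNAL_5" else "INTERNAL_3")
  }
  gap5 <- if (gene$strand == "+") start - anchor else anchor - end
  if (gap5 > 0) {
    if (gap5 <= params$u_close) return("UPSTREAM_CLOSE")
    if (gap5 <= params$d_up) return("UPSTREAM_FAR")
    stop("anchor outside all classification windows")
  }
  gap3 <- if (gene$strand == "+") anchor - end else start - anchor
  if (gap3 > 0 && gap3 <= params$d_down) return("DOWNSTREAM")
  stop("anchor outside all classification windows")
}

#' Assign binding regions to genes
#'
#' Each region is anchored at its midpoint (the most likely binding
#' position).  Candidates are: the gene(s) containing the anchor, the
#' nearest gene whose 5' end lies downstream of the anchor within `d_up`
#' (strand-aware), and the nearest gene whose 3' end lies upstream within
#' `d_down`.  Containment beats proximity.  When two candidates tie
#' (distance difference at most `tie_tol`) and an expression table flags
#' exactly one of them as differentially regulated, the flagged gene wins;
#' an unresolved tie reports both genes ("two genes, when it is not
#' possible to decide between flanking genes").  Regions with no candidate
#' get an explicit `NA` gene row, so region counts are conserved.
#'
#' @param regions region data.frame (needs `id`, `replicon`, `start`,
#'   `end`; `midpoint` recomputed if absent).
#' @param genes gene data.frame ([read_annotation()] layout); sRNA entries
#'   are handled like genes.
#' @param expression optional data.frame with a `gene_id` column listing
#'   differentially regulated genes (used only to break ties).
#' @param params an [assign_params()].
#' @return data.frame with one row per (region, gene): `region_id`,
#'   `replicon`, `gene_id`, `position_class`, `distance`.
#' @export
assign_regions <- function(regions, genes, expression = NULL,
                           params = assign_params()) {
  if (nrow(genes) == 0) stop("empty annotation")
  flagged <- if (!is.null(expression)) unique(expression$gene_id)
             else character(0)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    anchor <- region_midpoint(regions$start[i], regions$end[i])
    g <- genes[genes$replicon == regions$replicon[i], , drop = FALSE]
    cand <- candidate_genes(anchor, g, params)
    chosen <- choose_candidates(cand, flagged, params$tie_tol)
    out[[i]] <- if (is.null(chosen) || nrow(chosen) == 0) {
      data.frame(region_id = regions$id[i], replicon = regions$replicon[i],
                 gene_id = NA_character_, position_class = NA_character_,
                 distance = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(region_id = regions$id[i], replicon = regions$replicon[i],
                 gene_id = chosen$gene_id,
                 position_class = vapply(seq_len(nrow(chosen)), function(k)
                   classify_position(anchor,
                                     g[g$gene_id == chosen$gene_id[k], ],
                                     params), character(1)),
                 distance = chosen$distance, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all assignment candidates for one anchor: containment (distance 0,
# highest rank) plus nearest-by-5'-end upstream and nearest-by-3'-end
# downstream genes within the configured windows
candidate_genes <- function(anchor, genes, params) {
  if (nrow(genes) == 0)
    return(data.frame(gene_id = character(0), distance = integer(0),
                      containment = logical(0)))
  inside <- genes$start <= anchor & genes$end >= anchor
  gap5 <- ifelse(genes$strand == "+", genes$start - anchor,
                 anchor - genes$end)
  gap3 <- ifelse(genes$strand == "+", anchor - genes$end,
                 genes$start - anchor)
  up <- !inside & gap5 > 0 & gap5 <= params$d_up
  down <- !inside & gap3 > 0 & gap3 <= params$d_down
  pick_nearest <- function(sel, gap, tol) {
    if (!any(sel)) return(NULL)
    # keep every gene tied (within tol) with the nearest one, so that
    # e.g. two divergent gene starts flanking the anchor both survive
    k <- which(sel)[gap[sel] <= min(gap[sel]) + tol]
    data.frame(gene_id = genes$gene_id[k], distance = gap[k],
               containment = FALSE, stringsAsFactors = FALSE)
  }
  rbind(
    if (any(inside))
      data.frame(gene_id = genes$gene_id[inside], distance = 0L,
                 containment = TRUE, stringsAsFactors = FALSE),
    pick_nearest(up, gap5, params$tie_tol),
    pick_nearest(down, gap3, params$tie_tol))
}

choose_candidates <- function(cand, flagged, tie_tol) {
  if (is.null(cand) || nrow(cand) == 0) return(cand)
  if (any(cand$containment)) cand <- cand[cand$containment, , drop = FALSE]
  best <- min(cand$distance)
  tied <- cand[cand$distance <= best + tie_tol, , drop = FALSE]
  if (nrow(tied) > 1 && length(flagged)) {
    fl <- tied$gene_id %in% flagged
    if (any(fl) && !all(fl)) tied <- tied[fl, , drop = FALSE]
  }
  if (nrow(tied) == 1) return(tied)
  head(tied[order(tied$distance), , drop = FALSE], 2)  # report two genes
}

#' Summarize binding-region positions per replicon
#'
#' Collapses per-gene positional classes to Upstream / Internal /
#' Downstream super-classes, counted per gene assignment (a two-gene
#' region contributes twice), and reports per replicon and in total:
#' region count, distinct ascribed genes, the three super-class counts,
#' and the internal share `100 * internal / (up + internal + down)`
#' rounded to the nearest integer.
#'
#' @param assignments data.frame from [assign_regions()].
#' @return data.frame, one row per replicon plus a `"total"` row.
#' @export
summarize_positions <- function(assignments) {
  sup <- position_superclass(assignments$position_class)
  one <- function(d, sup) {
    data.frame(
      regions = length(unique(d$region_id)),
      genes = length(unique(d$gene_id[!is.na(d$gene_id)])),
      upstream = sum(sup == "Upstream", na.rm = TRUE),
      internal = sum(sup == "Internal", na.rm = TRUE),
      downstream = sum(sup == "Downstream", na.rm = TRUE))
  }
  parts <- lapply(split(seq_len(nrow(assignments)), assignments$replicon),
                  function(idx) one(assignments[idx, ], sup[idx]))
  res <- do.call(rbind, parts)
  res <- cbind(replicon = rownames(res), res)
  tot <- one(assignments, sup)
  res <- rbind(res, cbind(replicon = "total", tot))
  res$pct_internal <- internal_share(res$upstream, res$internal,
                                     res$downstream)
  rownames(res) <- NULL
  res
}

position_superclass <- function(class) {
  ifelse(is.na(class), NA_character_,
  ifelse(class %in% c("UPSTREAM_FAR", "UPSTREAM_CLOSE"), "Upstream",
  ifelse(class %in% c("INTERNAL_5", "INTERNAL_3"), "Internal",
         "Downstream")))
}

#' Internal (intragenic) share of binding positions
#'
#' `round(100 * internal / (upstream + internal + downstream))`, the
#' headline percentage of intragenically located binding regions.
#'
#' @param upstream,internal,downstream position counts.
#' @return integer percentage(s).
#' @export
#' @examples
#' internal_share(865, 1762, 79)  # 65
internal_share <- function(upstream, internal, downstream) {
  tot <- upstream + internal + downstream
  ifelse(tot == 0, NA_real_, round(100 * internal / tot))
}

#' Summarize functional categories of ascribed genes
#'
#' Counts genes per functional category (each gene once, in its primary
#' category) and the percentage of the total ascribed genes, rounded to
#' one decimal.
#'
#' @param genes data.frame with columns `gene_id` and `category` (missing
#'   categories default to `"hypothetical"`).
#' @return data.frame with `category`, `n_genes`, `percent`, sorted by
#'   descending count.
#' @export
summarize_categories <- function(genes) {
  cat <- genes$category
  cat[is.na(cat) | cat == ""] <- "hypothetical"
  cat <- cat[!duplicated(genes$gene_id)]
  n <- table(cat)
  res <- data.frame(category = names(n), n_genes = as.integer(n),
                    stringsAsFactors = FALSE)
  res$percent <- round(100 * res$n_genes / sum(res$n_genes), 1)
  res <- res[order(-res$n_genes, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare a found site list with an external prediction list
#'
#' Symmetric greedy matching: candidate pairs on the same replicon within
#' `tolerance` bp are matched in order of increasing distance, each site
#' used at most once.
#'
#' @param found data.frame with `replicon` and `position`.
#' @param predicted data.frame with `replicon` and `position`.
#' @param tolerance maximum distance (bp) for a match.
#' @return list with `common` (data.frame of matched index pairs and
#'   distances), `found_only` and `predicted_only` (row indices).
#' @export
compare_site_lists <- function(found, predicted, tolerance = 50) {
  if (tolerance < 0) stop("negative tolerance")
  pairs <- NULL
  if (nrow(found) && nrow(predicted)) {
    pairs <- do.call(rbind, lapply(seq_len(nrow(found)), function(i) {
      sel <- which(predicted$replicon == found$replicon[i] &
                   abs(predicted$position - found$position[i]) <= tolerance)
      if (length(sel) == 0) return(NULL)
      data.frame(found = i, predicted = sel,
                 distance = abs(predicted$position[sel] -
                                found$position[i]))
    }))
  }
  common <- data.frame(found = integer(0), predicted = integer(0),
                       distance = numeric(0))
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(pairs$distance, pairs$found, pairs$predicted), ]
    used_f <- logical(nrow(found)); used_p <- logical(nrow(predicted))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$found[r]; j <- pairs$predicted[r]
      if (!used_f[i] && !used_p[j]) {
        used_f[i] <- TRUE; used_p[j] <- TRUE
        common <- rbind(common, pairs[r, ])
      }
    }
  }
  list(common = common,
       found_only = setdiff(seq_len(nrow(found)), common$found),
       predicted_only = setdiff(seq_len(nrow(predicted)), common$predicted))
}

#' Q-PCR fold enrichment
#'
#' `enrichment = 2^(Ct_sample - Ct_control)`, with the input sample as the
#' control — the formula used to validate ChIP enrichment of a promoter
#' region.
#'
#' @param ct_sample,ct_control finite threshold-cycle values.
#' @return fold enrichment (> 0).
#' @export
#' @examples
#' qpcr_enrichment(25, 22)  # 8
qpcr_enrichment <- function(ct_sample, ct_control) {
  if (any(!is.finite(ct_sample)) || any(!is.finite(ct_control)))
    stop("non-finite Ct value")
  2^(ct_sample - ct_control)
}
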