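# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (full enumeration, explicit loops) and must not share
# code with the implementation they check.

# moving-sum coverage by direct recount
bf_coverage <- function(tags, x, w) {
  vapply(x, function(p) sum(tags >= p - w & tags <= p + w), numeric(1))
}

# 14-mer motif scan by per-window string comparison, with the same
# reporting rule: minus-strand record dropped when a plus record at the
# same window has the same score
bf_scan <- function(seq, min_score, require_g1 = FALSE) {
  consensus <- c("G", "T", "A", rep(NA, 8), "T", "A", "C")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(seq, "")[[1]]
  score_win <- function(win) {
    sum(win[c(1:3, 12:14)] == consensus[c(1:3, 12:14)])
  }
  out <- NULL
  for (i in seq_len(nchar(seq) - 13)) {
    win <- chars[i:(i + 13)]
    rcwin <- rev(unname(comp[win]))
    sp <- score_win(win)
    sm <- score_win(rcwin)
    keep_p <- sp >= min_score && (!require_g1 || win[1] == "G")
    keep_m <- sm >= min_score && (!require_g1 || rcwin[1] == "G")
    if (keep_p)
      out <- rbind(out, data.frame(start = i, strand = "+",
                                   sequence = paste(win, collapse = ""),
                                   score = sp))
    if (keep_m && !(keep_p && sp == sm))
      out <- rbind(out, data.frame(start = i, strand = "-",
                                   sequence = paste(rcwin, collapse = ""),
                                   score = sm))
  }
  if (is.null(out))
    out <- data.frame(start = integer(0), strand = character(0),
                      sequence = character(0), score = numeric(0))
  rownames(out) <- NULL
  out
}

# peak pairing by explicit greedy loops
bf_pair <- function(fwd, rev, min_lag, max_lag) {
  taken <- rep(FALSE, nrow(rev))
  res <- NULL
  for (i in order(-fwd$z, fwd$location)) {
    best_j <- NA
    best_lag <- Inf
    for (j in seq_len(nrow(rev))) {
      lag <- rev$location[j] - fwd$location[i]
      if (!taken[j] && lag >= min_lag && lag <= max_lag && lag < best_lag) {
        best_j <- j; best_lag <- lag
      }
    }
    if (!is.na(best_j)) {
      taken[best_j] <- TRUE
      res <- rbind(res, data.frame(start = fwd$location[i],
                                   end = rev$location[best_j]))
    }
  }
  if (is.null(res)) return(data.frame(start = integer(0), end = integer(0)))
  res[order(res$start), , drop = FALSE]
}

# minimal-distance site matching by exhaustive search: repeatedly find the
# globally closest admissible pair by full enumeration
bf_match <- function(found, predicted, tol) {
  used_f <- rep(FALSE, nrow(found))
  used_p <- rep(FALSE, nrow(predicted))
  pairs <- NULL
  repeat {
    best <- NULL
    for (i in seq_len(nrow(found))) for (j in seq_len(nrow(predicted))) {
      if (used_f[i] || used_p[j]) next
      if (found$replicon[i] != predicted$replicon[j]) next
      d <- abs(found$position[i] - predicted$position[j])
      if (d <= tol && (is.null(best) || d < best$d))
        best <- list(i = i, j = j, d = d)
    }
    if (is.null(best)) break
    used_f[best$i] <- TRUE; used_p[best$j] <- TRUE
    pairs <- rbind(pairs, data.frame(found = best$i, predicted = best$j,
                                     distance = best$d))
  }
  pairs
}

# exhaustive nearest-feature gene assignment for one anchor
bf_assign <- function(anchor, genes, params) {
  best <- NULL
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$start <= anchor && g$end >= anchor) {
      d <- 0; type <- "containment"
    } else {
      gap5 <- if (g$strand == "+") g$start - anchor else anchor - g$end
      gap3 <- if (g$strand == "+") anchor - g$end else g$start - anchor
      if (gap5 > 0 && gap5 <= params$d_up) { d <- gap5; type <- "up" }
      else if (gap3 > 0 && gap3 <= params$d_down) { d <- gap3; type <- "down" }
      else next
    }
    best <- rbind(best, data.frame(gene_id = g$gene_id, distance = d,
                                   type = type))
  }
  best
}

random_genome <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# tiny deterministic tag library builder
toy_library <- function(fwd, rev, sample = "chip", replicon = "chr") {
  tags <- list(list(fwd = fwd, rev = rev))
  names(tags) <- replicon
  tag_library(sample, tags)
}

# shared default simulation, built once per test run (~1 s)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_chip_experiment(sim_config(seed = 42L))
    cache
  }
})

top_regions <- function() {
  read.delim(system.file("extdata", "ntca_top_regions.tsv",
                         package = "regulonmapr"),
             stringsAsFactors = FALSE,
             colClasses = c(promoter_seq = "character"))
}
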