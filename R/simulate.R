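#' Configuration for the synthetic ChIP experiment
#'
#' The generator emulates a sonicated-chromatin ChIP-Seq experiment on a
#' small bacterial genome: ~200-bp fragments whose 5' ends pile up on the
#' forward strand upstream and on the reverse strand downstream of each
#' protein-bound site, a mixture of intragenic and intergenic sites
#' (defaults mirror the observed 65% intragenic share of the NtcA map),
#' wide per-site occupancy (affinity) variation, uniform background, and a
#' deeper uniform input library.
#'
#' @param genome_length replicon length in bp.
#' @param n_genes number of non-overlapping genes to place.
#' @param n_sites number of planted 14-nt GTAN8TAC-like sites.
#' @param frac_intragenic fraction of sites placed inside gene bodies.
#' @param fragment_mean,fragment_sd sonication fragment length model (bp);
#'   fragments are truncated at 50 bp.
#' @param strength_range per-site expected ChIP fragment-pair counts are
#'   drawn log-uniformly from this range (occupancy/affinity variation).
#' @param background_rate ChIP background tags per bp per strand.
#' @param input_rate input-library tags per bp per strand.
#' @param site_mutation_rate per-position substitution probability at the
#'   six constrained motif positions of a planted site.
#' @param seed integer; fully determines all generated output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 500000L, n_genes = 400L,
                       n_sites = 60L, frac_intragenic = 0.65,
                       fragment_mean = 200, fragment_sd = 20,
                       strength_range = c(20, 500),
                       background_rate = 0.002, input_rate = 0.01,
                       site_mutation_rate = 0.1, seed = 1L) {
  stopifnot(genome_length >= 1000, n_genes >= 0, n_sites >= 0,
            frac_intragenic >= 0, frac_intragenic <= 1,
            fragment_mean > 0, fragment_sd >= 0,
            length(strength_range) == 2, all(strength_range > 0),
            background_rate > 0, input_rate > 0,
            site_mutation_rate >= 0, site_mutation_rate <= 1)
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 n_sites = as.integer(n_sites),
                 frac_intragenic = frac_intragenic,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 strength_range = strength_range,
                 background_rate = background_rate, input_rate = input_rate,
                 site_mutation_rate = site_mutation_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

MIN_GENE <- 300L
MAX_GENE <- 3000L
MIN_GAP <- 50L

#' Generate a random genome with a gene complement
#'
#' Nucleotides are i.i.d. uniform over A/C/G/T.  Genes are non-overlapping,
#' of length 300-3000 bp (log-uniform, matching the right-skewed length
#' distribution of bacterial genes), on random strands, separated by
#' intergenic gaps of at least 50 bp.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` ([Genome], single replicon `"chr"`)
#'   and `genes` (gene data.frame).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    L <- config$genome_length
    n <- config$n_genes
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    genes <- data.frame(gene_id = character(0), replicon = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), product = character(0),
                        category = character(0), stringsAsFactors = FALSE)
    if (n > 0) {
      # draw lengths log-uniformly, truncating the range near the end so
      # the remaining genes and minimum gaps always fit
      lens <- integer(n)
      budget <- L - (n + 1L) * MIN_GAP
      for (i in seq_len(n)) {
        remaining <- n - i
        lmax <- min(MAX_GENE, budget - remaining * MIN_GENE)
        if (lmax < MIN_GENE)
          stop("genome too short to place ", n, " genes")
        lens[i] <- as.integer(round(exp(runif(1, log(MIN_GENE), log(lmax)))))
        budget <- budget - lens[i]
      }
      # distribute the leftover space over the n+1 gaps
      extra <- L - sum(lens) - (n + 1L) * MIN_GAP
      cuts <- sort(c(0, runif(n), 1))
      gaps <- MIN_GAP + as.integer(floor(diff(cuts) * extra))
      starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n])) + 1L
      genes <- data.frame(
        gene_id = sprintf("gene%04d", seq_len(n)),
        replicon = "chr",
        start = starts,
        end = starts + lens - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        product = "hypothetical protein",
        category = "hypothetical",
        stringsAsFactors = FALSE)
      stopifnot(all(genes$end <= L))
    }
    list(genome = Genome(c(chr = seq)), genes = genes)
  })
}

# draw one oriented 14-mer site sequence: GTA-N8-TAC with each constrained
# position mutated independently with the configured probability
draw_site_seq <- function(mut_rate) {
  bases <- c("A", "C", "G", "T")
  s <- c("G", "T", "A", sample(bases, 8, replace = TRUE), "T", "A", "C")
  const <- c(1:3, 12:14)
  for (i in const) {
    if (runif(1) < mut_rate) s[i] <- sample(setdiff(bases, s[i]), 1)
  }
  paste(s, collapse = "")
}

splice_seq <- function(seq, at, piece) {
  paste0(substr(seq, 1, at - 1), piece,
         substr(seq, at + nchar(piece), nchar(seq)))
}

#' Plant transcription-factor binding sites into a synthetic genome
#'
#' Writes `n_sites` 14-nt GTAN8TAC-like sites into the sequence (random
#' strand; the reverse complement is written for minus-strand sites).  The
#' configured fraction goes inside gene bodies, the remainder into
#' intergenic gaps.  Half of the intergenic sites additionally get full
#' bacterial Class II activator promoter geometry written downstream of the
#' site 3' end: a TAN3T -10 box after a 22-nt spacer and a transcription
#' start point (TSP) 35 nt from the site 3' end (so the site center lies
#' 41.5 nt upstream of the TSP).
#'
#' @param genome a [Genome] from [generate_genome()].
#' @param genes gene data.frame from [generate_genome()].
#' @param config a [sim_config()].
#' @return list with elements `genome` (modified sequence) and `truth`,
#'   a list holding `sites` (site records with position, strand, planted
#'   sequence, strength, intragenic and Class II flags) and `tsps`
#'   (TSP records with `replicon`, `position`, `strand`, `regulation`).
#' @export
plant_sites <- function(genome, genes, config) {
  stopifnot(inherits(genome, "Genome"), inherits(config, "sim_config"))
  with_local_seed(config$seed + 1L, {
    L <- genome$lengths[["chr"]]
    seq <- genome$replicons[["chr"]]
    n <- config$n_sites
    n_intra <- round(config$frac_intragenic * n)
    n_inter <- n - n_intra
    # candidate intervals; Class II geometry needs 35 nt downstream
    gaps <- intergenic_gaps(genes, L)
    placed_start <- integer(0)
    sites <- vector("list", n)
    tsps <- list()
    place_in <- function(lo, hi) {
      # sites are planted resolvable: at least 500 bp apart (2.5x the
      # fragment length), since closer pileups merge into one region by
      # construction of the assay
      for (try in 1:200) {
        p <- if (hi - 13 < lo) NA_integer_ else
          sample(seq.int(lo, hi - 13L), 1)
        if (!is.na(p) && (length(placed_start) == 0 ||
                          min(abs(placed_start - p)) >= 500)) return(p)
      }
      NA_integer_
    }
    k <- 0L
    make_site <- function(intragenic, class_ii, lo, hi) {
      strand <- sample(c("+", "-"), 1)
      # only the 14-mer must fit the target interval; Class II box/TSP
      # geometry may extend beyond it (promoters abut gene starts) but
      # must stay on the replicon
      if (class_ii) {
        if (strand == "+") hi <- min(hi, L - 35L) else lo <- max(lo, 36L)
      }
      p <- place_in(lo, hi)
      if (is.na(p)) return(NULL)
      oriented <- draw_site_seq(config$site_mutation_rate)
      top <- if (strand == "+") oriented else revcomp(oriented)
      seq <<- splice_seq(seq, p, top)
      placed_start <<- c(placed_start, p)
      strength <- exp(runif(1, log(config$strength_range[1]),
                            log(config$strength_range[2])))
      rec <- data.frame(site_id = NA_character_, replicon = "chr",
                        start = p, strand = strand, sequence = oriented,
                        strength = strength, intragenic = intragenic,
                        class_ii = class_ii, tsp = NA_integer_,
                        stringsAsFactors = FALSE)
      if (class_ii) {
        box <- paste(c("T", "A", sample(c("A", "C", "G", "T"), 3,
                                        replace = TRUE), "T"),
                     collapse = "")
        if (strand == "+") {
          box_start <- p + 13L + 23L        # 22-nt exclusive spacer
          tsp_pos <- p + 13L + 35L          # TSP base counted
          seq <<- splice_seq(seq, box_start, box)
        } else {
          box_start <- p - 28L
          tsp_pos <- p - 35L
          seq <<- splice_seq(seq, box_start, revcomp(box))
        }
        rec$tsp <- tsp_pos
        tsps[[length(tsps) + 1L]] <<-
          data.frame(replicon = "chr", position = tsp_pos, strand = strand,
                     regulation = "induced", stringsAsFactors = FALSE)
      }
      rec
    }
    # intragenic sites
    i <- 0L
    tries <- 0L
    while (i < n_intra) {
      tries <- tries + 1L
      if (nrow(genes) == 0 || tries > 10000L)
        stop("cannot place ", n_intra, " intragenic sites")
      g <- genes[sample.int(nrow(genes), 1), ]
      rec <- make_site(TRUE, FALSE, g$start, g$end)
      if (!is.null(rec)) { i <- i + 1L; k <- k + 1L; sites[[k]] <- rec }
    }
    # intergenic sites; half with Class II geometry
    n_class2 <- n_inter %/% 2L
    j <- 0L
    tries <- 0L
    while (j < n_inter) {
      tries <- tries + 1L
      if (nrow(gaps) == 0 || tries > 10000L)
        stop("insufficient intergenic space")
      gp <- gaps[sample.int(nrow(gaps), 1), ]
      rec <- make_site(FALSE, j < n_class2, gp$start, gp$end)
      if (!is.null(rec)) { j <- j + 1L; k <- k + 1L; sites[[k]] <- rec }
    }
    sites <- do.call(rbind, sites[seq_len(k)])
    if (is.null(sites))
      sites <- data.frame(site_id = character(0), replicon = character(0),
                          start = integer(0), strand = character(0),
                          sequence = character(0), strength = numeric(0),
                          intragenic = logical(0), class_ii = logical(0),
                          tsp = integer(0), stringsAsFactors = FALSE)
    if (nrow(sites)) {
      sites <- sites[order(sites$start), , drop = FALSE]
      sites$site_id <- sprintf("site%03d", seq_len(nrow(sites)))
      rownames(sites) <- NULL
    }
    tsps <- if (length(tsps)) do.call(rbind, tsps) else
      data.frame(replicon = character(0), position = integer(0),
                 strand = character(0), regulation = character(0),
                 stringsAsFactors = FALSE)
    list(genome = Genome(c(chr = seq)),
         truth = list(sites = sites, tsps = tsps))
  })
}

intergenic_gaps <- function(genes, L) {
  if (nrow(genes) == 0)
    return(data.frame(start = 1L, end = L))
  g <- genes[order(genes$start), ]
  starts <- c(1L, g$end + 1L)
  ends <- c(g$start - 1L, L)
  ok <- ends - starts >= 20
  data.frame(start = starts[ok], end = ends[ok])
}

#' Simulate ChIP and input tag libraries from planted-site truth
#'
#' Per site, a Poisson(`strength`) number of fragment pairs is drawn; each
#' fragment has length ~ Normal(`fragment_mean`, `fragment_sd`) truncated
#' at 50 bp and is centered on the site center with +/-10 bp uniform
#' jitter.  One forward tag is placed at the fragment's left end and one
#' reverse tag at its right end — the strand-paired pileup geometry that
#' double-strand peak calling exploits.  ChIP background and the whole
#' input library are homogeneous Poisson processes per strand.
#'
#' @param truth truth list from [plant_sites()] (may contain zero sites
#'   for a null experiment).
#' @param config a [sim_config()].
#' @return list with elements `chip` and `input`, both [tag_library()]s.
#' @export
simulate_tags <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed + 2L, {
    L <- config$genome_length
    fwd <- integer(0); rev <- integer(0)
    sites <- truth$sites
    if (!is.null(sites) && nrow(sites)) {
      for (i in seq_len(nrow(sites))) {
        k <- rpois(1, sites$strength[i])
        if (k == 0) next
        center <- sites$start[i] + 6.5 + sample(-10:10, k, replace = TRUE)
        len <- pmax(50, round(rnorm(k, config$fragment_mean,
                                    config$fragment_sd)))
        left <- round(center - len / 2)
        right <- left + len - 1L
        fwd <- c(fwd, pmax(1L, pmin(L, as.integer(left))))
        rev <- c(rev, pmax(1L, pmin(L, as.integer(right))))
      }
    }
    unif_tags <- function(rate) {
      n <- rpois(1, rate * L)
      sort(sample.int(L, n, replace = TRUE))
    }
    chip <- tag_library("chip", list(chr = list(
      fwd = c(fwd, unif_tags(config$background_rate)),
      rev = c(rev, unif_tags(config$background_rate)))))
    input <- tag_library("input", list(chr = list(
      fwd = unif_tags(config$input_rate),
      rev = unif_tags(config$input_rate))))
    list(chip = chip, input = input)
  })
}

#' Run the full synthetic ChIP experiment
#'
#' Convenience wrapper: genome + genes, planted sites, ChIP and input tag
#' libraries, all determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `genes`, `truth`, `chip`, `input`.
#' @export
simulate_chip_experiment <- function(config = sim_config()) {
  gg <- generate_genome(config)
  ps <- plant_sites(gg$genome, gg$genes, config)
  libs <- simulate_tags(ps$truth, config)
  list(genome = ps$genome, genes = gg$genes, truth = ps$truth,
       chip = libs$chip, input = libs$input)
}

#' Write a synthetic experiment to disk
#'
#' Emits FASTA (genome), GFF3 (genes), two BED6 tag files (ChIP, input)
#' and a truth TSV, under a common path prefix.
#'
#' @param sim result of [simulate_chip_experiment()].
#' @param out_prefix path prefix for output files.
#' @return named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, out_prefix) {
  files <- c(genome = paste0(out_prefix, ".fasta"),
             genes = paste0(out_prefix, ".gff3"),
             chip = paste0(out_prefix, "_chip.bed"),
             input = paste0(out_prefix, "_input.bed"),
             truth = paste0(out_prefix, "_truth.tsv"))
  write_fasta(sim$genome, files[["genome"]])
  write_annotation_gff3(sim$genes, files[["genes"]], sim$genome)
  write_tags_bed(sim$chip, files[["chip"]])
  write_tags_bed(sim$input, files[["input"]])
  write.table(sim$truth$sites, files[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(files)
}
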