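# regulonmapr

Mapping a bacterial transcription factor's regulon from ChIP-Seq tag data,
built around NtcA — the CRP-family nitrogen-control regulator of
cyanobacteria, which binds GTA-N8-TAC sites as a dimer and, at canonical
Class II activated promoters, sits centered ~41.5 nt upstream of the
transcription start point (TSP) with a TAN3T −10 box after a ~22-nt
spacer. The package is for computational biologists who have
strand-annotated 5′-end tag positions (aligned ChIP and input libraries,
BED), a genome (FASTA) and an annotation (GFF3/TSV), and want a tested,
reproducible path from tags to an annotated binding-region catalog.

## What it computes

* **Double-strand peak calling.** Strand-specific moving-sum coverage
  `C(x)` (±w bp); per-strand candidate maxima scored with the
  continuity-corrected one-sided statistic `z = (a − b − 1)/√(a + b)`,
  where `b` is the larger of the ±2w flank mean and the library-scaled
  input coverage; forward/reverse peaks paired by lag (50–400 bp) into
  regions scored on the summed coverages at the two peak locations.
* **Discrete-FDR control.** Tarone-modified distribution-free
  Benjamini–Yekutieli Q-values computed in log10 space:
  `q(k) = p(k)·m(k)·H(m(k))/k` with step-up monotonization, where `m(k)`
  counts tests whose smallest attainable p-value reaches `p(k)`. Regions
  are ranked by `NLQ = −log10 Q`, finite even when Q underflows doubles.
* **Gene assignment** (midpoint anchor; containment, long-5′-UTR-aware
  upstream/downstream windows, two-gene ties), positional classes
  (upstream far/close, internal 5′/3′, downstream) and table summaries.
* **Motif analysis.** GTA-N8-TAC scanning (0–6 constrained-position
  score), enrichment versus randomly located length-matched control
  subsequences, position-frequency matrices with per-column information
  content (bits).
* **Promoter architecture.** Class II activator geometry (TAN3T box,
  exclusive spacer 20–24 nt, TSP 30–40 nt from the site 3′ end, center
  at distance + 6.5), repressor-like site/promoter overlap, or site-only.
* **Synthetic experiments.** A seeded generator planting degenerate
  consensus sites (with Class II truth geometry for a subset) into a
  random genome and emitting fragment-end ChIP plus uniform input tag
  libraries — the ground truth for the end-to-end tests.

## Worked example

```r
library(regulonmapr)

cfg <- sim_config(seed = 1)                      # 500-kb genome, 60 planted sites
sim <- simulate_chip_experiment(cfg)
regions <- call_binding_regions(sim$chip, sim$input)
nrow(regions)
#> [1] 53
head(regions[c("id", "start", "end", "location", "z_pair", "Q", "nlq")], 3)
#>   id  start    end location z_pair          Q   nlq
#> 1 36 380411 380611   380511  31.07 3.264e-212 211.5
#> 2 25 238163 238363   238263  29.93 5.611e-197 196.3
#> 3 50 487074 487273   487173  28.37 1.005e-176 176.0
```

53 regions pass `Q ≤ 0.05`, each ~200 bp wide (the fragment length), with
`location` the averaged forward/reverse peak position and `nlq` the
ranking statistic (`Q` underflows long before `nlq` stops being useful).
Assigning regions to genes and summarizing positions:

```r
asn <- assign_regions(regions, sim$genes)
summarize_positions(asn)  # "total" row
#>   replicon regions genes upstream internal downstream pct_internal
#>      total      53    57       10       33         14           58
```

58% of position calls are intragenic here (the generator plants 65% of
sites inside genes; n = 60 gives ±12 points of binomial noise). Motif
content of the called regions versus random control subsequences:

```r
motif_enrichment(regions, sim$genome, n_controls = 200, seed = 7)$ratio
#> [1] 9.4   # strict-site density ~9x random; empirical p = 0/200
```

Promoter dissection of a published top region (the 49-nt promoter of the
highest-NLQ region, TSP at its final base):

```r
top <- read.delim(system.file("extdata", "ntca_top_regions.tsv",
                              package = "regulonmapr"))
s <- top$promoter_seq[top$id == 1203]
site <- best_site_in_region(s, min_score = 5)   # GTGTGTCTTGATAC, score 5
classify_promoter(s, site$start, "+",
                  tsps = data.frame(position = nchar(s), strand = "+"))[
  c("class", "minus10", "spacer", "tsp_distance", "center_to_tsp")]
#> $class        "CLASS_II_ACTIVATOR"
#> $minus10      "TATGCT"
#> $spacer       22
#> $tsp_distance 35
#> $center_to_tsp 41.5
```

A command-line interface covers the same stages
(`Rscript -e 'regulonmapr::regulonmap_cli()' simulate|callpeaks|annotate|motifs ...`).

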