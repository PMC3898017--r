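---
title: "Mapping a bacterial TF regulon from ChIP-Seq tags: methods and design"
author: "regulonmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a bacterial TF regulon from ChIP-Seq tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonmapr)
```

# The problem

NtcA is the CRP-family nitrogen-control transcription factor of
cyanobacteria. It binds DNA as a dimer at sites with the degenerate
consensus GTA-N8-TAC and, at canonical activated promoters, sits with its
center about 41.5 nt upstream of the transcription start point (TSP) with
a TAN3T −10 box in between — the geometry of bacterial Class II
activator-dependent promoters. At repressed promoters the site instead
overlaps the promoter elements. Genome-wide ChIP-Seq of NtcA in the
heterocyst-forming cyanobacterium *Anabaena* sp. PCC 7120 maps thousands
of such binding regions across the chromosome and plasmids, a majority of
them intragenic.

`regulonmapr` implements the computational pipeline for such a map as
reusable, tested components: double-strand peak calling on strand-specific
5′-end tag coverage, discreteness-aware FDR control, region-to-gene
assignment with positional classification, consensus-site scanning and
information-content summaries, and promoter-architecture dissection — plus
a seeded synthetic-data generator used to validate the whole chain
end to end.

# The peak-calling model

## Coverage and per-strand candidates

Sonicated ~200-bp chromatin fragments leave their 5′ ends on the forward
strand upstream of a protein-bound site and on the reverse strand
downstream of it. For each strand the pipeline evaluates a moving-sum
coverage

$$C(x) = \#\{\text{same-strand 5′ tag positions in } [x-w,\,x+w]\},$$

with half-width $w = 100$ bp by default (half the fragment length).
Candidate peaks are local maxima of $C$ scored by a one-sided
continuity-corrected statistic on Poisson-like counts,

$$z = \frac{a - b - 1}{\sqrt{a + b}},$$

where $a$ is the ChIP coverage at the maximum and the background
expectation $b$ is the larger of (i) the mean ChIP coverage on the two
flanks at $\pm 2w$ and (ii) the input-library coverage at the maximum,
scaled by the ratio of library sizes. Candidates need $z \ge 4$ — a
genome-scale pre-filter, not the final significance call. The underlying
double-strand scheme and the substitution of the summed
forward-plus-reverse coverage into the paired statistic follow the
Triform family of callers; the exact equations of that method are not
re-derived here, and this explicit $z$ is the package's own fully
specified statistic.

**A note on plateaus.** The top of a moving sum over a tag pileup is a
near-flat plateau roughly as wide as the fragment-length spread; its
single highest position can be decided by one stray background tag. Peaks
are therefore re-centered at the *median same-strand tag position within
$\pm w$* of the merged maximum — the maximum-density estimate of the
fragment-end pileup. Without this refinement, peak locations are biased
toward a plateau edge by tens of bp, which is larger than the
localization tolerance the recovery tests demand.

## Pairing and the paired score

Forward and reverse candidates on a replicon are paired greedily by
descending forward $z$: each forward peak takes the nearest unused
reverse peak whose lag lies in $[\texttt{min\_lag}, \texttt{max\_lag}]$
(defaults 50–400 bp, bracketing the fragment length). The region spans
the two peak locations; the reported binding location is the floor of
their mean, and the region midpoint is the best estimate of the bound
position. The paired score re-applies the $z$ formula with
$a_{pair} = C_{fwd}(\text{fwd peak}) + C_{rev}(\text{rev peak})$ and the
summed background expectation.

## P-values, Q and NLQ in log space

The one-sided p-value is the upper normal tail of $z_{pair}$, computed
entirely in log10 space (`pnorm(..., log.p = TRUE)`), because deeply
sequenced bacterial ChIP peaks reach $-\log_{10} p$ in the thousands —
far beyond double-precision probabilities. Multiple testing uses the
**Tarone-modified distribution-free Benjamini–Yekutieli** procedure: with
p-values sorted ascending,

$$m_k = \#\{j : \text{minp}_j \le p_{(k)}\}, \qquad
  q_{(k)} = p_{(k)} \cdot m_k \cdot H(m_k) / k,$$

followed by the step-up monotonization $Q_{(k)} = \min_{l \ge k} q_{(l)}$
capped at 1, where $H$ is the harmonic number and $\text{minp}_j$ is the
smallest p-value test $j$ could attain — here the tail probability of the
most extreme outcome in which the whole observed total $a_{pair}+b_{pair}$
falls in the peak. Discrete tests that cannot reach a given level do not
inflate the correction (Tarone's idea), and the harmonic factor keeps FDR
control under arbitrary dependence (Benjamini–Yekutieli). With all
minp = 0 the procedure reduces *exactly* to standard BY; the test suite
checks this against R's independent `p.adjust(method = "BY")` at 1e-12.
Reported regions have $Q \le$ `fdr` (default 0.05), ranked by
NLQ $= -\log_{10} Q$. A Q below ~1e-308 is printed as "0" while NLQ stays
finite — NLQ, not Q, is the ranking statistic.

# Gene assignment and positional classes

Each region is anchored at its midpoint. Candidate genes are the gene(s)
containing the anchor, the nearest gene whose 5′ end lies downstream
within `d_up`, and the nearest gene whose 3′ end lies upstream within
`d_down`. Containment beats proximity; a tie (distance difference ≤
`tie_tol`) is broken by a differential-expression flag if exactly one
tied gene carries it, and otherwise both genes are reported — mirroring
"two genes, when it is not possible to decide between flanking genes".
Classes are strand-aware: `UPSTREAM_CLOSE`/`UPSTREAM_FAR` (split at
`u_close`), `INTERNAL_5`/`INTERNAL_3` (split at the gene midpoint, center
going 5′), and `DOWNSTREAM`.

The window sizes are declared conventions, not biology fixed by data:
the source map distinguishes far/close upstream and 5′/3′ internal
positions but never quantifies the cutoffs. Defaults — `u_close` 200 bp,
`d_up` 1500 bp, `d_down` 300 bp, `tie_tol` 10 bp — encode the long
cyanobacterial 5′-UTR allowance and are all configurable.

# Motif scanning and information content

A site is a 14-mer scored 0–6 by its matches at the six constrained
positions G1 T2 A3 / T12 A13 C14; the 8-nt spacer is free and `N` never
matches. Because the constrained positions form a reverse-complement
palindrome, every window scores identically on both strands; a
minus-strand record duplicating a plus-strand record at the same window
with the same score is reported once. The default reporting threshold is
score ≥ 5 (admitting the single-mismatch sites accepted in curated
regions, e.g. GTG-N8-TAC); exploratory scans use score ≥ 4 with a
mandatory G1 (admitting GAA-N8-TAC). Enrichment is measured as the
strict-site (score 6) density in regions over the mean density in
`n_controls` sets of randomly located, length-matched subsequences, with
an empirical p-value; control placement is seeded for reproducibility.

Position-frequency matrices report per-column information
$I_j = 2 + \sum_b f_{bj}\log_2 f_{bj}$ bits, with $0\log 0 = 0$ and no
small-sample correction — the deterministic, closed-form definition a
sequence logo displays, at the cost of a small upward bias at small $n$.

# Promoter architecture

`classify_promoter()` works in the site's own strand frame (minus-strand
problems are mirrored):

* **CLASS_II_ACTIVATOR** — a TAN3T −10 box after an exclusive spacer of
  20–24 nt (center 22), and either no TSP information or a same-strand
  TSP 30–40 nt from the site 3′ end (center 35, TSP base counted). The
  identity center-to-TSP = distance + 6.5 then yields the canonical 41.5.
* **REPRESSOR_LIKE** — no Class II geometry, but the site overlaps the
  promoter footprint `[TSP − 35, TSP + 15]` of a same-strand TSP.
* **SITE_ONLY** — neither.

Two counting conventions are deliberate and jointly forced by the printed
worked examples (spacer 22 *and* TSP distance 35 on the same sequence):
the spacer counts only intervening bases (exclusive), while the TSP
distance counts the intervening bases plus the TSP base itself. The
repressor footprint window is a declared convention — the source
describes repressor sites as sitting downstream of the −35 box, without
a numeric window.

# The synthetic world

`sim_config()` states the simulated experiment; its defaults are the
package's fixed test world:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 500 kb | single replicon, i.i.d. uniform A/C/G/T |
| `n_genes` | 400 | non-overlapping, 300–3000 bp (log-uniform), ≥50-bp gaps |
| `n_sites` | 60 | planted 14-nt GTA-N8-TAC-like sites |
| `frac_intragenic` | 0.65 | intragenic share, as in the observed map |
| `fragment_mean`, `fragment_sd` | 200, 20 bp | sonication fragment model (truncated ≥50) |
| `strength_range` | 20–500 | per-site expected fragment pairs, log-uniform |
| `background_rate` | 0.002 /bp/strand | uniform ChIP background |
| `input_rate` | 0.01 /bp/strand | uniform input library |
| `site_mutation_rate` | 0.1 | per constrained position |

Design choices worth stating:

* **Fragment-end tags, no reads.** Each site draws Poisson(strength)
  fragment pairs; a fragment is Normal(200, 20)-long, centered on the
  site center with ±10 bp jitter, and deposits one forward tag at its
  left end and one reverse tag at its right end. This is exactly the
  object the peak caller consumes; sequencing errors, PCR duplicates and
  mappability are out of scope.
* **Resolvable sites.** Planted sites are at least 500 bp apart (2.5×
  the fragment length). Two sites within one fragment span produce a
  single merged pileup and are one binding region *by construction of
  the assay* — recovery statistics are only meaningful for sites the
  data could in principle separate. This is the strongest sense in which
  a green recovery test should be read: it establishes localization of
  isolated, sufficiently strong sites, not deconvolution of clustered
  ones.
* **Log-uniform strengths** give the wide NLQ dynamic range seen in real
  deep maps; the actual magnitudes are free simulation parameters, not
  estimates of any real dataset.
* **Class II truth geometry.** Half of the intergenic sites are written
  with a TAN3T box after a 22-nt spacer and a TSP 35 nt from the site 3′
  end, oriented by site strand; these drive the architecture tests. Only
  the 14-mer itself must be intergenic — with 400 genes on 500 kb the
  genome is ~94% coding and gaps are small, so box/TSP geometry may abut
  or overlap a neighboring gene start, as real promoters do.
* **Determinism.** `seed` fully determines the genome, sites and both
  libraries (each stage uses a fixed offset of the seed); tests assert
  byte identity across re-runs.

What the generator does *not* emulate — GC bias, copy-number structure in
the input, replication-origin coverage gradients, overdispersed
background, replicate structure — bounds what a green end-to-end test
establishes: correctness of the statistical machinery on its stated
model, not robustness to every artifact of real libraries.

# Numerical choices and degenerate inputs

* All p/minp/Q arithmetic is in log10 space; the normal tail uses R's
  internal asymptotic expansion, checked against a 200-digit `erfc`
  oracle to 1e-10 at z up to 200.
* Region midpoint = floor of the arithmetic mean (integer positions);
  an even-span region takes the left-of-center base.
* Coverage window edges are inclusive; `w` must be positive; a
  zero-tag input library is an error (no scale for normalization).
* Empty ChIP libraries, empty region lists and header-only tables are
  legal and round-trip through the writers.
* Ties: best site in a region — score, then proximity to the region
  midpoint, then leftmost, then plus strand; internal position — center
  goes 5′; site matching — greedy smallest distance first (not a
  maximum-cardinality matching; the suite checks it against an
  exhaustive repeated-global-minimum oracle).

# Known limitations

* The per-strand and paired z statistics are normal approximations to
  Poisson-like counts; at very low coverage the continuity correction
  makes them conservative rather than exact.
* `minp` is derived from the observed total count's most extreme split,
  a lower bound that serves the Tarone reduction without modeling the
  full discrete count distribution.
* Greedy peak pairing and greedy site matching are order-dependent
  heuristics; both are tested against their stated objectives, not
  against globally optimal matchings.
* The positional-class windows and the repressor footprint are
  conventions; comparisons across datasets should hold them fixed.
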