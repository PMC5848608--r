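---
title: "Quantifying tandem 3' UTR usage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tandem 3' UTR usage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrshift)
```

## The problem

Most mammalian genes carry several polyadenylation (pA) sites in their
3'-most exon. Alternative polyadenylation (APA) among these tandem sites
changes the 3' UTR length without touching the coding sequence, and with it
the complement of microRNA and RNA-binding-protein sites the transcript
exposes. Systematic shifts toward distal sites (3' UTR lengthening) have
been described in senescent cells, where they accompany reduced expression
of the affected genes; shifts toward proximal sites dominate in
proliferating and transformed cells. `utrshift` implements the complete
quantitative chain needed to detect such programs from 3'-end sequencing
(PA-seq style) tag data plus, optionally, conventional RNA-seq: pA-site
calling, per-gene usage summaries, differential testing, and the
downstream coupling statistics.

## Poly(A)-site calling

Aligned 3'-end tags are clustered per chromosome and strand by single
linkage: tags at most `window_bp` apart join one cluster. The default
window of 24 bp reflects the typical width of cleavage-site heterogeneity
around a single pA site; it is exposed as a parameter because protocols
differ. A cluster's representative position is its modal tag position
(ties resolved to the 5'-most position in transcription direction), and a
cluster needs `min_count = 3` pooled tags to be reported — singleton tags
are overwhelmingly alignment noise. Dropped tags remain accounted for in
the cluster attributes, so the suite can verify that no tag is lost or
duplicated by clustering.

Two sequence-level checks follow:

* **Internal priming.** Oligo(dT) priming at genomic A stretches mimics
  poly(A) junctions. A cluster is flagged when the 10 nt immediately
  downstream of its representative position (transcription-strand sense)
  contain a run of ≥ 6 adenosines or ≥ 7 adenosines in total — the common
  convention in pA-site catalogues. Flagged clusters are excluded from
  gene assignment by default but retained in QC output.
* **PAS annotation.** The 40 nt upstream are searched for the canonical
  poly(A) signal `AATAAA`, then `ATTAAA`, then ten weaker single-base
  variants, in fixed priority order; the offset of the best hexamer is
  reported. PAS enrichment is a standard reliability indicator for called
  sites and feeds the QC summary.

Clusters are assigned to the gene whose pA search space contains them on
the same strand. The search space runs from the stop codon to the
annotated 3' end plus `max_utr3_extension = 1000` bp, because genuine
distal sites frequently lie beyond annotation; it is truncated where it
would enter the next same-strand gene. When two genes' spaces both contain
a cluster, the nearer stop codon wins, with exact ties resolved to the
5'-most gene in genomic order (and logged). For multi-transcript genes the
transcript with the 3'-most stop codon defines the distance origin: a
tandem-UTR analysis needs a single origin per gene, and the 3'-most stop
maximizes the annotated UTR in which tandem sites can be interpreted.

### Coordinate convention

All internal coordinates are 1-based inclusive, the native convention of
`GenomicRanges` and every Bioconductor importer this package builds on;
BED and bedGraph inputs (0-based half-open on disk) are converted at the
boundary by `rtracklayer`. Holding the entire package to the single
convention its containers use is what prevents off-by-one drift here.

## Per-gene usage summaries

For gene *g* with tandem sites at stop-codon distances `d_i` and tag
counts `n_i` in a sample, the **effective 3' UTR length** is the weighted
mean `L_eff = Σ d_i n_i / Σ n_i`. It is invariant to sequencing depth,
bounded by the outermost sites, and strictly increasing when usage moves
distally. Distances are measured to each cluster's representative
position; using cluster spans instead would only blur the statistic by the
within-cluster jitter. Cross-sample trends are displayed as per-gene
Z-scores, using the sample (n − 1) standard deviation; genes with
identical lengths across samples get an all-zero row rather than a 0/0.

The **RUD index** (relative usage of distal pA sites) is an independent,
RNA-seq-only view of the same biology: mean read coverage over the
alternative UTR (proximal → distal site, present only in long isoforms)
divided by mean coverage over the common UTR (stop codon → proximal site).
Under uniform coverage RUD estimates the distal usage fraction. For genes
with more than two sites the two highest-count sites define the pair —
RUD is inherently a two-region contrast. A zero-coverage common UTR makes
RUD undefined and is reported as missing, never as 0; missing values
propagate throughout the package.

## Differential usage: TSI, testing, classification

The **tandem UTR isoform switch index** between conditions A and B is the
normalized effective-length change

```
TSI = (L_eff,B − L_eff,A) / (d_max − d_min)
```

which for a two-site gene reduces to the distal usage fraction in B minus
that in A. It is antisymmetric and bounded in [−1, 1]; positive values
mean lengthening in B. Significance comes from a two-sided Fisher's exact
test on the 2×2 table of proximal (site 1) versus distal (all other sites
pooled) counts by condition — the defensible exact default for small count
tables, with any zero-margin table returning p = 1 by convention.
Replicates are pooled within condition before testing (a matched-pair
Stouffer combination is available but off by default). Benjamini–Hochberg
adjustment controls the FDR, and a gene is called *lengthened* when
q ≤ 0.05 with TSI > 0, *shortened* when q ≤ 0.05 with TSI < 0.

Two coupling statistics connect APA calls to expression:

* genes pass the expression filter only with FPKM ≥ 1 in both conditions,
  and are classed up/down at an inclusive 1.5-fold change;
* among, say, the lengthened genes, an exact two-sided binomial test asks
  whether down-regulated genes outnumber up-regulated ones beyond chance —
  the signature of a lengthening program that suppresses expression.

A one-sided hypergeometric over-enrichment test (`overlap_test`) serves
for comparing gene sets between two systems against a common universe.

## What the simulator emulates — and what it does not

`simulate_genome_and_annotation()` lays out single-exon genes on a random
chromosome: CDS of 300 bp, 3' UTRs of 0.5–3 kb, 1–3 tandem sites placed
100–250 bp past the stop and 150–400 bp apart, `AATAAA` planted 21 nt
upstream of each site, and a U/G-rich 12-mer downstream of each cleavage
position (the downstream element of real sites; it also guarantees true
sites are never A-rich downstream). A configurable fraction of UTRs gets
an A₆–A₁₀ mispriming decoy at least 60 bp from any true site.
`simulate_pa_tags()` draws site totals Dirichlet-multinomial around the
true usage fractions (`rho = 0`, the default, is plain multinomial
sampling; positive `rho` adds the overdispersion seen between biological
replicates), jitters tag positions with a discretized Gaussian of sd 4 bp
truncated at ±10 bp — comfortably inside the 24 bp clustering window —
and adds decoy tags at 5% of gene depth, tightly clustered where oligo(dT)
would anchor. `simulate_rnaseq()` produces stepwise Poisson coverage that
drops after each pA site in proportion to the usage remaining distal to
it, which is exactly the signal RUD reads.

`make_senescence_scenario()` composes these into a two-condition dataset:
a chosen fraction of multi-site genes shifts distal usage up by `shift`
(drawn so the full shift always applies, taken from the proximal site, so
the true TSI equals `shift` exactly), and each shifted gene is
down-regulated with probability `coupling` (default 0.7, mirroring the
predominance of down-regulation among lengthened genes in senescence
systems).

The simulator deliberately omits several features of real data: multi-exon
gene structure and splicing, non-uniform RNA-seq coverage biases,
mappability artifacts, antisense transcription, and pA sites in introns or
internal exons. Passing the recovery tests therefore demonstrates the
correctness of the statistical chain under its stated sampling model, not
robustness to every artifact of real libraries; the internal-priming and
PAS modules exist precisely because real data need them.

## Numerical and testing choices

Exact tests are delegated to R's `fisher.test`/`binom.test`/`p.adjust`
and verified in the test suite against independent brute-force
enumerations (full hypergeometric enumeration over table space, the BH
step-up hand formula, direct binomial enumeration). The suite exercises
the pipeline at deliberately moderate problem sizes — a 2,000-gene null
scenario at depth 100 with `rho = 0.02` for type-I calibration, a
1,000-gene scenario with 20% of genes shifted +0.3 at depth 200 for
sensitivity and TSI accuracy, 200-gene simulations for peak-calling and
RUD fidelity — sizes at which the binomial error bands of the checked
proportions are already narrow. All generators are seed-deterministic;
analysis stages contain no randomness at all, and reruns of the pipeline
on identical inputs produce byte-identical tables.

## Known limitations

* Fisher's exact test on pooled counts does not model between-replicate
  overdispersion; with strongly overdispersed data (`rho` well above
  ~0.02) its p-values become anticonservative, which is why the
  replicate-aware Stouffer mode exists.
* The TSI formulation collapses multi-site geometry into a single length
  change; genes switching between two distal sites of similar distance
  produce small TSI even when the switch is real.
* RUD assumes uniform coverage within each UTR segment; strong 3' bias in
  the RNA-seq protocol biases RUD toward the segment the protocol favors.
* Gene assignment trusts the annotation's stop codons; unannotated distal
  exons beyond `max_utr3_extension` are unreachable by design.
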