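---
title: "Methods: CAGE promoter atlases, expression breadth and 5'UTR translatability"
author: "cageatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAGE promoter atlases, expression breadth and 5'UTR translatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cageatlas)
library(data.table)
```

## The problem

Cap analysis of gene expression (CAGE) sequences the 5' ends of capped
transcripts, producing per-base tag counts at transcription start sites
(CTSS). Most genes are transcribed from several promoters, and which promoter
a tissue uses can decide whether the resulting mRNA is translatable at all:
an alternate upstream promoter can splice a long, uORF-laden leader onto an
otherwise intact coding sequence and silence it translationally. `cageatlas`
turns multi-tissue CTSS data into a promoter atlas — normalized signal, tag
clusters, cross-tissue consensus promoters, gene assignment, and a
tissue-breadth class per promoter — and provides the companion analyses such
a study needs: 5'UTR leader reconstruction with a uORF census, GC content and
splice-junction checks, and neighbor-joining trees with bootstrap support for
promoter or protein-domain sequence comparisons.

## Data model and coordinates

All internal coordinates are 0-based half-open, on every type; GTF (1-based
closed) is converted at the boundary by `parse_gtf_transcripts()`, which also
orients minus-strand exon chains 5' to 3' and derives `cds_start` as the
transcript-relative offset of the first CDS base — so a leader's length
always equals `cds_start`. CTSS input is taken as 0-based BED-like; the
`one_based` flag of `read_ctss()` accepts the 1-based dialect. Chromosome
names are compared as exact strings: no "chr" stripping, so mismatched
assemblies fail loudly rather than silently mis-joining.

## Power-law normalization

CAGE tag counts are heavy-tailed: the number of positions with count at
least x falls approximately as a power law, `revcum(x) ~ c * x^(-alpha)`.
Libraries of different depth and complexity are made comparable by mapping
each library onto a common reference law with slope `alpha_ref = 1.14` and
an implied total of `total_T = 1e7` tags, then expressing signal as tags per
million (tpm):

* fit `(alpha_s, c_s)` to the sample's reverse-cumulative distribution in
  log-log space over distinct counts at or above `fit_min_count = 2`
  (singleton positions dominate CAGE libraries and bias the slope);
* map each count through
  `z(x) = (c_s * x^(-alpha_s) / c_ref)^(-1/alpha_ref)`, the value at which
  the reference law matches the sample law's reverse-cumulative count at x;
* report `tpm = z * 1e6 / total_T`.

The mapping is strictly increasing, so within-sample ranks are preserved
exactly. `c_ref` is anchored by discrete summation: the total tag count
implied by an integer-valued law equals the sum of `revcum(x)` over x, so
`c_ref = total_T / sum(x^-alpha_ref, x = 1..1e6)`. The discrete sum is a
reproducible convention; a continuum integral would shift `c_ref` by a few
percent and every downstream threshold with it.

Two numerical choices deserve explanation.

**Weighted fit.** The reverse-cumulative staircase has thousands of distinct
high counts each observed at one or two positions; an unweighted regression
over distinct values lets this sparse tail dominate the slope (on seeded
1e5-position samples it shows a standard deviation near 0.04 — too noisy to
honor a ±0.05 contract on the slope). The fit therefore weights each distinct
count by the number of positions observed at it, which is equivalent to
per-position least squares and is nearly unbiased (sd ≈ 0.004 at the same
size).

**Scale coupling.** The reference total `total_T` is not a free dial: the
absolute thresholds downstream (2 tpm to seed a consensus cluster, 0.2 tpm
median floor for breadth) assume tpm values on the scale of real CAGE
libraries (millions of tags). When normalizing small or synthetic libraries,
`total_T` should be set commensurate with the actual library scale —
the recovery benchmark below does exactly that. Feeding the normalizer a
library whose count marginal is far from power-law shaped (for example, a
toy library containing only a handful of promoters) makes the fitted slope
unstable and distorts expression *ratios* nonlinearly by
`ratio^(alpha_s/alpha_ref)`; this is a property of rank-matching
normalization itself, and the reason the synthetic generator simulates whole
libraries rather than bare promoters.

## TSS clustering

`cluster_ctss()` performs strand-aware single-linkage distance clustering:
within one (chromosome, strand), consecutive CTSS whose gap is at most
`max_dist = 20` bp merge transitively. Each tag cluster records its span,
total tpm, dominant (maximal-tpm) position, and the positions where the
running tpm sum reaches the 0.1 and 0.9 quantiles of the cluster total; the
distance between those two positions (plus one) is the interquantile width,
a promoter-width measure robust to low-signal tails. Dominant-position ties
break toward the transcript 5' end so output is deterministic. Running-sum
thresholds are compared with a relative tolerance of 1e-9 so that exact
quantile boundaries (e.g. a uniform cluster) do not depend on floating-point
accumulation order. No tpm floor is applied at this stage; the 2-tpm filter
belongs to consensus aggregation.

## Consensus promoters

`aggregate_clusters()` pools samples: tag clusters reaching 2 tpm in at
least one sample are projected as their interquantile ranges, and ranges on
one (chromosome, strand) merge transitively when their gap is at most
`agg_dist = 100` bp. Merging uses interquantile ranges rather than full
spans — the aggregation distance is defined on the quantile footprint — and
the consensus span is the union of the merged ranges (inclusive, in the
spirit of atlas-style consensus regions). Expression per tissue is then
*recomputed* by `expression_matrix()` as the sum of that tissue's normalized
signal inside the consensus span: summing member tag clusters would discard
sub-threshold signal in tissues where a promoter is weak, exactly the signal
the median-based breadth rule needs.

## The promoter atlas

`assign_to_genes()` attaches a consensus cluster to a gene when their spans
overlap on the same strand, with the gene span extended by
`upstream_flank = 500` bp on its 5' side (promoters often sit just upstream
of annotation); the largest overlap wins, ties break by gene id. Promoters
are then numbered `p1..pN` per gene in 5'-to-3' transcriptional order.
Positional class uses the cluster midpoint against the gene's longest
annotated transcript: exonic and 5' of the CDS start is `five_prime_utr`,
exonic at or after it is `coding_exon`, between exons is `intron`, outside
the transcript span is `intergenic`. GC content is computed over the
consensus span with the same `gc_content()` used for leaders.

Expression breadth follows a three-branch rule on the tissue profile:

* median below 0.2 tpm → `non_ubiquitous`;
* otherwise maximum strictly greater than 10× the median →
  `ubiquitous_nonuniform`;
* otherwise → `ubiquitous_uniform`.

The boundary case `max == 10 * median` is classified uniform: both published
branches are stated with strict inequalities, leaving equality open, and
assigning the tie to the uniform branch keeps "nonuniform" a strict
exceedance. A profile expressed in a small minority of tissues has median 0
and lands in `non_ubiquitous` regardless of how strong its peak is, which is
the intended reading of "nonubiquitous".

```{r breadth-example}
classify_breadth(c(kidney = 12, rep(1, 7)))
classify_breadth(rep(0.5, 8))
classify_breadth(c(20, rep(0, 7)))
```

## 5'UTR toolkit

`reconstruct_5utr()` splices exon sequences in transcript orientation
(reverse-complementing on the minus strand) and truncates at `cds_start`.
`find_uorfs()` opens a candidate at every ATG whose A lies within the
leader — including ATGs spanning the leader/CDS boundary — and translates in
frame through the leader and into the downstream sequence to the first
TAA/TAG/TGA. Three conventions matter:

* a uORF's stop may fall inside the CDS region; only the initiation site
  must be upstream (long uORFs overlapping the CDS are biologically real and
  appear in leader comparisons);
* peptide length (`aa_length`) excludes the stop codon, while
  `longest_orf()` reports nucleotide length *including* the stop — the two
  units conventionally used for uORFs and ORFs respectively;
* overlapping and nested uORFs are all reported, and candidates with no
  in-frame stop anywhere are flagged `has_stop = FALSE` and excluded from
  `n_uorfs`. Near-cognate (non-ATG) starts are ignored.

`check_canonical_junction()` applies the GT/AG rule to the first and last
intronic bases of an annotated junction.

## Phylogenetics

Distance matrices come from `p_distance()` (mismatch fraction over gap-free
columns, optional Poisson correction `-ln(1-p)`); maximum-likelihood
distance models are out of scope, since the package's tree machinery exists
to support sequence-similarity summaries, not model selection.
`nj_tree()` is a standard Saitou–Nei neighbor-joining implementation with
two determinism rules: Q-criterion ties join the lexicographically first
taxon pair (each internal node represented by its alphabetically first
descendant), and negative branch lengths are clamped to zero with the
deficit moved to the sister branch, preserving path lengths.
`bootstrap_support()` resamples alignment columns with replacement under one
seeded generator, rebuilds a tree per pseudoreplicate (100 by default), and
labels each internal split of the original tree with the percentage of
replicates containing it.

## The synthetic experiment generator

`simulate_ctss_experiment()` emulates the statistical structure the pipeline
is designed for, with planted ground truth:

* **Tissue panel** — eight organs (kidney, intestine, heart, lung, bone
  marrow, liver, brain, spleen) by default.
* **Promoters** — 1–3 per gene (configurable up to 8) at fixed spacing
  (1,200 bp) inside toy genes whose exon tiling places promoter k 150 bp
  into exon k; the CDS starts 250 bases into the transcript, so p1 is a
  5'UTR promoter and later promoters are internal. A configuration planting
  promoters closer than twice the 20-bp clustering framework is rejected as
  unidentifiable.
* **Expression profiles** — drawn per promoter from the three breadth
  categories: non-ubiquitous (1–2 active tissues at 0.5–2× `base_tpm`,
  others silent), ubiquitous-uniform (all tissues at 0.7–1.4× `base_tpm`),
  ubiquitous-nonuniform (baseline 0.3× `base_tpm` with one tissue boosted
  20-fold). `base_tpm` defaults to 15 tpm, a typical active-promoter level.
  Truth categories are recomputed by applying the breadth rule to the
  expected profiles, so category recovery is well-posed by construction.
* **Tag placement** — expected tpm converts to a tag mass at the library
  scale; per-position counts are discrete power-law draws
  (`count_alpha = 1.14`) trimmed to the mass, displaced around the center by
  a discrete-Laplace (double-geometric) kernel with scale `pos_spread = 3`
  bp — integer-valued and heavier-tailed than a Gaussian, resembling real
  TSS scatter — with larger counts placed nearer the center (the sharp-peak
  promoter shape). Poisson noise on the mass is on by default.
* **Background** — each library carries power-law background positions on a
  separate contig, sized so the per-tissue total approaches `lib_total`
  (1e6 tags by default, a low-end CAGE library). This serves two purposes:
  the pooled count marginal genuinely follows the configured power law, and
  the normalizer sees a library that satisfies its distributional
  assumption. Keeping background on its own contig keeps planted truth
  identifiable and emulates unannotated TSS activity.

What the generator does **not** emulate: read-level errors and mapping bias,
replicate variance beyond Poisson, promoter shape classes (broad vs sharp
beyond the Laplace kernel), correlated tissue profiles, and genomic sequence
composition around TSS. Passing recovery tests therefore demonstrates the
pipeline's algorithmic correctness under the stated statistical structure,
not robustness to alignment artifacts or biological covariance.

`simulate_utr_locus()` plants an exact uORF census: background sequence is
generated ATG-free (a base that would complete "ATG" is never emitted), each
planted uORF is `ATG + (aa-1) alanine codons + TAG` using a codon set that
cannot create ATG in any frame or across boundaries, and the leader is split
across exons with GT..AG (or CT..AG, for non-canonical truth) introns. The
reconstructed leader then contains exactly the planted uORFs.

## Scales used by the test suite

The suite exercises the study conditions at desk scale, chosen once: the
normalization contract at 1e5 positions; the clustering oracle on 200 random
instances up to 1,000 CTSS; the recovery benchmark on 50 genes × 8 tissues
at `lib_total = 1e6` with noise on (about 1.2 million CTSS records, matching
the pipeline run to the simulated library scale via `total_T`); uORF/ORF
oracles on 1,000 random sequences; NJ topology recovery on 100 additive
matrices of 4–8 taxa. The idealized noise-free, background-free fixture
plants only the two categories whose classification is invariant to the
ratio distortion described under *Scale coupling*; the full-library
benchmark exercises all three.

## Interface

The package's surface is its R API plus `scripts/acceptance.R`; the pipeline
is orchestrated by `run_pipeline()` (normalize → cluster → consensus →
expression → atlas), configured by `pipeline_config()`, which houses every
numeric threshold, and scored by `score_against_truth()`. Stage-level
reproducibility uses child seeds derived from the global seed by stable
hashing of stage names (`derive_seed()`). A shell subcommand wrapper would
add nothing over these functions for an analysis package and is not
provided.

## Known limitations

* The power-law fit needs at least two distinct counts at or above
  `fit_min_count`; sparse libraries (or a single repeated count) are
  rejected rather than guessed at.
* Expression breadth uses the uncorrected median across the supplied
  tissues; with very few tissues the 0.2-tpm floor is a blunt instrument.
* Positional classification reports one class per promoter, against the
  longest transcript; per-transcript reporting would be a straightforward
  extension.
* `p_distance` treats any non-gap mismatch equally; protein substitution
  models are deliberately out of scope.
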