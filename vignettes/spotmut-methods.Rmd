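---
title: "Mapping somatic SNVs onto spatial transcriptomics sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping somatic SNVs onto spatial transcriptomics sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatial transcriptomics captures polyadenylated mRNA at barcoded spots while
preserving tissue coordinates. The same reads that quantify expression also
carry somatic single-nucleotide variants (SNVs), so a tumor section can be
turned into a spatial map of mutation: which spots carry which variants, how
mutational burden varies across tumor, margin and normal tissue, and which
variants co-occur in space. `spotmut` implements that analysis downstream of
somatic calling: it consumes a Mutect2-style VCF plus per-read evidence
(spot barcode, UMI, locus, observed allele) and produces spot-level matrices,
burden statistics, spatially coherent SNV groups, margin decay fits and
mutant-peptide (neoantigen candidate) lists.

Calling variants from spatial mRNA is noisy: coverage tracks expression,
depth varies by an order of magnitude between spots, and reverse-transcription
or PCR artifacts produce sporadic false positives. The pipeline's design
choices all address one of those three problems.

## From reads to an effective-SNV matrix

**Filtering calls.** Records whose FILTER column carries any of
`weak_evidence`, `germline`, `strand_bias`, `slippage`, `contamination`,
`panel_of_normals` are discarded; `PASS` and other benign tags (e.g.
`clustered_events`) are retained. Multiallelic records are split and each
allele judged on its own; only single-base substitutions continue.

**Counting molecules, not reads.** Evidence rows are deduplicated on
`(barcode, UMI, chrom, pos)` before counting, so PCR duplicates of one
molecule count once. The locus is part of the key because distinct loci can
legitimately share a UMI within a spot. When a key occurs with conflicting
alleles the first row wins; reads supporting neither the reference nor the
called alternative are discarded entirely. A read increments
`counts[spot, snv]` only when its allele equals the SNV's alternative base.

**Effective SNVs.** An SNV is *effective* when it is supported by at least
`min_unique_reads = 20` deduplicated reads in total and observed in at least
`min_spots = 5` spots. Sporadic one-spot artifacts fail both thresholds. The
filter is idempotent and exactly reproducible by a per-column scan, which the
tests exploit as an oracle.

**Binarization and UMI normalization.** Raw SNV counts correlate strongly
with expression, so counts are first reduced to presence/absence and then
corrected for per-spot depth:

$$\mathrm{norm}_{s,i} = \ln\!\left(\frac{b_{s,i}}{U_s} + 1\right),$$

where $b_{s,i} \in \{0,1\}$ is presence of SNV $i$ in spot $s$ and $U_s$ the
spot's total mRNA UMI. The per-spot scalar burden uses the sum over SNVs in
place of $b_{s,i}$. Zero maps exactly to zero, the transform is monotone in
both arguments, and the natural log is used throughout (any fixed base only
rescales). Applying the normalization to raw counts instead is available via
`use_raw = TRUE`.

For raw Stereo-seq lattices, `aggregate_spot_bins()` sums counts and UMI in
100×100 blocks (bin100). The pipeline default is `bin_size = 1` — inputs are
assumed already at the working resolution — and 100 should be set explicitly
for raw Stereo-seq coordinates.

## Spatially correlated SNV groups

Individual SNV maps are sparse. Two devices recover structure: genomic
aggregation and spatial smoothing.

1. **Windows.** SNVs are pooled into 100-kb windows; an SNV at 1-based
   position $p$ belongs to window $\lfloor p / 10^5 \rfloor$, labeled
   `chrom@index`. Unique-read counts (not normalized values) fill the
   spots × windows matrix $M$ — co-occurrence in space is what matters here,
   which makes depth correction less critical at this stage.
2. **Smoothing.** A Gaussian k-nearest-neighbor kernel
   $W_{ij} = \exp(-D_{ij}^2 / 2\alpha^2)$ (union-symmetrized k-NN sets,
   $W_{ii} = 1$) spreads each spot's signal over its neighborhood:
   $M_w = W M$. The bandwidth $\alpha$ defaults to the mean k-NN distance of
   the section, which adapts to lattice pitch; $k$ defaults to 6. A
   row-normalized variant (constant columns left unchanged) is available via
   `row_normalize = TRUE`; the unnormalized product is the default.
3. **Correlation and graph.** For each window, spots below the median of its
   nonzero smoothed signal are zeroed (the "top 50%" of informative spots;
   including structural zeros would make the quantile degenerate for sparse
   windows), then $W_{corr} = M_w^\top M_w$. Each window keeps its top 50%
   highest-scoring partners, and scores become edge weights through a
   Gaussian decay on the rank-normalized score distance
   $r = 1 - s/s_{\max}$: $w = \exp(-r^2/2\gamma^2)$ with $\gamma = 0.5$. The
   decay scale is a free parameter of this implementation — the correlation
   scale itself is arbitrary, and rank-normalizing per row makes the graph
   invariant to it.
4. **Leiden groups.** Community detection on the (union-collapsed,
   max-weight) graph partitions windows into SNV groups, deterministic given
   a seed, ranked by within-group weight and labeled `0..G-1`. The
   modularity objective is the default; resolution defaults to 5, which on
   genome-scale window sets favors compact, internally consistent groups. On
   the package's 100-window synthetic fixture the planted partition is
   recovered at this default (extra fragmentation affects only the unplanted
   margin/differential windows).

Group scores are UMI-normalized like single SNVs,
$\ln(\sum_{w \in g} M_{s,w} / U_s + 1)$, using raw (unsmoothed) counts. A
group's score is expected to show stronger spatial autocorrelation than its
median member window — pooling cancels member-level noise — and the
acceptance suite checks exactly that on the synthetic section.

**Representative genes.** A window whose SNVs are all intergenic has no
representative. A single gene hit is chosen directly; with several candidate
genes the one whose expression profile best correlates (Pearson) with the
window's count vector wins, ties breaking to the larger correlation then the
lexicographically smaller id.

## Spatial statistics

**Moran's I** is implemented directly:
$I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}$ with
centered values $z$, self-weights excluded, $S_0$ the total weight. The
Gaussian k-NN weights are reused, but any square weight matrix is accepted
(the tests use rook adjacency, where a perfect checkerboard gives exactly
−1, and an $O(n^2)$ double loop as an oracle). Constant features are an
error, not a silent zero. Under random permutation of values the expected
value is $-1/(n-1)$, which the tests verify by simulation.

**Margin decay.** For each margin-labeled spot the mean Euclidean distance
to its $k = 5$ nearest tumor spots is computed, and ordinary least squares
fits $\ln(\text{burden})$ on $\ln(\text{distance})$. The slope is the decay
exponent of an assumed power law; $R^2$ is the squared Pearson correlation.
Spots with zero burden or distance are dropped (log undefined) and counted.
Across sections, the fitted slopes can be correlated against externally
computed immune scores (`slope_vs_immune`); the immune scoring itself is out
of scope and consumed as input.

**Signature scores** follow the binned-control scheme: genes are ranked into
`n_bins = 25` average-expression bins, `n_ctrl = 50` controls are drawn from
the bin of each signature gene, and the score is the signature mean minus
the control mean per spot. With very small gene universes wide bins are
advisable, otherwise the top bin can consist of the signature itself and the
score collapses toward zero by construction.

## Neoantigen candidates

Exonic nonsynonymous SNVs (annotated internally from GTF + CDS with the
standard genetic code; minus-strand codons via reverse complement) yield a
mutant amino-acid context of up to 15 residues on each side of the
substituted residue (31 aa total; "15 surrounding" is read per flank — a
7-per-side reading could not support centered 15-mers). All 8–15-mer windows
covering the mutation are enumerated: a full interior context gives exactly
$\sum_{k=8}^{15} k = 92$ peptides. Candidates are filtered by exact match
against every 8–15-mer of the translated reference CDS plus user-supplied
healthy-ligand lists; membership in known-epitope lists is annotated but
does not drop a peptide. Stop-gain and synonymous variants never enter this
path. Exports are FASTA + TSV for external HLA typing and affinity tools.

## The synthetic section

`generate_section()` produces the study conditions all integration tests
run under: a 50×50 lattice (2,500 spots) with a disk tumor core
(radius 0.22 m), margin annulus (to 0.40 m) and normal background; log-normal
per-spot UMI (median ≈ 3,000, σ = 0.5, region-scaled), i.e. roughly an order
of magnitude of depth variation; and four planted SNV families:

* **group SNVs** — 4 groups × 25 windows, one SNV per window, counts Poisson
  with a shared Gaussian spatial bump per group. The bumps sit at the four
  lattice corners (σ = m/14) so they stay clear of the margin annulus and
  the group and margin signals remain separately recoverable;
* **margin SNVs** — 60 SNVs whose Poisson rate in margin spots is
  $0.12\,(d/d_0)^{\beta}$ scaled by relative spot depth, with β = −0.8 by
  default and $d$ the same k-NN tumor distance the analysis measures
  (planting against raw boundary distance would confound the fit with the
  k-NN offset at small distances);
* **differential SNVs** — present essentially only in tumor spots;
* **noise SNVs** — sporadic counts built to fail the effective filter.

The evidence table is synthesized from the true counts with a 30% duplicate
rate (exercising UMI dedup) and ~10% reference-allele reads; the VCF carries
the planted SNVs as PASS plus records with disqualifying tags. Everything is
deterministic given a seed, and the `truth` manifest fully determines the
expected outputs of each stage.

What the generator does *not* emulate: alignment artifacts, strand bias,
3'-end capture bias along gene bodies, expression-linked false positives, or
segmentation error in region labels. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated generative model,
not calling accuracy on real tissue.

Two calibration notes. Binarization and zero-truncation compress a planted
power law: on section-scale data the recovered exponent sits a few
hundredths above β in magnitude, which is why the manifest check allows
±0.2 on the section-level slope while the dedicated n = 1,000 log-normal
regression fixture recovers β within ±0.08. And the toy genome
(`generate_toy_genome()`) plants codon-12 GGT→GAT (G12D) and codon-40
CTG→CCG (L40P) changes on both strands, giving hand-checkable amino-acid
annotations and a full-context peptide count of 92.

## Numerical and degenerate-input choices

* All coordinates are 1-based closed (VCF convention); window index is
  `floor(pos / window_size)`.
* `log1p` is used for every `ln(x + 1)`, preserving sparsity (0 → 0 exactly).
* Spots with `total_umi = 0` are an error when they carry SNV signal, and
  contribute zero burden otherwise.
* Windows with fewer than two nonzero smoothed spots get a zero correlation
  row; windows with no positive partners get no out-edges.
* Constant SNVs in the differential test return p = 1 and log-fold change 0
  rather than erroring; the Wilcoxon test is one-vs-rest per group with BH
  adjustment across all tests. The reporting threshold `p_max` defaults to a
  permissive 0.5 (useful when feeding trajectory analyses); 0.05 is the
  conventional strict choice.
* Leiden ties and RNG are pinned by `set.seed(seed)` before the backend call;
  group ids are stable because groups are re-ranked by within-group weight.
* Problem sizes in the tests — 50-spot Moran oracles, 2,500-spot sections,
  five recovery seeds, 1,000-point regressions — were chosen as the smallest
  scales at which each property is cleanly identifiable.

## Known limitations

* The internal annotator expects explicit `five_prime_utr` /
  `three_prime_utr` GTF features and one CDS per transcript id; GENCODE-style
  bare `UTR` features and multi-transcript reconciliation are not supported
  (full ANNOVAR parity is a non-goal).
* Exclusion matching is exact string equality; near-identical peptides
  (e.g. I/L swaps) are not collapsed.
* The k-NN weight matrix is built from a dense distance matrix, fine for
  sections up to a few tens of thousands of spots after binning, but not for
  raw sub-cellular lattices — aggregate first.
* Region labels are inputs; the package does not cluster expression to
  define tumor/margin/normal.
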