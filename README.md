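# spotmut

Spatially resolved somatic SNV analysis for spatial transcriptomics.

Tumor sections profiled with spatial transcriptomics (Stereo-seq, Visium,
Slide-seq, ...) carry somatic single-nucleotide variants in the very reads
used to quantify expression. `spotmut` turns spot-resolved SNV evidence into
a spatial map of mutation and the statistics needed to interpret it:
per-spot mutational burden corrected for sequencing depth, spatially
coherent SNV groups, distance-dependent decay of burden at tumor margins,
and mutant-peptide lists for neoantigen screening. It is aimed at
computational biologists working downstream of a somatic caller: variant
calling itself (Mutect2), alignment, HLA typing and binding-affinity
prediction stay outside the package and are consumed or fed as files.

## The method in brief

Given a filtered somatic VCF and a per-read evidence table
(`read_id, barcode, umi, chrom, pos, allele`):

1. **Effective SNVs.** Reads are deduplicated on `(barcode, UMI, locus)`;
   a read supports an SNV only if it shows the alternative base. An SNV is
   *effective* when it has ≥ 20 unique supporting reads and occurs in ≥ 5
   spots — sporadic artifacts fail both.
2. **Normalized burden.** Counts are binarized and corrected for per-spot
   depth: for SNV *i* in spot *s*,
   `norm(s,i) = ln(b(s,i) / U_s + 1)` with `U_s` the spot's total mRNA UMI;
   the per-spot burden uses the SNV sum in place of `b`.
3. **SNV groups.** Unique-read counts are pooled into 100-kb genomic
   windows (`chrom@index`), smoothed with a Gaussian k-NN kernel
   `W_ij = exp(-D_ij² / 2α²)` (`M_w = W M`), masked to the top 50% of each
   window's spots, correlated (`W_corr = M_wᵀ M_w`), pruned to each
   window's top partners with Gaussian-decayed rank weights, and clustered
   with Leiden. Groups score per spot like single SNVs and are summarized
   by Moran's I spatial autocorrelation.
4. **Margin decay.** For each margin spot, the mean distance to its k = 5
   nearest tumor spots; OLS of log burden on log distance estimates the
   power-law decay exponent of mutation away from the tumor boundary.
5. **Neoantigen candidates.** Exonic nonsynonymous SNVs yield a ±15-aa
   mutant context; all 8–15-mer windows covering the substitution (92 for a
   full context) are filtered against every 8–15-mer of the reference
   proteome plus healthy-ligand lists, annotated against known-epitope
   lists, and exported as FASTA/TSV for external HLA tools.

A synthetic-section generator (`generate_section()`, `generate_toy_genome()`)
plants all of these signals with a ground-truth manifest, so the entire
pipeline is testable offline.

## Worked example

Simulate a 50×50 section (disk tumor, margin annulus, four planted SNV
groups, margin SNVs decaying with exponent −0.8) and run the full pipeline:

```r
library(spotmut)

sec <- generate_section(seed = 1)
dir <- file.path(tempdir(), "section")
write_section(sec, dir)

res <- run_pipeline(dir, file.path(tempdir(), "out"))
#> 226 SNVs retained from VCF
#> 166 of 226 SNVs effective
#> 65 SNV groups over 166 windows
#> 14 spot(s) dropped from log-log fit (nonpositive burden or distance)

res$effective
#> spot_snv_matrix: 2500 spots x 166 SNVs [raw layer], 12322 nonzero

str(res$margin_fit)
#> List of 5
#>  $ slope    : num -0.762
#>  $ intercept: num -4.88
#>  $ r_squared: num 0.475
#>  $ n        : int 866
#>  $ n_dropped: int 14

head(res$moran_groups)
#>   feature          I
#> 1 group_0 0.69505565
#> 2 group_1 0.77172979
#> 3 group_2 0.61755766
#> 4 group_3 0.71936388
#> 5 group_4 0.46852502
#> 6 group_5 0.08758702
```

Reading the output: of 226 planted SNVs, the 166 with real support pass the
effective filter (the 60 noise SNVs fail). The margin fit recovers a decay
slope of −0.76 against the planted −0.8 — binarization and zero-truncation
compress the realized exponent slightly, see the methods vignette — with
R² ≈ 0.48 over 866 margin spots. The four planted groups appear as the four
top-ranked Leiden groups, each with strong spatial autocorrelation
(Moran's I 0.6–0.8); the remaining small groups are fragments of the margin
and tumor-differential windows. `check_manifest(res, sec$truth)` confirms
every planted structure is recovered.

The same run is available from a shell:

```sh
Rscript inst/cli/spotmut simulate --out /tmp/section --seed 1
Rscript inst/cli/spotmut all --in /tmp/section --out /tmp/section/out --seed 1
```

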