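# rrqtl — round-robin bulk-segregant QTL mapping

`rrqtl` maps quantitative trait loci from pooled sequencing of selected
segregant pools (bulk-segregant analysis with very large pools, "X-QTL")
in multi-parent *round-robin* yeast crosses: K diverse parent strains on a
cycle, each crossed to its two neighbors, so every allele segregates in at
least two crosses. It is aimed at yeast quantitative geneticists analyzing
selection experiments on recombinant haploid pools — e.g. stress-resistance
selections whose traits run through MAPK signaling pathways — and at anyone
who wants a tested, self-contained implementation of the pooled
allele-frequency contrast LOD machinery.

## What it computes

For a selected pool and its matched control, allele counts are summed into
100-bp bins and each pool's latent allele frequency `p` along a chromosome
is modeled as a hidden Markov chain on a frequency grid:

- transition across one bin: mean `(1 − ρ)p + ρ(1 − p)`, variance
  `ρ(1 − ρ)/N`, with `ρ` the Haldane recombination fraction of the bin at
  2200 bp/cM and `N` the pool size (default 1000);
- emission: exact Binomial(depth, `p`) for the bin's parent-A read count.

Forward–backward posteriors of the two pools give the per-bin score

    LOD(i) = log10( (1/T) / Σₚ post_sel(i,p)·post_con(i,p) ),

a Bayes-factor–style measure of evidence *against* equal latent
frequencies (clipped at 0). QTL are called at LOD > 5 with 2-LOD drop
intervals, replicated across the MATa/MATα selections of each cross,
combined across stress dosages (minimum LOD — conservative), and grouped
across crosses by interval overlap. Each group carries a per-cross vector
of replicate-averaged maximum LODs; every region variant is then scored by
the squared Pearson correlation `r²` between its cross-segregation pattern
and that LOD vector, with permutation p-values — the round-robin trick
that narrows candidate causal variants. A full synthetic-data generator
(meiosis, viability selection, mating-type sorting, Poisson/binomial
sequencing, copy-number regions) plus growth normalization, a midparent
epistasis test, and coverage-ratio copy-number estimation round out the
package.

## Worked example

Simulate a 6-parent round-robin experiment with one planted salt-survival
locus on chr1 near 60 kb (`β = 2.5` for the alternative allele), run the
whole pipeline, and look at the grouped QTL and the association table:

```r
library(rrqtl)
cfg <- list(
  seed = 42,
  sim = list(n_strains = 6,
             chrom_lengths = list(chr1 = 120000, chr2 = 40000, chr3 = 50000),
             markers_per_chrom = c(240L, 80L, 100L),
             pool_size = 400, depth = 60, private_frac = 0.5,
             condition = "NaCl",
             effects = list(list(chrom = "chr1", pos = 60000, beta = c(0, 2.5)))),
  lod = list(bin_bp = 200),
  thresholds = list(lod = 5, drop = 2, min_depth = 10))
res <- run_pipeline(cfg, "out")
print(res$groups)
#> QTL groups: 1 regions across 6 crosses
#>  group chrom lower upper n_crosses crosses conditions
#>      1  chr1 27501 94800         4 1,2,4,5       NaCl
#> crosses-per-group histogram:
#> 4
#> 1
head(subset(res$association, group == 1), 3)
#>      variant        r2          p significant group
#> 1 chr1:51201 0.9917695 0.08291708       FALSE     1
#> 2 chr1:59717 0.9917695 0.08291708       FALSE     1
#> 3 chr1:70626 0.9917695 0.08291708       FALSE     1
```

One QTL group spans the planted locus and is detected in exactly the four
crosses in which the causal allele segregates (the histogram's single
entry at 4). The top `r²` variants include `chr1:59717` — the marker the
effect was planted on (the nearest marker to 60 kb) — together with two
neighbors whose segregation pattern is identical in this panel: with six
crosses the segregation pattern, not the p-value, is what separates
candidates. `out/` holds the frequency, contrast, LOD (bedGraph), QTL
(BED-like) and association tables, all re-readable with the package's
readers.

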