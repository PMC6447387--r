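# compbias

Diagnosis and mitigation of amino-acid compositional heterogeneity in
phylogenomic supermatrices.

## The problem

Deep protein phylogenies are vulnerable to a compositional flavour of
long-branch attraction: lineages whose genomes drift toward low G+C
content convergently enrich their proteomes in the amino acids encoded by
AT-rich codons (F, I, M, N, K, Y — "FIMNKY") and deplete those encoded by
GC-rich codons (G, A, R, P — "GARP"). Stationary substitution models then
group unrelated AT-rich lineages into artefactual clades. This package is
for phylogeneticists who need to *detect* that bias in a supermatrix and
*reduce* it before tree inference. It provides:

- **Composition profiling** — per-taxon frequency vectors, the
  GARP:FIMNKY ratio
  `R_s = (π_G+π_A+π_R+π_P) / (π_F+π_I+π_M+π_N+π_K+π_Y)`,
  a ratio-cutoff taxon partition (default 1.06), per-taxon chi-square
  deviations `t_s = Σ_i (π_is − π_i)² / π_i`, and UPGMA clustering of
  compositions.
- **Site stripping** — the signed per-site bias statistic
  `ζ = (π_FIMNKY^AT − π_FIMNKY^GC) + (π_GARP^GC − π_GARP^AT)` ∈ [−2, 2],
  ranking, and progressive removal in 10% increments (also rate-based
  stripping from external site-rate files).
- **Dataset-specific recoding** — hill-climbing search for the reduced
  alphabet (4 or 6 bins) minimizing `max_s t_s` (minmax chi-square),
  scheme files like `ARNDQEILKSTV GHY CMFP W`, and recoded alignments
  ready for DNA-capable inference software.
- **Profile mixtures** — EM estimation of a K-class empirical amino-acid
  profile mixture from alignment columns, NEXUS-style export, and exact
  collapse of a 20-state mixture onto a recoded alphabet.
- **Homogeneity-based gene selection** — a parametric-bootstrap test of
  compositional homogeneity per gene (simulating null alignments on a
  tree, so phylogenetic correlation is respected) and ranking of the most
  homogeneous genes.
- **A synthetic generator** — two-regime alignments in which biased taxa
  from two unrelated clades share a convergent AT-rich composition, with
  full truth tables, so every stage is testable without downloads.

## Worked example

```r
library(compbias)

# a 30-taxon alignment in which 8 taxa from two unrelated clades share a
# convergent AT-rich composition
sim <- make_regime_alignment(regime_config(
  n_taxa_total = 30, n_taxa_biased = 8, n_sites = 2000, seed = 42))
a <- sim$alignment
a
#> aa_alignment: 30 taxa x 2000 sites (alphabet of 20 states)
#> missing data: 9.89%

comps <- taxon_compositions(a)         # sorted ascending by GARP:FIMNKY
head(comps[, c("taxon", "garp_fimnky")], 3)
#>    taxon garp_fimnky
#> 6   t006   0.5813149
#> 24  t024   0.5960503
#> 11  t011   0.6163410

part <- partition_taxa(comps)          # cutoff 1.06
part
#> taxon_partition (cutoff 1.06): 8 AT-rich, 22 GC-rich

z <- zeta_scores(a, part)
summary(z$zeta)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> -1.0000 -0.1132  0.1750  0.2097  0.5335  1.5152

res <- strip_sites(a, z$zeta, 0.30)    # drop the 30% most biased sites
length(res$removed)
#> [1] 600

sr <- search_scheme(a, n_bins = 4, n_restarts = 5, seed = 1)
sr
#> scheme_search: max_t = 0.00191401 over 5 restarts (seed 1)
#>   ACEHIKPSVY RFW NDQGLM T
chisquare_report(a)$max_t              # heterogeneity before recoding
#> [1] 0.0682
```

The 8 truly biased taxa are exactly the 8 taxa below the 1.06 cutoff, the
zeta distribution is right-shifted by the 30% disparity sites (median
0.18), and recoding drops the worst per-taxon chi-square deviation from
0.068 to 0.0019 — the bias is largely absorbed into within-bin exchanges.

`run_pipeline(pipeline_config(...))` chains all stages (profile →
partition → zeta → strip schedule → recode → mixture → homogeneity) and
writes a manifest with MD5 checksums of every artifact;
`inst/scripts/compbias-cli.R` exposes the same stages as shell
subcommands.

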