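---
title: "Diagnosing and mitigating amino-acid compositional heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing and mitigating amino-acid compositional heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(compbias)
```

## The problem

Stationary substitution models assume that amino-acid frequencies are the
same across lineages. In deep bacterial phylogenomics this assumption is
routinely violated: lineages whose genomes drift toward low G+C content
convergently shift their proteomes toward amino acids encoded by AT-rich
codons (F, I, M, N, K, Y, "FIMNKY") and away from those encoded by GC-rich
codons (G, A, R, P, "GARP"). Unrelated AT-rich lineages then look alike to
a stationary model, and maximum-likelihood or Bayesian trees can pull them
into an artefactual clade — a compositional flavour of long-branch
attraction. This package implements a family of diagnostics and mitigations
for that failure mode on protein supermatrices, together with a synthetic
generator that reproduces the confound so every stage can be validated
against known truth.

## Diagnostics

**Per-taxon profile.** For taxon $s$, `taxon_compositions()` computes the
frequency vector $\pi_{\cdot s}$ over non-missing cells and the ratio

$$R_s = \frac{\pi_G + \pi_A + \pi_R + \pi_P}
             {\pi_F + \pi_I + \pi_M + \pi_N + \pi_K + \pi_Y},$$

a proteome-level proxy for genomic G+C content. Plotting sorted $R_s$
typically shows a gap between compositionally biased taxa and the rest;
`partition_taxa()` splits the taxa at a cutoff placed in that gap (default
1.06, the conventional choice for alphaproteobacterial datasets). The
cutoff should always sit inside an empty interval of the observed ratios,
which is why a ratio exactly equal to the cutoff (a measure-zero event on
real data) is deterministically assigned to the GC-rich side.

**Per-site bias.** With the taxa split into an AT-rich group and its
complement, `zeta_scores()` scores each site by

$$\zeta = \left(\pi_{FIMNKY}^{AT} - \pi_{FIMNKY}^{GC}\right) +
          \left(\pi_{GARP}^{GC} - \pi_{GARP}^{AT}\right),$$

where each term is a group frequency over non-missing cells at that site.
$\zeta \in [-2, 2]$; it is signed on purpose — positive values mark sites
where the AT-rich group is FIMNKY-enriched *and* GARP-depleted relative to
the rest, which is the artefact being targeted. Sites are therefore ranked
by signed $\zeta$, not $|\zeta|$. A site at which one group is entirely
missing carries no between-group information; it gets $\zeta = 0$ and a
flag rather than an error.

**Chi-square heterogeneity.** `chisquare_report()` computes, per taxon,

$$t_s = \sum_i \frac{(\pi_{is} - \pi_i)^2}{\pi_i},$$

with $\pi_i$ the pooled (count-weighted) frequency of state or bin $i$
over all taxa. Pooling over cells rather than averaging per-taxon vectors
matches the classical homogeneity $X^2$ construction; the two coincide when
all taxa have equal non-missing lengths. Bins with $\pi_i = 0$ are dropped
from the sum — the limit of the statistic as the expectation goes to zero
with zero observed counts. $\max_s t_s$ is the single-number heterogeneity
summary used as the recoding criterion below.

**Clustering.** `upgma_compositions()` builds an average-linkage
(UPGMA) dendrogram from Euclidean distances between the 20-dimensional
frequency vectors. On biased datasets, unrelated AT-rich lineages cluster
together here even though they are phylogenetically distant — the visual
smoking gun. UPGMA is implemented directly so that ties in the minimum
pairwise distance can be broken deterministically (lexicographically by the
smallest member label); on tie-free inputs it agrees with
`hclust(method = "average")`, which the test suite uses as an independent
oracle.

## Mitigations

**Site stripping.** `strip_sites()` removes the top
$\mathrm{round}_{1/2\uparrow}(fL)$ sites by score for a removal fraction
$f$; `strip_schedule()` applies the conventional 10%–90% schedule in 10%
increments, and the removed sets are nested by construction. Round-half-up
is used so that, e.g., 30% of a 54,400-column supermatrix removes exactly
16,320 columns; ties between equal scores are broken by ascending site
index. Rate-based stripping (`strip_by_rate()`) uses externally estimated
site rates through the same contract, which makes the two removal schedules
directly comparable.

**Dataset-specific recoding.** `search_scheme()` looks for a partition of
the 20 amino acids into $k$ bins (4 or 6 in practice) minimizing
$\max_s t_s$ computed on bin frequencies — the minmax chi-square criterion.
The search is steepest-descent hill climbing over single-residue moves from
random restarts: all moves that do not empty a bin are evaluated, the one
with the largest decrease is taken (ties resolved by smallest residue
letter, then smallest destination bin index, so a seed fully determines the
outcome), and the climb stops at a local minimum. The search space for
two bins over five effective residues is small enough to enumerate
exhaustively (15 set partitions), which is how the optimizer is validated:
with 20 restarts the hill climb attains the enumeration optimum on all
tested instances. For full 20-letter alphabets no optimality guarantee is
claimed — only that the returned scheme is the best local minimum seen, and
that its criterion value is reproduced exactly by an independent
recode-then-report computation. Four-bin schemes are written with the
symbols `A C G T` so recoded matrices can be analyzed by DNA-capable
inference software; six-bin schemes use digits `0–5`.

**Profile mixtures.** `fit_mixture()` estimates a $K$-class empirical
mixture of amino-acid profiles from alignment columns, the dataset-specific
analogue of general C-series profile sets (e.g. $K = 60$). Columns are
summarized as count vectors over non-missing cells and fitted with a
multinomial-mixture EM: responsibilities in the E-step, weight and profile
updates with a Dirichlet(0.5) pseudocount in the M-step, k-means++-style
initialization on normalized counts, `tol = 1e-6`, `max_iter = 500`. The
reported `loglik` is the penalized objective (data log-likelihood plus the
Dirichlet log-prior term), which EM increases monotonically; the
unpenalized value is exposed as `data_loglik`. With $K = 1$ the estimate is
the pooled frequency vector up to the $O(1/\text{total counts})$ smoothing
perturbation. This estimator is a deliberately simple, fully testable
stand-in for published profile-set estimation procedures: it reproduces the
object's role (a dataset-specific profile set with weights) without
tree-aware estimation. `collapse_profiles()` converts a 20-state mixture to
a recoded alphabet by summing member frequencies per bin — collapsing is
linear and weight-preserving — and `export_mixture()` writes a NEXUS-style
`FMIX` block loadable as a custom model.

**Homogeneity-based gene selection.** The naive $X^2$ test for equal
compositions across taxa ignores phylogenetic correlation and rejects far
too often. `test_gene()` instead compares the observed count-based
statistic against a null distribution obtained by simulating `N` replicate
alignments on a supplied tree under a homogeneous model (parametric
bootstrap), with $p = (1 + \#\{X^2_{null} \ge X^2_{obs}\})/(N+1)$ — never
exactly zero. The count-based form is used (rather than the
frequency-based $t_s$) because the bootstrap needs a size-sensitive
statistic; both are exposed. Replicates inherit the observed alignment's
missing-data mask so per-taxon totals match. `simulate_alignment()` draws
root states from the model's equilibrium and evolves them with transition
kernels obtained from the eigendecomposition of the reversible rate matrix;
among-site rate variation uses discrete-gamma categories (equal
probability, category means — four by default). `select_homogeneous()`
ranks genes by descending $p$ (ties by smaller statistic, then name) to
assemble a reduced, compositionally homogeneous gene set.

## The synthetic generator

`make_regime_alignment()` emulates the confound, not any particular
dataset: a birth–death tree (depth scaled to 1) over `n_taxa_total` taxa
(default 100, supermatrix-like scale), with `n_taxa_biased` (default 25)
biased taxa drawn from two disjoint clades so that their compositional
similarity is convergent, never ancestral. A fraction of sites (default
0.3) carries the disparity: biased taxa draw residues from a
FIMNKY-enriched profile and background taxa from a GARP-enriched one, while
the remaining sites use one shared profile for everybody. Profiles are
constructed by transferring probability mass between the GARP and FIMNKY
sets of a baseline composition (LG equilibrium frequencies, bent to ratio
1.06 for the shared profile) proportionally to each member's baseline
frequency, with a floor of 0.001 per residue; the transfer amounts are
solved numerically so that *realized per-taxon* ratios land at
$1.06 \pm \mathrm{margin}/2$. An unreachable margin (given the floor) is a
configuration error, not a silent clamp. Gamma site rates
(shape 0.8, a typical protein-alignment value) are drawn and recorded in
the truth table; missing cells are inserted uniformly.

What the generator deliberately does *not* model: tree-correlated residues
within a site (draws are i.i.d. given the profile), lateral transfer,
among-gene rate variation, and alignment error. Passing tests on this
generator therefore demonstrate the estimators' correctness and calibration
under the stated two-regime mechanism, not robustness to every real-data
pathology.

`make_mixture_columns()` is the matching generator for the mixture module:
sites drawn i.i.d. from known class profiles with recorded labels.

## Numerical choices and degenerate inputs

- Missing symbols are `-`, `?`, `X`, all treated identically in frequency
  computations; `*` is rejected at parse time with the offending position
  named. Both X-counting conventions for the percent-missing figure are
  available (`missing_fraction(count_x=)`) and logged by the pipeline.
- Coordinates are 1-based inclusive in every file and report.
- A taxon with no non-missing cells is an error naming the taxon; a taxon
  with zero FIMNKY residues gets ratio $+\infty$ and a warning.
- All stochastic functions take an explicit integer seed and are
  bit-reproducible given it; the pipeline derives stage seeds from one
  master seed and double-run checksum equality is part of the test suite.
- Problem sizes used by the validation suite were chosen to keep each
  property cheaply checkable while leaving Monte-Carlo error well below the
  asserted tolerances: bootstrap calibration uses 500 genes of 20 taxa ×
  300 sites at $N = 99$ (the add-one estimator makes the rejection
  probability at $\alpha = 0.05$ exactly 5/100 under the null); mixture
  recovery uses 10,000 columns; regime recovery uses the generator defaults
  (100 taxa × 5,000 sites).

## Limitations

- The recoding search is a local optimizer; published fixed schemes
  (Dayhoff-6 and relatives) are accepted through scheme files but not
  built in.
- The mixture estimator is column-multinomial, not tree-aware; profiles
  estimated this way absorb both site-specific preferences and residual
  phylogenetic signal.
- The homogeneity test's power depends on the supplied tree and model
  being adequate for the null; it is a gene-ranking device, not a
  general goodness-of-fit test.
- Tree inference itself (ML/Bayesian, PMSF-style approximations) is out of
  scope; the package prepares inputs for, and consumes outputs of, external
  inference software.

## A worked desk-scale run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  sim = regime_config(n_taxa_total = 20, n_taxa_biased = 6,
                      n_sites = 600, seed = 1),
  K = 5, restarts = 5, replicates = 19, seed = 11,
  outdir = "compbias_demo")
manifest <- run_pipeline(cfg)
```

The manifest lists the composition table, the UPGMA dendrogram, the zeta
table, nine progressively stripped alignments, the best 4- and 6-state
schemes with their recoded matrices, the exported mixture (raw and
collapsed), and the homogeneity report — each with an MD5 checksum, so two
runs with the same configuration can be compared file by file.
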