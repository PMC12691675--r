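---
title: "Detecting species-specialized genes with phylogeny-deviation scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting species-specialized genes with phylogeny-deviation scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdscore)
```

## The problem

Across a bacterial family, the protein divergence of most genes scales with
the phylogenetic separation of the species carrying them: a gene in two
distantly related genomes is usually about as diverged as the 16S rRNA
yardstick predicts. Genes that have been recruited into a species-specific
role — a symbiont's secondary-metabolite machinery, a rewired repair pathway
— break that scaling in one lineage only: the gene copies of that species are
far more diverged from everyone else's than its 16S position warrants, while
all other species pairs stay on the trend.

`pdscore` turns that intuition into a per-gene statistic. It is aimed at
comparative genomicists who have a set of annotated genomes, one focal
("target") species, and a reference proteome to key ortholog groups on.

## The model

For one ortholog group $g$ over $N$ species, let $Og(a,b)$ be the pairwise
protein distance and $Phy(a,b)$ the pairwise 16S rRNA distance. Each matrix
is standardized on its strict upper triangle (subtract the mean, divide by
the sample standard deviation), which removes the gene's overall evolutionary
rate — the *scale* of divergence — and leaves only its *pattern*. Every
unordered species pair $(a,b)$ becomes a point

$$v_g(a,b) = \big[\widetilde{Phy}(a,b),\ \widetilde{Og}(a,b)\big]$$

in a 2D "distance space". A target species $c$ splits the
$N(N-1)/2$ points into the in-cluster $C_c$ (the $N-1$ pairs containing
$c$) and the out-cluster $C_{other}$ (everything else). For each point $i
\in C_c$ we compute the mean Euclidean distance $h(i)$ to the other
in-cluster points, the mean distance $f(i)$ to the out-cluster, and the
silhouette coefficient

$$s(i) = \frac{f(i) - h(i)}{\max\{f(i), h(i)\}} \in [-1, 1].$$

The **PD score** of gene $g$ for species $c$ is the mean of $s(i)$ over
$C_c$. A concordant gene leaves the target's pairs embedded in the
background cloud (PD near 0); a gene specialized in $c$ displaces all of
$c$'s pairs off the $y = x$ trend as a coherent, well-separated cluster
(PD toward 1). Calinski-Harabasz and Davies-Bouldin indices of the same
two-cluster partition are computed as companion scores (`chi_score()`,
`dbi_score()`); high CHI and low DBI point the same way as high PD.

Across all groups, PD scores are converted to z-scores and genes with
$z \ge 1$ (roughly the top 16% under normality) are flagged as candidates.
The threshold is deliberately defined on the z-scale rather than on a fixed
raw PD value, because the raw scale depends on the dataset's size and
divergence structure.

## Inputs and the surrounding pipeline

The scoring core consumes aligned per-group protein FASTA plus an aligned
16S FASTA. Around it the package provides the standard steps:

* **GenBank ingest** (`parse_genome_gb()`, `filter_cds()`): CDS are kept
  only if they are not pseudogenes or partial features, contain no
  ambiguous bases, have in-frame length, a methionine-initiated annotated
  translation, and re-translate exactly (bacterial code, table 11; the
  initiator codon is rendered as M, so GTG/TTG starts are accepted). Each
  rejection records the first failing rule. Genomes without a 16S rRNA
  annotation cannot be placed and are excluded from scoring.
* **Representative 16S** (`select_representative_16s()`): when a genome has
  several 16S copies, the copy with the least mean distance to all other
  sequences in the dataset-wide pool is chosen. The pool includes sibling
  copies of the same genome (this avoids making one genome's choice depend
  on another's), the candidate itself is excluded from its own mean, and
  ties break to the lexicographically lowest copy id.
* **Ortholog groups** (`build_ortholog_groups()`): from a 12-column tabular
  homology hit file, hits with e-value $\le 10^{-5}$ and identity
  $\ge 30\%$ survive; per (species, reference gene) the best hit wins,
  "best" meaning highest bitscore, then lower e-value, then lexicographic
  query id. Bitscore is used as the similarity criterion because it is
  length- and composition-normalized. One protein may legitimately win in
  several groups. Groups are kept for scoring when they contain the target
  and at least `min_species = 4` members — the minimum for both clusters
  to have an internal scale.

## Distances

Protein distances are pairwise maximum-likelihood estimates under the
Jones-Taylor-Thornton model with discrete-Gamma rate variation
(`dist_ml_jtt()`; shape $\alpha = 1$, 4 categories by default). The JTT
exchangeabilities and frequencies are bundled as constants. Each pair's
likelihood uses its symmetrized 20×20 amino-acid pair counts; the 1-D
optimization is a shared 60-point log-spaced likelihood grid over all pairs
followed by Brent refinement (`stats::optimize`, tolerance $10^{-8}$) in
the bracketing interval. Identical sequences short-circuit to 0; pairs
whose grid optimum sits at the upper bound report `d_max` (default 10
substitutions/site) with a saturation warning. Four Gamma categories
approximate the continuous distribution; agreement with other
implementations is expected to be monotone and close, not bit-identical.

16S distances default to the Gamma-corrected Kimura two-parameter model
(`dist_nt(..., "k2p_gamma")`, $\alpha = 1$), with Jukes-Cantor and raw
p-distance as alternatives. An amino-acid model is not meaningful for rRNA,
so the nucleotide model is an explicit, documented choice. Saturated
corrections (log or power argument out of domain) report `d_max` with a
warning rather than propagating infinities.

When a group lacks some species, the 16S matrix is subset to the group's
species and **re-standardized over that subset**, keeping both coordinates
on comparable scales within every group.

Standardization uses the sample standard deviation ($n-1$); the choice is
immaterial to the scores because the PD statistic is invariant to any
positive affine transform of either raw matrix — the property that
underwrites removing per-gene rate differences in the first place.

## Localizing the deviation: per-site dN/dS and divergence

For a flagged gene, `backtranslate()` threads the protein alignment onto
its CDS (terminal stop dropped, gap columns become `---`), and
`site_dnds_profile()` computes a per-codon-column Nei-Gojobori (1986) style
ratio of the target against all other species: fractional synonymous and
nonsynonymous site counts per codon (mutations to stop codons excluded from
the per-position denominator), path-averaged difference counts between
codon pairs (orderings passing through a stop are excluded; if every
ordering does, all orderings are used with stop-passing steps counted as
nonsynonymous), pooled over species pairs and, optionally, a centered odd
window (default 1: per-site). Conventions for sparse sites: no comparable
pair or no substitutions → missing; synonymous count zero with
nonsynonymous substitutions present → infinite ratio reported as a capped
sentinel (default 10) with a flag.

`detect_runs()` reports maximal stretches of at least 10 consecutive
columns above dN/dS = 1 (sentinels count as above; missing values break a
run). `gene_average_dnds()` pools counts over the whole gene per species
pair, applies the Jukes-Cantor-style correction $d = -\tfrac34\ln(1 -
\tfrac43 p)$ to both proportions, and averages the ratios over species;
pairs with no synonymous divergence or a saturated correction are excluded
with a warning. Whether to average ratios or pool counts first is exposed
(`method`), defaulting to the mean of pairwise corrected ratios.
`site_divergence_profile()` gives the per-column fraction of species
differing from the target (gaps in others count as differing; target-gap
columns are missing), and `flag_top_deviating_sites()` marks the 15
most-deviating columns that also differ from a chosen reference sequence.

## The synthetic benchmark

`generate_benchmark()` creates the package's study conditions without any
downloads: a Yule (pure-birth) species tree (`ape::rphylo`, no extinction —
the simplest process with realistic imbalance; the method consumes only
distances, so topology realism is secondary), a 16S-like neutral DNA
alignment, and protein families evolved along the same tree. Specialized
families multiply the rate on the target's terminal branch by
`accel_factor`; truth labels are recorded. Defaults: 30 species, 1,500-site
16S, 300-residue genes, 50 background + 5 specialized families,
acceleration 8×, base rate 0.1 substitutions/site/unit branch length —
sizes and rates chosen to resemble a within-family bacterial dataset with
moderate 16S divergence. By default the target is the tip with the longest
terminal branch, emulating the long-branch, fast-evolving symbiont lineage
this kind of screen is aimed at; any tip can be selected instead.

Sequence evolution is an equal-exchangeability model with JTT equilibrium
frequencies (proteins) or Jukes-Cantor (DNA). Estimating under full JTT
while simulating under a simpler kernel is deliberate model
misspecification: the PD score should not depend on absolute distance
calibration, only on the pattern, and standardization makes it so. CDS are
co-generated by uniform synonymous-codon sampling per residue, so dN/dS
profiling sees realistic synonymous variation while every amino-acid change
is nonsynonymous by construction.

What the generator does **not** emulate: indels (alignments are gap-free),
recombination, base-composition and codon-usage bias, paralogy, annotation
errors, and alignment uncertainty. Passing the synthetic recovery tests
therefore demonstrates the statistic's behavior under clean
lineage-acceleration signal, not robustness to those real-data artifacts.

Determinism: every family's seed is a fixed hash of the master seed and the
group id, so the whole benchmark is byte-reproducible from its
configuration.

## Numerical choices and edge cases

* Silhouette with both means zero (coincident points) is defined as 0, the
  standard degenerate convention; an all-coincident cloud scores PD = 0.
* CHI with zero within-cluster scatter but distinct centroids is $+\infty$;
  identical centroids give 0. DBI with coincident centroids is $+\infty$.
* Two-species groups are rejected rather than special-cased: with
  $|C_c| = 1$ there is no in-cluster scale and the score is meaningless.
* Per-gene scoring cost is $O(N^3)$ pairwise 2D distances, vectorized.
  Seeded subsampling of the out-cluster is available for very large $N$
  but off by default, so standard runs are exact.
* Ranking ties break lexicographically by group id, making "top $k$"
  exports reproducible.
* PHYLIP matrix output carries 12 decimal digits in scientific notation so
  write/read round trips hold to $10^{-10}$.

## Problem sizes used by the test suite

The shipped tests run the full default benchmark once (30 species, 55
genes, seed 1) for the headline recovery check; the no-acceleration null
comparison uses 10 seeds at a reduced size (15 species, 150-residue genes,
12 background + 8 "special" families with `accel_factor = 1`, PD pooled
across seeds) — the null property is size-invariant, so the smaller
instances test the same claim. Distance recovery uses 20,000-residue pairs
simulated at true distance 0.5 under the same discretized Gamma model the
estimator uses, so the ±0.05 band measures estimator error rather than
discretization bias. Oracle comparisons (brute-force silhouette, exhaustive
NG86 enumeration, run-scan) cover the full combinatorial spaces they check.

## Known limitations

* The PD score is a screen, not a test: it has no null distribution and no
  p-value; the z ≥ 1 flag is a ranking convention.
* NG86 counting is the simplest dN/dS method; it has no transition/
  transversion or codon-frequency correction and underestimates rates at
  high divergence. Maximum-likelihood codon models are out of scope.
* Per-site dN/dS over a handful of species is sparse; most sites are
  missing or based on few substitutions, which is why run detection and
  window pooling exist.
* One target species per run; joint multi-target scoring is not supported.
* The method is deliberately tree-free beyond the 16S distance matrix; it
  cannot distinguish acceleration on the target's terminal branch from
  artifacts that mimic it (e.g., a misassembled or contaminated target
  gene).
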