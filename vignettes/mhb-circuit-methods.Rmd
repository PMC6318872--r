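---
title: "From tripartite root metatranscriptomes to a Boolean regulatory circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tripartite root metatranscriptomes to a Boolean regulatory circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mhbcircuit` models how a mycorrhiza helper bacterium (MHB) rewires gene
regulation in plant roots. The experimental unit is a 2×2 factorial
community — a host seedling grown alone, with an ectomycorrhizal fungus,
with a candidate helper bacterium, or with both, three replicate root
transcriptomes per condition. This vignette explains the statistical model
behind each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## Quantification: bootstrap resolution of multi-mapped reads

Reads are aligned against the pooled gene models of all community members;
with 50-bp reads a fraction aligns equally well to several genes, sometimes
across organisms. Rather than discarding or fractionally splitting these
reads, each bootstrap iteration assigns every multi-aligned read uniformly
at random to one of its candidate genes; uniquely aligned reads always count
for their gene. Per iteration,

$$RPKM_g = \frac{n_g}{(L_g/1000)\,(N/10^6)},$$

where $L_g$ is the gene length in bp and $N$ the number of distinct aligned
reads (each read counted once regardless of how many alignments it has, so
the per-iteration library size is constant). The mean and SD over
iterations quantify both expression and assignment uncertainty. The default
of 10,000 iterations is far past Monte-Carlo convergence for the means
(which shrink as $1/\sqrt{iterations}$); tests and the acceptance script use
100–200, which is ample at their problem sizes.

**Expression significance.** A gene is called expressed from the probability
that its expression is at or below zero under a normal with the bootstrap
moments, $p = \Phi((0-\mu)/\sigma)$. Zero is the only null point that makes
"significantly expressed" coherent, and a zero bootstrap SD degenerates to
$p = 0$ (positive mean) or $1$. p-values are BH-adjusted within each sample
(pooling across samples would let a deeply sequenced sample change another
sample's calls); the call threshold is q < 0.05 *and* mean RPKM > 2. This
implementation re-assigns multi-mapped reads but does not additionally
resample reads with replacement; the two differ only in the width of the
bootstrap SD for uniquely aligned genes, which the significance call does
not use (their SD is zero either way).

**Normalization.** Expression is `log2(RPKM + 1)` (the pseudocount handles
zeros; its exact value only shifts the floor) followed by quantile
normalization, with ties replaced by the average of the tied quantiles.
After normalization every sample has identical order statistics, which is
the property the downstream ANOVA relies on.

## Differential expression: permutation ANOVA on the 2×2 design

Per gene, a classical two-way fixed-effects decomposition gives F statistics
for the fungus main effect, the bacterium main effect, and their
interaction; Type II sums of squares are computed via model-comparison
projections so unbalanced designs degrade gracefully. Significance comes
from permutations of whole sample columns with a single shared schedule —
sharing the schedule across genes and factors makes runs reproducible and
preserves between-gene correlation of the null. The estimator is
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, which can never return zero.

Two details matter in practice. First, the minimum attainable p is
$1/(n_{perm}+1)$; after BH correction across $m$ genes the smallest
achievable q is roughly $m/(n_{perm}+1) \cdot 1/rank$, so scaled-down runs
need at least ~2,000 permutations for anything to clear an FDR of 0.05 —
the package default remains 10,000. Second, a constant gene has both effect
and residual sums of squares at floating-point noise; effect SS below
$10^{-10}$ of the gene's total SS is treated as exactly zero so that
constant genes report F = 0, p = 1.

Genes never called expressed in any sample are excluded before testing
(configurable), reducing the multiplicity burden. A gene is SDE if it is
significant for at least one factor; both FDR-adjusted (default) and raw
permutation thresholds are exposed, since reasonable workflows have used
either.

## Clustering: K-means with silhouette model selection

SDE genes are clustered on their expression *shape*: gene-wise mean-centered
values, Euclidean distance, K-means++ seeding, best of 25 restarts, K chosen
to maximize the mean silhouette coefficient over K = 2…12 (ties toward
smaller K). Whether to cluster per-sample values or per-condition replicate
means was an open choice; the pipeline uses per-condition means. The reason
is mechanical: with three replicates, per-sample features carry
$\sqrt{3}$-fold more measurement noise per dimension, which inflates
within-cluster distances and makes the mean silhouette prefer coarse
merges of genuinely distinct response patterns, while replicate averaging
cancels exactly the noise that carries no co-regulation signal. At a fixed
correct K the two feature spaces give the same partitions (ARI ≈ 0.95 on
synthetic truth); the choice only affects model selection. Both remain
available, since `kmeans_fit()`/`select_k_silhouette()` accept any matrix.

Cluster condition profiles are means over member genes of the log2 deviation
from the host-only baseline, so the baseline column is identically zero. The
mycorrhization link is a Pearson correlation between each cluster's
4-condition profile and the percent-mycorrhization vector; the target
cluster's correlation is standardized against the other clusters,
$z = (r_t - \bar r)/sd(r)$, with a one-tailed upper normal p (the claim
being "higher than the rest"). At the working point $r_t = 0.99$ against a
reference mean of −0.25 and SD 0.45 this gives $p = \Phi(-2.756) \approx
0.0029$; a printed value of 0.002 at one significant digit is consistent
with intermediate rounding, and the package reports the computed value.

## Enrichment: exact hypergeometric tails

For each (cluster, term) pair with at least one annotated member, the
enrichment p-value is the exact cumulative hypergeometric upper tail
$P(X \ge k)$ for $k$ annotated genes in a cluster of $n$, against $K$
annotated genes among the $N$ annotated host genes. The background is the
annotated host genome only — the other organisms' genes are never
candidates. Terms are tested as annotated, without GO-graph ancestor
propagation, and a raw threshold of p < 0.05 flags enrichment (a BH option
exists but is off by default, matching common practice for descriptive
cluster annotation). A term is *uniquely* enriched when it is enriched in
exactly one cluster; uniqueness is what elevates an annotation from
descriptive to diagnostic in the sensor screen below.

## The regulatory circuit

**Nodes and states.** One node per cluster (its per-sample mean member
expression) plus two presence nodes (the 0/1 design indicators, constrained
to be network roots — community composition is set by the experimenter, not
by gene expression). Cluster nodes are discretized by rank; the default is a
binary median split. With three replicates per condition, conditional
distributions over three states cannot be estimated, and — more importantly —
a cluster that responds to *exactly one* symbiont being present is a
deterministic binary function of the two presence bits but only a noisy
three-state one, so binary states are what make the network and the Boolean
gate layer tell the same story. Rank-based binning also makes states
invariant under monotone transformations of a node's values.

**Structure search.** Greedy hill climbing over add/delete/reverse edge
moves maximizes a BDeu score (equivalent sample size 1) plus a sparsity
structure prior of one nat per parent, under a cap of 5 parents per node,
with 20 restarts (the first from the empty graph, the rest from random
presence-rooted DAGs). Two things here are deliberate and worth stating
plainly:

- *The sparsity prior is essential, not cosmetic.* On near-deterministic
  12-sample data the raw BDeu marginal likelihood increases with every
  added parent, so an unpenalized search maxes out every parent set at the
  cap, and the subsequent transitive pruning then deletes the direct
  presence→cluster edges through incidental chains. One nat per parent is
  enough to make parent sets minimal while leaving the (multi-nat) gains of
  real dependencies untouched.
- *Single-edge moves cannot discover an XOR.* A cluster regulated by
  "exactly one symbiont present" is statistically independent of each
  presence bit marginally, so no single edge addition ever improves the
  score. The move set therefore includes two composite moves: adding both
  presence roots to a node at once, and replacing a node's parent set by
  the two presence roots. These are still score-greedy local moves; they
  just make the jointly-informative pair reachable.

**Pruning and gates.** The learned DAG is transitively reduced (every edge
with an alternative directed path is removed; for a DAG the reduction is
unique and preserves reachability). On the pruned scaffold each cluster
node is binarized per condition — ON iff its condition-mean log2
fold-change versus baseline exceeds 0.5 (a dead zone: down-regulation is
OFF) — and the Boolean function of its parents minimizing condition
mismatches is found by exhaustive enumeration (all $2^{2^k}$ functions for
up to 3 effective inputs; larger parent sets are reduced greedily). Ties
prefer fewer dependent inputs, then canonical order, which makes gate
labels deterministic and invariant to parent order. The threshold of 0.5
log2 units sits well below the planted and observed effect sizes (±1–2.5)
and above replicate noise. The derived `mhb_activity` output node mirrors
the binary state of the mycorrhization-correlated cluster, which is how the
circuit's output is interpreted.

**Sensor screen.** Candidate sensors for MHB integration must satisfy:
(i) membership in a cluster whose gate depends on *both* presence inputs;
(ii) a sensor-type annotation (default `GO:0048544`, recognition of pollen —
receptors that integrate two extracellular ligands to down-regulate a gene
program) enriched in that cluster; and (iii) that enrichment being unique
to that cluster. The screen returns the member genes carrying qualifying
terms with per-criterion bookkeeping.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the study design so
every downstream stage can be validated against planted truth.

What it emulates: a 2×2 design with 3 replicates; three co-resident genomes
with read shares around 99% host / ~1.4% fungus (when present) / a small
bacterial share that roughly doubles-to-triples in the tripartite
condition; per-gene baseline abundances log-uniform over three orders of
magnitude; lognormal replicate noise (`noise_sd`, default 0.25 on the log
scale) on expected counts with Poisson sampling; a configurable fraction of
reads (default 5%) carrying 1–3 decoy alignments; six planted
condition-response clusters (the `"fig3-like"` preset) including one XOR
pattern, with magnitudes chosen to keep the patterns mutually separated
after row-centering while preserving their qualitative signs; planted
per-cluster annotation enrichments plus a sensor term on 8 XOR-cluster
genes; and a phenotype table with mycorrhization zero in fungus-absent
conditions and 1.7× higher with the helper present.

Deliberate departures from naive defaults, and why:

- *Decoys are mostly same-organism* (cross-organism with probability 0.015
  per decoy). Sampling decoys uniformly over the catalog would attribute
  over 1% of host reads to the fungus in fungus-free samples — an order of
  magnitude above the cross-alignment rate short 50-bp reads actually show —
  and would flatten the organism-presence fold enrichments the community
  statistics are meant to detect.
- *The bacterial share is scaled up* (~0.05–0.175% of aligned reads) relative
  to the vanishingly small share seen at tens of millions of reads of real
  depth, because at the simulated depth of $10^5$ reads per sample a
  realistic share would leave ~5 bacterial reads — too few for any
  per-sample statistic to be defined.
- *Planted regulated genes are drawn from above the 30th abundance
  percentile.* Planting a ±2 log2 response on a gene with two expected
  reads makes the truth unrecoverable by any method; restricting planting
  to the detectable range makes recovery metrics measure the pipeline
  rather than the sequencing-depth floor.

What it does not emulate: nucleotide sequences, quality scores or
alignment-error structure; gene-length biases in multi-mapping;
overdispersion beyond lognormal×Poisson; correlated noise between genes;
isoforms. Passing recovery tests therefore demonstrate the pipeline's
statistical machinery, not robustness to alignment artifacts of real data.

## Problem sizes and determinism

Default analysis settings mirror full-scale practice (10,000 bootstrap
iterations, 10,000 permutations, K = 2…12, α = 0.05 throughout, ≤ 5 BN
parents). The test suite and the acceptance script run the same code at
reduced sizes chosen as the smallest that leave the statistics
well-behaved: 1,000–2,000 host genes, $5\times10^4$–$10^5$ reads per
sample, 100–200 bootstrap iterations, 2,000–5,000 permutations (see the
FDR floor above), and 20 replicate experiments for the XOR-recovery rate.
Every stochastic stage draws its seed deterministically from one
configuration seed; re-running a configuration reproduces byte-identical
outputs, which the tests verify with file digests.

## Known limitations

With 12 samples the Bayesian-network posterior is weakly determined:
structures related by Markov equivalence or by deterministic proxies score
similarly, and only the composite presence-pair moves plus the sparsity
prior make the presence-rooted explanation win reliably. Gate fitting sees
only four condition-level states, so gates with more than three effective
inputs are never identifiable and are reduced greedily. The enrichment
stage deliberately applies no FDR and no GO-graph propagation; its outputs
are descriptive. The phenotype correlation uses four condition means — its
significance is a screening heuristic, not a replicated test.
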