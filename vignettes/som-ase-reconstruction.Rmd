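---
title: "Reconstructing allele-specific expression with self-organizing maps"
author: "somase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing allele-specific expression with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somase)
```

## The problem

An allele-specific expression (ASE) experiment on a population of diploid
individuals yields, for a family of genes, per-allele read counts: each
gene contributes a block of rows (one per observed allele) to a count
matrix whose columns are individuals. Diploidy constrains every gene block
to at most two non-zero entries per column — two for a heterozygously
expressed gene, one (carrying both copies' signal) for a homozygous gene,
none when the gene is not expressed. The multiset of expressed alleles of
an individual is its *signature* (homozygous alleles count twice), and the
set of distinct signatures in a population is its *genoset*.

Experimental failures corrupt individuals: some expressed alleles and
their read counts are zeroed out, and the affected column becomes
indistinguishable from a profile that simply expresses fewer alleles.
`somase` reconstructs such corrupted individuals in two phases:

1. a self-organizing map (SOM), trained on uncorrupted profiles, assigns
   the corrupted individual to a cluster;
2. a *completion rule* built from that cluster's subpopulation — allele-pair
   frequencies and conditional mean read counts per gene — fills in the
   missing alleles and estimates their counts.

The package also quantifies which alleles drive an individual's placement
on the map (two per-feature relevance indices with Z-score selection),
embeds populations in a spectral space derived from a Jaccard similarity
graph (with Nyström out-of-sample projection for corrupted individuals),
and generates synthetic populations for validation and augmentation.

## The map

The SOM is a `rows x cols` hexagonal lattice of nodes, each carrying a
model vector in the input space. Neighbourhood relations use the *link
distance* — the hop count on the lattice adjacency graph, computed by
breadth-first search on the explicit graph rather than a coordinate
formula, which avoids offset-convention errors. Training is batch by
default: per epoch every profile is assigned to its best-matching unit
(BMU, minimal Euclidean distance, ties to the lowest node index), and each
node's vector is replaced by the mean of all profiles whose BMU lies
within the current integer neighbourhood radius of it; nodes receiving
nothing keep their vectors. Membership in the batch neighbourhood is a
binary step function of link distance. The default schedule runs 200
epochs in two phases: an ordering phase (first 100 epochs) at radius 1,
where each node cooperates with its six immediate hexagonal neighbours,
and a tuning phase (100 epochs) at radius 0, where the update is pure
competitive vector quantization — the k-means limit a SOM approaches as
its neighbourhood shrinks toward zero, which is also what makes the final
prototype configuration quantization-error-driven rather than
topology-driven. This choice is deliberate for ASE count profiles: the
input space consists of many roughly equidistant signature clusters, and
wide early neighbourhoods (the classical radius 3 → 1 decay, available as
`decaying_radius_schedule()`) blend neighbouring prototypes into dense
averages that both mix signatures within clusters and attract corrupted
profiles to the wrong nodes. Keeping cooperation local during ordering
and letting the radius reach zero in tuning reduces the allele
reconstruction error at high corruption from roughly a third to a tenth
in our validation runs. The schedule is fully configurable
(`radius_schedule`).

An online mode implements the classical per-sample rule
$w_i \leftarrow w_i + \alpha(t)\, h(i, i^*; t)\,(x - w_i)$ with a Gaussian
neighbourhood over lattice positions, $\alpha$ decaying linearly from 0.5
to 0.01 and $\sigma$ decaying exponentially from half the grid diameter to
0.5; these values are conventional choices, since batch mode is the
reference procedure. With the batch radius pinned at 0 the update
coincides exactly, epoch by epoch, with Lloyd's k-means on the node
vectors — the zero-neighbourhood limit that motivates the
`kmeans_baseline()` comparison backend (`stats::kmeans`, Lloyd algorithm).

Model initialization is *linear* by default: vectors are placed on a
regular lattice in the plane of the first two principal components through
the data mean. *Random* initialization (sampling data points) is
available; linear initialization converges faster and makes batch training
deterministic given the data.

## The completion rule

For cluster $i$ with subpopulation $P_i$ and a gene $g$ flagged as
corrupted, write $\bar r(\alpha\mid\beta)$ for the mean read count of
allele $\alpha$ among members of $P_i$ expressing the unordered pair
$(\alpha, \beta)$; homozygous members contribute the pair
$(\alpha, \alpha)$ with $\bar r(\alpha\mid\alpha)$ the mean of their
single entries. Three cases:

* **Both alleles unknown** — take the most frequent pair
  $(\alpha_1, \alpha_2)$ in $P_i$ and predict counts
  $(\lceil \bar r(\alpha_1\mid\alpha_2)\rceil,
    \lceil \bar r(\alpha_2\mid\alpha_1)\rceil)$.
* **One allele $\hat\alpha_1$ known and seen in $P_i$** — choose
  $\hat\alpha_2 = \arg\max_\alpha \pi(\hat\alpha_1, \alpha)$, the allele
  most often paired with it (empirical pair frequencies; unseen pairs have
  probability 0, no smoothing), and scale the known count:
  $\hat r_2 = \lceil \hat r_1\,
     \bar r(\hat\alpha_2\mid\hat\alpha_1)/
     \bar r(\hat\alpha_1\mid\hat\alpha_2)\rceil$.
* **One allele known but never seen in $P_i$** — choose the most frequent
  $g$-allele by occurrence (homozygous occurrences count twice) and scale
  by the mean of the conditional-mean ratios over the pairs that allele
  occurs in.

Ties are broken toward lexicographically smaller allele labels, making
reconstruction deterministic. Conditional means are restricted to the
selected pair (the literal reading of "count of $\alpha$ when paired with
$\beta$"). Predicted counts are integer ceilings with a floor of 1, so
completed entries are always positive integers. A gene the cluster never
expresses falls back to whole-population statistics; a gene expressed
nowhere in the training data raises a named error. When the known-allele
case predicts $\hat\alpha_2 = \hat\alpha_1$ the gene is predicted
homozygous and the column is left as is — there is no second row to fill.

Which genes to reconstruct is an *input* (the corruption mask): by
construction, a corrupted profile cannot reveal whether a single-entry
gene is error-free homozygous or heterozygous with one loss, so automatic
error detection is out of scope and the evaluation harness supplies the
mask.

## Evaluation indices

Clustering quality against a ground-truth labeling uses three indices in
$[0,1]$: SQI (product of the two averaged best-overlap fractions between
clusters and labels), the Fowlkes–Mallows index
$\sqrt{\mathrm{precision}\cdot\mathrm{recall}}$ over element pairs, and
normalized mutual information. NMI is normalized by
$\sqrt{H(G)\,H(C)}$ — the geometric-mean variant, which is the standard
form bounding the index by 1. Similarity between the clusterings of a
population and of its corrupted copy is the standard pairwise Rand index
over $\binom{m}{2}$ element pairs; the cruder per-individual agreement
(fraction assigned to the same node) is exposed separately as
`same_cluster_fraction()` because both readings are useful when comparing
corruption levels. Degenerate denominators (no co-clustered pair, zero
entropy) return 0 by convention.

Reconstruction is scored by *allele accuracy* (fraction of deleted
alleles whose identity is recovered, count-agnostic) and *read error*
(mean relative absolute count error over correctly guessed alleles; 1.2
means predictions average 2.2 times the truth). Individuals with nothing
deleted (or nothing guessed, for read error) are marked not applicable
and excluded from averages rather than zero-filled.

## Relevance indices

After training, each corrupted individual $\hat p$ yields two per-allele
vectors: the *local error contribution*
$R[k] = (\hat p[k] - \mathrm{BMU}[k])^2 / \sum_l (\hat p[l] -
\mathrm{BMU}[l])^2$, and the *discriminative index* $D[k] =
\delta[k] / \sum_l |\delta[l]|$ with
$\delta[k] = (\hat p[k] - \mathrm{sBMU}[k])^2 - (\hat p[k] -
\mathrm{BMU}[k])^2$. The denominator of $D$ sums absolute margins over all
features (the only reading that yields an informative index rather than a
constant-magnitude sign pattern). $R$ sums to 1; $\sum_k \delta[k] \ge 0$
because the BMU is at least as close as the runner-up. Degenerate inputs
(profile equal to the BMU vector, or all margins zero) return flagged
all-zero vectors.

Population analysis averages the vectors over each corrupted test
population, then across repeats at the same corruption level, and
standardizes each level's mean vector across alleles into Z-scores.
Alleles with $Z_R \ge 1.96$ (right tail only — alleles contributing
*more* error than average) at one or more corruption levels are
R-selected; alleles with $|Z_D| \ge 1.96$ are D-selected with the sign
recorded, since features undermining an assignment are as interesting as
those supporting it. Standardization is within a corruption level, not
across levels, so selection reflects each level's own distribution. Genes
are reported as the union of their selected alleles' genes; no per-gene
score is invented.

## Spectral embedding

As an alternative to training on raw high-dimensional sparse count
vectors, a population can be embedded via its signature similarity graph:
edge weights are multiset Jaccard similarities (shared allele
multiplicities over union multiplicities), the normalized symmetric
Laplacian $L = I - D^{-1/2} W D^{-1/2}$ is eigendecomposed, and each
individual is represented by the eigenvectors of the $K$ smallest
Laplacian eigenvalues (the standard spectral-clustering convention for
"top" eigenvectors), $K$ defaulting to the SOM node count. Eigenvector
signs are fixed deterministically and coordinate rows are normalized to
unit length by default (switchable, since either convention is defensible
and the choice only rescales distances). The decomposition is dense
(`eigen`), appropriate for populations up to a few thousand.

Corrupted individuals are projected by Nyström extension: their Jaccard
similarities to the training individuals are degree-normalized like the
training affinity and folded through the eigenvectors with a $1/\lambda_k$
scaling. With the self-similarity diagonal set to 1 (the default), a
training individual's own similarity row reproduces its in-sample
coordinates exactly. Two caveats are inherent to the method: coordinates
along near-null eigendirections ($|\lambda| \le 10^{-10}$) are zeroed, and
self-consistency only holds within the column space of the affinity
matrix — whose rank is bounded by the number of distinct signatures — so
the embedding dimension should not exceed the genoset diversity.
Individuals with no similarity to any training point are flagged and
mapped to the origin.

## Synthetic populations

The validation design mirrors a simulated RNA-seq experiment: 10 genes
with 10 observed alleles each, a genoset of 100 distinct signatures (2
distinct alleles per gene, 20 per signature), training populations of
5,000 individuals whose signatures are drawn uniformly from the genoset,
and independent uniform integer counts in $[1, 700]$ for expressed
alleles. The signature index is the ground-truth label. A 10×10 map gives
the SOM as many nodes as there are signatures. These defaults *are* the
study conditions; smaller configurations used in unit tests shrink genes,
alleles and population size but keep the same structure.

What this generator does — and does not — emulate: counts are independent
and uniform, so there is no expression covariance, no sequencing-depth
effect, no overdispersion, and every gene is expressed in every
individual. Passing recovery tests on these populations demonstrates that
the clustering-plus-completion machinery works when cluster structure is
driven by signatures; it does not bound performance on real ASE data,
where sparsity and shared alleles across signatures blur clusters. Read
error is not meaningful here at all, since counts are pure noise around
nothing — the tests accordingly assert allele identity recovery, not
count recovery.

Two augmentation generators create synthetic individuals from an existing
matrix. The *evolutionary* generator represents each parent as a paired
(allele-index, read-count) structure over all expression rows, selects two
random parents, computes the mating index
$I = 1 + \sigma^2_{father} - \sigma^2_{mother}$ (whose sign only decides
which parent the Bernoulli indicator refers to), builds a Hardy–Weinberg
offspring inheriting each locus from exactly one parent with probability
0.5, and generates several mutated candidates, keeping the one whose
count vector is closest to the population mean count vector (the
`fitness_ref = "median"` switch uses the median instead). Mutation
touches exactly $\lceil 0.03\,\hat a\rceil$ loci; `scramble` permutes the
selected loci's contents, `swap` cycles them, and `reset` redraws a
locus's state from a random reference individual at the same locus, so
states stay within each locus's observed support. Scramble and swap are
confined to gene blocks by default (`within_gene = TRUE`), which
preserves the per-gene expressed count; since locus-independent
inheritance can still overfill a gene block, a repair pass keeps the two
largest entries of any violating block before a matrix is emitted, so
every generator output satisfies the diploid constraint.

The *SMC* generator augments a random half of the population by 30% of
the subset size (both fractions configurable). Per feature, particles are
initialized by resampling the observed counts; each synthetic value is
drawn from the particle set, after which a quarter of the particles are
resampled with weights $\propto \exp(-|p - v|/\mathrm{MAD})$ and the rest
are rejuvenated from the empirical distribution. The rejuvenation step
matters: a pure resample-reweight chain progressively collapses the
particle support onto recent proposals, distorting the very distributions
the generator is meant to preserve, whereas with rejuvenation the
per-feature Kolmogorov–Smirnov distance to the source stays at the
plain-resampling noise floor. Synthetic values always lie in the observed
per-feature support; presence/absence follows by sign, with the same
diploid repair pass.

Both generators reproduce the described procedures, including their known
biases (a tendency toward "average" individuals); no attempt is made to
correct them.

## Numerical and design choices

* Counts are integers end to end; completion ceilings keep predictions
  integral and at least 1.
* Corruption deletes non-zero *matrix entries*: deleting the single entry
  of a homozygous gene removes both signature copies at once, because
  read counts live one per entry.
* BMU ties, argmax ties and pair orientation are all resolved
  deterministically (lowest node index; lexicographic labels; unordered
  pairs stored with sorted labels), so identical seeds give bit-identical
  outputs.
* Randomness follows the base-R convention: functions draw from the
  global RNG and reproducibility comes from `set.seed()`. The experiment
  driver derives a recorded sub-seed per network and per test population
  from the top-level seed, so any cell of a result table can be
  regenerated in isolation.
* The experiment driver averages per-individual metrics within a test
  population, then across test populations, then across networks, in that
  order.

## Problem sizes

The headline validation in `scripts/acceptance.R` and the acceptance test
uses the full design (training populations of 5,000; 10×10 map; 200
epochs) with 3 independently trained networks × 10 test populations of
500 individuals and deletion levels 0/2/4/6 — 6 deletions corrupt 30% of
a 20-allele signature. Unit and property tests use reduced configurations
(hundreds of individuals, 3×3 or 4×4 grids, 15–40 epochs) chosen to
exercise the same code paths at interactive speeds.

## Known limitations

* The completion rule returns a single best completion; it does not rank
  alternatives or model count dispersion.
* Error detection is out of scope: the corruption mask must be supplied.
* SQI and FMI are sensitive to class imbalance and can reward cluster
  fusion; NMI is the more reliable quality index when one cluster
  dominates.
* The spectral basis must be recomputed if the training population
  changes; only out-of-sample *projection* is cheap.

## A worked example

```{r example, eval = FALSE}
library(somase)
set.seed(1)

cfg <- artificial_config(n_genes = 6, alleles_per_gene = 6,
                         genoset_size = 20)
pop <- generate_artificial_population(cfg, 800)

X <- t(pop$matrix$counts)
model <- som_train(init_models(som_grid(5, 4), X), X, epochs = 100)
rules <- build_completion_rules(pop$matrix, som_assign(model, X)$bmu)

victim <- corrupt(pop$matrix, "ind17", num_del = 4)
cluster <- som_assign(model, victim$column)$bmu
fixed <- reconstruct_individual(
  rules, cluster, victim$column,
  unique(pop$matrix$family$row_gene[victim$record$rows]))
fixed$report
mean(fixed$column[victim$record$rows] > 0)  # recovered alleles
```
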