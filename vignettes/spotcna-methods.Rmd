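---
title: "Methods: spot-level CNA inference from spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot-level CNA inference from spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`spotcna` infers per-spot copy-number-alteration (CNA) profiles from a
spatial transcriptomics experiment in two stages. The first stage groups
spots into transcriptionally and spatially coherent clusters: a fused
spot graph combines expression similarity with physical adjacency, a
multi-task variational graph autoencoder (VGAE) embeds every spot into a
low-dimensional latent space, and Louvain community detection partitions
the embedding. The second stage calls CNAs: genes are ordered along
chromosome arms, each spot's arm sequence is smoothed with multi-level
median filters, and a three-state Gaussian-emission hidden Markov model
(HMM), fitted per cluster by Baum–Welch and decoded per spot by Viterbi,
labels every gene deletion (copy number 0–1), neutral (2), or
amplification (>2). Downstream utilities classify the spatial pattern of
an event with Ripley's K-function against a resampling null, and test
event pairs for co-occurrence or mutual exclusion within clusters.

The premise throughout is the established positive correlation between
gene dosage and expression: an amplified arm shifts the (normalized,
baseline-centred) expression of its genes upward coherently along the
genome, a deleted arm downward, and smoothing plus a sticky Markov prior
turn these coherent shifts into contiguous state calls while single-gene
fluctuations are suppressed.

# Preprocessing

`normalize_expression()` applies, in order: spot filtering (at least
`min_genes_per_spot = 200` detected genes), gene detection filtering
(detected in at least `min_spots_per_gene = 3` retained spots),
library-size scaling of every spot to the median library size, an
expression cutoff, `log1p`, and per-gene centring by the median over the
reference spots (all spots when no reference is designated). After
centring, a copy-neutral gene fluctuates around zero, which is the
baseline the HMM's neutral state assumes.

The expression cutoff (`min_mean_expression = 1`, in library-scaled
counts) deserves explanation because it is load-bearing. Genes whose
median count is zero are centred against a zero median, so every
non-detected measurement maps to exactly 0 in the centred matrix. A
median filter returns order statistics — actual data values — so this
atom of identical values survives and *grows* under smoothing, and the
HMM's maximum-likelihood fit then collapses its neutral state onto the
atom with vanishing variance, destroying specificity: everything not
exactly zero is called a CNA. Excluding weakly expressed genes is the
same cutoff every expression-based CNA caller applies, and it removes
the atom at its source. For sparser platforms the cutoff can be lowered;
with UMI data at very low coverage a value around 0.1 with a
correspondingly larger `min_spots_per_gene` is a reasonable starting
point.

Gene positions come from a GTF/BED annotation plus a UCSC-style cytoband
table. A gene belongs to the p arm iff its start lies strictly before
the chromosome's centromere start (the smallest q-band start); the
half-open convention makes the boundary deterministic and
strand-independent. Within an arm genes are ranked by start position,
ties broken lexicographically by gene id. Genes on contigs absent from
the cytoband table are dropped and counted.

# The fused spot graph

`build_spot_graph()` joins spots i and j when either is among the
other's `k = 15` nearest neighbours in Euclidean distance over the
normalized matrix (union symmetrisation), with weight `W1 = 1`. When the
two endpoints of an existing edge are also physically adjacent —
Euclidean distance between array coordinates at most `radius`, which
defaults to 1.5 times the minimum spot spacing so that square-grid
4-neighbourhoods and hexagonal Visium packing both qualify — the edge
weight is increased by `W2 = 1`. Equal default weights reflect no prior
preference between similarity and adjacency; both are exposed. By
default physical adjacency only reinforces expression edges; the
`create_edges` flag also admits pure-spatial edges for tissues where
expression noise overwhelms the KNN structure. Unit self loops are added
before the symmetric normalization `D^{-1/2}(A + I)D^{-1/2}`, standard
graph-convolution practice that keeps every row stochastic-scaled and
bounds the spectrum in [-1, 1].

KNN distances are computed on the normalized matrix directly. A PCA
pre-step would be cheaper for very wide matrices but introduces a second
dimensionality choice; at the package's target sizes (up to a few
thousand spots) the exact computation is affordable.

# The multi-task VGAE

The encoder applies two graph-convolution propagation steps,

$$\mu = \tilde A\,\mathrm{ReLU}(\tilde A X W_0)\,W_\mu,\qquad
\log\sigma^2 = \tilde A\,\mathrm{ReLU}(\tilde A X W_0)\,W_\sigma,$$

with the first-layer weights shared between the two heads (stored once,
so the sharing is structural, not an initialization accident). The
latent sample is `Z = mu + exp(log_var/2) * eps` with fresh standard
normal noise each epoch — the reparameterization trick. The
log-variance parameterization keeps the variance positive without
constraints and is the numerically stable convention.

Two independent 2-layer ReLU MLP decoders reconstruct the two views of
the data: the expression head maps Z back to the gene space, and the
adjacency head maps Z to an embedding F whose inner products give edge
logits, `A_gen = sigmoid(F F')` — symmetric by construction. An inner
product is the standard way to turn per-node decoder output into a
node-pair matrix; the decoder hidden width (128) and embedding width
(32) are exposed.

The loss is

$$L = \lambda_1\,\mathrm{KL}\!\left(q(Z\mid X, A)\,\|\,N(0, I)\right)
 + \lambda_2\,\mathrm{BCE}(A^{01}, A^{G})
 + \lambda_3\,\mathrm{MSE}(X, X^{G}),$$

with the KL term in closed form, the BCE summed over all spot pairs and
divided by the number of spots, and the MSE averaged over all entries.
The BCE target is the *binarized* adjacency (edge present = 1,
including the self loops): a cross-entropy target must live in [0, 1],
and the weighted adjacency does not. The literal alternative — using
the real-valued normalized adjacency as the positive-class coefficient
and no negative-class term — is implemented behind
`bce_target = "normalized"` for completeness. Sparse graphs make the
positive class rare, so the positive term is reweighted by
`(n^2 - |E|)/|E|`. The default `lambda1 = 1/(n d)` scales the KL term
(a sum over n×d latent dimensions) to the same order as the two
averaged reconstruction terms; `lambda2 = lambda3 = 1`.

Training is full batch — the target sizes fit comfortably in memory —
with Adam at learning rate 1e-3 for 400 epochs, gradients derived
analytically (they are verified against finite differences in the test
suite). Everything is deterministic given the seed. Downstream
clustering consumes the posterior mean `mu`, never a stochastic `Z`
sample, so the pipeline's output does not depend on the last noise draw.

# Clustering

`louvain_cluster()` builds a union-symmetrized KNN graph with unit
weights over the latent means and maximises modularity with Louvain.
The function defaults (`k_latent = 15`, `resolution = 1`) are the
common generic settings for expression clustering. The *pipeline*
defaults differ deliberately: `k_latent = 50`, `resolution = 0.2`.
Clone structure is coarse — a tumour section carries a handful of
clones, each spanning hundreds of spots — and modularity optimisation
at resolution 1 on a sparse KNN graph reliably fragments communities of
that size into pure sub-communities (the resolution limit works in the
wrong direction for large communities). A denser latent graph and a
sub-unit resolution recover clone-scale partitions; on the package's
reference simulation the latent space separates clones essentially
perfectly and the fragmented partition is a strict refinement of the
true one, so the coarse setting loses nothing. Users clustering for
finer cell-type structure should move the resolution back up.

ARI, NMI and AMI are provided for evaluation against reference labels.
All three are computed from the shared contingency table; NMI and AMI
normalize by the arithmetic mean of the label entropies, and AMI
subtracts the expected mutual information under the permutation model.
A single-cluster labeling has zero entropy and returns 0 by convention.

# CNA calling

Each (spot, chromosome arm) expression vector, ordered by genomic
start, is smoothed by a cascade of median filters with windows
(11, 31, 51) followed by one final window-5 pass. Multi-level filtering
reduces the sensitivity of the result to any single window choice;
windows are clipped per arm to the largest odd number not exceeding the
arm length so short arms remain well-defined, and edge windows shrink
rather than pad, so no boundary values are invented. The alternative
combination — filtering the original sequence once per window and
taking the per-position median across scales — is available as
`combine = "across_scale"`; the cascade is the default reading of
"filters applied in order, then one more median filter". Median
filtering (robust to single-gene outliers such as dropout) rather than
mean smoothing is a deliberate property of the method.

One HMM is fitted per cluster by Baum–Welch on the pooled smoothed arm
sequences of the cluster's spots, then every spot's every arm is decoded
individually by Viterbi — pooling stabilises the parameter estimates
while preserving spot-level output; `fit_level = "global"` switches to
one shared fit. Arms are independent sequences: no transition crosses
an arm boundary. Clusters contributing fewer than `min_obs = 500`
observations fall back to the global fit rather than estimating 12
parameters from a handful of values. Designated reference clusters can
be forced all-neutral.

Numerical choices: the forward–backward recursion is scaled per
position with per-position renormalisation of the emission densities,
so extreme outliers cannot underflow it; emission standard deviations
are floored at 1e-3 (clamps are reported); EM stops when the relative
log-likelihood change falls below 1e-8 or after 100 iterations, and the
per-iteration log-likelihood is non-decreasing (asserted in tests).
Initialisation is deterministic and scale-adaptive: emission means at
the 10th/50th/90th percentiles of the pooled values, a common pooled
standard deviation, 0.9 self-transitions, uniform start. After
convergence states are sorted by emission mean, with the consistent
permutation applied to the transition matrix and initial distribution,
fixing the deletion ≤ neutral ≤ amplification order. Viterbi runs in
log space and breaks exact ties toward the lower state index.

A three-state model is *forced* onto every cluster, including CNA-free
ones, where maximum likelihood will happily split noise into three
states separated by a fraction of the noise scale. The guard is
`min_delta = 0.2`: a deletion or amplification state whose fitted mean
sits within 0.2 centred-log-expression units of the neutral mean is not
biologically interpretable as a copy-number change — a single-copy
change at moderate expression shifts the centred value by roughly 0.35
(gain) to 0.5 (loss), so 0.2 is about half the smallest real effect —
and decoded positions of such a state are relabelled neutral. On
CNA-free simulations this sends >99% of calls to neutral while leaving
genuine fold-0.5/1.5 segments callable.

# Spatial statistics

For a gene's event spots, `ripley_k()` computes
$K(d) = \lambda^{-1} N^{-1}\sum_i \sum_{j\ne i} 1[d_{ij} \le d]$ with
no edge correction, and density λ = N divided by the number of spots in
the tissue (unit cell area): the spot lattice itself is the sampled
domain. `csr_envelope()` draws `R = 999` resamples of N spots uniformly
without replacement from the same lattice; because the null is computed
on the identical domain, boundary effects cancel by construction, which
is why no analytic edge correction is applied. Per distance, the
Monte-Carlo p-value `(1 + #{K_sim >= K_obs})/(R + 1)` tests the
hypothesis K_obs ≤ K_exp and its rejection labels the pattern
*aggregation*; the mirrored p-value labels *dispersed*; otherwise
*CSR*. (Stated as a pair of one-sided null hypotheses: rejecting
"observed ≥ expected" yields the dispersed label and rejecting
"observed ≤ expected" the aggregation label — the standard
interpretation of a high K as clustering.) Labels are per distance and
deliberately not corrected
across distances — the distance profile is the object of interest.

Event tables binarize the profile per cluster, keeping (gene, state)
events reaching `ceiling(0.05 × cluster size)` spots. Co-occurrence and
mutual exclusion between two events are the two one-sided Fisher's
exact tests on their 2×2 table, with Benjamini–Hochberg correction
across all testable pairs within a cluster; Fisher's exact test is the
convention of the mutation co-occurrence literature. Differential CNA
contrasts each cluster against a designated normal cluster per gene and
event type with the one-sided (enrichment) Fisher test, BH-corrected
across genes, reported as −log10(q) signed positive for amplification
and negative for deletion.

# The synthetic data generator

`simulate_spatial_cna()` generates the study condition the package is
validated on: a 40×40 unit lattice partitioned by Voronoi regions
around fixed, well-spread seeds into one normal region and three
tumour clones (spatial contiguity of clones is the method's premise);
2,000 genes on ten synthetic arms (5 chromosomes × p/q, 200 genes
each); arm-level segments with deletion fold 0.5 and amplification fold
1.5 — the expression consequence of losing or gaining one of two
copies; per-gene log-normal baselines (meanlog 1, sdlog 1, i.e. a
median count of ~2.7 and a long right tail, resembling moderately deep
data); per-spot log-normal library factors (sdlog 0.15);
negative-binomial counts with dispersion 0.3 (spot-level counts are
overdispersed; Poisson available behind a flag); and 5% binomial
dropout. Region seeds are fixed rather than random so that the clone
geometry is balanced for every simulation seed; the seed governs all
stochastic draws.

What the generator deliberately does not emulate: cell-type mixture
within spots, spatial expression gradients unrelated to copy number,
batch/section effects, allele-specific signal, and sub-arm breakpoint
structure (segments are gene-rank intervals). Passing the end-to-end
checks therefore demonstrates that the machinery recovers multiplicative
arm-scale dosage signal under realistic count noise — not that real
tumour sections, with their confounded biology, will yield the same
accuracy.

`simulate_hmm_sequences()` and `simulate_point_patterns()` provide the
independent generating processes used to validate the HMM estimator and
the K-function calibration (CSR, Matérn-style clustered, and
minimum-distance inhibited patterns).

# Problem sizes and runtime

The reference configuration (1,600 spots × 2,000 genes, 400 VGAE
epochs) runs the full pipeline in a few minutes on one CPU core; the
test suite uses that size for the end-to-end recovery check and smaller
grids (e.g. 14×14 or 16×16 with 4 synthetic chromosomes) for
integration and determinism checks, sizes chosen to exercise every code
path at interactive turnaround. Monte-Carlo calibration checks use 100
CSR simulations at R = 999 resamples.

# Known limitations

- Calls are gene-level and three-state; integer copy numbers, sub-gene
  breakpoints and allele-specific states are out of scope.
- The HMM treats smoothed values as independent Gaussian emissions;
  median filtering induces autocorrelation on the window scale, so
  persistent noise excursions can still produce false segmental calls
  in high-noise data — the specificity margin comes from `min_delta`
  and the expression cutoff, both of which trade sensitivity for it.
- Clustering quality gates CNA quality: a cluster mixing clones fits a
  compromise HMM. The reference/normal designation, when available,
  should be used.
- Centring against the all-spot median assumes every gene is
  copy-neutral in the majority of spots. When a single clone carrying
  an event covers close to half the tissue, the median lands between
  the neutral and altered modes, the apparent shift halves, and the
  event can fall under the `min_delta` callability guard. Designating
  `reference_spots` (any confidently normal region) removes this
  failure mode and should be routine when a normal region is known.
- The VGAE is full batch; far beyond ~10^4 spots, memory for the dense
  n×n reconstruction becomes the binding constraint.
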