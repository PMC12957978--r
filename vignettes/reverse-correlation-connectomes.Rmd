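---
title: "Locating group-discriminative connections in weighted connectomes by reverse correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating group-discriminative connections in weighted connectomes by reverse correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Whole-brain structural networks built from diffusion tractography assign a
nonnegative connection probability to every pair of anatomical regions.
Global graph properties of such networks (efficiency, clustering,
modularity, rich-club organisation) often fail to separate clinical groups
at the whole-network level even when a classifier trained on those same
properties can discriminate the groups. `revcorrnet` implements a
reverse-correlation strategy for turning such a classifier back into an
*edge-level* localisation: perturb a healthy reference network with random
subsets of the patient-minus-reference difference matrix, keep the
perturbed networks that organise like patient networks, classify each one,
and ask which difference edges occur disproportionately often among the
perturbations assigned to each class. The aggregated inclusion
frequencies point at candidate connections underlying the classifier's
decision — without any per-edge statistical test, which is also the
method's principal limitation (it yields a ranking, not p-values).

## The data model

A `connectivity_matrix` is a square, symmetric, nonnegative weighted
adjacency matrix with a zero diagonal and labelled nodes (82 regions of
the Desikan–Killiany parcellation in the motivating setting; the package
treats labels as opaque strings). Directed tract-probability pairs are
collapsed to undirected weights by their arithmetic mean
(`symmetrise_connectivity()`); the mean is a convention, chosen because
probabilistic tracking yields two estimates of the same underlying
connection.

Network properties are computed across a grid of connection densities:
at density $d$ the $\lceil d\,n(n-1)/2 \rceil$ strongest edges are
retained (`threshold_by_density()`; ties at the cutoff weight are broken
by ascending lexicographic edge index so results are reproducible). Each
property is then summarised as its trapezoidal area under the curve (AUC)
across the grid, giving a threshold-free summary. The default grid is
0.05–0.40 in steps of 0.01, a common operating range for probabilistic
connectomes: below ~0.05 the graphs fragment, above ~0.40 weak
probabilistic edges dominate.

## The eight network properties

For a thresholded weighted network the package computes
(`network_feature_vector()`):

* **aCp** — mean weighted clustering coefficient, Onnela form:
  $C_i = \frac{1}{k_i(k_i-1)}\sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$
  with $\hat w = w/\max(w)$ and $k_i$ the binary degree. The max
  normalisation makes $C$ invariant to uniform weight rescaling.
* **aEg, aLp** — global efficiency and characteristic path length over
  shortest paths with edge length $1/w$ (the standard transform for
  probability weights): $E_g$ is the mean inverse shortest distance over
  node pairs (disconnected pairs contribute 0), $L_p$ the mean shortest
  distance over connected pairs only, with a disconnection flag.
* **aEloc** — local efficiency: mean over nodes of the global efficiency
  of each node's neighbour-induced subgraph; nodes with fewer than two
  neighbours contribute 0.
* **aQ** — Newman modularity maximised by Louvain with 20 seeded restarts
  (best of the restarts is kept; a single community, $Q = 0$, is the floor,
  so $Q$ is never negative). Resolution is fixed at 1.
* **Rich_s, Feeder_s, Local_s** — rich-club, feeder and local connection
  strengths. Rich-club nodes are the top $\lceil 0.15\,n\rceil$ nodes by
  nodal strength (the fraction is configurable; 0.15 puts ~12 of 82 nodes
  in the club, a typical hub-set size). An edge is *rich* if both
  endpoints are in the club, *feeder* if exactly one is, *local* if
  neither; each class strength is the mean weight of the existing edges
  in that class (0 for an empty class). The mean-edge-weight definition
  is this package's documented convention for these strengths.

Shortest paths run through a vectorised Floyd–Warshall kept in base R:
the pipeline evaluates distances on thousands of small neighbourhood
subgraphs per run, where per-call graph-construction overhead in a graph
library would dominate the arithmetic. Louvain itself is delegated to
igraph.

## Partition similarity: the NMI

Two partitions of the same $N$ nodes are compared with the normalised
mutual information computed from the contingency counts $N_{ij}$ and the
marginals $N_i, N_j$:

$$\mathrm{NMI}(A_1,A_2) =
\frac{-2\sum_{i}\sum_{j} N_{ij}\,\log\!\left(\frac{N_{ij}\,N}{N_i N_j}\right)}
{\sum_i N_i \log\frac{N_i}{N} + \sum_j N_j \log\frac{N_j}{N}}$$

with $0\log 0 := 0$. Natural logarithms are used; the ratio is invariant
to the base. The degenerate case of two identical single-community
partitions (a 0/0 ratio) is defined as 1. This ratio form is
algebraically the familiar information-theoretic NMI with arithmetic-mean
normalisation, and the test suite checks both the equivalence and the
symmetry/relabelling invariances on random partition pairs.

A network's *partition profile* (`partition_profile()`) is the pair
(Louvain modular partition, rich-club two-community partition), computed
at a reference density (the median of the analysis grid by default).
Candidate networks are scored against patient and control profiles by the
mean of the modular and rich-club NMI. The mean is this package's choice;
either single score can be selected instead, because nothing in the
method fixes how the two partition types enter the criterion.

## The reverse-correlation engine

Given control matrices and a patient group:

1. **Reference matrix** (`build_reference_matrix()`): per-edge trimmed
   mean across control subjects, dropping the top and bottom 2.5% of
   subject values at each edge (with $S$ subjects, $\lfloor 0.025\,S\rfloor$
   from each tail — zero for $S < 40$, where the trimmed mean degrades
   gracefully to the plain mean).
2. **Difference matrix** (`build_difference_matrix()`): element-wise
   patient-group mean minus the reference; entries may be negative.
3. **Randomised networks** (`sample_randomised_network()`): each
   upper-triangle edge of the difference matrix is independently included
   with probability 0.5, and the masked differences are added to the
   reference, clipping at zero (probabilities cannot be negative). The
   Bernoulli edge mask mirrors classic reverse-correlation noise masks
   and is what makes frequency aggregation informative; an alternative
   mode that additionally permutes the included values among included
   positions is available behind a flag. The flowchart-only description
   of the original procedure admits several readings; the mask is this
   package's definition, stated prominently because the interpretation of
   "occurrence" below depends on it.
4. **NMI selection** (`nmi_select()`): each candidate's profile is scored
   against the patient (LOD) and control (HC) profiles. Two directions
   are implemented because the source material states both: `"printed"`
   retains candidates with $\mathrm{NMI}_{LOD} < \mathrm{NMI}_{HC}$,
   `"resemble_lod"` retains $\mathrm{NMI}_{LOD} > \mathrm{NMI}_{HC}$
   (candidates organising like patient networks). Ties fail in both
   modes. The package default is `"printed"`; the synthetic recovery
   experiment uses `"resemble_lod"`, since recovering patient-associated
   edges requires retaining the patient-resembling perturbations.
5. **Classification and aggregation**: retained candidates are summarised
   by their six-feature vector, classified by the trained MLP, and the
   inclusion masks are aggregated per predicted class
   (`aggregate_edge_frequencies()`). *Occurrence* of an edge means
   inclusion in the mask. The top 5% most frequent edges of the
   nonzero-count edges are selected per class (`select_top_edges()`),
   with all edges tied at the cutoff count included and flagged.

One master seed fixes every draw: cycle seeds are derived from it, and
the Louvain restarts inside candidate profiling and feature extraction
use a single fixed metric seed so that candidate features are a
deterministic function of the candidate matrix, computed exactly as the
training features were. Two runs with the same configuration produce
byte-identical outputs.

## The classifier

The cognitive-status model is a feed-forward network with three hidden
layers of six tanh units and a two-unit softmax output, trained
full-batch by scaled conjugate gradients (Møller's algorithm with
$\sigma = 10^{-4}$ and initial $\lambda = 10^{-6}$) on the softmax
cross-entropy, with no regularisation. Records are split 8:1:1 into
train/test/validation with class stratification; training stops at 1000
iterations or after 6 consecutive validation cross-entropy increases,
returning the best-validation weights. These constants — tanh, softmax,
the SCG parameters, the validation-failure count — follow the default
behaviour of the numerical environment in which such models are
conventionally trained; all are configurable. Features are standardised
with training-set statistics only, to avoid leakage. The default feature
set is the six properties (aQ, Local_s, Rich_s, aEg, aEloc, aLp); the
clustering coefficient and feeder strength are computed but excluded by
default, with `all_features()` available to include them.

## The synthetic cohort generator

`generate_cohort()` produces the cohorts every stage is validated on:

* a seeded **template** connectome — edges present with probability
  `base_density` (default 0.3, a realistic probabilistic-connectome
  density), weights drawn from Beta(2, 5), matching the right-skewed,
  bounded distribution of tract probabilities;
* **control subjects** — the template times independent per-edge
  lognormal noise with mean 1 and CV `noise_cv` (default 0.2);
  multiplicative lognormal noise keeps weights nonnegative and
  right-skewed and leaves the group mean unbiased;
* **patient subjects** — additionally multiply the planted-cluster edges
  by `planted_effect` (default 0.6, a 40% weakening, emulating a regional
  temporal-pole alteration).

The planted cluster is defined on nodes: all edges inside
`planted_nodes` are affected, and those edges are guaranteed present in
the template (an effect can only be planted on existing connections).
Because no node-set size yields exactly twelve within-edges
($\binom{k}{2} \ne 12$), an explicit `planted_edges` subset is accepted;
the package's recovery experiment plants the first twelve of the fifteen
within-edges of a six-node cluster, in lexicographic order.

What the generator does **not** emulate: spatial embedding and
distance-dependent connection probability, hub-concentrated degree
distributions, subject-level global scaling differences, and
registration/tracking artefacts. Passing the recovery experiment
therefore shows the pipeline recovers a planted multiplicative cluster
effect under i.i.d. multiplicative noise — not that it would localise
alterations in real tractography cohorts with their far richer structure.

## The recovery experiment and its operating characteristics

`run_recovery_experiment()` chains the full pipeline on one generated
cohort: features for all subjects, stratified 8:1:1 split, SCG training
(patients labelled `impaired`), trimmed-mean reference from controls,
difference matrix, 2000 randomisation cycles, and precision/recall of the
impaired-class top-5% edge set against the planted edges. The validation
configuration uses 40-node networks, 30 subjects per group, a coarse
density grid $\{0.10, 0.20, 0.30, 0.40\}$ and 3 Louvain restarts inside
the engine's inner loop — sizes chosen so a full five-cohort replication
runs on a single CPU in minutes; the package defaults (82 nodes, 36-point
grid, 20 restarts) remain those of the motivating setting.

A structural property of this design worth understanding before reading
recovery numbers: the detectability of a planted edge is proportional to
its template weight, because a multiplicative effect on weight $w$
contributes $|\Delta| = 0.4\,w$ to the difference matrix. Planted edges
that happen to draw near-zero Beta(2, 5) weights contribute differences
indistinguishable from the Bernoulli coin-flip background of the
~780-edge mask, so their inclusion frequency among impaired-classified
masks stays near 0.5 regardless of cycle count. Recall of the planted
set is therefore bounded by the fraction of planted edges with
non-trivial weight, and the top-5% selection (39 of ~780 nonzero-count
edges) bounds precision near $12/39 \approx 0.31$ from above. The
acceptance script reports the measured medians; the mechanism above is
what to check first when they fall short of their targets.

## Numerical choices and degenerate inputs

* Symmetry tolerance on file read: $10^{-9}$ absolute; sub-tolerance
  asymmetry is averaged away, anything larger is a parse error naming the
  offending entry.
* Zero-variance features abort training with the feature named; an
  edgeless graph yields 0 for all properties at that density with a
  warning for the undefined modularity; an all-zero frequency map is an
  error for top-edge selection, and all-equal counts return every edge
  with a warning.
* Rich-club ties in nodal strength are broken by ascending node index;
  threshold ties by lexicographic edge index; NMI selection ties fail.
* Matrix files round-trip at 15 significant digits.

## Known limitations

* Selected edges come with frequencies, not statistical significance.
* The rich/feeder/local strengths use the mean-existing-edge-weight
  convention; other conventions (sums, normalised strengths) would shift
  the feature scales, though not the classifier, which standardises.
* The engine's cost is dominated by per-candidate graph metrics; at the
  82-node default with the full grid, a 10,000-cycle run is an
  hours-scale computation on one core.
* Multiplicative planted effects on weak edges are undetectable in
  principle (above); simulation studies wanting full recall should plant
  effects on edges with substantial weight.
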