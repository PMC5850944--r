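---
title: "Stratifying treatment response with Boolean network families: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying treatment response with Boolean network families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnstrat)
```

`bnstrat` discriminates two treatment-response classes of patients (complete
remission, CR, versus primary resistance, PR) from a single continuous
proteomics profile per patient plus a signed prior knowledge network (PKN).
This vignette explains the model underneath each stage, the parameters that
matter, what the synthetic generator does and does not emulate, and the
design decisions taken where the problem left genuine freedom.

## The model space: a clause hypergraph

The PKN is a signed digraph over proteins. Topology fixes the roles:
in-degree-0 nodes are **stimuli** (clampable entry layer), out-degree-0 nodes
are **readouts** (the predicted outputs), the rest are **inhibitors**
(intermediates, also clampable when measured). Candidate regulatory logic is
the hypergraph of AND clauses: for each regulated node, one clause per
incoming signed edge and one 2-literal AND per unordered pair of distinct
incoming edges. Gates wider than 2 inputs are excluded — they would explode
the search space without adding much expressive power at typical in-degrees,
and 2-input gates already capture the classic coherent/incoherent motifs. A
Boolean network is a clause subset; several clauses on one target are OR-ed,
giving an OR-of-ANDs update rule per node, and a hypergraph with $N$
candidate clauses spans exactly $2^N$ networks (reported exactly by
`search_space_size()`, since $N$ in the hundreds is routine for real PKNs).

Self-loops are parsed but excluded from the hypergraph: a node serving as
its own regulator degenerates under fixed-point semantics. Proteins measured
but absent from the PKN are dropped with a warning; PKN nodes without
measurements are kept as latent intermediates through which signal can
propagate.

## Semantics: synchronous logical steady state

Update semantics for logic models trained on steady-state data are not
canonical, so this package fixes the simplest reproducible contract:
clamped inputs are held at their binarized values, every other node starts
at 0, and all nodes update synchronously by the OR of their selected AND
clauses until a fixed point, with an iteration cap of $|nodes| + 1$. A run
that has not stabilized at the cap is declared oscillatory and its unclamped
nodes (hence readouts) report 0, with a warning. On acyclic PKNs —
the layered networks the generator emits, and the dominant structure of
curated signaling maps — the cap is never binding, because a signal front
crosses each node at most once. The cap only bites on feedback cycles, where
a genuinely different semantic choice (trap spaces, asynchronous attractors)
would be defensible; that is the largest semantic gap of the package and it
is deliberately confined to a warning rather than silently resolved.
Conformance with an independently written step-by-step simulator is enforced
in the test suite for networks up to 10 nodes.

## Preprocessing

**Binarization (inputs).** All stimulus/inhibitor measurements are pooled
(default `scope = "global"`; `"per-protein"` is available when protein
scales differ) and split into two clusters by 2-means. One-dimensional
2-means is solved *exactly*: the optimal 2-partition of sorted values is
contiguous, so scanning the $n-1$ split points finds the global
within-cluster sum-of-squares minimum with no random initialization — the
result is deterministic by construction and the `seed` argument exists only
so call sites can thread one seed through the pipeline. Each measurement
inherits its cluster center; centers are rescaled onto $[0,1]$ by the pooled
min–max range, and the bit is 1 iff $1 - c \le 0.5$. Applying the threshold
to the rescaled *center* (rather than the raw value) is what makes
"clusters centered at 0 and 1" meaningful for arbitrary raw scales; it also
makes the map monotone in the raw value. A constant value set binarizes to
all zeros with a warning; missing values are rejected at load.

**Normalization (readouts).** $r = (r' - \min)/(\max - \min)$ with one
global (min, max) over every readout of every patient (the literal reading
of "all the readouts"); `"per-protein"` is available. The map is invariant
under affine rescaling of the raw data, so the RPPA scale itself carries no
information downstream. A degenerate range ($\max = \min$) is an error.

## Selection: couples as pseudo-perturbations

Learning logic models needs multiple perturbation conditions, which
patient data cannot provide. The selection stage manufactures them: for a
subset $K$ of $k$ input proteins, a CR patient $j$ and a PR patient $j'$
have *affinity* 1 when their binarized profiles agree on every protein of
$K$. Such a pair is one pseudo-experiment — identical inputs, two
class-specific readout vectors. Couples must not reuse patients
("non-redundant"), and *maximum number of non-redundant couples* is
formalized as the maximum-cardinality matching of the bipartite affinity
graph — the unique formalization under which that phrase is well defined.
The matching is delegated to `igraph`; correctness at small sizes is checked
against a brute-force matching enumeration in the tests.

The search scans all $\binom{|S|+|I|}{k}$ subsets exhaustively (skipping
subsets whose affinity-pair count already cannot beat the incumbent
matching). When several subsets or several maximum matchings are co-optimal,
a second objective ranks them: the total readout divergence
$\sum_{(j,j')} \sum_{i \in R} |r^{CR}_{ij} - r^{PR}_{ij'}|$, maximized via a
weighted matching in which a large constant keeps cardinality primary. The
two objectives are applied lexicographically, the secondary one only when
ties exist; remaining ties resolve by sorted protein names, for determinism.
Both the affinity-pair count and the couple count are reported, since either
can be read as "the" objective. `sweep_k()` tabulates couples and redundant
pairs across $k$ — the standard instrument for choosing $k$ as a compromise
between experiment count and input coverage (see the README example: more
proteins means fewer couples but far more specific models).

## Learning: exhaustive co-optimal families

Per class, every clause subset is scored by the mean squared error between
its steady-state readout predictions and the observed normalized readouts,
over all (experiment, readout) cells. The objective is lexicographic:
minimal MSE first, minimal size (number of selected clauses — a 2-literal
gate counts once) second. `learn_networks()` returns *every* co-optimal
subset — the family — rather than a single witness: co-optimal models are
genuinely distinct mechanistic hypotheses, and their spread is the result.
Optimality tolerances (`fit_tolerance`, `size_tolerance`) default to 0
(strict co-optima) and can be relaxed.

Two implementation choices matter. First, clauses whose target is clamped in
every experiment are removed before enumeration: a clamp overrides the
update rule, so such clauses cannot influence any prediction and would only
pad families with irrelevant variants. Second, the enumeration is a chunked,
fully vectorized scan — all (subset × experiment) pairs of a chunk are
stacked as rows of one state matrix and iterated together — rather than a
branch-and-bound; at the in-scope catalogue sizes (a cap of $2^{20}$
subsets, refused with an explicit error beyond it) the vectorized scan
outperforms per-node bounding in R and is trivially exhaustive-correct. The
family is then partitioned into **input–output behaviors**: two networks are
equivalent when their readout steady states coincide on all $2^n$ clampings
of the $n$ inputs (refused above 20 inputs). Unmeasured intermediates
default to 0 at the fixed point, as everywhere else in the semantics.
`clause_frequencies()` and `union_network()` summarize a family as the
per-clause membership fraction and the annotated clause union (the analog
of thick-edge family diagrams); the union is a reporting device with no
optimality claim.

## Classification

For a new patient, both families predict the readouts under the patient's
binarized inputs (family prediction = mean of member steady states, or mean
over one representative per behavior with `aggregate = "behaviors"`); the
label is the class with the lower MSE, and
$\text{confidence} = \frac{mse_{PR}}{mse_{CR} + mse_{PR}} \in [0,1]$ is
oriented so 1 means confident remission. The formula is a package decision —
the requirement is only a $[0,1]$ score with that orientation; this ratio is
symmetric (swapping the families maps $c \mapsto 1-c$, a tested invariant)
and parameter-free. Exact ties (including $0/0$, scored 0.5) fall back to CR
under Method 1 — the majority class in the motivating cohort — with a tie
flag, and to `unknown` under Method 2. Method 2 additionally classifies only
patients whose readouts carry significant signal, i.e. values below `low`
(default 0.25) or above `high` (default 0.6); the quantifier is ambiguous in
prose, so both are exposed with `mode = "all"` (every readout significant,
the strict reading) as default. Excluded patients leave the accuracy
denominators, which is why per-class counts shrink under Method 2. Balanced
accuracy is the unweighted mean of per-class accuracies, `NA` when a class
has no classified patient.

## The synthetic generator

`synth_generate()` emulates the statistical structure the pipeline assumes,
so every stage is testable without any external data: a layered acyclic PKN
(stimuli → inhibitors → readouts) whose edges superset two planted truth
networks; per-patient input bits i.i.d. Bernoulli(`input_bit_prob`), or the
complete $2^n$ enumeration with `complete_inputs = TRUE`; readout signals =
the class truth network's steady state plus Gaussian noise clipped to
$[0,1]$; and an affine map of both onto a positive RPPA-like scale (inputs
$2 + 4x$, readouts $1 + 3x$), so normalization and binarization are
exercised non-trivially. Class divergence is planted as sign flips of
single-literal readout clauses; to keep the flipped clause inside the
hypergraph, each readout's first parent carries both an activating and an
inhibiting edge (dual, context-dependent regulation — common in curated
signed networks), and extra OR clauses are restricted to inhibitor targets.
A sign-flipped readout differs between the classes on *every* input pattern,
which is what makes the zero-noise recovery guarantee exact: with full input
coverage and no noise, every MSE-0 network reproduces the planted behavior,
and held-out patients classify at 100% balanced accuracy. Defaults
(`noise_sd = 0.1`, `input_bit_prob = 0.5`, `divergence = 2`,
`clause_density = 0.15`, 8 patients per class for the tiny preset, 30 for
small, 96+95 for the cohort preset mirroring a realistic RPPA cohort)
were fixed once as plausible study conditions.

What the generator does **not** emulate: technical replicates and batch
effects, heavy-tailed RPPA noise, correlated inputs, clinical covariates,
feedback cycles (available only via unit-test constructions, not the
generator), and model misspecification — the planted truth always lies
inside the hypergraph. Passing tests therefore demonstrate correctness of
the algorithms and graceful noise degradation under the assumed structure;
they do not certify accuracy on real cohorts, where the true logic is
neither Boolean nor inside the PKN and measured accuracies are far more
modest.

## Numerical choices and degenerate inputs

- Exact 2-means: ties between split points resolve to the first (lowest)
  optimal split; constant vectors binarize to zeros with a warning.
- MSE comparisons in learning are exact floating-point comparisons against
  the chunk-wide minimum; tolerances enter only through the explicit
  `fit_tolerance`/`size_tolerance` arguments.
- The weighted tie-break matching uses a cardinality constant
  `sum(gap) + 1` and `eps = 1e-9`, keeping the couple count exact while
  maximizing the gap among maximum matchings.
- Canonical orderings everywhere (clauses by target then sorted literals,
  couples by CR patient id, selections by gap then protein names) make
  every output deterministic; `run_pipeline()` seals this with md5 content
  hashes in a manifest that reproduces byte-for-byte under a fixed seed.
- Degenerate cases error early and name the offender: isolated PKN nodes,
  empty edge files, unknown sign tokens, degenerate readout ranges,
  single-class datasets, missing clamps, oversized catalogues.

## Problem sizes

The shipped studies are deliberately desk-scale: synthetic PKNs of 8–102
nodes, clause catalogues up to $2^{19}$ candidates for learning (seconds on
one core thanks to the vectorized scan), selection instances up to 8 input
proteins and 6 patients per class for oracle comparisons, and 20-seed noise
sweeps at three noise levels. Real studies with hundreds of clauses require
the same code paths but an external solver-backed search, which is out of
scope here (the `strategy` arguments accept only `"exhaustive"`, the exact
reference implementation).

## Known limitations

- Fixed-point semantics on cyclic PKNs reduce to "oscillation = 0 +
  warning"; no attractor analysis.
- The exhaustive learner is capped at $2^{20}$ subsets; no heuristic or
  ASP-backed search is bundled.
- Confidence is a ratio of two MSEs, not a calibrated probability.
- The binarization assumes the input measurements are bimodal enough for a
  2-cluster split to be meaningful; unimodal inputs binarize arbitrarily
  around the WSS-optimal split.
- Couples treat patients as exchangeable perturbation replicates; any
  within-patient correlation structure is ignored.
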