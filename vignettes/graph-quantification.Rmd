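---
title: "Graph quantification with prefix-graph flows: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph quantification with prefix-graph flows: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceflow)
```

## The problem

Conventional RNA-seq quantifiers estimate the abundances of a *fixed list*
of reference transcripts. When the reference is incomplete — which is the
norm for genes with complex alternative splicing — reads from unannotated
isoforms are forced onto the wrong transcripts, and downstream quantities
such as percent-spliced-in (PSI) inherit the distortion. *Graph
quantification* drops the fixed list: the unit of annotation is the splice
graph (exons plus junctions), and **every** source-to-sink path of the
graph is a potential transcript. The inference target becomes a network
flow rather than a transcript abundance vector.

The difficulty is phasing. A fragment spanning three or more exons
witnesses that those exons co-occur on one molecule; a flow on the plain
splice graph cannot represent that evidence, because the flow through two
consecutive junctions does not determine the flow through the pair jointly.
This package implements the resolution: unroll the splice graph *just
enough* to recognize every observed phasing path, using an Aho–Corasick
automaton, and infer a flow on the unrolled ("prefix") graph.

## The generative model and its reparameterization

Fragments are generated from transcripts under the standard model: a
transcript $T_i$ with abundance $c_i$ is chosen with probability
$\propto c_i \hat{\ell}_i$, and then a window $(j,k)$ within it with
probability $A_{p}(j,k)/\hat{\ell}_i$, where $A_p(j,k)$ is the *affinity*
(the unnormalized likelihood of that fragment; $D(k-j+1)$ under the pure
fragment-length model) and

$$\hat{\ell}_i \;=\; \sum_{j \le k \le \ell_i} D(k-j+1)
 \;=\; \sum_t D(t)\,(\ell_i + 1 - t)$$

is the effective length. The classical formula
$\big(\sum_{t\le \ell_i} D(t)\big)(\ell_i + 1 - \mu)$ with $\mu$ the
truncated mean is algebraically the same quantity
(`transcript_eff_len()` exposes both forms; their agreement is one of the
package's standing checks).

Every window maps to the *phasing path* $p$ its exon span traces. Grouping
windows by path gives the reparameterization on which everything rests:
with path abundance $c_p = \sum_{i:\,p \subset T_i} c_i$ and path effective
length $\hat{\ell}_p$ (the affinity mass of windows mapping exactly to
$p$; `path_eff_len()`),

$$\sum_i c_i \hat{\ell}_i = \sum_{p} c_p \hat{\ell}_p,
\qquad
P(F \mid c) \;\propto\; \prod_{f}
  \frac{\sum_{p \in M(f)} c_p\,A(f|p)}{\sum_p c_p \hat{\ell}_p},$$

where $M(f)$ is the set of candidate mappings of fragment $f$. The
likelihood depends on transcripts only through the path abundances, so it
suffices to optimize over any parameterization whose image is exactly the
set of realizable $\{c_p\}$.

## Prefix graphs

That parameterization is a network flow. Recognizing which phasing paths a
transcript contains, one exon at a time, is multi-pattern matching; the
Aho–Corasick automaton over the phasing set (alphabet = splice-graph
vertices, transitions restricted to splice-graph successors) yields:

* the **prefix graph** (`build_prefix_graph()`): vertices are automaton
  states (prefixes of phasing paths), and a path $p$ is recognized at the
  vertex set $AS(p)$ — states with $p$ as a suffix;
* the **compact prefix graph** (`build_compact_prefix_graph()`): vertices
  are singletons plus *strict* prefixes, recognition happens on edges
  ($AS(p) = \{e : p \text{ suffix of } t(e)\}$, with $t(e)$ the edge
  label). It is never larger than the prefix graph and is the default.

Source–sink paths of either rollout biject with splice-graph
source–sink paths (`lift_path()` / `project_path()`), transcripts map to
flows (`transcripts_to_flow()`), flows decompose back
(`decompose_flow()`), and $c_p$ equals the flow through $AS(p)$
(`path_abundance()`). The recognition correctness — each lifted transcript
meets $AS(p)$ exactly once if it contains $p$ and never otherwise — is
enforced by an exhaustive test over all source–sink paths of small random
graphs; it is the authoritative contract for the recognition-set
semantics. The original formulation states the compact recognition sets
with an ambiguous suffix direction; the implementation uses
$\{e : p \text{ suffix of } t(e)\}$, which the exhaustive test confirms,
because the strict prefix $p_0$ of a recognized $p = p_0 y$ is always a
compact-graph vertex and hence a suffix of the traversed edge's origin
label.

A construction note: prefix closure can name states that no transcript
ever realizes (a longer suffix always matches first). Such vertices lie on
no source–sink path and can carry no flow; the constructors prune them so
that the "every vertex on a source–sink path" invariant holds.

Under two conditions — the phasing set is prefix-closed, and every
splice-graph vertex has out-degree at most two — the linear map from
compact-graph flows to $\{c_p\}$ is injective (minimal sufficiency). The
package checks this by a rank computation on the stacked
recognition/balance system; `build_phasing_set(prefix_closed = TRUE)`
produces conforming inputs.

## Inference

The single-gene problem is concave with linear constraints:
maximize $\sum_p w_p \log c_p$ over flows $f \ge 0$ with balance at
internal vertices and $\sum_p c_p \hat{\ell}_p = m$, where $c_p$ is the
recognition-set flow. A key structural fact: because every window of a
transcript is recognized exactly once along its lifted path, the
transcript effective length is *edge-additive* on the rollout
($\hat{\ell}_i = \sum_{e \in \text{lift}(T_i)} \omega_e$ with
$\omega_e = \sum_{p:\,e \in AS(p)} \hat{\ell}_p$), so the normalization is
a linear functional of the flow.

`solve_single_gene()` is a fully corrective column-generation solver:

* the restricted master over the active source–sink columns is the
  classical mixture-EM update, accelerated by SQUAREM-style extrapolation;
* pricing searches for the maximum-ratio source–sink path
  (recognition gradient over effective-length mass) by Dinkelbach
  iterations on a longest-path DP over the rollout;
* the Frank–Wolfe duality gap $m\,r^* - \sum_p w_p$ certifies the
  objective; the solver stops at relative gap `gap_tol` (default `1e-8`).

The original description leaves the solver open ("general-purpose convex
solvers"); column generation was chosen over a plain multiplicative flow
update because it terminates with a computable optimality certificate and
its per-iteration cost is a single DP on the rollout. Counts below
$10^{-12}$ of a gene's total are treated as uncounted in the M-step: their
objective contribution is below float noise while their gradient
($w_p/c_p$ with $c_p$ free to approach zero) is unbounded and would poison
the certificate.

Multi-gene data and multimapped fragments use EM (`run_em()`):

* **Global E-step** $z_{f,p} \propto c_p A(f|p)$ over each fragment's
  candidate mappings;
* **Gene-level M-step**: each gene solves its flow program independently
  with normalization mass $s_g/|F|$, where $s_g$ is the gene's expected
  fragment count; the gene abundance is $c_g = s_g/|F|$ (gene abundance
  proportional to expected reads), which makes the decoupled solves
  jointly optimal under the global constraint $\sum_g c_g = 1$.

Fragments with identical mapping sets are collapsed into equivalence
classes; uniquely mapped fragments additionally factor their affinity into
an additive log-likelihood constant, since their responsibilities do not
depend on it. Initialization of the outer EM is a uniform abundance vector
(the first recorded objective value is already post-M-step, so the trace
is monotone from its first entry); the master is warm-started across EM
iterations with the previous columns. Convergence: relative
log-likelihood change below `1e-9` (configurable), cap 1000 iterations. A
decrease beyond `1e-9` relative aborts — it would indicate an M-step
solver failure, not a data problem.

## Effective lengths, affinities, trimming

`build_phasing_set()` enumerates every path whose minimal exactly-mapping
fragment length (interior length + 2) is within the distribution's
support, computes $\hat{\ell}_p$ in closed form for the `no_bias` model,
and always keeps every singleton (the automaton's alphabet must be
complete). Counts are aggregated from fragment mappings,
affinity-normalized for multimappers.

Positional bias enters through the affinity interface:
$A_p(j,k) = \sum_i \hat r_i B_i(j',k') / \sum_i \hat r_i$ over reference
transcripts containing $p$ (`positional_affinity()`), with $B_i$ modeled
as a piecewise-constant function of relative fragment midpoint (five bins
by default) times $D$. The `no_bias` and positional models can be mixed
("two affinities": $D$ for effective lengths, bias-corrected affinities
for fragment likelihoods) by passing different affinity models to
`build_phasing_set()` and to the fragment mappings; the consistent single
model is the default, since exactness of the reparameterization is only
guaranteed there. Sequence-composition (GC/motif) bias is an interface
hook only.

Long-tailed fragment-length distributions inflate the phasing set with
long paths that could only be generated through the tail.
`trim_phasing_set()` removes paths with **no mapped fragments** whose
effective length falls below a threshold; the default threshold is the
mass a single window at the 99.5th percentile of $D$ would contribute.
Trimmed paths simply leave the normalization (no renormalization): the
resulting overestimation is bounded by the trimmed effective-length mass,
which the trimming rule makes negligible, and paths with data are never
touched.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` emulate a bulk paired-end short-read
experiment on a single gene:

* fragment lengths: discretized normal, mean 350, sd 70, truncated to
  [50, 600] bases — the regime of typical paired-end libraries;
* subexon lengths uniform on 50–300 bases, matching the scale at which
  fragments regularly span several subexons (the regime where phasing
  matters);
* ground-truth abundances Dirichlet with $\alpha = 1$ (a flat prior over
  the simplex; nothing in the model favors particular compositions);
* fragments drawn exactly from the generative model
  ($T_i \propto c_i\hat{\ell}_i$, windows $\propto D$), so the sampler and
  the likelihood agree by construction;
* multimapping: with probability `multimap_rate` (default 0.2) a fragment
  is reported through its two 100-base anchor blocks only, and every exon
  chain consistent with the anchors and the length distribution becomes a
  candidate mapping with affinity $D(\text{implied length})$.

What the generator does *not* emulate: sequence-level reads (no errors, no
alignment ambiguity beyond the inner-gap chains), bias (affinities are
pure $D$ unless a bias model is supplied), genome-scale gene panels, or
annotation noise. Tests passing on these fixtures therefore demonstrate
the *algorithmic* claims — equivalence, preservation, recovery under the
declared model — not robustness to real-data artifacts.

## Numerical choices

* Flow balance tolerance: relative $10^{-9}$ of total flow, absolute
  $10^{-15}$.
* Decomposition: greedy widest path with deterministic (topological-order)
  tie-breaking; residual below $10^{-12}$ of total flow is clipped; at most
  one path per edge.
* PSI from a flow uses the canonical greedy decomposition and warns:
  decompositions are not unique, and PSI is decomposition-invariant only
  when every chain connecting the event exons is itself a phasing path.
  Reporting min/max PSI over decompositions would require an LP solver and
  is out of scope.
* Degenerate inputs: fragments whose every candidate chain has zero length
  probability are rejected at mapping time; counted paths with zero
  effective length abort the solve (the model cannot explain them);
  zero-count genes get zero flow and are skipped.
* Problem sizes in the shipped checks: random graphs with up to 8 internal
  vertices and at most 64 source–sink paths, $10^3$–$10^4$ fragments for
  equivalence runs and $10^5$ for recovery — sizes at which the
  transcript-enumeration oracle is exact and fast while the splice graphs
  still exercise nontrivial phasing.

## Known limitations

* The phasing-path enumeration and the automaton are exponential in the
  pattern length in the worst case; with transcript-length reads the
  rollout approaches the full transcript enumeration it is meant to avoid.
  The package targets short-read fragment scales.
* Overlapping annotated exons are not split into subexons; supplying
  disjoint (sub)exons is the caller's preprocessing step.
* Flow non-identifiability is intrinsic: different transcript sets can
  induce identical flows. Everything reported per *path* is identifiable
  under the minimal-sufficiency conditions; per-*transcript* output
  (decompositions) is one canonical representative.
* No uncertainty quantification on flows, and no differential PSI testing
  across samples.
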