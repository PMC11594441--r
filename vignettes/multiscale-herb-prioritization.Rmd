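---
title: "Prioritizing herbs and ingredients by network diffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing herbs and ingredients by network diffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbwalk)
```

## The problem

Medicinal herbs are multi-compound, multi-target interventions: a single herb
carries tens of ingredients, each hitting a handful of proteins. Asking
whether a herb is relevant to a disease is therefore not a single
ligand--receptor question but a network question: do the herb's targets,
taken together, perturb the same region of the interactome as the disease's
proteins? `herbwalk` answers it by propagating both the herb's targets and
the disease's proteins over a *multiscale interactome* -- a graph whose
nodes are proteins **and** biological functions -- and comparing where the
two propagations settle.

## The multiscale interactome

The walk substrate has two node classes and three edge layers:

* **ppi** -- physical protein--protein interactions (undirected);
* **annotation** -- protein--function associations (undirected);
* **hierarchy** -- function--function links, stored as (child, parent) and
  traversable in both directions, so the walker can generalize up to a
  broader function or specialize down.

Node kinds are inferred from layer membership, and an id claimed by both
classes is rejected at load time. Edges are canonicalized on construction
(self-loops dropped and counted, undirected pairs stored in sorted
orientation, duplicate rows collapsed), which makes deduplication and
file round-trips well defined. Zero-degree nodes are legal -- targets that
never mapped into the interactome -- and are flagged in the validation
report rather than silently dropped.

## Diffusion profiles

For a seed distribution $s$ (a herb's top targets, an ingredient's full
target set, or the disease's proteins, uniformly weighted), the diffusion
profile $r$ is the stationary point of a random walk with restart:

$$ r = (1 - \alpha)\, T^{\top} r + \alpha\, s $$

where $\alpha$ is the restart probability and $T$ the row-stochastic
transition matrix. The walk is *biased*: the probability of stepping from
$u$ to a neighbor $v$ through edge class $c$ is $w_c / Z(u)$, with
$Z(u)$ the total class weight over $u$'s outgoing (neighbor, class) pairs.
Five class weights are exposed: protein$\to$protein, protein$\to$function,
function$\to$protein, function$\to$parent and function$\to$child. Setting
the weights *into* the function layer above the others makes the profile
reflect the functional neighborhood of the seeds rather than raw
interaction degree, which is the point of the multiscale construction.

**Defaults and why.** The defaults are $\alpha = 0.17$ and weights
$w_{pp} = 1, w_{pf} = 2, w_{fp} = 1, w_{up} = 2, w_{down} = 1$. The
upstream multiscale-interactome literature tuned its walk hyperparameters
against drug--disease gold standards and did not publish a single canonical
set; rather than guess, we fix a documented set that realizes the intended
bias toward functions and record the parameters in every profile's
metadata and every pipeline output's config hash. No result in the test
suite depends on these being "right": every quantitative check pins its
parameters explicitly.

**Numerics.** Profiles are computed by power iteration with an L1
fixed-point residual (default tolerance $10^{-10}$, cap 10,000 iterations;
non-convergence is an error carrying the final residual, never a silent
result). Mass lost to dangling nodes (no positively weighted outgoing
edge) is redirected to the seed distribution each step, which keeps
$\sum_i r_i = 1$ to $10^{-9}$ and matches the convention that a stuck
walker restarts. The iteration is validated in the tests against the dense
closed-form solve $r = \alpha (I - (1-\alpha) T_\mathrm{eff}^{\top})^{-1} s$
on batteries of random networks (agreement to $10^{-8}$ in $L_\infty$).
All orderings (node order in the operator, every ranking tie-break) go
through locale-independent radix sorting on ids, so outputs are
byte-reproducible across machines; ranking ties are always broken by
ascending id.

## From profiles to a ranking

* **Seeding.** A herb is seeded with its top-50 targets by *simple pathway
  count* -- the number of the herb's distinct ingredients hitting each
  target -- so convergently targeted proteins carry the seed. An ingredient
  is seeded with its full target set. Uniform seed weights are the default;
  pathway-count weighting is a documented switch, since the upstream
  description does not state a weighting.
* **Correlation score.** Pearson correlation (Spearman by option) between
  the entity profile and the disease profile, aligned on the union of node
  universes with missing entries zero. Pearson on raw propagation scores is
  the convention of the framework this follows; zero-variance inputs are an
  error rather than NA.
* **Overlap statistics.** With $N$ eligible proteins (network protein
  count by default), $K$ disease proteins, an entity with $n$ targets and
  overlap $k$: the upper-tail hypergeometric p-value $P(X \ge k)$ and the
  fold enrichment $(k/n)/(K/N)$. Herbs use the top-50 list as $n$
  (matching published overlap denominators of 50 or the smaller target
  count); ingredients use their full target set.
* **Prioritization rule.** An entity is flagged when $p < 0.05$, fold
  enrichment $\ge 5$, and -- for herbs -- at least five ingredients are
  individually significant against the disease proteins. The raw 0.05
  cutoff mirrors the upstream procedure; BH-adjusted p-values are emitted
  alongside for transparency but do not drive the flag. The
  ingredient-support test uses the hypergeometric criterion alone (the
  weakest reading of "significantly associated"); a correlation floor is
  available as optional configuration.
* **Core targets.** Proteins hit (via any ingredient) by at least 3 of the
  top 10 herbs.

The published p-values of this procedure are not reproducible from the
published tables alone -- the background $(K, N)$ behind them is never
printed --
so the package treats only the *internal consistency* of the printed fold
enrichments as a checkable quantity: any one table row pins the background
fraction $p_0$, and every other row's printed enrichment must follow as
$(k/n)/p_0$. That check is what `scripts/acceptance.R` recomputes.

## Over-representation analysis

Core targets are tested against GMT gene-set libraries with the one-sided
exact hypergeometric test per term, BH adjustment across terms, and a
combined score $-\ln(p) \times z$. The z-score is computed against a
seeded random-set null: the overlap mean and standard deviation over 1,000
uniform draws of $|targets|$ genes from the background (default background:
the union of the library's genes). This differs deliberately from the
Enrichr platform's rank-deviation correction, which is not published as a
formula; the random-set null has the same qualitative semantics, is fully
self-contained, and is deterministic under the pinned seed recorded in the
output. Published combined scores from Enrichr are therefore comparable in
spirit but not digit-for-digit. With $-\ln$ as the log, larger combined
scores mean stronger enrichment, and a zero-overlap term can never score
above zero.

## Mechanism subnetworks

For an ingredient--disease pair the mechanism subnetwork is the induced
graph on the union of the top-$k$ nodes of the two profiles (default
$k = 20$ per profile, following the observation that the top 10 nodes
already carry roughly half the visitation mass, so 20 per profile gives
headroom), the ingredient's direct targets, and the disease proteins
present in either top-$k$ set. Targets not *associated* with
disease-related nodes are then excluded. "Associated" is operationalized
as reachability within the induced subgraph to a disease protein or a
disease-profile function -- the weakest defensible reading of the
exclusion rule -- with direct adjacency available as a stricter option. An
excluded target leaves the subnetwork entirely. The ingredient and the
disease are attached as pseudo-nodes (`targets` and `disease_link` edges)
that do not participate in the walk; they exist to reproduce the
ingredient--disease topology of the exported figures. Exports are SIF and
GraphML plus a node-annotation CSV; identical inputs give byte-identical
SIF output.

## The synthetic study generator

Real inputs of this kind (herb--ingredient compilations, drug--target
databases, curated disease genes, PPI repositories, GO) are licensed and
cannot ship with the package, so `generate_study()` builds studies with
the same statistical shape and *known ground truth*:

* **PPI layer**: preferential attachment (`igraph::sample_pa`), connected,
  with the heavy-tailed degree distribution that walk-based methods are
  most sensitive to -- a uniform random graph would understate hub effects.
* **Function layer**: a rooted spanning tree (child $\to$ parent rows) plus
  uniform cross-links up to the configured branching density.
* **Annotations**: uniform protein--function pairs at a configured density.
* **Disease module**: the first $m$ nodes of a breadth-first search from a
  random protein -- connected by construction.
* **Herb catalog**: each herb draws 3--8 ingredients, each ingredient 1--8
  targets. A planted fraction of herbs draws each target from the module's
  one-hop neighborhood (the module plus its direct interactors -- the
  standard operationalization of "disease neighborhood") with probability
  $1 - \mathrm{leakage}$; the default leakage of 20% draws uniformly
  instead, so recovery is nontrivial. Background herbs draw uniformly.
  Every planted herb is guaranteed at least one in-neighborhood target.

Defaults are 800 proteins, 300 functions, a module of 15, 60 herbs, 20%
planted. At these sizes the whole study ranks in about a second on one
core, which is what lets the test suite run the full recovery experiment
over ten seeds. Under those conditions the planted herbs separate from
background by correlation score with mean ROC-AUC well above 0.9 and most
planted herbs inside the top 10 -- the recovery property asserted in the
acceptance tests.

What passing these tests does **not** show: the generator does not mimic
real GO semantics, real target-promiscuity distributions (quercetin-like
ingredients with hundreds of targets), shared ingredients across herbs, or
literature-biased disease annotations. Recovery on synthetic studies
validates the machinery -- propagation, scoring, statistics, determinism --
not the biological conclusions one would draw on real databases. On the
default synthetic conditions, for instance, herbs rarely pass the
five-significant-ingredients support rule that real top herbs pass easily,
because synthetic ingredients have few, weakly clustered targets; the flag
logic is exercised separately on a strongly planted fixture.

## Design choices on genuinely open points

* **Hierarchy direction**: file rows are read (child, parent); up- and
  down-traversal get separate weights because the bias toward functions
  must distinguish generalizing from specializing moves.
* **Annotation orientation**: stored protein-first; since endpoints are
  type-distinguishable this is equivalent to sorted canonical form and
  type-safe.
* **Population $N$**: network protein count by default, configurable;
  printed p-values from proprietary-data studies cannot pin it, so it is
  never silently inherited from data.
* **Top-50 tie-breaks**: ascending protein id at the cutoff -- the source
  procedure is silent and determinism is required for testing.
* **Per-profile $k$** in subnetworks ($k = 20$ from each profile, not 20
  total), matching "top k from either the drug or the disease".
* **Problem sizes in tests**: oracle comparisons run on networks of up to
  50 nodes where the dense linear solve is exact and cheap; recovery runs
  on the default 800-protein study, chosen as the smallest size at which
  hub structure, module locality and catalog sparsity all resemble the
  real regime.

## Known limitations

* Walk hyperparameters are fixed by documentation, not optimized against
  gold-standard pairs; rankings at very different $\alpha$ or bias weights
  are not guaranteed to agree.
* The correlation score is computed over full profiles; dominant hub mass
  inflates the baseline correlation between any two profiles, which is why
  rankings (not absolute correlation values) are the meaningful output.
* The exclusion rule in subnetworks depends on the induced subgraph, so an
  ingredient target can be excluded at small $k$ and retained at larger
  $k$.
* No id mapping across namespaces: inputs are assumed pre-mapped to one
  protein id space.

## A minimal session

```{r example, eval = FALSE}
study <- generate_study(synthetic_config(rng_seed = 1))
cfg <- pipeline_config(study$network, study$catalog, study$disease,
                       out_dir = "results")
res <- run_rank_herbs(cfg)
head(res$ranking)

herb <- res$ranking$entity[1]
run_rank_ingredients(cfg, herb)
run_subnetwork(cfg, herb_ingredients(study$catalog, herb)[1])
```

The numbered scripts under `analysis/` run exactly this workflow end to
end, from simulation through subnetwork export, printing what each stage
found.
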