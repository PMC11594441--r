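# herbwalk

Network-pharmacology prioritization of medicinal herbs and their
ingredients for a disease, by **biased random walks with restart on a
multiscale interactome**.

Herbal medicines act through many compounds hitting many protein targets
at once, so "is this herb relevant to this disease?" is a question about
network neighborhoods, not single interactions. `herbwalk` is for
computational systems-biology and network-pharmacology researchers who
want that question answered reproducibly: it propagates an entity's
protein targets and a disease's protein set over a graph of proteins *and*
biological functions, compares where the two propagations settle, and
ranks herbs and ingredients accordingly — with every statistic, threshold
and tie-break pinned and tested.

## The model

The walk substrate is a two-class graph with three edge layers:
protein–protein interactions, protein–function annotations, and a
function hierarchy traversable both up (child → parent) and down. For a
seed distribution *s* the diffusion profile *r* solves the restart
fixed point

```
r = (1 − α) Tᵀ r + α s
```

where the transition matrix *T* is **biased by edge class**: a step from
node *u* through class *c* has probability `w_c / Z(u)`. Weighting the
classes into the function layer (`w_pf`, `w_up`) above the rest makes a
profile reflect the functional neighborhood of its seeds, not raw degree.
Entities are then ranked by the Pearson correlation between their profile
and the disease profile, with an upper-tail hypergeometric test of the
target overlap k/n against the disease proteins K/N and a fold enrichment
`(k/n)/(K/N)`. Core targets are proteins hit by ≥ 3 of the top 10 herbs;
over-representation of those targets against GMT gene-set libraries uses
the exact test, BH adjustment, a seeded random-set z-score and the
combined score `−ln(p)·z`. Mechanism subnetworks link an ingredient to
the disease through the top-20 nodes of the two profiles.

Because the real inputs of such studies (herb–ingredient compilations,
drug–target and disease–gene databases, PPI repositories, GO) are
licensed, the package ships a seeded synthetic-study generator with
planted ground truth, so the full pipeline is testable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated study. Step 01 generates an 800-protein / 300-function
interactome, a 15-protein disease module and 60 herbs of which 12 are
planted near the module; step 02 ranks the herbs:

```
$ Rscript analysis/01_simulate.R
$ Rscript analysis/02_rank_herbs.R
top 10 herbs by correlation score:
 rank entity correlation_score overlap_k n_targets hypergeom_p enrichment
    1   H001         0.4033625         3        31  0.01748908   5.161290
    2   H027         0.4002178         3        28  0.01319020   5.714286
    3   H033         0.3832173         2        21  0.05611587   5.079365
    ...
planted-herb recovery: ROC-AUC = 0.979; planted ranks: 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 15, 20
core targets (>= 3 of top 10 herbs): 17 proteins
```

Every herb in the top 10 is a planted one: herbs constructed to target
the disease module's neighborhood out-correlate background herbs
(ROC-AUC 0.979 here), and H001's top-31 targets overlap the 15 disease
proteins 3 times where ~0.6 would be expected by chance (enrichment 5.2,
p = 0.017). Steps 03–05 rank the top herb's ingredients the same way
(full target sets as overlap denominators), test the 17 core targets for
over-representation — they land almost entirely inside the module's
one-hop PPI neighborhood (17/165, adjusted p ≈ 1e−11) — and export
SIF/GraphML mechanism subnetworks for the two leading ingredients.

All tables carry a configuration hash, and re-running any step with the
same inputs reproduces its outputs byte for byte.

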