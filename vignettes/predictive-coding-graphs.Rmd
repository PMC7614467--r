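---
title: "Predictive-coding graphs: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive-coding graphs: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pcgraph)
```

## The model

A predictive-coding graph is a directed graph on `n` vertices with no
self-loops. Vertex `b` carries three quantities:

* a **value** $x_b$ — the current activity of the vertex,
* a **prediction** $\mu_b = \sum_{a \to b} \theta_{a,b}\, f(x_a)$, the
  activation-weighted sum over its in-neighbours,
* an **error** $\varepsilon_b = x_b - \mu_b$.

The scalar objective is the total squared prediction error,

$$E(x, \theta) = \tfrac{1}{2} \sum_b \varepsilon_b^2 .$$

Both dynamics are plain gradient descent on $E$, and both are *local*: each
update for a vertex or edge only touches quantities at that vertex, its
neighbours, and the edge weight itself.

* **Inference** (values move, weights frozen):
  $\Delta x_b = \gamma\,\big({-\varepsilon_b} + f'(x_b) \sum_{b \to c}
  \varepsilon_c\, \theta_{b,c}\big)$.
* **Learning** (weights move, values frozen):
  $\Delta \theta_{a,b} = \alpha\, \varepsilon_b\, f(x_a)$, averaged over the
  batch.

The tests verify, by central finite differences on $E$, that both updates are
the exact negative gradients (maximum relative error below $10^{-6}$ across
random graphs and both smooth activations).

### Index convention

Weights are stored as an `n x n` matrix with `theta[a, b]` on the edge
`a -> b`, so the prediction for a whole batch is one matrix product,
`f(x) %*% theta`, and the masked weight update is
`crossprod(f(x), eps) / batch_size * mask`. This is the unique convention
under which the inference and learning rules above are simultaneously the
exact gradients of `E`.

### Queries

A trained graph is interrogated through two query modes, both built from the
same relaxation loop (`run_inference()`):

* **Query by conditioning** — a subset of vertices is *clamped* to the cue
  for every step; the remaining values descend the energy. Used for
  classification (clamp pixels, read the label block), generation (clamp a
  one-hot label, read the pixels), completion (clamp the visible pixels) and
  masked associative recall.
* **Query by initialization** — the cue only sets the *starting* values;
  every vertex then relaxes freely. Used for denoising, where no pixel can be
  trusted enough to clamp.

"Until convergence" means: up to `max(n_iter, 5000)` steps, stopping early
when the largest value change falls below `tol` (default $10^{-6}$). The
closed-form tests (e.g. a free vertex between two clamps must reach the
quadratic minimizer $x = 0.5$) use `tol = 1e-8` to leave headroom below the
$10^{-5}$ assertion tolerance.

## Training

`pc_train()` repeats, for each batch in each epoch:

1. clamp the sensory vertices to the data rows (pixels, plus the one-hot
   label block when the dataset is labelled);
2. re-initialize the internal vertices from $\mathcal N(0, 0.01^2)$;
3. run `n_iter` inference steps with rate `gamma`;
4. apply one weight update with rate `alpha`, masked to the topology.

Off-topology weights are exactly zero at construction and provably stay
exactly zero through training (asserted bit-wise over 500 updates).

### Parameter defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| `gamma` (inference rate) | 0.1 (0.2 in the task examples) | Largest rate that kept energy descent monotone on random graphs in our property tests; task runs tolerate 0.2. |
| `alpha` (learning rate) | 0.01 (0.1 in the task examples) | 0.1 was selected by a small grid search on the multitask benchmark; larger values (0.4) diverged on deep hierarchies. |
| `n_iter` (steps per presentation, `T`) | 32 | Enough for the value relaxation to settle on graphs of ~100–300 vertices; the tasks are insensitive between 24 and 64. |
| `epochs` | 100 (300 in the task examples) | Full-batch training on the glyph datasets plateaus by ~300 epochs. |
| `tol` | 1e-6 | Early-stop threshold on the max value change; tight enough that task metrics are unchanged by further iteration. |
| weight init | $\mathcal N(0, 1/n)$ | Variance $1/n$ keeps initial predictions $O(1)$ regardless of in-degree. |
| value init | $\mathcal N(0, 0.01^2)$ | "Near zero but not zero": breaks the symmetry of the all-zero fixed point without perturbing the clamped cue. |

These training hyperparameters are legitimately tunable — the reference
values were found by searching over them on the synthetic benchmark, and all
tests and the acceptance script state the configuration they use explicitly.

## Topologies

`topology_spec()` + `build_mask()` produce binary adjacency masks:

* `fully_connected` — every ordered pair except self-loops.
* `layered_forward` / `layered_generative` — consecutive layers connected
  `l -> l+1` (discriminative) or `l+1 -> l` (generative).
* `layered_lateral` — forward plus all within-layer edges.
* `assemblies` — Erdős–Rényi blocks ("neuron assemblies"): each cluster is an
  internal directed ER graph with edge probability `p`, plus full bipartite
  connections along the listed `inter_cluster_edges`. Combined with a top-k
  activation (`pc_activation(..., clusters=, keep_frac=)`) that keeps the
  `ceiling(k * cluster_size)` most active units of each cluster (ties broken
  toward the lowest vertex index) and gates $f'$ by the same keep-mask.
* `custom` — any user mask.

### The `layers` argument

Layered specs normally carve `1:n` into contiguous layers from
`layer_sizes`. The `layers` argument instead accepts an explicit list of
index vectors, which need not be contiguous. This exists because sensory
vertices are `1:d` by convention, with the label block at the *end* of the
sensory range — but in a generative hierarchy the labels belong at the *top*
of the hierarchy, not next to the pixels at the bottom. For an 8×8, 4-class
hierarchy with 210 hidden units:

```{r}
spec <- topology_spec("layered_generative",
                      layers = list(1:64, 69:278, 65:68))
mask <- build_mask(spec)
sum(mask)  # 210*64 + 4*210 = 14280 directed edges
```

puts pixels (1–64) at the bottom, hidden units on top of them, and the label
vertices (65–68) at the apex, so generation is top-down prediction flow.

### Source vertices and "zero energy"

A vertex with no in-edges predicts $\mu = 0$, so its error is the constant
$x - 0$ no matter what the rest of the graph does. On a DAG driven
feed-forward from its sources, therefore, every *non-source* error is zero
but the total energy equals $\tfrac12 \sum_{\text{sources}} x^2$. The tests
phrase the feed-forward invariant accordingly. Relatedly, because
$f(0) = 0$ for all shipped activations, the all-zero state is always a fixed
point: an all-zero cue provides no drive, which is why retrieval tests use
patterns whose visible half is non-zero.

## Synthetic glyph data

`make_synthetic()` draws from eight fixed binary 8×8 prototypes (vertical /
horizontal stripes, checkerboard, frame, cross, diagonal band, quadrants,
centre dot), adds i.i.d. Gaussian pixel noise, and clips to $[0, 1]$. It is a
stand-in for image benchmarks with the properties the training loop actually
needs — class-separable, low-resolution, balanced, bit-reproducible from the
seed — and nothing more. It does **not** emulate natural-image statistics:
there is no translation or deformation variability, no correlated noise, no
class overlap, and within-class variation is purely isotropic pixel noise. A
model that succeeds here has demonstrated the mechanics of multitask
inference, not robustness on real images.

`corrupt()` implements the retrieval cues: `half_mask` zeroes the trailing
half of the pixels (row-major, so the bottom rows of the glyph),
`fraction_mask` zeroes a trailing fraction, and `gaussian_noise` perturbs
every pixel with variance `sigma2`.

## Problem sizes used in tests and the acceptance script

* Gradient/descent properties: random dense graphs, 4–12 vertices, 100
  instances.
* Multitask benchmark: 4 classes × 8 patterns, 64 pixels + 4 label vertices,
  fully connected `n = 200`, trained ~300 epochs — classification,
  generation, completion and denoising from one set of weights.
* Associative memory: 5 stored glyphs, `n = 200`.
* Topology comparison: fully connected `n = 120` vs a 64/210/4 generative
  hierarchy, matched at 14280 edges, averaged over 5 seeds.
* Assemblies: 4 clusters of 30, `p = 0.1`, `k = 0.2`.

## Limitations

* Inference is plain gradient descent with a fixed rate; no momentum,
  preconditioning or line search. Very deep hierarchies train slowly and
  somewhat seed-dependently under these dynamics.
* Energy descent is only guaranteed for sufficiently small `gamma`; the
  divergence guard in `inference_step()` raises an error rather than
  returning non-finite values.
* The glyph generator is deliberately minimal (see above); conclusions about
  relative topology quality are specific to this data scale.
* Batch processing stores values densely (`batch x n`); graphs beyond a few
  thousand vertices would need a sparse weight representation.
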