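---
title: "Populating an ontology skeleton with word embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Populating an ontology skeleton with word embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontopop)
```

## The problem

Curated domain ontologies — the motivating case is a food ontology with
thousands of classes such as "cow milk cheese" and tens of thousands of
instances such as "Brie cheese food product" — grow by manual curation.
Assigning each newly encountered instance to its parent class is the
bottleneck. `ontopop` implements a semi-supervised *ontology population*
procedure: the class hierarchy (a single-rooted, multi-parent directed
acyclic graph, DAG) is kept fixed, a handful of known instances per class
("seeds") are revealed, and every remaining ("candidate") instance is
assigned to the target class whose seeds and label it most resembles in a
word-embedding space.

## The model

Labels are preprocessed into tokens and represented by the arithmetic mean
of their tokens' word-embedding vectors. Writing $\vec{\iota}$ for a
candidate instance vector, $\vec{c}$ for the class-label vector, and $I_c$
for the seed set of class $c$, each candidate is scored against every
target class by a convex combination of two similarities:

$$
\mathrm{score}(c;i) \;=\; \alpha \,\underbrace{\mathrm{sim}\!\Big(\vec\iota,\ \tfrac{1}{|I_c|}\sum_{i' \in I_c}\vec{\iota'}\Big)}_{\text{sibling score: seed centroid}}
\;+\; (1-\alpha)\,\underbrace{\mathrm{sim}\big(\vec\iota,\ \vec{c}\big)}_{\text{parent score: class label}},
\qquad \hat c = \arg\max_c \mathrm{score}(c;i).
$$

`sim` is cosine similarity by default (Euclidean negative distance is
available; cosine performs better and is the convention here). Every
candidate receives exactly one class, even if its ground truth lists
several parents.

### Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `alpha` | 0.8 | [0, 1] | weight of the sibling term; 0.8 is the empirically established optimum of the 0.0–1.0 sweep at 0.1 steps. `alpha = 1` is nearest-seed-centroid, `alpha = 0` nearest-class-label — both verified against independent implementations in the tests. |
| `n_seed` | 2 | count ≥ 1 | seeds revealed per target class; classes with fewer instances contribute all of them. Precision is non-decreasing in `n_seed` (measured below). |
| `similarity` | cosine | — | cosine in [−1, 1]; Euclidean ranks by −‖u−v‖, comparable only within a run, which argmax tolerates. |
| `dim` | 100 (training) | 50–300 | embedding dimension; the reference protocol trains 50/100/200/300-d skip-gram vectors. |
| `epochs`, `window`, `min_count` | 100, 5, 1 | — | skip-gram hyperparameters of the reference protocol; everything else (negative = 5, no subsampling, single worker) is recorded in `training_meta`. |

## Text preprocessing

`preprocess()` applies eight steps in a fixed order: lower-casing, synonym
mapping, punctuation stripping, white-space stripping, numeric stripping,
stop-word removal, short-word stripping (tokens shorter than 3 characters;
the threshold is configurable because the convention only names the step),
and lemmatization. Choices where the procedure is conventionally
under-specified:

* the stop-word list ships as a versioned plain-text file (apostrophe-free
  contraction variants included, since punctuation is stripped first);
* the lemmatizer is a small irregular-noun dictionary plus conservative
  noun-preference suffix rules — deterministic and idempotent, not a full
  morphological analyzer;
* the synonym map defaults to empty (no canonical resource is assumed); it
  must be idempotent (no chains), which is validated;
* the stop-word and length filters are re-applied after lemmatization so
  the output invariants (no punctuation, digits, stop-words, short tokens)
  hold unconditionally, and `preprocess()` is idempotent;
* corpus documents are single token streams; no sentence splitting is
  performed, so skip-gram windows stay within a document but may cross
  line breaks.

## Embeddings

`train_embeddings()` is a skip-gram model with negative sampling,
implemented in C++ and deliberately single-threaded with a self-contained
PRNG: a rerun with the same corpus, hyperparameters and seed is
bit-identical. Pre-trained vectors in word2vec or GloVe text format are
loaded with `load_vectors()`. Label vectors average over the token
*multiset* (a repeated token counts twice); out-of-vocabulary tokens are
skipped rather than zero-imputed, and per-label coverage is reported so
fully-OOV labels are auditable. A label with zero coverage cannot be
scored; such candidates are assigned a uniformly random target class with
`fallback = TRUE` so that precision denominators stay comparable across
methods. When exactly one of the two score components is undefined for a
class (say, an OOV class label), the defined component is used alone
rather than disqualifying the class; this never occurs on synthetic data,
which has full coverage by construction.

## Baselines

Three non-embedding baselines share the assignment machinery:

* **Jaccard** — token-set similarity of preprocessed labels;
* **Hamming** — positional similarity of raw lower-cased label strings,
  `1 − (mismatches + length difference) / max length`;
* **random** — a uniform draw over target classes.

Whether the string baselines should use the same $\alpha$-combination or a
single pairwise similarity is genuinely open; we use the combined form for
comparability (the sibling term becomes the mean pairwise similarity to
the seed labels, the set/string analogue of a centroid) and expose
`combine_scores = FALSE` for the pairwise-only variant. Ties in the argmax
are broken toward the lexicographically smallest class id, making every
method deterministic given its seed.

## Metrics

* **precision** = TP/(TP+FP); a candidate is TP iff its predicted class is
  a member of its ground-truth parent set (a `strict_single` switch scores
  against the primary parent only). Since every candidate is assigned,
  TP+FP equals the candidate count.
* **hop distance** — shortest path between predicted and true class on the
  *undirected* class graph, minimized over true parents. Undirected is the
  only convention under which a sibling misassignment is finite (2 hops);
  the 0-hop mass of the distance histogram equals the TP count by
  construction, and `evaluate_mapping()` asserts this on every call.
* **granularity** of a superclass = distinct instances in its subtree /
  classes in its subtree (subtree includes the superclass itself).
* **cohesiveness** = fraction of a superclass's judged direct subclasses
  marked consistent with its organizing principle; judgments are expert
  input (TSV), the package computes the ratio and validates that judged
  ids are direct subclasses.
* `correlate_structure()` gives the Pearson correlation (with two-sided
  p-value) between per-superclass precision and a structural metric.
* Repeated experiments: `run_experiment()` builds skeleton $r$ with
  `rng_seed = base_seed + r` so each repeat is independently reproducible;
  it reports both the unweighted mean over repeats and the
  candidate-pooled aggregate, because the two differ when candidate
  counts vary and published tables do not always say which was used.
  Method comparisons report two-sided Wilcoxon signed-rank p-values paired
  per repeat; the test name is printed with the result.

## The synthetic world

`generate_ontology()` + `generate_embeddings()` state a desk-scale world
with the structural features that drive the method's behavior: 100
classes grown breadth-first to depth ≤ 5, a second parent with
probability 0.1 (so some classes have several paths to the root),
Poisson(3) instances per class — matching the ~3 instances/class average
of the motivating curated ontology and leaving a minority of classes
empty, exactly the classes that are excluded from the target set — and
clustered embeddings: each class has a latent centroid (random unit
vectors rescaled so the minimum pairwise distance equals
`centroid_separation`), and every token of a label is its class's
centroid plus isotropic `N(0, noise_sigma²)` noise. Instance labels use
fresh unique alphabetic tokens, so the full text pipeline runs end to end.

What the generator does **not** emulate: lexical overlap between labels
(tokens are unique per label, so Jaccard/Hamming baselines carry no signal
on synthetic data and behave like the random baseline — by design, they
are controls there, not competitors), heavy-tailed instance counts, and
the deep, uneven branching of a real curated hierarchy. A green synthetic
test therefore establishes the correctness of the machinery and its
limiting behavior, not full-scale performance numbers: those require the
real ontology and corpus.

Limiting behaviors verified in the test suite:

* `noise_sigma = 0`, separated centroids → precision exactly 1, all hop
  distances 0;
* `centroid_separation = 0` → embedding precision statistically equal to
  the random baseline;
* uniform random mapping on a single-parent ontology with $k$ target
  classes → precision $1/k$ within Monte-Carlo error;
* smaller noise never yields worse mean precision (paired generations).

### Seed-count monotonicity

The `n_seed` experiment uses a world fixed in advance of measurement: 40
classes, single-parent, Poisson(12) instances per class (so `n_seed = 8`
still leaves candidates), 16-d embeddings, `noise_sigma = 0.25` at unit
separation — enough noise that centroid estimation matters, not so much
that the mapping collapses. Mean precision over 20 repeats:

```{r nseed, eval = FALSE}
spec <- synthetic_spec(n_classes = 40L, max_depth = 4L, branching = 3,
                       multi_parent_prob = 0, instances_mean = 12,
                       dim = 16L, centroid_separation = 1,
                       noise_sigma = 0.25, rng_seed = 77)
b <- generate_benchmark(spec)
vapply(c(1L, 2L, 4L, 8L), function(ns)
  run_experiment(b$ontology, vectors = b$vectors, config = mapper_config(),
                 n_seed = ns, n_repeats = 20L,
                 base_seed = 500)$mean_precision, numeric(1))
#> 0.9898 0.9977 0.9995 1.0000
```

The increase is small because this world is an easy one at `n_seed = 1`
already; the direction is what the acceptance criterion checks.

## Numerical and design notes

* All randomness flows through explicit integer seeds; library calls
  restore the caller's RNG state. Skeleton seeds, the random method, and
  zero-coverage fallbacks each draw from their own seeded stream.
* Depth is the minimum-length path to the root (classes are binned by a
  single depth; minimum is the standard convention); `paths_to_root()`
  counts all distinct directed paths by topological dynamic programming
  and is cross-checked against exhaustive enumeration.
* An instance drawn as a seed for any class is removed from the candidate
  set globally, preventing train/test leakage for multi-parent instances.
* Degenerate inputs: an empty candidate set maps to an empty result;
  labels that preprocess to nothing warn at tokenization and fall back at
  mapping; a class with fewer than `n_seed` instances contributes all of
  them; cosine against a zero vector is a named error, not a NaN.
* The ontology TSV writer emits sorted rows so write→read→write round
  trips are byte-identical.
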