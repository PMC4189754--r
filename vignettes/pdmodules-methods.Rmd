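---
title: "Discovering phenotype-defining protein-family modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering phenotype-defining protein-family modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmodules)
```

## The problem

Microbial phenotypes such as lignocellulose degradation are rarely carried
by a single gene: they rest on *modules* of protein families — glycoside
hydrolases, polysaccharide lyases, carbohydrate-binding modules, and their
accessory domains — that co-occur across the genomes able to express the
phenotype. `pdmodules` discovers such modules from nothing more than
per-genome (or per-metagenome-bin) protein-family annotation profiles plus
a partial phenotype labeling, ranks them by how well they separate
phenotype-positive from phenotype-negative genomes, stabilizes them across
repeated stochastic fits, and turns them into a phenotype classifier and a
gene-cluster mapper.

## The topic model

Each genome or bin is a *document*: a bag of protein-family identifiers
(e.g. `GH5`, `PF00041`), one token per annotated protein, with per-family
counts capped (default 10) so single expanded families cannot dominate a
document. Latent Dirichlet allocation assumes each document mixes $T$
latent topics; topic $t$ is a multinomial $\varphi_t$ over the family
vocabulary $V$ and document $d$ has topic weights $\theta_d$, so

$$P(w \mid d) = \sum_{t=1}^{T} \varphi_t(w)\, \theta_d(t).$$

We fit by collapsed Gibbs sampling: token assignments $z_i$ are resampled
from

$$P(z_i = t \mid z_{-i}, w) \propto
  \frac{n_{w,t}^{-i} + \beta}{n_{\cdot,t}^{-i} + V\beta}\,
  \left(n_{d,t}^{-i} + \alpha\right),$$

and after a burn-in phase we average the posterior-mean estimates
$\hat\varphi_t(w) = (n_{w,t}+\beta)/(n_{\cdot,t}+V\beta)$ and
$\hat\theta_d(t) = (n_{d,t}+\alpha)/(n_{d,\cdot}+T\alpha)$ over collected
samples. A topic becomes a discrete candidate module by thresholding:
$M_t = \{w : \varphi_t(w) \ge C\}$ with $C = 0.01$.

### Sampler parameters

| parameter | production default | scaled test default | meaning |
|---|---|---|---|
| `n_topics` (T) | 400 | 20 | number of latent topics |
| `alpha` | 50/T = 0.125 | 0.5 | document-topic Dirichlet mass per topic |
| `beta` | 0.01 | 0.01 | topic-word Dirichlet mass per family |
| `burn_in` | 2000 | 600 | sweeps before sampling |
| `n_samples` | 50 | 10 | collected Gibbs samples |
| `sample_lag` | 10 | 10 | sweeps between samples |

Two scaled-test values deviate from a naive shrink of the production
settings, for measured reasons:

* **`alpha`.** The conventional `50/T` rule ties the prior to the topic
  count; at T = 400 it gives a per-topic mass of 0.125, but at T = 20 it
  gives 2.5 — a nearly flat document prior that pushes every document to
  use many topics and makes chains merge genuinely distinct topics. On
  planted-module corpora, single-topic recovery rose from 9/18 to 17/18
  when the scaled config used `alpha = 0.5`, which restores a per-document
  topic sparsity comparable to the production regime.
* **`burn_in`.** 200 sweeps (a naive 10× shrink) left chains unconverged on
  harder corpus draws: planted modules stayed split into half-modules that
  600–1500 sweeps resolve. The scaled default is 600.

Within one chain we do not relabel topics across collected samples; label
drift over a 100-sweep window is rare after burn-in, and cross-run label
switching is handled by the consensus machinery instead. One seeded
generator drives initialization and every sweep, so a fit is bitwise
reproducible from `(corpus, config, seed)`.

## Ranking modules by phenotype association

The *completeness score* of module $M_t$ in document $d$ is

$$\mathrm{weight}_t(d) = \frac{\lvert M_t \cap d\rvert}{\lvert M_t\rvert}
  \times 100\,\%,$$

the percentage of the module's families annotated in the document
(presence only; counts beyond 1 are ignored). For each module we pick the
classification threshold $\gamma_t$ maximizing the $F_{0.5}$ score of the
rule $\mathrm{weight}_t(d) \ge \gamma_t \Rightarrow$ positive, searching
exhaustively over the distinct observed weights plus an all-negative
sentinel; $F_{0.5}$ weights recall half as strongly as precision, which
suits a screening setting where false positives are costlier than missed
degraders. Among equal-$F$ thresholds we keep the largest (most stringent)
one — a deliberately conservative tie-break. One measurable consequence,
relevant when reading the tests: if the smallest positive weight is unique,
a leave-one-out fold that holds it out trains a threshold *above* that
value, so even perfectly separated data can show one LOO false negative;
the classic "perfect separation gives F = 1" identity requires the boundary
weight to be non-unique.

## Consensus across runs

Gibbs sampling is stochastic, so the pipeline fits R independent runs
(default 18) and keeps only modules that recur. Runs are compared pairwise:
module distances are Jaccard distances between discrete family sets (a
symmetrized Kullback–Leibler distance on the smoothed $\varphi$ rows is
available behind a flag; the two orderings agree on identical < overlapping
< disjoint). The Hungarian algorithm provides an optimal one-to-one
mapping between two runs' topics.

For clique-finding across many runs, however, the package's default edge
rule is a plain distance threshold: every pair of modules from different
runs, both within their runs' top-15 ranking, is connected iff their
Jaccard distance is at most `d_max` (default 0.7). The stricter rule —
edges only between Hungarian-matched pairs — is available as
`edge_rule = "hungarian"` but is *not* the default, for a structural
reason: when T exceeds the number of effective topics, the posterior
contains near-duplicate and split topics, and a global one-to-one matching
routes different run-pairs through different duplicates. Cliques then fail
transitivity and stable modules are lost even though every run contains
them (we observed maximal cliques capped at 4 of 6 runs this way).
Duplicates persist at 3000-sweep burn-in, so this is a property of the
posterior, not of convergence.

Maximal cliques of the module graph are enumerated with Bron–Kerbosch
(with pivoting); because the graph has no intra-run edges, a clique
contains at most one module per run, and we keep cliques spanning at least
75 % of the runs (14 of 18). Overlapping cliques are resolved greedily —
larger first, ties to the smaller mean internal distance. A clique's
*consensus module* contains every family occurring in at least a quorum of
its member modules; the quorum defaults to $\lceil R/2 \rceil$ (9 at
R = 18) so the rule generalizes when fewer runs are fitted. Families below
quorum are reported separately.

## Evaluation and prediction

Classifier quality for a consensus module is estimated with the threshold
re-fitted inside every fold:

* **Leave-one-out**: each labeled sample is held out once; the threshold is
  optimized on the rest; precision, recall and $F_{0.5}$ come from the
  pooled single predictions.
* **Repeated 10-fold CV** (plain random folds; stratification off by
  default, matching random splitting): per-repeat accuracy is averaged
  over 10 repeats; macro-accuracy is (TPR + TNR)/2 from the pooled
  predictions; a 95 % Clopper–Pearson interval is computed from
  `round(mean accuracy × n)` successes of n — a single-interval summary
  per module; at n = 120 this reconstruction and pooled counting
  coincide for the reference values the tests reproduce.

Degenerate training folds containing one class fall back to the
majority-class prediction. Prediction for unlabeled samples applies
`weight >= gamma` with thresholds optimized on the full learning set. A
separate, model-free *saprophyte rule* flags genomes carrying at least one
cellulase family and three or more hemicellulase/pectinase families from
fixed CAZy lists (distinct families, not protein counts — the phrasing in
the source is ambiguous; distinct-family counting is the stricter and, we
believe, intended reading).

## Gene clusters

Genomic co-localization corroborates a module: for a consensus module we
scan each replicon for runs of genes carrying at least one module family
where consecutive such genes are separated by at most 2 kb, keeping runs of
four or more genes with at least two distinct module families. Intergenic
distance is `max(0, next_start − prev_end − 1)` on 1-based inclusive
coordinates; overlapping genes count as distance 0 (no formula is given in
the source; this is the natural convention). Unannotated genes inside a
tolerated gap do not break a chain — "neighboring" is read over
module-annotated genes — with a strict mode requiring consecutive gene
indices available as a flag. Clusters of different modules whose spans
overlap are merged into distinct clusters for counting; summary statistics
report the mean intergenic distance and the percentage of module families
covered by at least one cluster. BED export converts to 0-based half-open
coordinates.

## The synthetic world

`generate_corpus()` runs the generative model forward with planted ground
truth so that every stage is testable without external data. Defaults
mirror the learning-set shape of a real study: 38 positives, 82 negatives,
80 unlabeled; V = 300 families; 12 true topics of which 3 are phenotype
modules of sizes 18, 23 and 13 (echoing observed consensus-module sizes);
document lengths Poisson(150); counts capped at 10.

Module *carriage* is per document and per module: a positive document
carries each phenotype module independently with probability 0.95, a
negative one with probability 0.01; a carried module contributes Dirichlet
mass 4 to the document's topic prior, an uncarried one contributes none.
This design encodes three facts about the real system: degraders do not
all carry every module (observed per-module recalls run from ~58 % to
~92 %); a few non-degraders do carry module-like family sets (observed
precisions sit below 100 %); and module combinations vary across genomes
— which is also what makes the modules statistically identifiable. Two
simpler designs fail measurably and are documented here as negative
results: a global enrichment multiplier with a non-negligible baseline lets
heavy-tailed small-α Dirichlet draws hand occasional negatives a complete
module (uncontrolled false positives), while a negligible baseline makes
all positives carry all modules jointly, removing the document-level
variation LDA needs and merging the planted topics.

What a green recovery test establishes: on well-separated corpora of this
size, the full pipeline (fit → extract → rank → consensus) returns the
planted family sets as its top-ranked consensus modules (Jaccard ≥ 0.8)
and they classify the phenotype with LOO $F_{0.5} \ge 0.9$. What it does
not establish: performance under annotation noise correlated with
phylogeny, unmodeled family co-occurrence outside modules, database-bias
effects, or paper-scale settings (T = 400, 18 runs, thousands of genomes)
— the synthetic corpus has none of these features.

The gene-table generator plants clusters satisfying the detection criteria
and decoys violating exactly one criterion each (an oversized gap, too few
genes, or a single distinct family), every layout on its own replicon, so
detector output can be compared to construction truth exactly.

## Numerical and design choices

* Ranking ties: equal-$F$ modules are ordered by topic index (stable,
  deterministic); equal-$F$ thresholds resolve to the largest γ.
* `optimize_threshold` is exhaustive over observed weights — the tests
  re-scan all candidates independently to assert no candidate is skipped.
* `sym_kl_distance` refuses zero entries rather than smoothing silently;
  β-smoothed $\varphi$ estimates are strictly positive by construction.
* Hungarian matching is implemented in compiled code (shortest augmenting
  paths with potentials, $O(n^3)$) and is checked against exhaustive
  permutation search; maximal cliques delegate to `igraph::max_cliques`
  and are checked against subset enumeration.
* Degenerate cases are defined, not errored: F with TP = 0 is 0; the
  Jaccard distance of two empty sets is 0; empty modules weigh 0
  everywhere; empty documents are retained (sparse bins are real).
* Multiple runs derive per-run seeds as `seed + run_index − 1`; runs are
  sequential but independently reproducible, so a parallel executor may
  compute them in any order.
* Serialization: corpora as TSV with a JSON header (round-trip identity is
  tested), models as JSON at full double precision, configs as JSON (YAML
  is deliberately unsupported — no parser in the supported dependency
  set).

## Known limitations

* Consensus at small R is brittle by construction: 6 runs at 75 %
  stringency tolerate a single poorly converged chain; occasional planted
  modules are lost on unlucky seeds (about one in twenty at test scale).
  The production setting (18 runs, tolerance 4) is correspondingly more
  robust.
* Within-run topic duplicates are a posterior property when T exceeds the
  effective topic count; the threshold edge rule absorbs them at the
  consensus stage but single-run rankings can still show a module split
  across two ranked topics.
* The CV interval treats `round(mean accuracy × n)` of n as binomial
  successes; repeats are not independent, so the interval is approximate
  by design, matching the summary style it reproduces.
* The cap, counting unit (distinct proteins per family) and uniform
  application to both Pfam and CAZy families are package decisions where
  the source is silent or ambiguous; `count_unit = "annotation"` switches
  to domain-level counting.
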