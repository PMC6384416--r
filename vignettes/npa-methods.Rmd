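---
title: "Scoring transcriptomic contrasts on causal network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transcriptomic contrasts on causal network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbnpa)
```

## The problem

Causal biological network (CBN) models encode mechanistic knowledge — for
example of mucociliary clearance in the airways — as signed, directed graphs
whose nodes are biological entities (proteins, activities, processes) and
whose edges are causal statements curated from the literature in the
Biological Expression Language (BEL). Such models have two layers:

* a **backbone** of non-measurable entities connected by signed causal
  edges, and
* a **downstream layer** of signed links from backbone nodes to measurable
  transcripts, encoding the expected transcriptional consequence of each
  backbone entity's activity.

Given a differential-expression contrast (per-gene log2 fold-change
$\beta_g$ with variance), the **network perturbation amplitude (NPA)**
summarizes how strongly, and through which nodes, the contrast perturbs the
model. `cbnpa` implements the whole pipeline: BEL-subset parsing and
compilation, layer splitting and trimming, backbone inference, scoring,
companion permutation statistics, and leading-node decomposition, plus a
synthetic-data generator with known ground truth.

## The model

### Backbone inference

Let the backbone have nodes $x \in V_b$, undirected signed edges
$(x, y, \sigma_{xy}, w_{xy})$, and matched downstream edges
$(x, g, s_{xg}, w_{xg})$. The inferred differential values $f$ minimize

$$
\sum_{(x,y)} w_{xy}\,(f_x - \sigma_{xy} f_y)^2
+ \sum_{(x,g)} w_{xg}\,(f_x - s_{xg}\beta_g)^2
+ \varepsilon \sum_x f_x^2 ,
$$

a signed harmonic extension of the data into the backbone: edges ask
adjacent nodes to agree up to sign, downstream edges anchor nodes to the
observed fold-changes, and the ridge $\varepsilon$ (default $10^{-10}$) is
numerical safety only. The unique minimizer is the closed form
$f = -L_{bb}^{-1} L_{bg} \beta$, where $L_{bb}$ and $L_{bg}$ are the signed
Laplacian blocks assembled by `assemble_system()`:
$L_{bb}[x,x]$ is the total absolute incident weight (backbone plus matched
downstream) plus the ridge, $L_{bb}[x,y] = -\sum \sigma w$ over edges
between $x$ and $y$, and $L_{bg}[x,g] = -s_{xg} w_{xg}$. Only *matched*
downstream edges (genes present in the expression table) enter the system;
connected components with no matched gene carry no information and are
dropped with a warning. $L_{bb}$ is positive definite on what remains,
which the code asserts via Cholesky and a condition-number guard
($\kappa > 10^{12}$ is an error).

Treating backbone edges as undirected for inference is deliberate:
information flows *backwards* from measured transcripts into their causal
ancestry, and a symmetric operator is what makes that diffusion well posed.
Edge direction is kept and used for trimming and display.

### The score and its decomposition

The default score is the **mean-square amplitude**

$$ \mathrm{NPA} = \frac{1}{|V_b|} \sum_x f_x^2 , $$

with per-node contributions $f_x^2 / |V_b|$ that are non-negative and sum
exactly to the score. An alternative quadratic form, the backbone-only
signed Laplacian $\frac{1}{|V_b|} f^\top \tilde L f$, is available via
`mode = "backbone-laplacian"`; its contributions
$f_x (\tilde L f)_x / |V_b|$ may be negative, which the result flags. The
exact quadratic form used by other NPA implementations is not uniquely
documented, so both modes are labelled explicitly in every output and the
mean-square form — the simplest one satisfying the invariances below — is
the default.

Properties that the test suite enforces rather than assumes:

* **gauge invariance** — negating all signs incident to a node set $S$
  negates $f$ on $S$ and leaves the score unchanged;
* **homogeneity** — scaling $\beta$ by $c$ scales the score by $c^2$;
* **conservation** — contributions sum to the score;
* **oracle equivalence** — the closed form agrees with direct numerical
  minimization of the objective above (an independent conjugate-gradient
  minimizer working only from the term-wise gradient) to machine precision.

**Leading nodes** are the shortest prefix of nodes, ordered by absolute
contribution (ties broken by node id), whose cumulative share reaches 80%
of the total — the set "carrying" the perturbation, each annotated with its
inferred direction ($\mathrm{sign}(f_x)$, zero below $10^{-12}$).

### Confidence interval

Per-gene variances are propagated to the score by the first-order delta
method: with $M = -L_{bb}^{-1} L_{bg}$,
$\mathrm{Var}(\mathrm{NPA}) \approx \sum_g (\partial\,\mathrm{NPA} /
\partial \beta_g)^2 \mathrm{Var}(\beta_g)$, giving
$\mathrm{NPA} \pm z_{0.975}\sqrt{\mathrm{Var}}$ at the default 95% level.
The gradient is validated against central finite differences of the full
pipeline. How the original analyses computed their intervals is not
documented; the delta method is the default here, and a Monte-Carlo
alternative (resampling $\beta^* \sim N(\beta, \mathrm{Var})$;
`ci_method = "montecarlo"`) is available when the quadratic nonlinearity or
near-zero scores make the linearization doubtful. The **star** flag marks
intervals excluding zero.

### O and K specificity statistics

A large score can be an artifact of scale. Two permutation nulls probe
specificity:

* **O** — permute gene labels across downstream slots (signs stay with the
  slot). Destroys the gene-to-backbone biology, preserves graph scale.
* **K** — permute backbone edge *heads* across edges (tails, signs and
  weights stay put), a tail-degree-preserving rewiring; self-loop draws are
  re-drawn up to 100 times, then accepted. Whether the historical K
  statistic preserved the degree sequence is not documented; the scheme
  used here is recorded in every result's metadata.

Each permutation re-runs the full assemble–infer–score pipeline with the
same expression table. The p-value uses the add-one estimator
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_{\mathrm{perm}} + 1)$,
which cannot return zero and is invariant under monotone transforms of the
scores. When at most 10,000 permutations exist, `exhaustive = TRUE`
enumerates them all for an exact p. Flags: *strong* at $p < 0.05$, *weak*
at $0.05 \le p < 0.1$. One master seed drives deterministic child streams
per statistic, so any fit is reproducible bit-for-bit from its seed (the
run manifests written by `run_score()`/`run_simulate()` record it).

## Model construction choices

* **Grammar subset.** Only entity-level terms — `p()`, `r()`, `a()`,
  `bp()`, `complex(NS:ID)`, `act()` — and the four causal relations are
  parsed; everything else (translocations, degradations, modifications,
  list-form complexes) is rejected with a position-carrying parse error.
  The models this package targets are built from entity-level causal
  relations; silently approximating richer constructs would corrupt them.
* **Activity collapse.** `act(p(X))` and `p(X)` denote the same backbone
  entity for scoring, so activity wrappers collapse to the inner entity for
  node identity and are recorded per edge as `via_activity`. How published
  backbones merged activities with their parent entities is not stated
  anywhere we could verify; this rule is this package's choice.
* **Duplicates and contradictions.** Same-sign parallel statements merge
  into one edge with an evidence count; opposite-sign edges between the
  same pair coexist (contradictory findings are retained without
  preferential treatment). Edge weight stays 1 regardless of evidence
  volume by default (`weight_by_evidence = TRUE` opts out) — evidence
  volume reflects publication intensity, not effect size.
* **Trimming** removes backbone nodes with no *directed* path to any
  biological-process node ("hanging" nodes that do not lead to a process
  described in the model), iterated to a fixpoint; `undirected = TRUE`
  relaxes this. Process nodes always survive.
* **Probe collapse.** Expression tables must have one row per symbol;
  `collapse_probes()` averages probe-level $\beta$ and takes
  mean(variance)/n, the variance of the mean under independence.

## The synthetic generator

`generate_model()` draws a uniform random spanning tree (random Prüfer
sequence) on `n_backbone` nodes plus extra distinct edges — connected by
construction — signs $-1$ with probability `p_negative`, random edge
orientations, one node designated a bioprocess so trimming is exercisable,
and `genes_per_node` unique transcripts per node with equiprobable signs.
True node effects are i.i.d. $N(0, \mathrm{effect\_sd}^2)$ by default;
`coherent = TRUE` instead propagates a root value of magnitude `effect_sd`
through the edge signs, giving a maximally network-consistent truth.
`simulate_expression()` then sets
$\beta_g = s_{xg} f^{\mathrm{true}}_x + N(0, \mathrm{noise\_sd}^2)$.

Default conditions (chosen once as representative of a mid-sized curated
model and used throughout the statistical suites): `n_backbone = 30`,
`n_edges = 60`, `genes_per_node = 10`, `p_negative = 0.3`,
`effect_sd = 1` (a two-fold change on the log2 scale), `noise_sd = 0.2`
for recovery and `0.1` for power (tight replicate noise), `noise_sd = 1`
for the null calibration.

What the generator deliberately does **not** emulate: probe-level
artifacts, batch effects, correlated noise across genes, hub-heavy degree
distributions of curated networks, or moderated-statistics estimation of
$\beta$ — the pipeline consumes $(\beta, \mathrm{Var})$ regardless of
origin, and the upstream microarray processing is out of scope. Passing the
synthetic suites therefore demonstrates the *statistical machinery* is
correct and calibrated, not that any particular biological model is.

### What the suites check

* **Calibration** (500 null datasets, 200 permutations each): the fraction
  of $p_O < 0.05$ under pure noise must sit in $[0.03, 0.07]$ — the
  permutation null is exchangeable under the global null, so $p_O$ is
  uniform up to discreteness.
* **Power and specificity** (100 runs): with a *coherent* truth of effect 1
  and noise 0.1, $p_O$ and $p_K$ are below 0.05 in at least 95% of runs on
  the generating model, while the same signal re-labelled onto an
  independently generated, gene-disjoint decoy model leaves $p_O \ge 0.05$
  in at least 90% of runs. Coherent truth matters for K specifically:
  i.i.d. node effects carry no information about backbone wiring, so no
  statistic could (or should) detect rewiring under them — a coherent
  effect is precisely the signal the wiring predicts. The decoy is the
  synthetic analogue of a contrast perturbing the model it targets but not
  an unrelated one.
* **Recovery** (20 replicates at noise 0.2): mean Pearson correlation
  between true and inferred backbone values of at least 0.9.

Replicate and permutation counts (500/100/20 datasets, 200 permutations)
are the package's chosen benchmark sizes: large enough that the binomial
noise on each rate is well inside the asserted bands, small enough to run
routinely. `run_benchmark()` executes reduced versions of all suites;
`scripts/acceptance.R` in the source repository runs the full versions and
writes the numbers as JSON.

## Worked example

A two-node chain with one measured transcript per node:

```{r toy}
net <- compile_network(parse_script(c(
  "p(HGNC:X) increases p(HGNC:Y)",
  "p(HGNC:X) increases r(HGNC:G1)",
  "p(HGNC:Y) decreases r(HGNC:G2)")))
model <- split_layers(net)
expr <- expression_table(c("G1", "G2"), beta = c(2, -2), variance = c(1, 1))
fit <- npa(model, expr, seed = 1, exhaustive = TRUE)
fit
coef(fit)
```

G1 up by 2 and G2 down by 2 are exactly what a coherent $f = (2, 2)$
predicts, so the mean-square score is 4 and both nodes contribute equally.
With only two downstream slots the exhaustive O null has two permutations,
both scoring 4, hence $p_O = 1$: a two-gene model cannot demonstrate
specificity, only magnitude.

A synthetic end-to-end run with known truth:

```{r synth}
truth <- generate_model(synth_config(n_backbone = 12, n_edges = 18,
                                     genes_per_node = 5, noise_sd = 0.2),
                        seed = 7, coherent = TRUE)
expr <- simulate_expression(truth, seed = 8)
fit <- npa(truth$model, expr, n_perm = 200, seed = 9)
fit
recovery_metrics(truth$f_true[names(coef(fit))], coef(fit))
head(fit$leading, 4)
```

## Numerical notes and limitations

* Ridge $10^{-10}$ and the $10^{12}$ condition guard are safety rails, not
  tuning knobs; a well-posed model (every component measured) never
  approaches them.
* Direction calls use a $10^{-12}$ zero tolerance on $f$.
* Ties in contribution ranking break by node id, making leading sets and
  degree tables deterministic.
* Unscoreable permuted models (a permutation stranding a component without
  genes) are re-drawn, up to $10 \times n_{\mathrm{perm}}$ redraws.
* The K statistic's power depends on the signal being network-coherent; on
  incoherent signals K is (correctly) uninformative.
* Scores across models of different size or downstream coverage are not
  directly comparable; the O/K statistics and the star flag are the
  intended basis for cross-model statements.
* Confidence intervals are first-order; near score zero the quadratic
  makes them conservative. Use the Monte-Carlo interval when that matters.
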