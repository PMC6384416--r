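# cbnpa — network perturbation amplitude scoring on causal network models

`cbnpa` is for systems biologists who keep mechanistic knowledge as causal
network models — signed graphs of proteins, activities and processes curated
in the Biological Expression Language (BEL) — and want to ask, for a given
differential-expression contrast: *how strongly does this contrast perturb
the model, is the response specific to the model's biology, and through
which nodes does it act?*

The package implements the full pipeline around the **network perturbation
amplitude (NPA)**:

* a restricted BEL 1.0 parser and compiler (entity-level terms, four causal
  relations, annotation state, evidence merging, contradictions retained),
  plus node-link JSON and edge-TSV graph formats;
* **two-layer model construction**: RNA nodes are split out of the backbone
  into a downstream layer of signed node-to-transcript links; hanging nodes
  (no directed path to a biological process) are trimmed; degree/hub tables
  and component diagnostics;
* **backbone inference**: the differential values `f` minimize the signed
  harmonic-extension objective
  `Σ_edges w (f_x − σ f_y)² + Σ_downstream w (f_x − s·β_g)²`, solved in
  closed form as `f = −L_bb⁻¹ L_bg β` with signed-Laplacian blocks;
* **scoring**: mean-square amplitude `NPA = |V_b|⁻¹ Σ f_x²` (default; a
  backbone-Laplacian quadratic form is available), an exact per-node
  contribution decomposition, delta-method or Monte-Carlo confidence
  intervals, and the **leading nodes** — the smallest node set carrying 80%
  of the score, with inferred directions;
* **O/K specificity statistics**: permutation nulls that shuffle the
  downstream gene assignment (O) or rewire backbone edge heads (K), with
  add-one p-values, exhaustive enumeration for small models, and
  strong/weak significance flags at 0.05/0.1;
* a **synthetic-data generator** with known ground truth, powering
  calibration, power/specificity and parameter-recovery benchmarks.

## Worked example

A small synthetic airway-mucus cascade ships with the package
(`example_model.bel`, an invented demonstration model, with a matching
expression table):

```r
library(cbnpa)

net <- read_network(system.file("extdata", "example_model.bel", package = "cbnpa"), "bel")
net
#> <causal_network> 10 nodes, 11 edges
#>   kinds: bioprocess=1, protein=4, rna=5

model <- split_layers(net, name = "example")
model
#> <two_layer_model> 'example': 5 backbone nodes, 5 backbone edges, 6 downstream edges (5 genes)

expr <- read_expression(system.file("extdata", "example_expression.tsv", package = "cbnpa"))
fit <- npa(model, expr, n_perm = 200, seed = 1)
fit
#> Network perturbation amplitude (mean-square)
#>   model: 'example' (5 backbone nodes, 6 downstream edges, coverage 100%)
#>   NPA = 1.911  [1.261, 2.56] (95% CI, delta)  *star* (O n.s.) (K n.s.)
#>   O statistic p = 0.1692
#>   K statistic p = 0.1841
#>   leading nodes: 4 of 5 (80% cumulative contribution)

round(coef(fit), 3)
#> bp(GO:"mucus secretion")             p(HGNC:EGFR)            p(HGNC:FOXA2)
#>                    1.391                    1.412                   -1.354
#>            p(HGNC:MAPK1)            p(HGNC:SPDEF)
#>                    1.324                    1.429
```

Reading this: the mucin transcripts are up and the FOXA2 target SCGB1A1 is
down, which the model explains as EGFR→MAPK→SPDEF activation with FOXA2
repression (`f` positive everywhere except FOXA2), a mean-square amplitude
of 1.91 whose 95% interval excludes zero (`*star*`). With only five
backbone nodes and six downstream slots, however, the O and K permutation
nulls cannot separate this response from a relabelled one (p ≈ 0.17) —
specificity claims need models and gene sets of realistic size, which is
exactly what the synthetic benchmarks use. `fit$leading` lists the leading
nodes (here 4 of 5 nodes carry 80% of the score, SPDEF first);
`plot(fit)` draws the signed contribution bars.

Model-level utilities:

```r
run_describe(system.file("extdata", "example_model.bel", package = "cbnpa"))
trim_dangling(model)         # remove nodes that do not lead to a process
degree_table(model$backbone) # hub table
validate_model(model)        # component/coverage diagnostics
```

Synthetic ground-truth studies:

```r
truth <- generate_model(synth_config(n_backbone = 30, n_edges = 60,
                                     genes_per_node = 10), seed = 1)
expr  <- simulate_expression(truth, seed = 2)
fit   <- npa(truth$model, expr, n_perm = 200, seed = 3)
recovery_metrics(truth$f_true, coef(fit))
run_benchmark(seed = 1)      # calibration / power / specificity / recovery
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/npa.R` (subcommands `describe`, `trim`, `score`, `simulate`,
`benchmark`; every scoring or simulation run writes a manifest from which
it can be reproduced bit-for-bit).

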