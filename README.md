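# fedlung

A desk-scale simulator of hierarchical federated learning (FL) for
three-way lung nodule classification — **normal** (no positive region of
interest), **benign** (a positive RoI with a smooth, non-expanding
boundary) and **malignant** (a positive RoI with spiculated, active
growth). The package is aimed at anyone who wants to study, test or teach
the mechanics of threshold-filtered federated averaging on a medical
imaging task without access to clinical data: everything runs from
synthetic CT-like slices, deterministically, on one CPU.

## What it implements

* **Synthetic cohort** — 64×64 grayscale slices in the three classes,
  with nodule boundaries rasterized from
  r(θ) = r₀(1 + a·Σₖ sin(kθ + φₖ)), plus extraction of the 8-dimensional
  feature vector Pa ⊕ Pd: physical attributes (density, mass,
  orientation, weight) and digital attributes (pixel ratio, growth
  pattern = P²/4πA boundary irregularity, pixel intensity, expansion
  density).
* **Federation topology** — clients Sᵢ assigned round-robin to routing
  servers SRₖ under a central server SX; IID or Dirichlet label-skew
  data partitioning.
* **Local model** — a seeded multilayer perceptron (8 → 16 → 3, flat
  parameter vector) trained by plain mini-batch gradient descent on
  softmax cross-entropy.
* **DNT aggregation** — per-round client validation scores split by
  attribute group (v = (v_Pa + v_Pd)/2) recorded in the append-only
  validation matrix R; Distributed Network Thresholding admission
  (`off`, `absolute` v ≥ τ, or `robust` v ≥ median − z·MAD); federated
  averaging θ ← Σwᵢθᵢ / Σwᵢ router-wise, then centrally.
* **Evaluation** — 3×3 confusion matrices (rows = truth), accuracy,
  per-class and macro sensitivity/specificity (one-vs-rest), the
  published centralized/decentralized confusion-table fixtures, a
  centralized-vs-decentralized harness, and a node-scaling harness over
  the ladder {5, 10, 20, 40, 80, 160}.

See `vignettes/fedlung-methods.Rmd` for the model, the design decisions
and the known discrepancies in the published tables the fixtures
preserve.

## Worked example

```r
library(fedlung)

cohort <- generate_cohort(50, seed = 42)
cohort
#> Synthetic nodule cohort: 50 cases (seed 42 )
#>    normal    benign malignant
#>        17        17        16

sp <- split_cohort(cohort, 0.6, seed = 7)        # stratified 60/40
fed <- run_federation(sp$train, sp$test, n_clients = 5, rounds = 10,
                      cfg = training_config(epochs = 30),
                      policy = dnt_policy("robust", z = 2))
fed
#> Federation result: 10 rounds, 5 clients
#> final test accuracy: 1
tail(fed$history, 3)
#>    round test_accuracy n_admitted fallback aggregate_norm
#> 8      8             1          5    FALSE       4.224415
#> 9      9             1          5    FALSE       4.287953
#> 10    10             1          5    FALSE       4.341429
round(fed$R$v[8:10, ], 3)       # validation matrix R, last three rounds
#>          client_0 client_1 client_2 client_3 client_4
#> round_8     0.917    0.917    0.917    0.917        1
#> round_9     0.917    0.917    0.917    0.917        1
#> round_10    0.917    0.917    0.917    0.917        1
```

The 50-case cohort splits into 30 training and 20 test cases; all five
clients clear the robust threshold every round (`n_admitted = 5`, no
fallback), and the aggregated model separates the three synthetic classes
perfectly on the held-out slices. Each cell of `fed$R$v` is a client's
combined calibration score v for that round.

The shipped fixture of the federated testing confusion table and its
metrics:

```r
cm <- load_paper_table("T2_test")
cm
#>           normal benign malignant Total
#> normal        16      3         0    19
#> benign        12     18         4    34
#> malignant      6     13        18    37
#> Total         34     34        22    90
cm_metrics(cm)
#> accuracy 0.5778 | macro sensitivity 0.6193 | macro specificity 0.7951
```

The accuracy printed here is the cell arithmetic 52/90; the discrepancy
with the 89.63 % figure published alongside that same table is
documented, not repaired (see the methods vignette).

## Command line

A thin CLI over the package functions ships in `inst/cli/fedlung.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fedlung.R",package="fedlung"))')" \
    run --config experiment.yaml --out out_dir
```

Subcommands: `generate` (cohort → PNGs + CSV manifests), `run` (federated
experiment → R matrix, history, params, metrics), `compare`
(centralized vs decentralized), `scale` (node ladder), `metrics`
(report from a confusion-matrix CSV). Configuration is YAML with explicit
seeds for every randomness source; `resolve_config()` shows the defaults.

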