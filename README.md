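# drugrules

Drug-likeness rule violation counters and Random Forest surrogates for
peptide screening.

## What this is for

Early-stage triage of candidate molecules — peptides in particular —
against empirical oral-bioavailability filters. Classical heuristics were
built for small molecules; peptides routinely break them while still
being orally developable, so the package implements three filters side by
side and works with the *number of criteria violated* rather than a
pass/fail flag:

| Rule | Criteria | Max count |
|---|---|---|
| Ro5 (Lipinski) | Mw ≤ 500 Da, logP ∈ [0, 5], HBD ≤ 5, HBA ≤ 10 | 4 |
| bRo5 (peptide extension) | Mw ≤ 1000 Da, logP ∈ [−2, 10], HBD ≤ 6, HBA ≤ 15, TPSA ≤ 250 Å², NRotB ≤ 20 | 6 |
| Muegge (core-6 / full) | Mw ∈ [200, 600], logP ∈ [−2, 5], TPSA ≤ 150, NRotB ≤ 15, HBA ≤ 10, HBD ≤ 5 (+ rings ≤ 7, C > 4, heteroatoms > 1) | 6 / 9 |

HBD counts N–H plus O–H hydrogens (nOH + nNH), HBA counts N plus O atoms
(nO + nN); logP is Wildman–Crippen, TPSA is Ertl's fragment method, and
rotatable bonds are acyclic single bonds between non-terminal heavy atoms
excluding amide C–N. Boundary values comply; a criterion is violated only
by a strict inequality.

Around the counters sits a surrogate-modelling experiment: Random Forest
classifiers and regressors (10/20/30 trees, library-default
hyperparameters) trained to predict violation counts from either the
nine-descriptor vector or a Morgan-style circular fingerprint, on
synthetic descriptor tables drawn to cover every threshold. Since labels
are a deterministic function of the descriptors, descriptor-based
surrogates should recover the counters almost exactly — a falsifiable
claim the test suite verifies — while fingerprint-based ones lag, which
is the experiment's point. Micro-averaged multiclass metrics, pooled
one-vs-rest ROC/AUC, scatter exports and a reference-comparison module
(exact / off-by-one / missing accounting against SwissADME-style CSV
exports) complete the pipeline.

## Worked example

```r
library(drugrules)

mols <- read_molecule_csv(system.file("extdata", "example_molecules.csv",
                                      package = "drugrules"))
tab <- descriptor_table(parse_molecules(mols))
tab[, c("id", "mw", "logp", "hbd", "hba", "tpsa", "n_rotb")]
#>                     id     mw   logp hbd hba   tpsa n_rotb
#> 1              aspirin 180.16  1.310   1   4  63.60      3
#> 2             caffeine 194.19 -1.029   0   6  61.82      0
#> 3            ibuprofen 206.28  3.073   1   2  37.30      4
#> 4              glycine  75.07 -0.270   3   3  63.32      1
#> 5       leu_enkephalin 392.45  1.277   6   9 150.62     11
#> 6 cyclosporin_fragment 315.41  1.962   5   7 121.52      9

data.frame(id     = tab$id,
           ro5    = count_violations_table(tab, builtin_ruleset("ro5")),
           bro5   = count_violations_table(tab, builtin_ruleset("bro5")),
           muegge = count_violations_table(tab, builtin_ruleset("muegge")))
#>                     id ro5 bro5 muegge
#> 1              aspirin   0    0      1
#> 2             caffeine   1    0      1
#> 3            ibuprofen   0    0      0
#> 4              glycine   1    0      1
#> 5       leu_enkephalin   1    0      2
#> 6 cyclosporin_fragment   0    0      0
```

Caffeine and glycine each pick up one Ro5 violation from the lower logP
bound (both have negative logP); the tetrapeptide leu-enkephalin breaks
the Ro5 donor limit but clears every bRo5 threshold — exactly the pattern
the peptide-adapted rule exists to capture. Muegge's lower weight bound
(Mw ≥ 200) flags the small molecules instead.

Training a surrogate and using it on the same molecules:

```r
cfg   <- sampler_config(20000, seed = 7, stratify_rule = "ro5")
ds    <- build_dataset_from_descriptor_table(sample_descriptor_vectors(cfg),
                                             builtin_ruleset("ro5"))
parts <- split_dataset(ds, split_spec(0.2, 42))
model <- train_model(parts$train,
                     model_spec("classifier", "ro5", n_trees = 20, seed = 1))
evaluate_model(model, parts$test)$metrics[c("accuracy", "auc_micro")]
#> held-out micro accuracy: 0.9998  (AUC 1.0000)

data.frame(id = tab$id,
           oracle    = count_violations_table(tab, builtin_ruleset("ro5")),
           predicted = predict_counts(model, tab[descriptor_keys()]))
#>                     id oracle predicted
#> 1              aspirin      0         0
#> 2             caffeine      1         1
#> 3            ibuprofen      0         0
#> 4              glycine      1         1
#> 5       leu_enkephalin      1         1
#> 6 cyclosporin_fragment      0         0
```

A shell entry point (`exec/drugrules`) exposes the same pipeline as
subcommands: `descriptors`, `count`, `simulate`, `train`, `predict`,
`evaluate`, `compare` and `reproduce` (the seeded end-to-end parity run).

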