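---
title: "Drug-likeness rule counters and their Random Forest surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-likeness rule counters and their Random Forest surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugrules)
```

## The problem

Early drug-likeness triage asks a simple question of every candidate
molecule: how many criteria of an empirical oral-bioavailability filter
does it break? Classical small-molecule heuristics travel badly into
peptide space -- peptides are heavy, hydrophilic and flexible -- so this
package implements three filters side by side and treats the *violation
count* as the central quantity:

* **Ro5** (Lipinski's Rule of Five): Mw $\le$ 500 Da, logP $\in [0, 5]$,
  HBD $\le$ 5, HBA $\le$ 10. Four criteria, so counts run 0--4.
* **bRo5** (beyond Rule of Five), the peptide-oriented extension:
  Mw $\le$ 1000 Da, logP $\in [-2, 10]$, HBD $\le$ 6, HBA $\le$ 15,
  TPSA $\le$ 250 Å², rotatable bonds $\le$ 20. Counts 0--6.
* **Muegge's criteria**: Mw $\in [200, 600]$, logP $\in [-2, 5]$,
  TPSA $\le$ 150, rotatable bonds $\le$ 15, HBA $\le$ 10, HBD $\le$ 5,
  plus -- in the `full` variant -- rings $\le$ 7, carbons $>$ 4 and
  heteroatoms $>$ 1.

On top of the deterministic counters the package trains Random Forest
*surrogates* (classifiers and regressors with 10, 20 or 30 trees) that
predict the counts from either the physicochemical descriptor vector or a
Morgan-style circular fingerprint. Because the labels are a deterministic
function of the descriptors, a descriptor-based surrogate that has seen
enough of the space should recover the counter almost exactly -- a
falsifiable prediction the test suite checks -- while a fingerprint-based
surrogate must infer physicochemistry indirectly from substructures and
is expected to do visibly worse. That contrast, not raw screening speed,
is what makes the surrogate experiment informative.

## Rule sets as data

Rule sets are ordered lists of inclusive interval criteria over named
descriptors. A criterion is violated iff the value falls *strictly*
outside its interval, so a molecule sitting exactly on a threshold
complies; this "$\le$ as printed" reading is applied uniformly because the
filters are stated with non-strict inequalities. Rule sets serialize to
JSON and carry a stable MD5 fingerprint that is embedded in every dataset
and model artifact, so a model can refuse labels produced under different
thresholds.

Two genuinely open choices are exposed as options rather than hard-coded:

* **Ro5 lower logP bound.** The rule as stated bounds logP below by 0,
  but popular web platforms only penalise logP $>$ 5. The bound defaults
  **on** here; `builtin_ruleset("ro5", ro5_logp_lower = FALSE)` reproduces
  the platform convention. For hydrophilic molecules (glycine, large polar
  peptides) the two conventions differ by exactly one violation, which is
  the signature to look for when model predictions sit one above a
  platform's numbers.
* **Muegge variant.** The six property criteria (`core6`) are the default
  training target; the `full` nine-criterion variant adds the
  topological/elemental checks and matches what SwissADME evaluates. A
  counter trained on `core6` systematically undercounts relative to a
  `full` evaluation by construction -- up to the three extra criteria --
  which is the expected direction of disagreement when comparing against
  SwissADME-style references.

## Descriptors

Nine descriptors feed the counters: Mw, logP, HBD, HBA, TPSA, rotatable
bonds, carbon count, heteroatom count and ring count. Parsing and the
continuous properties come from OpenBabel: molecular weight from the
standard atomic-weight table, logP by the Wildman--Crippen
atom-contribution method and TPSA by the Ertl fragment method. The
counting descriptors are computed in package code from the
hydrogen-explicit molecular graph, because the filters define donors and
acceptors by *counting*, not by pharmacophore perception:

* HBD = number of N--H plus O--H hydrogens (glycine: 3);
* HBA = number of N plus O atoms (glycine: 3);
* ring count = smallest set of smallest rings (edges $-$ vertices $+$
  components of the molecular graph);
* rotatable bonds = acyclic single bonds between two non-terminal heavy
  atoms, excluding amide C--N. Only the amide exclusion is applied; some
  toolkits additionally exclude ester single bonds, so aspirin counts 3
  here against RDKit's 2. The tests pin this choice.

Multi-fragment inputs (salts) are reduced to the largest carbon-containing
fragment before anything is computed, so counterions cannot inflate Mw or
HBA; the number of dropped fragments is recorded per molecule.

One caveat deserves emphasis: Wildman--Crippen logP is a method, not a
number. OpenBabel's and RDKit's implementations agree closely on small
molecules but diverge on peptide amide nitrogens (by 1--2 log units on a
tetrapeptide). The estimator is therefore recorded in dataset and model
provenance, and absolute logP values from different toolkits should never
be mixed in one dataset. This is also the main reason independent
platforms disagree with each other near rule boundaries.

Fingerprints are OpenBabel ECFP vectors (radius $r$ maps to ECFP$2r$),
natively 4096 bits and folded by bitwise OR to the requested power-of-two
width. Defaults are radius 2, 2048 bits -- the common ECFP4 setting --
and are recorded in model metadata.

## Synthetic training data

The surrogate experiment needs broad coverage of descriptor space, not
chemical realism. The sampler draws each descriptor independently and
uniformly: Mw in [50, 2000] Da, logP in [-8, 12], HBD 0--30, HBA 0--40,
TPSA in [0, 600] Å², rotatable bonds 0--50, carbons 1--120, heteroatoms
0--60, rings 0--12; count descriptors are integers. The intervals bracket
every built-in threshold with generous margins so that each criterion is
exercised on both sides.

Independent draws deliberately ignore the strong correlations of real
chemistry (Mw with HBA, TPSA with heteroatoms, and so on). For learning
axis-aligned threshold logic this is a feature: independence maximises
coverage of every decision boundary. It also bounds what a green test
proves -- surrogate fidelity on this distribution demonstrates that the
models recover the counters' logic, not that they have seen anything like
a natural product library. The peptide assembler (below) provides the
chemically structured counterpart.

Unstratified sampling leaves the all-compliant class vanishingly rare
(about $3 \times 10^{-4}$ for the six Muegge criteria), so the sampler
supports stratification on one rule: batches are drawn until every
violation class $0..k$ holds at least $\lfloor n / (2(k+1)) \rfloor$
rows. After the first batch only rows of still-deficient classes are
retained and batch sizes adapt to the observed class rates, which keeps
memory flat even when tens of millions of candidate rows are needed; a
bounded attempt count turns an unsatisfiable configuration into an error
rather than a hang. Given a seed, the emitted table is byte-identical
across runs.

The default study scale is 200,000 rows per rule with an 80/20 split
(split seed 42), mirroring the order of magnitude of a curated compound
library at desk scale. The surrogate-fidelity property tests run at
100,000 rows -- the package's choice of the smallest scale at which the
off-boundary fidelity contract below holds with margin for all nine
rule-by-tree configurations.

The peptide assembler concatenates residue backbone fragments
(`N[C@@H](side chain)C(=O)`, glycine and proline special-cased) and caps
the C-terminus with a hydroxyl, yielding linear peptides over the 20
proteinogenic residues that are guaranteed parseable. It stands in for a
bench test set: labels remain computed by the counters.

## Models

Forests are fitted with ranger under library-default hyperparameters
(the protocol's grid search over `max_features` and leaf/split minima
found defaults best, and defaults keep the surrogate claim clean).
Classifiers train on the count as a factor with the full level set
`0..max`, so a class absent from the training rows is still
representable. Two numerical choices matter for reproducibility:

* **Tie-breaking.** ranger's own prediction aggregation breaks vote ties
  with a random seed drawn from the caller's RNG, which would make
  predictions depend on session state. Predictions here are aggregated
  from the per-tree votes directly, with ties resolved toward the smaller
  count; they are identical across calls and invariant to row order.
* **Regressor rounding.** The regressor's mean-of-trees output is turned
  into a count by rounding half away from zero and clipping to
  `[0, max]`: 2.5 predicts 3, $-0.3$ predicts 0. Any convention would do;
  this one is symmetric around class midpoints and is pinned by tests.

Model artifacts are a serialized ensemble plus a human-readable JSON
sidecar (spec, feature names, thresholds fingerprint, provenance, and an
MD5 of the ensemble file); loading verifies the checksum so a swapped or
truncated artifact fails loudly.

The tested fidelity contract: on held-out synthetic rows farther than
0.5% of each descriptor's sampled range from every threshold, classifier
predictions match the counter oracle on at least 99.9% of rows for every
rule and tree count, and classifier and rounded regressor agree on at
least 99%. Errors concentrate in the thin boundary shells, where a
finite training sample cannot place the split exactly on the threshold --
which is also why accuracy grows with training size and why web platforms
disagree with each other in the same shells.

## Evaluation

All classification metrics are multiclass with **micro averaging**: the
one-vs-rest (instance, class) decisions are pooled over classes before
the binary formulas apply. For single-label multiclass data this forces
precision = recall = F1 = accuracy -- the reason a model's four metric
columns print identically -- and that identity is verified as a property
over random label vectors rather than assumed. Macro averaging is
available behind a flag.

ROC curves use the classifier's per-tree vote fractions as per-class
scores, binarized one-vs-rest and pooled into a single micro curve; the
AUC is the trapezoidal integral with threshold ties grouped. The pooled
sweep is cross-checked against an independent ROC implementation (pROC)
in the tests. R² uses the population variance, and a zero-variance truth
vector reports R² as undefined rather than 0.

## Comparing against reference platforms

`compare_predictions()` reproduces the bookkeeping used when predictions
are checked against external platforms: per-molecule signed deltas, exact
and off-by-one tallies, and -- importantly -- missing references (a
platform that cannot process a long SMILES) excluded from that source's
denominator rather than imputed. The signed-delta histogram makes
systematic one-violation biases visible at a glance: a counter with the
Ro5 lower logP bound on sits at $+1$ against a platform without it for
hydrophilic molecules, and a `core6` Muegge counter sits at $-1$ against
a nine-criterion evaluation.

## Degenerate inputs and edge cases

Unparsable SMILES name the offending molecule id and are reported, never
silently dropped; a batch in which every molecule fails is an error.
OpenBabel is lenient about some valence errors, so a handful of formally
invalid SMILES parse -- the parser contract is "sanitized or error", not
full valence audit. Empty datasets, single-row splits, zero-variance R²,
single-class training targets (warned, classifier still fits) and
corrupted model sidecars all have defined, tested behaviour.

## Known limitations

* Descriptor absolutes are estimator-specific; cross-toolkit comparisons
  of logP (and to a lesser degree Mw) shift molecules across rule
  boundaries. Counters are exact given descriptors; descriptors are not
  exact given a molecule.
* The synthetic sampler makes no claim of chemical realism (see above);
  a Gaussian-copula correlation option was considered and left out of
  scope to keep the default distribution interpretable.
* The fingerprint arm trains classifiers only; regressors on
  fingerprints were deliberately omitted from the protocol after the
  classifier results showed the representation does not carry the
  threshold information.
* No 3D conformers, no pKa/charge-state enumeration, no consensus logP,
  and no live queries to external platforms; reference comparisons read
  exported CSV files only.
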