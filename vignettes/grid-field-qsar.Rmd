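---
title: "Grid-field 3D QSAR, pharmacophore modelling and screening with fieldqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-field 3D QSAR, pharmacophore modelling and screening with fieldqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A congeneric series — compounds sharing a scaffold and differing in their
substituents — with measured inhibitory potencies (pIC50) is the classical
input of field-based 3D QSAR. The working assumption is that, once the
series is aligned on its common core, differences in potency are explained
by differences in the interaction fields the molecules project into the
space around them. `fieldqsar` implements that workflow end to end:
alignment, probe-interaction fields on a grid, descriptor selection, a
partial-least-squares (PLS) model, statistical validation, pharmacophore
perception, and library screening with activity prediction.

## The model

### Alignment and charges

Molecules are matched against a template substructure (VF2 subgraph
isomorphism on the element-labelled heavy-atom graph) and rigidly superposed
onto a reference compound by least squares (Kabsch). Congeners whose
template RMSD exceeds a cutoff (default 1.0 Å; the threshold is a free
parameter because no universal value exists) are excluded.

Partial charges are Gasteiger–Marsili PEOE: atomic electronegativity is
modelled as χ(Q) = a + bQ + cQ², charge flows across each bond from the
less to the more electronegative atom, damped by (1/2)^n in iteration n.
Six iterations (the conventional fixed point) are the default. Charges are
conserved exactly, so they always sum to the net formal charge, and they
depend only on the bond graph — hence they are invariant to atom reordering
and rigid motion.

### Fields

A rectangular grid covers the aligned series' bounding box plus a margin
(defaults: margin 5 Å, spacing 2 Å, giving O(10²–10³) points for drug-sized
ligands). At every point three probe energies are computed against all
atoms (hydrogens included):

* steric: Lennard-Jones 6–12 against an sp3 carbon probe
  (r_vdw 1.7 Å, ε 0.07 kcal/mol, Lorentz–Berthelot combination with a
  bundled per-element table);
* electrostatic: Coulomb, 332.063·q·q_probe/(ε_d·r) kcal/mol with probe
  charge +1 e and constant dielectric ε_d = 1.0;
* hydrophobic: a Gaussian-damped atomic hydrophobicity,
  h_atom·exp(−r²/2σ²) with σ = 1.5 Å and a coarse Crippen-type per-element
  contribution table. The literature names this field without fixing a
  functional form; the Gaussian envelope is this package's choice and is
  deliberately simple.

Lennard-Jones and Coulomb terms are truncated to ±30 kcal/mol (the usual
CoMFA convention) so grid points inside atoms stay finite; all stored
values obey the bound. Columns are named `S_k`, `E_k`, `H_k` where `k` is
the 1-based x-fastest linear grid index, and columns whose sample variance
falls below 0.1 (the "invariable columns") are removed before modelling.

### Model building

The activity column is pIC50. The test set either comes from the user
(mirroring manual selection) or from `activity_ranked_split()`, which keeps
the test set interpolative twice over: strictly inside the training
activity range, and restricted to compounds central in descriptor space
(leading principal components), with test activities spread evenly across
the range. Unicolumn statistics (average, max, min, sd, sum per set) and
the strict inequalities max(train) > max(test), min(test) > min(train)
document that choice.

Descriptor selection is stepwise-forward: starting from the empty model,
each step adds the descriptor that maximizes the leave-one-out
cross-validated q² of the fitted linear model, stopping at 4 descriptors
(the conventional cap) or when no addition improves q². Ties break toward
the lower column index, making selection deterministic. Because a linear
fit with as many PLS components as descriptors equals ordinary least
squares, the search scores candidates with the exact hat-matrix LOO
identity (PRESS residual e/(1−h)) rather than n refits.

The final fit is NIPALS PLS1 on centered (not autoscaled — all field
columns share kcal/mol units) training data; the component count is chosen
by LOO q² over 1..4 and the model is exported as its equivalent linear
equation (coefficients on the original descriptor scale plus intercept).
Per-descriptor contributions are reported as signed percentages
100·c_i·range_i / Σ|c_j·range_j| over the training range — the vendor
formula behind published contribution plots is unpublished, so this
transparent convention is used instead and absolute contributions sum
to 100.

### Validation

* q² (internal): every training compound is left out once, the model refit
  (selection frozen to the full-fit descriptors by default — the common
  commercial-tool practice; a reselect-per-fold strict mode exists), and
  q² = 1 − Σ(y−ŷ)²/Σ(y−ȳ_train)².
* pred_r² (external): same form over test compounds, with the
  **training-set mean** in the denominator — deliberately, as the defining
  formula states, although some tools use the test mean.
* Fit statistics: r² = 1 − SSE/SST, se = √(SSE/(n−k−1)),
  F = ((SST−SSE)/k)/(SSE/(n−k−1)).
* Y-randomization: activities are permuted over the training compounds
  (seeded), selection + fit rerun per permutation (100 by default), and
  each observed statistic h is summarized as Z = (h−μ)/σ against the
  random-model distribution, plus the best random value and an empirical
  one-sided p-value (#random ≥ h + 1)/(n+1) — reported instead of the
  vendor's opaque "alpha" values. Z-scores convert to percent area under
  the standard normal curve via 100·Φ(z). One subtlety deserves a
  deliberate choice: cross-validating after selecting descriptors on the
  full set is positively biased, so under the default (frozen-selection)
  protocol models refit on permuted activities still reach q² ≈ 0.2–0.6
  from selection bias alone — the Z-score and the empirical p-value remain
  meaningful because the observed model carries the same bias, but "random
  models score near zero" does not hold. `strict_cv = TRUE` switches every
  q² inside the comparison — observed and random alike — to
  reselect-per-fold leave-one-out, which removes the bias from both sides:
  randomized models then score near or below zero, as the no-predictivity
  question demands. The strict random distribution is heavy-tailed
  (occasional wildly negative q² on large descriptor pools can deflate the
  Z-score), so the default report keeps the frozen protocol and the strict
  flag answers the stricter question.

The conventional validity thresholds are r², q² > 0.6 and pred_r² > 0.5.

### Pharmacophore

Feature perception is rule-based (the rule set is an editable object):
donors (N/O with H, direction along the H), acceptors (N/O with a lone
pair; quaternary and amide N excluded), aromatic rings (5/6-rings whose
atoms either carry an in-ring double bond or contribute a lone pair;
centroid site with the ring normal as direction), hydrophobes (≥2
contiguous carbons touching only C/H; centroid site), and ionisable groups
by formal charge. Hypotheses are all 5-site combinations per active, keyed
by sorted type letters plus the intersite-distance vector binned at 1.0 Å
(canonicalized over within-type permutations); keys shared by at least
⌈0.9·n⌉ actives become common hypotheses, numbered `LETTERS.k` by
decreasing match count.

Scoring follows the survival form
S = W_site·S_site + W_vec·S_vec + W_vol·S_vol + W_sel·S_sel + W_rev^m −
W_E·ΔE + W_act·A: site score 1 − RMSD/tolerance (tolerance 2.0 Å), vector
score the mean |cosine| of matched direction vectors, volume score the
shared/union hard-sphere volume (1.7 Å heavy-atom spheres sampled on a
0.4 Å grid), selectivity the rarity −log10 of the key's frequency among
all enumerated combinations. The reversed-hypothesis term `W_rev^m` is
typographically ambiguous in the defining equation (exponent versus product
with an undefined score); it is implemented as a disabled-by-default
configurable term (W_rev = 0) rather than guessed semantics. ΔE defaults
to 0 for single-conformer input and W_act to 0, so survival is purely
geometric unless enabled.

### Screening

A library molecule matches a hypothesis when some type-respecting
assignment of its feature sites superposes onto the hypothesis sites with
RMSD ≤ tolerance; the minimizing assignment defines the align score, the
rigid transform into the training frame, vector and volume scores, and
fitness w₁(1 − align/tol) + w₂·vec + w₃·vol with default weights (1,1,1)
(the vendor fitness formula is unpublished; this linear convention is
stated in the report header). Matched molecules are carried into the
training frame, their grid descriptors computed, and activity predicted
with the QSAR model — including the published-equation fixture
`published_model()`. External (e.g. docking) scores enter only through
`merge_external_scores()`.

## The synthetic generator

`generate_congeneric_series()` emulates the study conditions: a
benzaldehyde-thiosemicarbazone scaffold with two phenyl attachment points,
16 common substituents, 33 compounds (a 28-compound training pool plus a
5-compound interpolative test set, echoing a 23/5 usable split after
train/test assignment), activities spanning roughly 5.3–7.6 pIC50 (spread
0.7, mean 6.5) planted as a linear function of four grid-field descriptors
plus Gaussian noise (default sd 0.2 pIC50, a typical assay-level error).

Planted descriptors are chosen for identifiability, which is the point of
planting: ground truth must be recoverable by the method under study.
Three filters implement that:

* truncation-saturated columns (values pinned at ±30 near atoms) are
  excluded — they behave like step functions with many near-duplicates;
* candidate columns must have no strong proxy anywhere in the matrix
  (max |cor| with any other column ≤ 0.75, relaxed only as far as a given
  geometry requires) and be mutually weakly correlated (|cor| < 0.3);
* coefficients carry geometrically decaying variance shares (2^−k,
  total spread 0.7), so a forward search meets the terms in order.

Each candidate set is then certified: emulating the default workflow
(interpolative split, selection on the training subset), forward selection
must recover the planted set exactly in the noiseless limit and keep
recovering at least 3 of 4 descriptors on three internal noise replicates.
The first certified set is planted; the realized truth (names,
coefficients, intercept, noise sd) is serialized beside the data so tests
never re-derive it.

What the generator does **not** emulate: conformational flexibility (one
deterministic conformer per molecule), activity cliffs, correlated or
heteroscedastic assay error, measurement censoring, and any receptor-side
effect. Passing tests on synthetic data therefore demonstrate that the
pipeline recovers a planted linear field-activity relationship under the
stated noise — not that any real series obeys one.

## Numerical choices

* 3D embedding of SMILES uses RDKit ETKDGv3 with a fixed per-record random
  seed plus a bounded (500-iteration) MMFF94 cleanup, through a bundled
  helper script; embedding is byte-deterministic for a fixed seed.
* Grid points coincident with atoms are clamped to r = 1e-6 Å before the
  energy evaluation and then truncated, never infinite.
* NIPALS stops early when the residual X'y norm falls below 1e-12 (the
  constant-response case returns the flat model: zero coefficients,
  intercept ȳ).
* Stepwise ties (identical q² gains, e.g. duplicated columns) resolve to
  the lower column index; improvement must exceed 1e-12 to continue.
* A perfect fit reports F as +Inf rather than failing; a zero randomized
  spread reports Z as +Inf with a warning.
* Degenerate LOO folds (hat value within 1e-10 of 1) score −Inf and are
  never selected.

## Problem sizes

The bundled analysis and the test suite run the full chain at 33 compounds,
~750 grid points (≈2 250 raw descriptors, ~1 500 after filtering), 100
randomization permutations, and 10-seed repetitions for the stochastic
checks — sizes chosen so a complete run stays interactive on a laptop while
keeping every statistic in the regime the method is designed for
(n ≪ p, four-descriptor equations).

## Known limitations

* PEOE parameters cover H, C, N, O, S, P and halogens; exotic elements
  raise an error naming the element rather than guessing values.
* Aromaticity is a kekulé-pattern heuristic, not Hückel counting; exotic
  heteroaromatics may be missed.
* The assignment search in matching is exhaustive over type-respecting
  permutations and capped at 5 000 assignments; molecules with dozens of
  equivalent features would be truncated (with a warning).
* Published model statistics from the original study (r² 0.8267, q² 0.7232,
  pred_r² 0.7460, F 30.2078) depend on the commercial tool's exact
  structures, grid and descriptors, none of which are public; they are not
  reproduction targets. The published equation itself is carried as a
  fixture (`published_model()`) and all formula-level quantities (the
  regression constant, Z-score areas, validation identities) are verified
  exactly.

## A worked run

```{r}
library(fieldqsar)

series <- generate_congeneric_series(n = 33, seed = 1,
                                     planted = planted_model(noise_sd = 0.2))
m <- series$matrix
split <- activity_ranked_split(m, n_test = 5)
selected <- stepwise_forward_select(m, split, max_descriptors = 4)
model <- fit_pls(m, split, selected, max_components = 4)
report <- validate_model(m, split, model, n_permutations = 100, seed = 42)
print(report)
```

The numbered scripts under `analysis/` run exactly this chain (simulate,
fit, validate, pharmacophore, screen) and write their tables under
`results/`.
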