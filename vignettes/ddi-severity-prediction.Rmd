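---
title: "Predicting drug-drug interaction severity from paired structural descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interaction severity from paired structural descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddipass)
```

## The problem

A drug-drug interaction (DDI) arises when one drug changes the exposure or
effect of a co-administered one, typically through inhibition or induction
of metabolizing enzymes or transporters. Clinically, pairs are graded on the
five-class ORCA scale: 1 contraindicated, 2 provisionally contraindicated,
3 conditional, 4 minimal risk, 5 no interaction. Curated compendia label
only a tiny sliver of the pairwise space — a library of 767 drugs spans
`r format(possible_pairs(767), big.mark = ",")` possible pairs, and a
compendium labeling 2,090 of them covers 0.71% — so a useful model must
generalize to pairs, and ideally to compounds, it has never seen. `ddipass`
does this from the structural formulas alone.

## Molecular graphs

Structures enter as MDL V2000 MOL/SDF records. Loading applies three fixed
transformations:

* **Largest fragment.** Multi-fragment records (salts, co-crystallized
  counter-ions) keep only the fragment with the most heavy atoms (ties
  broken by total atom count; a remaining tie is an error). Descriptors
  computed on counter-ions would contaminate the pair representation. How
  the field's curated MOL collections treat salts is generally unstated;
  this rule is the package's own choice and is documented as such.
* **Hydrogen completion.** Implicit hydrogens are materialized from default
  valences (C 4, N 3, O 2, S 2/4/6, P 3/5, halogens 1). The step is
  idempotent: explicit hydrogens already present are counted, not
  duplicated. Formal charges and isotopes are ignored with a warning —
  descriptor labels are bare element symbols.
* **Ring perception.** An atom is a ring atom iff it lies on *some* cycle,
  computed from the bridge set of the graph. Unlike membership in a
  smallest-set-of-smallest-rings, cycle membership needs no basis choice and
  is therefore canonical; it is also exactly the distinction the descriptor
  grammar encodes.

Aromatic systems must be supplied in Kekulé form; bond type 4 is rejected
rather than guessed at, since descriptor strings never look at bond orders
and kekulization would add a perception step with conventions of its own.

## MNA and PoSMNA descriptors

The level-k MNA descriptor of an atom is defined recursively:

* level 0 — the atom label: element symbol, prefixed `-` iff the atom is
  not in a ring (`C`, `-N`, `-H`, ...);
* level k — `label(sorted concatenation of neighbours' level-(k−1)
  descriptors)`, all neighbours including hydrogens, duplicates retained.

A molecule is represented by the *set* of level-2 descriptors rooted at its
heavy atoms; topologically equivalent atoms collapse to one entry, so the
set is invariant under any reordering of the input atoms. For benzene the
set is the single string `C(C(CC-H)C(CC-H)-H(C))`.

Sibling descriptors inside the parentheses are sorted under a fixed
collation: compare strings with all `-` marks deleted, byte-wise, and break
ties on the raw string. Plain byte ordering would place `-H(...)` before
ring-`C(...)` (`-` sorts before any letter), which contradicts the
neighbour order in published reference strings such as
`C(C(CCC-H)C(CC-H-H)-H(C)-N(C-H-H))`; the mark-blind comparison reproduces
them. Any fixed deterministic collation preserves the set semantics — this
one is chosen because it matches the reference strings exactly, and it is
applied uniformly to sibling sorting, descriptor-set ordering and pair
orientation. The tie-break direction (marked before unmarked) is not pinned
down by any unambiguous published string; it is fixed here byte-wise and
frozen by the golden tests.

A pair of molecules is represented by its **PoSMNA** set: all pairs of MNA
descriptors, one from each molecule, joined by a single space with the
collation-smaller string first. The construction is symmetric by design, so
victim and precipitant roles are not distinguished. The cross product runs
over descriptor *sets*, not per-atom multisets, keeping the feature space
stable under symmetric atoms. Pairs of identical descriptors and the
"diagonal" elements a self-cross would produce are retained — nothing in
the definition excludes them.

## The classifier

Each ORCA class $c$ is scored one-vs-rest. With $n(d)$ the number of
training pairs containing descriptor $d$, $n(d,c)$ those of class $c$,
$\pi_c$ the class prior and smoothing weight $\alpha$:

$$\hat P(c\mid d) = \frac{n(d,c) + \alpha\,\pi_c}{n(d) + \alpha},
\qquad
S_c = \sin\!\Big(\operatorname{mean}_{d \in D}
      \arcsin\big(2\hat P(c\mid d) - 1\big)\Big),$$

where $D$ is the set of query descriptors known to the model. The arcsine
transform stabilizes the variance of the per-descriptor probability
estimates before averaging, so a handful of extreme descriptors cannot
dominate hundreds of uninformative ones; this estimator family is the
established form for this kind of descriptor-spectrum classifier, and the
exact combination rule used by closed-source implementations is not public
— the one here is a documented reconstruction. Descriptors never seen in
training are ignored; if nothing is known, $S_c$ falls back to the prior
score $2\pi_c - 1$.

Raw scores become probabilities by rank calibration. During fitting every
training pair is scored with its own contribution removed from all counts
(leave-self-out), producing per-class score distributions. For a query with
score $S_c$: **Pa** is the fraction of class-$c$ training pairs scoring
strictly below it plus half the equal fraction, **Pi** the analogous
fraction of non-class-$c$ pairs scoring above. Both are therefore invariant
under any strictly increasing transform of the scores. A class with no
training pairs has Pa defined as 0. Calibration is per class, not joint: no
normalization couples the five classes, matching the one-activity-at-a-time
semantics of spectrum prediction.

Tunables and defaults: `level = 2` (the standard depth; level is exposed
for experimentation), `alpha = 1` (one pseudo-observation toward the
prior). Both are arguments of `ddipass()`.

## Validation

**IAP** (invariant accuracy of prediction) is the probability that a random
positive outranks a random negative — identical to AUC, computed by
mid-ranks so ties count half. It is undefined without at least one positive
and one negative, and the package says so rather than returning a number.

Two protocols are implemented:

* `compound_out_loo()` — for each pair (x, y), *every* pair containing x or
  y is removed before refitting, and (x, y) is scored by the reduced model.
  Both compounds are therefore completely unseen: a cold-start estimate.
  Per-class IAP uses the raw class score as the ranking statistic; Pa − Pi
  is a monotone transform of it, so the ranking (and hence IAP) is
  identical, and the cheaper statistic is preferred. Pairs whose exclusion
  leaves fewer than two classes to train on are skipped and listed in the
  report. The protocol involves no randomness and is invariant to pair
  order. Internally the per-pair refit subtracts the excluded pairs'
  contributions from the global count tables; a test verifies this equals a
  naive refit-from-scratch oracle exactly.
* `kfold_cv(k = 20)` — pairs are shuffled under a mandatory seed, dealt
  into k folds stratified by class, and each fold is scored by a model
  fitted on the rest. IAP is computed on the pooled out-of-fold scores, so
  a fold lacking a class is benign. Folds split by *pair*: a compound can
  sit on both sides of a split, which makes this protocol systematically
  easier than compound-out; whether historical 20-fold results split by
  pair or by compound is usually unstated, so the report records the
  choice. `k = n` reduces exactly to pair-out leave-one-out.

The reported average IAP is the unweighted mean over classes for which IAP
is defined.

## The synthetic benchmark

Real severity compendia cannot be redistributed, so the package generates
its own benchmark with the same statistical shape: a library of a few
hundred small molecules and a sparse pair table whose class histogram is
skewed like a curated compendium (defaults proportional to
59/236/1139/523/133 across classes 1–5).

Molecules are assembled from a fragment grammar — alkyl chains, 5/6-membered
carbocycles, O-substitutions — and 0–3 pharmacophore motifs drawn from a
catalogue of four (a sulfonamide, a pyridine, an N,N-dimethyl amide, and a
thiophene decoy). Scaffolds use only C and O while motifs carry N or S, so
motif presence is unambiguous and the generator's bookkeeping is audited
against a subgraph-isomorphism oracle in the tests. Labels follow hidden
co-occurrence rules: sulfonamide × pyridine across the pair ⇒ class 1; a
remaining sulfonamide ⇒ class 2; pyridine × amide or pyridine × pyridine ⇒
class 3; any remaining pyridine/amide ⇒ class 4; no rule motifs ⇒ class 5.
The class-3 and class-4 rules deliberately share motifs, planting the fuzzy
3/4 boundary that real severity data exhibit. A `label_noise_rate` flips
each label to a random other class.

Two construction choices matter and were fixed once, by design: motifs are
≥ 4 heavy atoms, because an MNA/2 neighbourhood only sees two bonds of
context and smaller motifs would be invisible; and scaffolds are kept small
(3–7 heavy atoms before decoration) so that a planted motif dominates its
molecule's descriptor set — this is what keeps the planted classes
recoverable when both compounds of a pair are excluded from training, and
in particular keeps the absence-defined class 5 separable from
single-motif class-4 pairs.

What the generator does *not* emulate: pharmacological realism (no
drug-likeness filters), stereochemistry, charged species, and any
label-generating mechanism other than substructure co-occurrence. Passing
tests on this benchmark show that the descriptor/classifier/validation
pipeline recovers planted structure-label signal under cold-start
conditions; they do not certify accuracy on real severity data.

## Study sizes and numerical choices

The benchmark used throughout the tests and the acceptance script is 200
molecules / 600 labeled pairs (3% coverage of the pairwise space), with
label noise 0 and 0.3; at this size the full compound-out protocol (600
refits) runs in a few seconds. At noise 0 the compound-out IAP of the
marginal classes 1 and 5 exceeds 0.95 and every class exceeds 0.80 across
the seeds exercised; 20-fold CV tracks compound-out within 0.05 per class;
label noise degrades every class monotonically. Chance-level checks on
permuted labels use the Mann–Whitney null standard error per class rather
than a flat band, because the rare classes (≈ 17 positives) have a null
sampling spread near 0.12.

Smaller numerical decisions, recorded here so they are not rediscovered:
probability arguments to `arcsin` are clamped to [−1, 1] against rounding;
all string ordering uses radix (byte-wise) sorting, immune to locale;
pair tables are canonicalized to byte-order `(min, max)` orientation;
`%` displays round half-up to two decimals while JSON keeps raw values;
model serialization is versioned JSON and refuses other versions;
prediction output orders classes by Pa − Pi with R's stable order as the
tie-break.

## Limitations

* The exact combination rule and collation of the original closed-source
  spectrum classifier are unpublished; both are reconstructions constrained
  by the published reference strings and semantics, and are frozen by
  golden tests rather than derived.
* Descriptors are constitution-only: no stereochemistry, charge, tautomer
  or 3D information, and no descriptor weighting or truncation.
* Compound-out validation says nothing about extrapolation to chemistry
  outside the training library's fragment vocabulary; unknown descriptors
  are simply ignored, and a fully unknown pair falls back to class priors.
* V3000 molblocks are not parsed.
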