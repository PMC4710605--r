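---
title: "Exposure and ADME triage of screening actives: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure and ADME triage of screening actives: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admetriage)
```

## The problem

High-throughput in vitro screens built around a molecular initiating event
(MIE) — here, inhibition of acetylcholinesterase (AChE) — report which
chemicals perturb the target in a dish. That list is a poor proxy for in
vivo hazard in both directions. An assay-active chemical may never reach the
target in a person: nobody is exposed to it, it is not absorbed, or it
cannot cross the blood–brain barrier (BBB) to reach brain AChE. Conversely,
an assay-inactive chemical may be a parent compound whose metabolite is the
true inhibitor, making the in vitro result a false negative for the in vivo
question.

`admetriage` implements both refinements as a reusable pipeline:

1. **Triage of actives.** Each active is gated through exposure, absorption
   and distribution rules and labeled `high` or `low` priority with
   machine-readable reason codes and a full gate trace.
2. **False-negative screening of inactives.** Each inactive is compared to
   every active by MACCS-166 fingerprint Tanimoto similarity; inactives
   whose nearest active neighbor meets the similarity threshold are flagged
   as possible false negatives, unless that neighbor is itself low priority,
   in which case the low priority is inherited.

## The decision trees

For a **parent compound** the gates run in a fixed order and short-circuit:

* *Exposure* — annotation categories are 1 (widespread), 2
  (occupational/special cases), 3 (unknown) and 4 (low/no likelihood).
  Category 4 demotes to low priority immediately; nothing else is
  evaluated. Category 3 passes: unknown exposure is not evidence of no
  exposure, and demoting on ignorance would silently discard chemicals that
  most need follow-up.
* *Absorption* — `Negligible` demotes; `Limited` passes but adds a
  `limited_absorption` ranking note (such chemicals stay high priority yet
  rank lower in later quantitative analysis); `Yes` passes. The predictor
  only ever produces `Yes`/`Limited`; `Negligible` is reserved for
  annotations, which carry the kind of route-specific evidence a descriptor
  filter cannot.
* *Distribution* — `No` (cannot cross the BBB, so cannot reach brain AChE)
  demotes; `Yes` passes.

Unknown or unannotated values at any gate pass through: insufficient data
never confidently assigns low priority. Every gate evaluation is recorded in
the call's `gate_trace` (gate, input, outcome, source), so each decision is
auditable.

A **metabolite** with its own environmental exposure (category 1–3) is
treated exactly like a parent compound. Without independent exposure, its
fate is tied to its parent: a parent with no exposure (category 4) or
negligible absorption demotes the metabolite; otherwise the metabolite's own
BBB distribution decides. This is why `run_workflow()` requires either an
exposure category or a resolvable `parent_id` on every active.

Annotations always take precedence over predictions. Predictions are
computed only for gates that are unannotated and only when a structure is
available.

## Structure washing

Annotated structures arrive as salt forms. Before descriptors or
fingerprints are computed, `wash_structure()`:

* keeps the largest fragment by heavy-atom count (ties broken by molecular
  weight, then canonical-SMILES order);
* applies a fixed table of standard neutralizations — protic cations
  (`[NH3+]`, `[NH2+]`, `[NH+]`, `[nH+]`) lose a proton, common anions
  (`[O-]`, `[S-]`, `[NH-]`) gain one — while internally compensated charges
  (nitro groups, N-oxides) and permanent cations (quaternary ammoniums such
  as didecyldimethylammonium, the gentian violet dye cation) are never
  rewritten;
* emits Open Babel canonical SMILES.

Washing is idempotent and spelling-invariant, both asserted as property
tests. Inorganic records (mercuric chloride) are retained and flagged
`is_organic = FALSE`; their descriptor sets carry `low_confidence = TRUE`
rather than erroring, because annotation-driven triage must still run on
them. Protonation is handled by the fixed transformation table rather than a
pH model, and no 3D conformers are generated: no downstream step consumes
3D coordinates.

## Descriptors and the classification rules

Descriptors come from Open Babel: molecular weight, atom-contribution
(Crippen-type) logP, topological polar surface area, and hydrogen-bond donor
counts. Hydrogen-bond acceptors use the classic N + O heavy-atom count, and
rotatable bonds are counted with the standard non-terminal, non-ring
single-bond SMARTS definition.

**Absorption** uses the Rule-of-5 extended by the rotatable-bond and TPSA
bioavailability criteria: violations are `mw > 500` g/mol, `logp > 5`,
`hbd > 5`, `hba > 10`, `rotatable_bonds > 10`, `tpsa > 140` Å². All six are
strict inequalities — a chemical exactly at a threshold is not in
violation — and the class is `Yes` exactly when no violation fires.

**Distribution** uses a transparent physicochemical rule set (all enabled
rules must pass): `tpsa ≤ 90` Å², `mw ≤ 450` g/mol, `1 ≤ logp ≤ 4`,
`hbd ≤ 3`, net formal charge `≥ 0`. These bounds follow the well-known
CNS-permeability envelope: CNS drugs are small, moderately lipophilic, weak
donors, with limited polar surface, and anions essentially do not cross.
Every rule is configurable (or disableable) through the YAML config because
the reference calls in the packaged case study came from a proprietary
trained classifier that cannot be reproduced rule-for-rule.

On the 21 structure-bearing, annotation-carrying actives of the packaged
case study the default rule set agrees with 11 of 21 annotated BBB calls.
The disagreements are almost all conservative `No` predictions for polar
organophosphates and carbamates that sit below the `logp ≥ 1` bound, plus
anthralin, which passes every physicochemical rule yet is annotated
non-permeant (its sequestration in dermal tissue is pharmacokinetic
knowledge no descriptor filter can see). This agreement is documented, not
gated: in triage, annotations always win, and the two chemicals demoted for
BBB impermeability in the case study (raloxifene, pentamidine) are also
predicted `No` by the default rules, which the test suite does require.

## Fingerprints and similarity

Fingerprints are the 166 public MDL MACCS keys as implemented by Open
Babel; bit *i* is key *i*. The Tanimoto coefficient is
|A ∩ B| / |A ∪ B| over set bits. Two all-zero fingerprints get similarity 0,
not 1: an empty key profile is absence of structural evidence, not evidence
of identity (a warning is raised).

The flagging threshold defaults to 0.75 and the comparison is **inclusive**
(`tanimoto ≥ threshold`); the threshold is configurable. Nearest-neighbor
ties are broken by lowest active AC50 (most potent neighbor first), then by
lexicographic id, and all tied neighbors are reported in the hit — the
tie-break is not hypothetical: in the packaged case study malaoxon is
equally similar to mevinphos and to bis(2-ethylhexyl) decanedioate, and the
potency rule selects mevinphos.

Different MACCS implementations ("dialects") disagree slightly in key
SMARTS definitions, so coefficients computed here can differ by a few
points from values computed with commercial toolkits. The packaged
case-study pairs agree with their reference percentages to within 0.015 on
the coefficient; the test suite enforces an absolute tolerance of 0.04
together with exact threshold classification of each pair.

## Promiscuity flagging

Some assay signals come from nonspecific interference (dye absorbance,
aggregation, reactive cores) rather than target binding. `flag_promiscuity()`
matches washed structures against a deliberately small default alert set —
triarylmethane dye cations, permanently charged azinium aromatics, and the
rhodanine PAINS core — and honors per-record overrides (which always win,
in either direction). Flags annotate calls with a `promiscuity_suspect`
rank note but do not change priority by default, because interference is
grounds for suspicion, not proof of inactivity; `demote_promiscuous = TRUE`
switches to the stricter reading. Reports carry both `n_high` and
`n_high_non_promiscuous` so either convention can be read off.

## The synthetic-data generator

`generate_screening_library()` emulates the structure of a screening
inventory at desk scale: scaffold "actives" with randomized gate
annotations, planted analogs, and decoys.

* Analogs are derived from a scaffold by 1–2 edits from a fixed vocabulary
  (halogen swap, O/S swap, chain extension, methyl addition) and accepted
  only if their MACCS Tanimoto to the scaffold meets the generation
  threshold — rejection sampling re-scored with the package's own
  fingerprint code, so recovery by `screen_inactives()` is exact by
  construction, not approximate.
* Decoys are drawn from a built-in pool of diverse drugs, natural products
  and simple organics, and kept only if their similarity to *every* scaffold
  is below the threshold.
* All randomness flows through one explicit integer seed; the global RNG
  state is saved and restored, and the same seed reproduces the identical
  library.

What the generator does *not* emulate: realistic activity cliffs (planted
analogs are trivially similar by construction), assay noise and
concentration–response fitting, the chemical-space distribution of a real
inventory, or metabolite relationships. Passing the planted-recovery suite
therefore demonstrates the correctness of the screening machinery — not
that a 75% MACCS threshold has any particular sensitivity/specificity on
real chemistry.

## Numerical and degenerate-input choices

* Tanimoto values are kept at full double precision; rounding to integer
  percent happens only at display/report time.
* Equal similarity ties are compared exactly (IEEE division of equal
  rationals is exact), so tie detection needs no epsilon.
* Structureless records participate in annotation-driven triage but are
  excluded from fingerprint screening with an explicit skip note; in the
  packaged case study all eight structureless actives are failed
  pharmaceuticals that are exposure-gated anyway.
* Unparsable SMILES abort single-record operations with an error naming the
  record, but batch screening collects them into a skip list and continues.
* An empty active table produces an empty report with zero counts rather
  than an error.

## Validation problem sizes

The shipped suite exercises: the 30-active / 8-inactive packaged case study
end to end; the full 60-combination gate-annotation grid against an
independently coded truth table; nearest-neighbor equivalence against an
exhaustive scan on random fingerprint sets up to 200 actives; Tanimoto
symmetry/range/identity on hundreds of random fingerprint pairs; and
planted-analog recovery with zero decoy flags on synthetic libraries across
20 seeds. These sizes keep the default test run fast while covering every
code path; all generators scale to larger libraries by argument.

## Known limitations

* The BBB rule set is a transparent stand-in, not a trained classifier;
  users with access to measured or predicted permeability calls should
  supply them as annotations, which always take precedence.
* Absorption is route-agnostic: oral-bioavailability heuristics stand in
  for dermal and inhalation routes, which matter for several pesticides in
  the case study. Route notes never change the class.
* Metabolite handling requires explicit `parent_id` links and annotations;
  the package does not predict metabolites.
* MACCS/Tanimoto similarity is 2D; stereochemistry and 3D pharmacophores
  are invisible to it.
* Quantitative, rate-based ranking of high-priority chemicals (relative
  absorption/metabolism/excretion rates) is out of scope; the rank notes
  are the hook where such a ranking would attach.
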