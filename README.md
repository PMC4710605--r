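# admetriage

Rule-based exposure/ADME triage of active chemicals from high-throughput
in vitro screens, with fingerprint-based detection of possible in vitro
false negatives.

## The problem

Screening assays built around a molecular initiating event — the packaged
case study uses inhibition of human acetylcholinesterase (AChE) — report
in vitro activity, not in vivo hazard. An active chemical is irrelevant if
nobody is exposed to it, if it is not absorbed, or if it cannot cross the
blood–brain barrier (BBB) to reach its target. An *inactive* chemical can
still matter if it is the parent of an active metabolite (chlorpyrifos →
chlorpyrifos oxon is the canonical example). `admetriage` is for
computational toxicologists and cheminformaticians who need to refine a hit
list in both directions, reproducibly and with auditable reasons.

## What it computes

**Triage of actives.** Each active runs through ordered gates with
short-circuiting:

```
exposure (category 4 -> low)  →  absorption (Negligible -> low)
                              →  BBB distribution (No -> low)  →  high
```

Annotations always beat predictions. Where a gate is unannotated,
absorption is predicted by Rule-of-5 style criteria (violations: MW > 500,
logP > 5, HBD > 5, HBA > 10, rotatable bonds > 10, TPSA > 140; strict
inequalities) and BBB permeability by a configurable physicochemical rule
set (defaults: TPSA ≤ 90 Å², MW ≤ 450, 1 ≤ logP ≤ 4, HBD ≤ 3, net formal
charge ≥ 0). Unknown values never demote. Every call carries reason codes
and a gate trace.

**False-negative screening of inactives.** Structures are washed (salt
stripping, fixed-table neutralization, canonicalization), fingerprinted with
the 166 public MDL MACCS keys, and each inactive is assigned its nearest
active neighbor by Tanimoto similarity

    T(A, B) = |A ∩ B| / |A ∪ B|

over set bits. Inactives with `T ≥ 0.75` (inclusive, configurable) are
flagged; a flagged inactive whose nearest neighbor is itself low priority
inherits low priority, and the rest are reported as possible false
negatives. Promiscuity suspects (dye cations, azinium salts, rhodanines, or
per-record overrides) are annotated, and optionally demoted.

Chemistry (parsing, canonical SMILES, descriptors, MACCS keys, SMARTS) is
delegated to Open Babel via ChemmineOB/ChemmineR.

## Worked example

```r
library(admetriage)

fx <- load_table1_fixture()        # 30 printed actives + 8 worked inactives
report <- run_workflow(fx$actives, fx$inactives)
print(report)
#> Exposure-ADME triage report
#>   actives: 30  (high: 20, low: 10)
#>   low by exposure: 7, by absorption: 0, by BBB: 3
#>   flagged inactives: 7 (inherited low: 1, possible false negatives: 6)
#>   promiscuity suspects: 2 (high priority excluding them: 18)
```

Ten of the 30 actives are set aside: 7 failed pharmaceuticals with no
exposure potential and 3 chemicals (anthralin, raloxifene, pentamidine)
that cannot reach brain AChE. The similarity hits:

```r
report$hits[, c("query_id", "neighbor_id", "tanimoto", "flagged")]
#>             query_id              neighbor_id tanimoto flagged
#>         chlorpyrifos        chlorpyrifos_oxon   0.8958    TRUE
#>             aldicarb                 methomyl   0.8824    TRUE
#>          trichlorfon                    naled   0.8696    TRUE
#>           dichlorvos                    naled   0.8333    TRUE
#>            phosalone             azamethiphos   0.8169    TRUE
#>          zamifenacin raloxifene_hydrochloride   0.7593    TRUE
#>  chlorpyrifos_methyl        chlorpyrifos_oxon   0.7551    TRUE
#>             malaoxon                mevinphos   0.5676   FALSE
```

Chlorpyrifos — inactive in the assay but 90% similar to its oxon
metabolite — is flagged as a possible in vivo false negative. Zamifenacin
is flagged too, but its nearest active (raloxifene) is low priority, so it
inherits low priority instead. Malaoxon stays below threshold even at 0.60.

A command-line interface wraps the same pipeline:

```sh
inst/cli/admetriage run --actives actives.csv --inactives inactives.csv --out results/
# writes report.csv, hits.csv, summary.json, effective-config.yaml
```

Synthetic screening libraries with planted, guaranteed-recoverable analogs
and guaranteed-dissimilar decoys are available through
`generate_screening_library()` (see the vignette for what they do and do
not emulate).

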