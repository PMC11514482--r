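# smtaom

Single-molecule telomere profiling from optical genome mapping label
patterns.

## What it does, and for whom

In two-colour optical mapping of telomeres, each linearized DNA molecule
carries a genome-wide pattern of green motif labels — a fingerprint of the
subtelomeric region of one chromosome arm — and red segments marking
telomeric DNA. This package is for groups analysing (or planning) such
experiments: it assigns each molecule to a chromosome arm, classifies every
chromosome end, measures telomere length across a 0.1–100 kb dynamic range,
and produces per-arm and cohort-level statistics. Because raw molecule sets
from such assays are rarely deposited, a fully specified simulator with
ground truth is part of the package, so the whole chain is testable and its
operating characteristics (recall, arm-assignment accuracy, length
recovery) are measurable.

Every chromosome end falls into one of four categories:

| category | meaning |
|---|---|
| `END_TEL` | identifiable arm ending in a red (telomeric) tract |
| `TFE` | identifiable arm reaching its terminus with no red signal |
| `ITS_PLUS` | fusion: red tract between an identifiable arm and a short unassignable fragment |
| `ITS_MINUS` | fusion of the same topology with no red at the junction |

The core algorithmic piece is arm assignment by dynamic-programming
alignment of label spacings. A monotone matching of reference labels to
molecule labels is scored as

    S = Σ r  −  Σ (Δref − Δmol/s)² / (2 σ² Δref)  −  c_miss·n_miss − c_false·n_false

with a per-pair reward `r`, a global stretch `s` fitted by golden-section
search, interval variance growing linearly with interval length (σ in
kb/√kb, the standard optical-map sizing error model), and penalties for
labels skipped between matched pairs. A fragment is assigned only when it
clears three floors — matched-label count, score, and margin over the
runner-up arm — so "cannot be unambiguously assigned" is an explicit,
testable condition. Classification then works relative to the arm terminus
projected onto the molecule through the alignment; telomere length uses
segment extent above the optical resolution floor and integrated intensity
below it.

## Worked example

Simulate a small two-cohort experiment against a synthetic 10-arm
reference, classify it, and compare the cohorts:

```r
library(smtaom)

refset <- synthesize_reference(n_arms = 10, seed = 1)
treated <- simulate_cohort(refset,
  sim_config(event_rates = cohort_event_rates("sgTelo"), seed = 2),
  cohort = "treated", n_molecules = 300)
control <- simulate_cohort(refset,
  sim_config(event_rates = cohort_event_rates("sgNS"), seed = 3),
  cohort = "control", n_molecules = 300)

calls_t <- classify_cohort(treated$molecules, refset, quiet = TRUE)
calls_c <- classify_cohort(control$molecules, refset, quiet = TRUE)
summarize_cohort(calls_t)
summarize_cohort(calls_c)
```

```
<cohort treated: 298 classified molecules over 10 arms (2 unclassified)>
  End Tel mean 11.4 kb | ITS+ mean 11.5 kb | ITS+ 15.4% (46/298) | ITS- 6.4% (19/298) | TFE 7.7% (23/298)
<cohort control: 297 classified molecules over 10 arms (3 unclassified)>
  End Tel mean 11.4 kb | ITS+ mean 10.2 kb | ITS+ 4.4% (13/297) | ITS- 0.34% (1/297) | TFE 3.0% (9/297)
```

The treated cohort's fusion-with-ITS frequency is several times the
control's and its fusion-without-ITS frequency an order of magnitude
higher, at indistinguishable end-telomere means — the signature of
chromosome-end fusion induction rather than bulk telomere shortening. The
comparison object makes this quantitative:

```r
cc <- compare_cohorts(calls_t, calls_c)
cc$overall[, c("metric", "value_a", "value_b", "fold_change", "p_value")]
```

```
            metric   value_a    value_b fold_change      p_value
1     its_plus_pct 15.436242  4.3771044    3.526588 7.036106e-06
2    its_minus_pct  6.375839  0.3367003   18.936242 3.067475e-05
3          tfe_pct  7.718121  3.0303030    2.546980 1.689067e-02
4  end_tel_mean_kb 11.372226 11.3553775    1.001484 9.629661e-01
5 its_plus_mean_kb 11.452669 10.1963808    1.123209 2.074052e-01
```

`run_pipeline()` drives the same chain from a YAML or list config and
writes molecules (minimal BNX), reference (minimal CMAP dialect), call
tables, a report whose cells read like `15.4 (46/298)`, and a manifest with
checksums; reruns with the same seed are byte-identical.

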