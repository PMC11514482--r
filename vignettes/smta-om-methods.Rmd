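---
title: "Single-molecule telomere profiling from optical map label patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule telomere profiling from optical map label patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtaom)
```

## The measurement this package models

Optical genome mapping reads single, linearized DNA molecules hundreds of
kilobases long. In the two-colour telomere variant, a motif-labelling enzyme
deposits green fluorescent labels genome-wide, a telomere-specific nicking
reaction paints telomeric tracts red, and the backbone is counter-stained.
Each imaged molecule therefore carries (i) a green label pattern that is a
fingerprint of the subtelomeric region of one chromosome arm and (ii) zero or
more red segments marking telomeric DNA. From these two channels, every
molecule that reaches a chromosome end can be placed into one of four
categories:

* **End telomere (END_TEL)** — an identifiable arm terminating in a red tract:
  the normal chromosome end. The red signal measures telomere length.
* **Telomere-free end (TFE)** — an identifiable arm that reaches its terminus
  with no detectable red signal: a chromosome end that has lost its telomere.
* **Fusion with interstitial telomeric sequence (ITS+)** — a red tract flanked
  by an identifiable arm on one side and a short labelled fragment on the
  other, too short to place: two chromosome ends joined with telomeric DNA
  trapped at the junction.
* **Fusion without interstitial telomeric sequence (ITS−)** — an identifiable
  arm joined directly to a short, unplaceable labelled fragment, with no red
  at the junction: a fusion of two telomere-free ends.

Cohort-level contrasts of these frequencies — e.g. a telomere-stressed
population against a control — are the scientific output: fusion frequencies
are the molecular signature of breakage–fusion–bridge cycle initiation.

The package implements the full computational chain: reference arm maps,
single-molecule simulation with ground truth, arm assignment by
dynamic-programming alignment, end classification, telomere quantification,
and cohort statistics. Raw molecule sets from the original instrumentation
are not publicly deposited, so the simulator is a first-class, tested
component: it defines the study conditions under which every downstream
stage is validated.

## Reference maps and the synthetic reference model

A reference arm map is the ordered list of green-label coordinates on the
distal segment of one chromosome arm, in bp, with a single canonical
orientation: coordinates increase toward the telomere terminus on *both* p
and q arms (p-arm input in genomic orientation is mirrored at load time).
One orientation convention removes arm- and strand-special-casing from every
downstream stage.

Synthetic references model label placement as a Poisson process: spacings
i.i.d. exponential with mean `100 / labels_per_100kb` kb (default rate 15
per 100 kb, the density regime of genome-wide motif labelling enzymes). Each
arm models a 500 kb distal segment, comfortably longer than any simulated
molecule, and must carry at least `signature_min = 12` labels in its distal
`signature_window_kb = 150` kb identification window — the window length
matches the >150 kb molecule regime the assay operates in. Pairwise
distinguishability of a reference set is checked by aligning each arm's
signature window against every other arm
(`check_distinguishability()`); for independent exponential spacings the
cross-scores sit far below the self-scores.

## The molecule simulator

`simulate_cohort()` draws, per molecule: an arm (round-robin quota,
`molecules_per_arm = 30` by default), an event class from the configured
rates, and a backbone built from the arm's distal reference labels
(`min_molecule_kb = 150` to `max_molecule_kb = 300`). Fusion events join a
short fragment (20–80 kb, 2–8 labels — below the assignability floor by
construction) taken from the distal end of a second arm, oriented
terminus-to-terminus as a real end-to-end fusion is. Telomere tract lengths
are log-normal with mean 11.5 kb and CV 0.35 by default: the published
per-arm summaries report only means and SDs, and log-normality guarantees
positivity with the right skew telomere data shows. A residual event rate
(when the four class rates sum below 1) produces interstitial debris
molecules that exercise the classifier's rejection path.

The measurement model applies, in order: label dropout
(`p_missing_label = 0.10`), false labels (Poisson, 1 per 100 kb),
per-interval multiplicative sizing noise (CV 0.03, the nanochannel sizing
error scale), resolution merging (labels closer than `resolution_kb = 1.5`
collapse to their midpoint — the optical resolution scale of nanochannel
imaging), red-signal fluorescence yield (`intensity_per_kb = 100` a.u. with
CV 0.10), and a random end-for-end flip with probability 0.5, since
nanochannel loading has no preferred orientation. Two cohorts differ only in
their event-rate vectors (`cohort_event_rates()` exposes the two published
cohorts' rates, computed from their event counts).

What the simulator does *not* emulate: image-level artifacts (point-spread
blur, backbone intensity variation, molecule overlaps), chimeric molecules
formed in the flow cell, arm-specific label-density differences, and
per-arm event-rate heterogeneity (rates are uniform across arms unless
overridden). Passing tests therefore demonstrate correctness of the
computational chain under a realistic noise model, not performance on any
particular instrument run.

## Arm assignment: the alignment model

A molecule's green labels are segmented into fragments at red segments; each
fragment is aligned against every reference arm in both orientations. The
score of a monotone matching of reference labels to fragment labels is

$$S = \sum_{k} r \;-\; \sum_{k>1}
\frac{\left(\Delta^{\mathrm{ref}}_k - \Delta^{\mathrm{mol}}_k/s\right)^2}
     {2\,\sigma^2\,\Delta^{\mathrm{ref}}_k}
\;-\; c_{\mathrm{miss}} n_{\mathrm{miss}} - c_{\mathrm{false}} n_{\mathrm{false}},$$

where $r$ is the per-pair match reward, $\Delta_k$ are the intervals between
consecutive matched pairs, $s$ is a single global stretch factor
(molecule-over-reference; a molecule stretched by 1.02 fits $s = 1.02$),
$\sigma$ is the sizing-error scale in kb per $\sqrt{\mathrm{kb}}$ — interval
variance grows linearly with interval length, the standard optical-map error
model — and $n_{\mathrm{miss}}, n_{\mathrm{false}}$ count reference and
molecule labels skipped *between* matched pairs. Unmatched labels before the
first and after the last pair are free on both sides: a fragment is local in
the reference, and fusion molecules carry labels from a second arm distal to
the matched one that must be skippable without distorting the fit.

The optimum over matchings is found by dynamic programming (exact up to the
band `max_step`, the largest allowed index step between consecutive pairs;
default 6, i.e. up to 5 consecutive skips — set it to the label count for a
provably unbanded optimum, as the enumeration-oracle tests do). The stretch
is fitted by golden-section search on the DP score over
`stretch_bounds = [0.9, 1.1]`, with $s = 1$ kept when the search does not
beat it. Reference labels closer than `ref_collapse_kb = 1.5` are merged to
their midpoint before alignment, mirroring the resolution merging the
instrument applies to molecules; without this, every sub-resolution
reference pair would cost a spurious miss penalty.

A fragment is **assigned** only if three floors all pass: at least
`min_matched_labels = 9` matched pairs, score at least `min_score = 15`, and
a relative margin of at least `min_margin = 0.10` between the best and
second-best arm. Nine labels mirrors common optical-map confidence practice;
the margin rule is what makes "cannot be unambiguously assigned"
operational — a fragment matching two arms equally well is UNASSIGNED no
matter how well it matches. Orientation ties break toward the
terminus-forward reading, then lexicographic arm id, for determinism.
Because fusion partners are simulated with 2–8 labels, they sit strictly
below the `min_matched_labels` floor: the fusion categories are
*threshold-conditional*, and changing the floors changes which junctions
count as fusions. The scanning pass scores all arms at $s = 1$ and refines
the top two with the stretch fitted; refinement can only raise a score, so
the ranking is preserved.

## End classification

Classification works on the signed molecule axis pointing toward the
assigned fragment's **projected terminus** $T$: the arm terminus position
mapped onto the molecule through the last matched pair and the fitted
stretch. Decision order: a red segment starting within
`junction_window_kb = 5` of $T$ makes the molecule ITS+ (if a labelled
fragment with at least `min_fragment_labels = 2` labels lies beyond the red)
or END_TEL (if the molecule ends within `end_slack_kb = 20` of the red);
with no red at $T$, at least 2 labels beyond $T$ make it ITS−, and otherwise
a molecule end within $[-10, +20]$ kb of $T$ (the `tfe_overhang_kb` /
`end_slack_kb` tolerances) is a TFE. Everything else — unassignable
molecules, interstitial fragments whose end falls short of the terminus,
red tracts followed by long unlabelled tails — is UNCLASSIFIED with a
diagnostic flag, and UNCLASSIFIED molecules are excluded from every
statistical denominator.

Two design points deserve emphasis. First, the TFE rule is a *reach-the-
terminus* test against the projected terminus, not a raw overhang past the
last matched label: the gap between the last reference label and the
terminus is exponentially distributed (mean ≈ 6.7 kb at default density), so
any fixed overhang threshold on that gap would both miss true TFEs and fail
to reject interstitial truncations, whose last-label gap has the same
distribution. Projection through the alignment makes the test sharp: true
chromosome ends land within a few kb of $T$; interstitial debris falls tens
of kb short. Second, the TFE window is also bounded *above* (`end_slack_kb`
beyond $T$): DNA extending far past a chromosome terminus is evidence of a
fusion with an unlabelled or sparsely labelled partner, not of a clean
telomere-free end, and such molecules stay UNCLASSIFIED rather than inflate
the TFE count. The windows are config-exposed because the reported
frequencies depend on them; defaults are scaled to the label density and
resolution of the simulated instrument. A fusion whose partner fragment is
itself assignable is reported in its ITS category with the partner arm
recorded and a `both_assignable` flag, since the published taxonomy only
names the one-assignable case.

## Telomere quantification

Telomere length is measured in two regimes. Above the optical resolution
floor (`resolution_floor_kb = 1.5`), the red segment's pixel extent times
the fitted kb-per-pixel is the length. Below it, the segment is an
unresolved dot whose *integrated intensity* still scales with tract length,
and length is intensity divided by the fitted per-kb yield — this is what
extends the measurable range down to ~0.1 kb, an order of magnitude below
what extent alone resolves. Both conversions are least-squares fits through
the origin (`calibrate_telomere()`): zero telomere implies zero signal, and
an additive offset would admit negative lengths. Calibration demands at
least 10 points spanning a decade of true length; the conversion constants
are always data-derived, never hard-coded. On simulator defaults the median
relative error is below 10% above 2 kb (extent regime, bounded by the sizing
CV) and below 50% at 0.3 kb (intensity regime, bounded by the intensity CV),
spanning 0.1–100 kb.

## Cohort statistics and rendering conventions

`summarize_cohort()` computes per-arm and pooled frequencies
(`100 · events / classified molecules`) and telomere means; the end-telomere
mean uses END_TEL molecules only (telomere-free ends carry no length and are
excluded by construction), the fusion mean uses ITS+ molecules only. All
values are kept at full precision internally; rendering rounds percentages
to one decimal at or above 1% and two significant figures below, which is
how the published table prints its cells (e.g. `0.36`). Report fold changes
are computed on the *rendered* percentages — reproducing the convention
under which 4.0/0.36 prints as an 11.1-fold change — while
`compare_cohorts()` carries the raw-count ratios alongside.

Frequency contrasts use a two-sided 2×2 test; Fisher's exact test, the
(uncorrected) chi-square test and the two-proportion z test are all
available because the published table does not name its test, and the report
names the test used. Length contrasts use Welch's t-test. Per-arm scans
across 35 arms additionally report Benjamini–Hochberg adjusted p-values per
metric, alongside — never instead of — the raw p-values, since the original
analysis reported raw values only. Arms with fewer than 5 classified
molecules render their mean cells as NA: at ~30 molecules per arm a mean of
fewer than 5 lengths is too unstable to print.

One published-table note: the stressed cohort's TFE cell prints `8.0
(86/1061)`, but 86/1061 is 8.1% at one decimal — the printed percentage and
the printed counts disagree. This package treats the counts as
authoritative and renders 8.1; consequently the TFE increase computed from
counts is 62%, while the published 60% is recovered exactly when the
operation is applied to the published percentage values (8.0 and 5.0).

## Numerical choices and degenerate inputs

Golden-section stretch search uses tolerance `2e-3` on a [0.9, 1.1]
interval (the fitted stretch is only used at ~0.5% precision); the DP is
deterministic, and all tie-breaks (orientation, arm id) are lexicographic.
Degenerate inputs never throw during classification: fragments with fewer
than 2 labels, empty reference overlaps, or unassignable molecules route to
UNASSIGNED/UNCLASSIFIED with flags. Parsing and validation errors are
classed conditions (`smta_format_error`, `smta_validation_error`, ...) that
name the offending line or arm. Simulation, fixture generation and the
pipeline are deterministic given their seeds, and draw from a private RNG
stream that leaves the caller's `.Random.seed` untouched.

## Problem sizes used by the test suite

The suite validates the aligner against exhaustive monotone-matching
enumeration on 500 random instances of up to 8 labels a side; recovery of
two full-size cohorts (35 arms, 1061 and 1100 molecules at the two published
rate vectors, default noise) with per-class recall, binomial coverage of the
realized frequencies, and end-telomere mean recovery; and the 0.1–100 kb
quantification range at 1000 simulated tracts. Smaller reference sets (3–10
arms) back the per-module tests. These sizes were chosen to make each
statistical check well-powered while keeping a full run of the suite in the
minutes range on a single core.

## Known limitations

* Reference maps are user-supplied or synthetic; no motif-scanning of a real
  genome assembly is performed.
* The minimal CMAP/BNX dialects are documented text formats, not bit-exact
  renditions of the instrument vendor's formats.
* Fusion mechanism (which repair pathway produced a junction) is out of
  scope; the classifier reports topology only.
* Per-arm fusion frequencies are threshold-conditional on the assignability
  floors, as they are in any label-pattern assignment scheme.
* The two-regime length estimator assumes the fluorescence yield per kb is
  constant along a tract; saturation or quenching at very long tracts is not
  modelled.
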