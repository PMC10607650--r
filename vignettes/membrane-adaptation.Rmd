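---
title: "Quantifying fungal membrane adaptation from fatty-acid profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fungal membrane adaptation from fatty-acid profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidadapt)
library(dplyr)
```

## The scientific problem

Fungi remodel the fatty-acid composition of their membrane phospholipids to
keep membrane fluidity in a workable range — the classic *homeoviscous
adaptation*. Two stressors drive remodelling in food-relevant settings:
temperature, and dissolved CO~2~ from modified-atmosphere packaging (MAP,
typically 20% CO~2~ / 80% O~2~ for meat products). CO~2~ is both water- and
lipid-soluble, dissolves into the bilayer, and is expected to disorder it;
the open question is whether fungi respond by *solidifying* the membrane
(as they do against heat) or whether the membrane ends up *more* fluid.

The measurable quantity is the fatty-acid methyl ester (FAME) profile: for
each organism and growth condition, the percentage of total GC peak area
attributable to each fatty acid, averaged over biological replicates.
`lipidadapt` turns such profiles into two membrane-level statistics and a
set of condition contrasts.

## The two statistics

**Degree of unsaturation (DU).** The composition-weighted mean number of
C=C double bonds per fatty acid:

$$DU = 1\cdot\frac{\%\,\text{monoenes}}{100}
     + 2\cdot\frac{\%\,\text{dienes}}{100}
     + 3\cdot\frac{\%\,\text{trienes}}{100}$$

extended so that acids with four or more double bonds contribute their
actual bond count. Percentages enter exactly as reported (percent of total
peak area); we deliberately do **not** renormalize them, because the
reported values are already fractions of the same total and renormalizing
would silently reweight profiles whose minor components were censored. DU
is linear in composition: moving $x$ percentage points from a saturated
acid to a triene changes DU by exactly $3x/100$ — a property the test
suite exploits.

**Weighted average melting temperature (WAMT).** The composition-weighted
mean of the pure-compound melting points $T_{m,i}$ of the profile's acids:

$$WAMT = \frac{\sum_i w_i\,T_{m,i}}{\sum_i w_i}\quad[^\circ\mathrm{C}]$$

Lower WAMT means a membrane built from lower-melting acids, i.e. a more
fluid membrane. Unlike DU, WAMT needs an external reference: a melting-point
table. Our default covers the ten acids observed in the packaged study,
with values from standard physical-chemistry references and a per-entry
provenance note (`default_melting_table()`), and is fully overridable from
a two-column TSV. Because published WAMT columns depend on whichever
reference table their authors used, absolute agreement cannot be expected
from any independently assembled table; all our WAMT-based checks are
therefore *ordering* and *sign* checks (rank correlation with the published
column, direction of condition differences), which are insensitive to
moderate disagreement in individual $T_m$ values. The weights $w_i$ are
renormalized over the acids covered by the table — whether published WAMT
values renormalize is generally unstated, so we made renormalization the
documented behaviour and report `wamt_coverage`, the fraction of the total
quantified percentage that had a melting temperature, so low-coverage
values can be discounted.

Hydroxy acids are a special case: the melting point of 3-hydroxystearic
acid is less well attested than those of the plain acids, so its entry is
flagged low-confidence and `default_melting_table(include_hydroxy = FALSE)`
excludes hydroxy acids entirely.

## The censoring dialect

Replicate GC tables report three kinds of cell: a quantified
`mean ± sd`, `"nd"` (not detected in any replicate), and `"<1"` (detected
below the 1% reporting threshold). `"nd"` always resolves to 0. For `"<1"`
the default *zero* policy also uses 0 — this choice reproduces published DU
columns — while the *midpoint* policy (0.5%) is available for sensitivity
analysis. Censored standard deviations written `"± <0.1"` are stored as
half the bound. Profiles whose quantified means sum outside 90–102% are
rejected at construction: a compositional table far from 100% indicates a
transcription or parsing problem, not biology.

## Condition contrasts

`delta_matrix()` builds the organisms × acids matrix of mean-percentage
differences between two conditions (positive = higher under the first
condition). An acid is *not applicable* (grey in heatmaps) exactly when it
is censored or undetected in **both** conditions; if it is quantified on
one side only, the change from or to trace level is real and kept. For
display, `normalize_deltas()` divides each organism's row by its maximum
absolute delta, so every organism's strongest change has magnitude 1 and
weak responders remain visible. This per-organism max-abs scaling was a
genuinely open design choice — the alternative z-score variant is available
via `method = "zscore"` — and we chose max-abs because it preserves signs
and within-organism ratios, which is what the green/red heatmap reading
relies on.

Per-acid significance uses **Welch's unequal-variance t-test computed from
summary statistics** (`replicate_test()`), since only `mean ± sd` over
`n` replicates is available for published tables. P-values are reported
uncorrected by default — per-acid claims in this literature are customarily
uncorrected, and with ~7 acids per organism the correction is mild — with
any `stats::p.adjust` method available as an option.
`adaptation_summary()` combines everything into one row per organism:
`delta_du`, `delta_wamt`, a direction call (*fluidization* if
`delta_wamt < -0.05` °C, *solidification* if `> +0.05` °C, else
*unchanged*; the 0.05 °C dead band absorbs rounding-scale noise), and the
per-acid tests.

## The packaged study

The package ships the complete replicate-mean fatty-acid tables of 20
fungal strains (9 yeasts, 11 filamentous fungi) isolated mainly from MAP
food and mofettes, grown under 20% CO~2~ at 10 °C, normal atmosphere at
10 °C, and normal atmosphere at 25 °C — 60 profiles over 10 fatty acids,
with biological triplicates (one profile has n = 2). One strain
(*Rhizopus oryzae* M1) carries γ-linolenic acid (C18:3 cis 6, 9, 12)
instead of α-linolenic (C18:3 cis 9, 12, 15); the two isomers count
identically for DU but are distinct identities for melting-point lookup.

```{r study}
profiles <- load_fungal_profiles()
summarize_profiles(profiles) |> head()
adaptation_summary(profiles) |> select(-tests) |> head()
```

Recomputing DU from the shipped compositions reproduces the published DU
column to ±0.02 for 56 of the 60 profiles. The four exceptions (strain WT7
under CO~2~; strain M12 under all three conditions) are not reproducible
from their own published compositions under any censoring policy — most
plausibly unlisted trace acids or transcription artefacts in the source
tables — and are flagged `du_discrepant` in
`load_printed_reference()` rather than forced into agreement. For strain
M12, reproducing the published WAMT requires its trailing composition
column to be the high-melting 3-hydroxystearic acid; that assignment is
used in the fixture.

## The synthetic generator

`generate_profiles()` draws replicate compositions so that every pipeline
stage can be tested against known truth. For each organism × condition it
perturbs the condition mean (baseline plus the applicable effect vector)
with independent per-acid Gaussian noise, clips negative draws to zero
(trace acids can vanish, mirroring `"nd"`), and closes each replicate to
exactly 100%. Defaults were fixed once to mirror the packaged study: 20
organisms, 3 replicates, a typical control composition as baseline, a CO~2~
effect of +6 points linolenic, +4 linoleic, −7 oleic, −3 palmitic (analytic
DU shift $= (3\cdot6 + 2\cdot4 - 7)/100 = +0.19$), the reverse-direction
temperature effect (−4/−3/+5/+2), and noise scales of
$\min(8, \max(0.1, 0.15\,\mu_i))$ percentage points — inside the 0.1–8
point SD range of the real tables. One master seed derives per-organism
streams, so enlarging the cohort never reshuffles existing organisms.

What the generator does *not* emulate: a full compositional covariance law
(only closure-induced correlation), between-organism baseline variation,
chromatographic co-elution, or censoring of the generated means (written
files can optionally re-censor). Passing tests on synthetic data therefore
demonstrate correctness of the computations and calibration of the
testing machinery, not robustness to every property of real GC data.

## Numerical and statistical choices

* All internal computation is at full precision; the publication convention
  (DU to 2 decimals, WAMT to 1) is applied only at display/reporting time.
* `sign_recovery_rate()` scores the Welch test against ground truth. With
  effects ≥ 3× the noise scale and 10 replicates, sign recovery exceeds
  0.9 (in practice ≈ 1.0). Under a zero-effect specification at n = 3 the
  empirical rejection rate at α = 0.05 is ≈ 0.032, reproducibly *below*
  nominal. This is not a generator artefact — the same rate obtains for
  plain normal draws without closure — but the well-known conservatism of
  the Welch–Satterthwaite approximation at very small equal group sizes,
  where the random degrees of freedom fall between 2 and 4. We report the
  test as implemented (it agrees with `stats::t.test` to machine precision
  on reconstructed replicates) rather than substituting a pooled-variance
  test that would be nominal at n = 3 but unsafe under variance
  heterogeneity, which real per-acid SDs clearly show.
* Problem sizes used in the shipped checks — 1,000 random profiles for the
  DU oracle comparison, 1,000 null cells and 400 effect cells for
  calibration and power — were chosen to give binomial standard errors
  below one percentage point while keeping the whole suite fast.
* Degenerate inputs error early and explicitly: empty profiles, zero
  melting-point coverage, both group SDs zero, fewer than 2 replicates.

## Known limitations

* WAMT values are only as good as the melting-point table; they are best
  used comparatively (between conditions, with the same table).
* Mean-only profiles (no replicate vectors) limit inference to the
  summary-statistic Welch test; n = 3 gives low power, so "no significant
  change" must not be read as "no change".
* The package does not model lipid-class (head-group) composition, sterols,
  or chain-length remodelling beyond what the acid identities carry, and
  performs no chromatogram processing.
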