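---
title: "Methods: triplex real-time PCR diagnostics for Helicoverpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplex real-time PCR diagnostics for Helicoverpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliplex)
```

## The diagnostic problem

*Helicoverpa armigera* (Old World bollworm) and *H. zea* (corn earworm) are
two of the most damaging agricultural pests worldwide. Since *H. armigera*
reached the New World, geographic origin no longer identifies immature
*Helicoverpa*: larvae of the two species are morphologically
indistinguishable and adults require genitalic dissection. A hydrolysis-probe
triplex real-time PCR assay separates them in one closed-tube reaction: a
single ITS2 primer pair (425F/568R) amplifies a 140–143 bp fragment carrying
two species-discriminating probe sites (FAM-labelled probe for *H. armigera*,
HEX for *H. zea*), while an 18S rDNA primer/probe system (Quasar 670)
amplifies a conserved 68 bp fragment as a DNA-quality control. This package
implements the computational side of that assay: oligo thermodynamics,
in-silico PCR, Cq calling from fluorescence traces, the interpretation rules,
standard-curve quantification, and a synthetic data generator that makes the
whole pipeline testable without an instrument.

## Oligo model and melting temperatures

Oligos are IUPAC degenerate sequences; the ITS2 forward primer carries two
`Y` (C/T) positions and the *H. armigera* probe one, to cover the known
intraspecific haplotypes. Tm uses the long-oligo salt-adjusted formula

$$T_m = 100.5 + 41\,\frac{GC}{N} - \frac{820}{N} + 16.6\,\log_{10}[\mathrm{Na}^+]$$

at the package default of 0.05 M monovalent salt. This sodium value is the
one under which the panel's published one-decimal Tm values reproduce
exactly for the non-degenerate primers and the degenerate 425F range
(60.5–64.6 °C), so it is the default of `tm_params()` rather than a
hard-coded constant. Two caveats are deliberate:

* Degenerate Tm ranges are computed by exhaustive expansion (cap 1024)
  rather than by a min/max-GC shortcut, so the production path can be
  cross-checked against a brute-force oracle; for this formula the two
  coincide.
* The published upper bounds of the two 23-mer probes (66.6 °C) sit about
  0.2 °C above this formula's value (66.4), an ambiguity between variants of
  the salt-adjusted formula in circulation. The formula is **not** adjusted
  to force agreement; tests anchor on the exactly-reproduced entries and
  allow ±0.3 °C on the remainder.
* Reporting rounds half away from zero to one decimal (commercial
  convention); full precision is kept internally.

Sequences shorter than 14 nt are rejected: the short-oligo formula is a
different regime and deliberately out of scope, as are nearest-neighbour
thermodynamics and LNA-modified probes.

## In-silico PCR

Binding-site search treats two IUPAC codes as matching when their base sets
intersect (an `N` on either side matches anything), since templates from
direct sequencing carry ambiguity codes. Matching is purely combinatorial —
no annealing thermodynamics. Defaults are strict (`max_mismatches = 0`), and
when mismatches are allowed the three 3'-terminal bases of a *primer* must
still match exactly (polymerase extension is intolerant there); probes are
exempt. Coordinates are 0-based half-open on the template's forward strand
and the amplicon length includes both primer footprints — the convention
under which the 18S product is exactly 68 bp. Products are enumerated in
both orientations (a forward-primer `+` site upstream of a reverse-primer
`-` site, and vice versa), which makes predictions invariant under
reverse-complementing the template.

The bundled `synthetic_templates()` are constructed stand-ins, not the
deposited GenBank accessions (those would require a network fetch): real
primer and probe sites embedded in arbitrary filler, shaped to the assay's
amplicon geometry (68 bp; 140–143 bp across six ITS2-like haplotypes with
mutually exclusive probe sites and the C/T polymorphism under the armigera
probe's `Y`). They exercise the machinery; they say nothing about real
template diversity.

## Cq calling

Traces are per-cycle relative fluorescence readings (40 cycles). The caller
mirrors instrument behaviour at the level the interpretation layer depends
on — threshold crossing — without claiming equivalence to any vendor's
baseline algorithm:

* **Baseline**: a least-squares line over a pre-amplification window
  (default cycles 3–15), subtracted across all cycles. The window is
  auto-shrunk to end 5 cycles before the first cycle exceeding 10% of the
  signal range, and only traces with a signal range above 200 RFU are
  considered amplifying (flat control traces keep the configured window).
  When fewer than 8 clean cycles remain the baseline degrades gracefully to
  a constant (a fitted slope on 3–5 noisy points extrapolates its noise into
  the crossing region); when fewer than 3 remain, `subtract_baseline()`
  errors, and `call_plate()` falls back to subtracting the mean of the first
  three cycles with a QC note rather than failing the plate.
* **Cq**: first crossing of the threshold (default 1000 RFU, the assay's
  published operating point), linearly interpolated between flanking cycles.
  Absence is a distinct state (`NA`), never 0; the 0-coded convention exists
  only in the `zero_coded` CSV dialect for instrument-export round trips.
* **End RFU** is the final-cycle corrected reading. A trace whose end RFU
  stays below threshold always yields an absent Cq — this is precisely the
  mechanism that suppresses the sub-1000-RFU cross-reactive signal the
  wrong-species probe produces.

## Interpretation rules

Four rules, with thresholds held in `assay_config()` (they are
instrument-dependent and were calibrated on one platform):

1. control probe Cq in (0, 40], else **NO_DNA**;
2. target probe Cq in (0, 40];
3. ΔCq = control − target in (0, 7] — the control system is tuned less
   sensitive than the diagnostic probes, so a genuine target sits a bounded
   distance *below* the control;
4. both targets in-window simultaneously is not interpretable.

`interpret_sample()` evaluates 1 → 4 → 2 → 3, deciding dual positivity
before any single-species logic (the published rule list does not fully fix
the branch order; this ordering is this package's choice). A target outside
(0, 40] is treated as absent throughout, since rules 2 and 4 share the same
window. Control firing with no target is reported as
**NEGATIVE_NON_TARGET** — "not *H. armigera* or *H. zea*" — not as a
failure. A single in-window target failing rule 3 is **INCONCLUSIVE**; the
decision-tree figure in the source assay does not state whether that branch
means "retest" or "negative", so no concordance is claimed for it. Every
call carries a rule-by-rule trace for auditability, and boundary semantics
are exact: Cq = 40.0 passes, ΔCq = 7.0 passes, ΔCq = 0 fails.

Bulk-trap pooled samples and hybrid individuals are out of scope: the assay
is documented not to work on bulk mixtures, and hybrids were never tested.

## Standard curves

`fit_standard_curve()` regresses Cq on log10(concentration) by OLS over
per-concentration means (matching how replicate dilution series are
averaged; raw-replicate mode behind a flag). Efficiency is derived from the
slope as $E = 10^{-1/\text{slope}} - 1$ — standard vocabulary, reported even
though the source assay never prints it. The detection floor is the lowest
concentration with every replicate detected, all higher concentrations also
complete — matching the "applicable to ≥ 0.01 ng/µl" usage. A flat series is
flagged degenerate (efficiency undefined) rather than fit.
`compare_multiplex_modes()` screens simplex/duplex/triplex runs for shifts
beyond a 0.5-cycle equivalence margin.

## What the synthetic generator emulates — and what it does not

`generate_plate()` draws the control-channel Cq from a truncated normal per
class and the target channel as control − ΔCq with ΔCq from its own
truncated normal. Parameters are the per-class summaries observed on the
452-specimen development cohort (means, SDs and ranges for *H. armigera*,
*H. zea* and non-target Heliothinae; see `default_species_profiles()`).
Modelling choices a user should know:

* The truncated-normal family is a choice; only summary statistics were
  published. Bounds are the published ranges.
* ΔCq-coupled generation (control drawn first, then the difference) reflects
  that rule 3 operates on the difference and that its distribution is what
  was characterised. The correlation between control Cq and ΔCq is
  unreported; they are generated independently, an assumption.
* Cross-reactive wrong-channel signal occurs with probability 0.5 per
  target-bearing well (frequency unpublished — "low levels of binding" on
  the alternate species) with end RFU uniform on 100–600, below the 1000-RFU
  threshold and usually < 500, as observed.
* Traces are logistic sigmoids with per-well plateau 1500–4000 RFU (end RFUs
  "in excess of 2000 for most samples"), growth rate 0.8–1.2 per cycle,
  linear drift up to 1.5 RFU/cycle, offset 50–300 RFU and 2-RFU read noise.
  The midpoint is placed so the analytic threshold crossing equals the drawn
  Cq, making the Cq caller testable against exact ground truth (recovery is
  within 0.1 cycles; the residual is linear-interpolation bias on a convex
  sigmoid plus baseline estimation error).
* Mixed-template behaviour is pattern-programmed, not mechanistic: the
  minor species' channel reports only at the characterised ratios (DNA:
  armigera-minor at 1:1 only, mean Cq 19.35; zea-minor through 1:100, means
  16.70/19.85/22.77; legs: armigera-minor at 1:1 only, mean 21.02). The
  mechanism (RNA or ITS2 copy-number competition) was hypothesised but never
  modelled. Leg bulks with *zea* as the minor species were never
  characterised and are refused rather than invented. The control channel
  of a mixed well is unpublished; it is coupled to the major species'
  channel through that species' ΔCq distribution.
* No mechanistic PCR kinetics (primer depletion, polymerase saturation) and
  no inter-instrument noise model.

Passing tests on this generator therefore demonstrate that the pipeline is
correct *given* the published statistical structure — not that it would
survive instrument artefacts (spikes, evaporation drift, optical cross-talk)
absent from the model.

## Numerical choices and degenerate inputs

* Truncated-normal sampling by inverse-CDF, so a fixed seed reproduces runs
  byte for byte; impossible bounds error out.
* Cq interpolation is linear between flanking cycles (log-linear was
  evaluated and is *worse* near plateau-limited crossings, and the linear
  rule is what single-threshold instrument software documents).
* Writers emit fixed decimal formats and stable column order: outputs are
  diffable across runs at fixed seed.
* Multi-plate runs are supported by naming wells `P<k>-A01..H12`; a "plate"
  is a run, not a 96-well cap.
* Validation sizes used in the test suite: 10,000-well draws for
  distribution means, a 452-sample cohort for end-to-end calling, 200
  seeded dilution series (5 decades × 3 replicates, 0.2-cycle noise) for
  slope recovery, chosen to make sampling error a small fraction of the
  tolerances being asserted.

## Worked example

```{r example}
run <- generate_plate(c(armigera = 4, zea = 4, non_target = 2, ntc = 1),
                      seed = 11)
results <- call_plate(run$traces)
calls <- interpret_plate(results, default_assay_config())
table(calls$call)
```

```{r trace}
print(structure(list(sample_id = calls$sample_id[1], call = calls$call[1],
                     delta_cq = calls$delta_cq[1],
                     rule_trace = calls$rule_trace[[1]]),
                class = "diagnostic_call"))
```

## Known limitations

* The Tm formula variant ambiguity above (±0.2 °C on two probe upper
  bounds).
* The rule thresholds are platform-calibrated; on other instruments (e.g.
  a SmartCycler-class machine with its 30-unit threshold — see the bundled
  `"cepheid"` configuration) the ΔCq bounds may need re-derivation.
* The in-silico layer evaluates *given* oligos; it does not design primers,
  search genomes, or predict dimers/hairpins.
* Species calls outside *H. armigera* / *H. zea* / "neither" are not
  attempted; the assay was characterised against New World Heliothinae
  only.
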