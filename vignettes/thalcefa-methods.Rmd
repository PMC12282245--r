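---
title: "Dosage-ratio genotyping of thalassemia from CE fragment data: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-ratio genotyping of thalassemia from CE fragment data: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalcefa)
```

## The measurement model

A multiplex fluorescent PCR panel amplifies, in one capillary run per
sample, three kinds of evidence about the alpha- and beta-globin loci:

* **Dosage amplicons.** Four reference amplicons — `alpha1` and `alpha2` in
  the NED channel, `Y1` and `Y2` in the VIC channel — sit in the homologous
  segments of the alpha-globin cluster that are gained and lost by unequal
  crossover between the X/Y/Z boxes. Peak height in a fragment
  electropherogram is proportional to starting template copy number, so the
  height ratios alpha1/alpha2 and Y1/Y2 report the diploid copy
  configuration. Each chromosome-level allele contributes an integer copy
  count (0, 1 or 2) to each of the four amplicons; a diploid genotype
  contributes the sum over its two alpha alleles. The normal allele
  contributes (1, 1, 1, 1); the 3.7 kb rightward deletion (1, 0, 0, 1); the
  4.2 kb leftward deletion (1, 0, 1, 0); the two triplications are the
  crossover complements of the deletions, (1, 2, 2, 1) and (1, 2, 1, 2); the
  rearranged `HKaa` allele is (1, 1, 0, 2); and the whole-cluster deletions
  (`--SEA`, `--THAI`) are (0, 0, 0, 0). This copy table is the unique
  small-integer solution that reproduces all six published theoretical
  heterozygote-with-normal ratio pairs, and it satisfies the crossover
  conservation law: deletion plus matching triplication equals twice the
  normal allele, segment by segment.
* **Breakpoint (gap) amplicons.** Deletions with characterized junctions
  (`--SEA`, `--THAI`, the rare `-a2.4`/`-a21.9`/`-a27.6` and fusion alleles
  on the alpha side; the Chinese ^G^γ^+^(^A^γδβ)^0^, SEA-HPFH and Taiwanese
  deletions on the beta side) are evidenced by junction-specific amplicons
  that appear only when the deletion is present.
* **Allele-specific mutation amplicons with wild-type controls.**
  Non-deletion point variants are evidenced by ARMS-style amplicons —
  alpha-side in VIC, beta-side in FAM. For a configurable subset of sites a
  NED amplicon specific to the wild-type base is also present: mutation peak
  plus wild-type peak reads as heterozygous, mutation peak without it as
  homozygous. Sites without a wild-type control cannot distinguish the two
  (`HET_OR_HOM`), which is exactly the published irreducible ambiguity for
  the βCD37 case; the default panel deliberately reproduces it.

GAPDH (FAM) and AMEL (VIC) internal controls must amplify above the
analytical threshold in every sample; failure is terminal for that sample
(`UNINTERPRETABLE`), distinct from a quality `NO_CALL`, because a control
failure indicates degraded template rather than ambiguous dosage — the
remedy is re-extraction, not re-interpretation.

## Copy-number classification

Measured ratios are classified in log space. Ratios are multiplicative
quantities, and the published per-class spreads are small, so the
delta method gives the log-scale SD of a class as `sd/mean` of its
published ratio. The six validated heterozygote-with-normal classes carry
their published means and SDs; all other copy configurations expressible by
the allele catalog ("extended" classes: homozygous deletions and
triplications, trans compounds) are generated programmatically from the
copy table, with the largest validated log-SD (0.175) as their spread.

Candidate classes are first filtered by the absence pattern: a class whose
zero-copy amplicons do not match the observed absent peaks is excluded
outright, and an observed pattern matching no class is an explicit
`NO_CALL`. Survivors are scored per defined ratio dimension by
`z = (log m − log r) / sd_log` and ranked by penalized Gaussian negative
log-likelihood

```
NLL(class) = sum(z^2)/2 + sum(log sd_log) − log(prior)
```

rather than by the bare distance `sqrt(sum(z^2))`. The two refinements
matter:

* **Likelihood normalization** (`+ log sd`). A wide class otherwise wins
  ties anywhere near a narrow class's centroid simply because its `z` grows
  slowly; including the normalizing constant compares densities, not
  distances.
* **Class priors.** Validated carrier classes have prior weight 1; extended
  configurations 10^-3^. Homozygous triplications and trans
  deletion-plus-triplication compounds are orders of magnitude rarer in a
  screening population than carrier states, and the prior encodes that the
  way any genotype caller with population context would. At the default
  noise scale this choice is what keeps the six validated classes at
  ≥ 99% correct classification (measured 500/500 per class in the test
  suite) while leaving extended configurations still callable: at zero
  noise an extended class at its own centroid beats every validated
  neighbour by more than 5 log-likelihood units.

Two quality gates remain on top of ranking: the call is refused when the
best class's combined distance `sqrt(z_a^2 + z_y^2)` exceeds `max_z`
(default 4), or when the runner-up is within `tie_margin` (default 0.5 log
units — a likelihood ratio below ~1.65). Classification is scale-invariant
by construction: a shared amplification factor cancels from both ratios.

## Genotype assembly

The assembler enumerates every unordered alpha-allele pair and beta-allele
pair in the panel catalog (precomputed once per panel as evidence
signatures) and intersects four constraints: the pair's copy-configuration
class must equal the called class; its predicted breakpoint-marker set,
mutation-amplicon set, and wild-type-control presence/absence must each
equal the observation. Alpha and beta evidence are disjoint by channel
design, so the match factorizes into independent alpha-side and beta-side
lookups.

One surviving genotype is an `OK` call. Several are reported as
`AMBIGUOUS`, all listed, ordered by total variant-allele count so the most
parsimonious interpretation leads. Zero survivors is a `NO_CALL` with the
conflicting side recorded — this covers evidence that is internally
inconsistent, e.g. a `--SEA` junction peak alongside clean 2:1 dosage
ratios, a situation the assay itself cannot produce.

Ambiguity is deliberately not collapsed. Two distinct sources exist:

* **Missing discriminating target.** βCD37 carriers without the wild-type
  control, and beta-deletion carriers (called from their junction peak
  only, with no beta dosage amplicons in the panel) are reported with both
  zygosities and flagged `ZYGOSITY_UNRESOLVED`.
* **Copy-compensated configurations.** A deletion and its matching
  triplication in trans sum to (2, 2, 2, 2) — dosage, marker and mutation
  evidence identical to wild type. Wild-type samples therefore list the
  trans compounds as alternates (flag `CNV_COMPENSATED_ALTERNATES`), with
  the wild-type interpretation first. Collapsing to the parsimonious
  genotype would silently miscall a true trans carrier; listing preserves
  the truth in the call set for every genotype the panel can express, which
  the exhaustive round-trip test verifies for all 861 genotypes with up to
  two variant alleles.

The rare alpha deletions (`-a2.4`, `-a21.9`, `-a27.6`, the fusion allele)
rest on their junction amplicons; their dosage copy maps are modelling
defaults of the `-a4.2` type and calls involving them carry a
`LOW_CONFIDENCE_ALLELE` flag. Whether `--THAI` removes Y1/Y2 exactly as
`--SEA` does is likewise assumed (both are whole-cluster deletions) rather
than measured.

## Trace processing

Raw traces are handled with deliberately simple, testable primitives, since
production instruments ship their own peak software: baseline is a rolling
minimum (default window 51 scans) subtracted and clamped at zero; peaks are
local maxima above a height threshold with a topographic-prominence
requirement; the size standard is fitted by matching the tallest LIZ peaks
in scan order to the known ladder series (a 20–600 bp series of 36
fragments by default) and interpolating scan-to-bp piecewise linearly, with
leave-one-out residuals as the quality check (≥ 8 matched points,
residuals ≤ 1 bp, else `LADDER_FAILURE`, terminal for the sample). The
mapping is monotone by construction and invariant to affine
reparameterization of migration. Peak quantity is height, not area,
matching how the ratios were validated.

Peak-to-target binding uses a tolerance of 1.4 bp — intentionally less
than half the 3 bp minimum same-dye spacing the panel design guarantees, so
no peak can ever satisfy two targets. Ties on height break toward smaller
size error, then smaller size; binding is deterministic and independent of
input row order. Exact amplicon sizes are panel metadata, not algorithm:
the shipped panel places them on a deterministic grid (85 bp start, 4 bp
steps per dye) that satisfies the design constraints, and every piece of
calling logic is size-agnostic.

## The simulator and what it does (not) show

The simulator exists so the whole pipeline is testable without instrument
data. For a genotype it renders one peak per expected target: height =
`base_height × efficiency × dose × lognormal noise`, with dose the summed
copy count (dosage amplicons), carrier count (variant and control
amplicons) or 2 (internal controls); size is jittered (SD 0.15 bp) around
the target's expected size; peaks below a dropout threshold vanish.
Traces render each peak as a Gaussian (σ = 3 scans) under an affine bp→scan
map, plus the full ladder in LIZ and a constant baseline.

Height noise is lognormal because amplification errors are multiplicative.
The two dosage pairs share primers (alpha1/alpha2 a common upstream primer,
Y1/Y2 both primers), so their within-pair noise is correlated; the
simulator models this with a shared pair-level component (default
correlation 0.5) plus an independent component. At the default
`noise_cv = 0.07` this yields a dosage-ratio log-SD of ≈ 0.07 — the scale
of the published per-class ratio SDs — where fully independent per-peak
noise would inflate it by √2. A `table1` efficiency preset skews the
dosage amplicons so cohort ratio means land on the published measured
means (e.g. 1.04/0.92 for wild type) instead of the exact theoreticals,
emulating systematic primer-efficiency bias. An optional shared per-sample
scale factor exercises scale invariance. All randomness is seed-driven;
identical parameters and seed give byte-identical peak tables, and cohorts
derive independent per-sample seeds from one master seed.

What passing simulated tests does **not** show: the simulator has no
stutter, pull-up/spectral overlap, injection bias, baseline drift beyond a
constant, or inter-run migration variation, and its noise is exactly the
model the classifier assumes. Results on real electropherograms depend on
upstream peak software and instrument behaviour that these tests do not
exercise. The published clinical figures (200-sample cohort, 99.5%
accuracy) are population-scale wet-lab results; the package's analogues are
the exhaustive zero-noise round trip and the noisy per-class
classification rates, both computed by the test suite at desk scale
(861 genotypes; 500 samples per validated class).

## Defaults worth knowing

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `analytical_min_height` | 200 | RFU | Peaks below are not interpreted; the published method names the threshold concept but not a value. |
| `size_tolerance` | 1.4 | bp | < half the 3 bp same-dye spacing ⇒ binding is unambiguous. |
| `min_same_dye_spacing` | 3 | bp | Panel design rule. |
| `max_z` | 4.0 | – | Combined-z quality gate for the dosage class. |
| `tie_margin` | 0.5 | log units | Refuses calls the evidence cannot separate. |
| `noise_cv` | 0.07 | – | Per-peak lognormal CV; with pair correlation 0.5 it reproduces the published ratio spread. |
| `pair_correlation` | 0.5 | – | Shared-primer correlation of dosage-pair heights. |
| extended class prior | 10^-3^ | – | Rarity of unvalidated copy configurations relative to carrier classes. |

## Worked example

```{r}
panel <- default_panel()
zero <- sim_params(noise_cv = 0, size_jitter_sd = 0)
s <- simulate_peak_table(list(alpha = c("aCD74a", "-a4.2"),
                              beta = c("bCD17", "bN")),
                         panel, zero, seed = 1)
call <- call_sample(s, panel)
call
c(a = call$ratios$a_ratio, y = call$ratios$y_ratio)
```

## Known limitations

Beta-side copy number is not modelled at all (no beta dosage amplicons);
beta deletions are breakpoint-only evidence with unresolved zygosity.
Severity interpretation, prenatal risk, and sex determination from AMEL
fragment sizes are out of scope — AMEL is presence/absence QC only. The
dosage behaviour of the four rare alpha alleles is a flagged default. The
copy model cannot separate configurations with identical copy sums, and
does not try to: they are reported as ambiguity.
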