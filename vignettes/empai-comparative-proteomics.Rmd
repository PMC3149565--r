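---
title: "Label-free comparative proteomics with emPAI: models, parameters, and design choices"
author: "empaiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free comparative proteomics with emPAI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empaiq)
```

## The problem

Two related bacterial strains — here a spinosad-producing
*Saccharopolyspora spinosa* parent (SP06081) and a higher-yielding
derivative (PR2) — are profiled by shotgun LC-MS/MS. Each strain is grown
as two biological cultures, and each culture is injected three times, so
every strain contributes six runs. The identification step (database
search, FDR filtering) is upstream of this package: the inputs are a
protein FASTA, a per-run spectral-count table, a run design map, and a
flat GO-category map. The questions the package answers are the
semiquantitative ones: which proteins are exclusive to one strain, which
shared proteins changed abundance, how the functional composition of the
two proteomes differs, and whether selected transcripts move in the same
direction by RT-PCR.

## Abundance model

The abundance estimate is the exponentially modified protein abundance
index. For a protein with spectral count $SC$ in one run and $OP$
observable tryptic peptides,

$$\mathrm{emPAI} = 10^{SC/OP} - 1 .$$

Dividing $SC$ by $OP$ corrects the raw count for protein size: a large
protein offers more peptides to the mass spectrometer and accumulates more
spectra at equal molar abundance. $OP$ is obtained by in silico tryptic
digestion (cleavage after K/R, suppressed before proline) followed by a
mass filter: only peptides whose mass falls inside the instrument scan
window, 600–3500 Da for the LTQ-class ion trap assumed here, are
observable. The source study's methods section elides the emPAI formula
line itself; the definition above is the standard one from the
spectral-counting literature the study builds on, and we flag that
reconstruction here and in `?empai`.

Per strain, the six per-run emPAI values are summarized as their mean
(MEP) and the root-mean-square deviation about it (MSD). "Mean square
deviation" is read literally as the population RMS deviation (divide by
$n$); `sample_sd = TRUE` switches to the $n-1$ form, and the choice is
part of the reported configuration. A run in which a detected protein was
not observed contributes $SC = 0$, hence emPAI $= 0$ — a measured absence,
not a missing value.

## Differential calls

Each strain's expression of a shared protein is an interval
$[\mathrm{MEP}-\mathrm{MSD},\ \mathrm{MEP}+\mathrm{MSD}]$. With PR2 as
test and SP06081 as reference, a protein is

* **increased** when $p < 0.05$ and
  $\dfrac{\mathrm{PR2}(\mathrm{MEP}-\mathrm{MSD})}{\mathrm{REF}(\mathrm{MEP}+\mathrm{MSD})} \ge 1.5$,
* **decreased** when $p < 0.05$ and
  $\dfrac{\mathrm{PR2}(\mathrm{MEP}+\mathrm{MSD})}{\mathrm{REF}(\mathrm{MEP}-\mathrm{MSD})} \le 0.67$,
* **constant** otherwise (overlapping intervals fail both gates).

The thresholds are kept exactly as published. Note $0.67 \ne 1/1.5$, so
the rule is slightly asymmetric under a strain swap; we prefer fidelity
over elegance and document the asymmetry rather than repairing it. The
gate is a two-sided Welch $t$-test on the per-run emPAI values
(pooled-variance available via `var_equal`); the published analysis says
only "$t$-test", and Welch is the safer default for groups whose variances
need not match. No multiple-testing correction is applied by default
because the original analysis gates on raw $p < 0.05$; `p_adjust = "BH"`
is available. Strain-exclusive proteins are never classified — presence
vs. absence is not a ratio — and are reported in separate tables.

Because MEP − MSD can be non-positive, ratios need a convention: a
non-positive denominator with a positive numerator is treated as $+\infty$
(the evidence for separation is maximal), and a ratio with numerator and
denominator both non-positive is undefined and yields *constant*. The
published analysis mentions "six expression profiles" but defines only
up/down/constant; we implement the three defined classes.

## Functional profiling and protein properties

Proteins map to ten biological-process categories (biosynthetic process,
catabolic process, oxidation reduction, transcription, translation,
transport, TCA cycle, proteolysis, glycolysis, other) through a flat
accession-to-category table; anything unmapped lands in "no description".
The map is a file, not a live ontology query, for reproducibility. A
strain's profile is the percentage of its identified proteins per
category, and the between-strain fold change is the PR2 percentage divided
by the SP06081 percentage — values above 1 mean the category gained weight
in the PR2 set. A zero reference percentage makes the ratio undefined
(`NA`), never infinite. Percentages are stored at full precision and
rounded to integers only in summaries.

Theoretical pI is the root of the Henderson–Hasselbalch net-charge
equation over the termini and the D, E, C, Y, H, K, R side chains, found
by bisection (charge is strictly decreasing in pH, so the root is unique).
The default pK set is the EMBOSS scale; other published scales shift pI by
roughly 0.1–0.3 units, so the scale is part of any reported result and is
configurable. The bisection tolerance is $10^{-6}$ pH so that the residual
charge is far below $10^{-3}$ elementary charges even for lysine-rich
proteins. Molecular weight is the sum of average residue masses plus one
water; monoisotopic masses drive the peptide-level scan-window filter.
Both residue tables are built in and validated against an independent mass
calculator in the test suite.

## RT-PCR confirmation

Transcript-level confirmation uses the comparative-Ct method:
$\Delta Ct = Ct_{target} - Ct_{reference}$ per sample,
$\Delta\Delta Ct = \Delta Ct_{test} - \Delta Ct_{calibrator}$, and the
relative expression is $2^{-\Delta\Delta Ct}$ with the reference gene
*sigA* and the SP06081 sample as calibrator (ratio 1 by construction).
Replicate Ct measurements are averaged before exponentiation. The
amplification efficiency is fixed at 2.0 — the classic assumption of
perfect doubling — with an `efficiency` argument for assays with measured
efficiencies. Replicate fold determinations are summarized as mean ±
standard error (SEM; `error = "sd"` switches to the standard deviation).

## What the synthetic generator emulates

`sim_config()` freezes the study conditions: 288 proteins, of which 84 are
exclusive to SP06081 and 64 to PR2 (so 140 are shared), 21 planted
up-regulated and 23 planted down-regulated proteins at a 5-fold effect,
two strains × two biomasses × three technical replicates, and
overdispersed counts (negative binomial with
$\mathrm{Var} = \mu + d\mu^2$; $d = 0$ gives Poisson, the default $d =
0.05$ is mild technical-replicate overdispersion).

Sequences are i.i.d. residues over the 20 canonical amino acids with
mildly enriched K/R content, lengths uniform on 90–900 residues
(roughly 10–100 kDa), rejected in the rare case they yield no observable
peptide, so emPAI is defined for every protein. Being i.i.d., they do not
reproduce the composition biases of a real proteome — in particular the
bimodal pI distribution of real bacterial proteomes arises from real
acidic/basic protein classes, not from random sequences — so the pI/Mw
histogram stage is exercised mechanically, not distributionally.

Two generator choices deserve emphasis because they decide whether planted
effects are recoverable at all:

* **Counts scale with protein size.** A protein's expected spectral count
  per run is `base × OP / op_reference`: more observable peptides, more
  spectra. This is the very size dependence emPAI divides away. Without
  it, a small protein given a typical count draw has $SC/OP \gg 1$ and
  its emPAI explodes ($10^{20}$ and beyond), which makes MEP ± MSD
  intervals and $t$-tests on emPAI meaningless. Real data do not live in
  that regime (typical emPAI values run from well below 1 to a few tens).
* **Planted effects sit where they are measurable.** Plants are placed on
  proteins with at least `plant_min_op = 50` observable peptides and a
  moderately abundant base draw (`plant_abundance_range`, 10–13 expected
  SC per run at reference size). This is the logic of a spike-in
  experiment: a 5-fold depletion of a protein whose expected count is
  already below one spectrum per run is invisible to any classifier over
  six runs, so planting effects there would measure the detection floor,
  not the classifier. Background proteins keep the broad abundance range
  (2–15 SC per run at reference size), so the constant and exclusive
  populations still span the sparse regime.

Strain-exclusive proteins are structurally absent (mean zero) from the
other strain by default, matching a hard presence/absence partition;
`exclusive_mode = "dropout"` instead leaves a small mean
(`dropout_factor`) to emulate sampling dropout, since the real mechanism
behind the 84/64 exclusives is unknowable from the published data.
Category assignment is uniform over the ten categories unless weights are
given. All stages derive their RNG streams from the single `seed`, and
identical configurations are byte-identical in their outputs, FASTA
included.

What passing the synthetic tests shows, therefore, is that the arithmetic
and the decision rules are implemented correctly and that the pipeline
recovers effects that are in principle recoverable; it does not show that
the published biological calls on real spectra would be reproduced, which
would require the unreleased raw data.

## Numerical and degenerate-input conventions

* Scan-window bounds are inclusive: eliminated means strictly outside
  600–3500 Da.
* The observable-peptide count uses fully cleaved products
  (`missed_cleavages = 0`) and unique peptide sequences by default; the
  upstream database search allowed one missed cleavage, but the OP
  convention of the digestion tool used in the original analysis is
  unstated, so the conservative definition is the default and both knobs
  are exposed.
* $t$-tests on degenerate (zero-variance) data fall back to $p = 1$ for
  equal means and $p = 0$ otherwise instead of erroring.
* Empty protein sets, missing quantification records, unsorted histogram
  edges, non-canonical residues, and missing Ct measurements raise typed
  errors naming the offender; histogram bins are half-open with a closed
  last bin, so no value at the final edge is silently lost.
* The pipeline removes partial outputs when a stage fails and labels the
  error with the stage name; every completed run writes a JSON metadata
  file carrying the full configuration echo, its MD5 hash, and the seed.

## Problem sizes used by the test suite

The shipped tests run the full design at its natural size (288 proteins,
12 runs) for the recovery checks, 500 proteins for the null-calibration
check (≤ 10% non-constant calls at `effect_fold = 1`), 100-instance
brute-force oracle sweeps for digestion, emPAI, MEP/MSD, pI, Mw, and ddCt,
and 40–120 proteins for pipeline smoke and determinism checks. These sizes
were chosen as the smallest that exercise every code path with comfortable
statistical margins.

## Known limitations

* The emPAI formula is a reconstruction (see above); any analysis that
  used a different normalization would need a different `empai()`.
* The interval classifier has no error control beyond the raw $t$-test
  gate; with 140 proteins and six runs it is a screening rule, not an
  inference procedure.
* The generator does not simulate peptide-level identification, shared
  peptides between homologous proteins, or run-to-run alignment effects;
  counts are drawn independently per run.
* pI and Mw are sequence-only predictions; modifications and processing
  are ignored.
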