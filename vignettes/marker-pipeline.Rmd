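---
title: "Mining and validating species-diagnostic KASP and SCAR markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating species-diagnostic KASP and SCAR markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermine)
```

## The problem

Endangered plant taxa that hybridize freely with sympatric relatives — the
motivating case is a terrestrial orchid growing alongside two congeners in
an island habitat — cannot be reliably identified from morphology alone.
Hybrid swarms produce individuals whose flowers mimic a parental species
while their genomes carry introgressed alleles, and conversely produce
atypically coloured individuals that are genetically close to the
purebreds. Propagating a cryptic hybrid as breeding stock risks outbreeding
depression in the very population a programme is trying to restore.

`markermine` implements the genomics-to-assay workflow that addresses this:
mine a genotyping-by-sequencing (GBS) panel for *fixed homozygous alleles*
unique to the target species, convert the best loci into cheap PCR assays
(fluorescence-read KASP for the laboratory, gel-read SCAR for the field),
call species from the raw assay observations, and quantify diagnostic
performance against the field classification.

## The fixed-allele definition and two-stage training

A locus is diagnostic when

1. every confirmed purebred of the target species is homozygous for one
   common allele, and
2. that allele is entirely absent — counting heterozygous carriers — from
   the contrast population.

`mine_fixed_alleles()` enforces the strictest reading: any missing genotype
in either set disqualifies a locus, because "100% homozygous" and
"frequency = 0" are not defined under missingness, and a permissive reading
risks designing an assay around an artifact. Heterozygous reference
genotypes likewise disqualify (fixation *is* homozygosity).

Training proceeds in two stages (`two_stage_mining()`). Stage 1 takes the
entire morphologically classified target pool — typical individuals plus
atypical colour variants — as the reference. If that pool hides a cryptic
hybrid, stage 1 finds *no* diagnostic loci: an F1 is heterozygous at every
genuine fixed difference, violating condition (1) everywhere. Assay
validation then exposes the hybrid (dual fluorescence at every marker), the
training set is refined, and stage 2 re-mines with the confirmed purebreds
only.

One design point deserves emphasis. The contrast set consists of the
non-target *species* individuals; known hybrids — both the natural F1s and
any reclassified cryptic hybrid — are excluded from it. A hybrid carries
one target-derived allele at every genuinely diagnostic locus by descent,
so placing it in a contrast set whose rule is "frequency exactly 0" would
veto the entire candidate list. Reclassified *variants*, which genotype as
non-target at diagnostic loci, do join the stage-2 contrast and sharpen it.
This is the only reading of the two-condition definition under which a
panel containing hybrids can yield any markers at all.

## The QC cascade

`filter_loci()` applies, in a fixed order: per-genotype depth masking
(depth ≥ 3 reads, inclusive), site mapping quality (MAPQ ≥ 20, inclusive),
per-locus missingness (< 30%, strict, computed after depth masking so that
low-depth calls count as missing), folded minor-allele frequency (> 5%,
strict, computed panel-wide over non-missing calls), and an exact
Hardy–Weinberg equilibrium test within the confirmed purebred population,
removing loci with p < 0.001. The boundary semantics follow the
conventional threshold statements exactly as printed above.

The equilibrium test (`hwe_exact_test()`) is the exact conditional test:
given the observed allele counts, it sums the probabilities of all
heterozygote counts no more probable than the observed one. An exact test
is preferred over the chi-square approximation because the purebred
population is small (n = 32 in the emulated design). Two subtleties:

* the HWE population must be the *confirmed purebreds*. Running it on the
  mixed training pool (purebreds + variants + a cryptic hybrid) removes
  exactly the diagnostic loci being sought — a mixed pool shows a massive
  heterozygote deficit at every fixed difference. `run_full()` therefore
  refines the training set from the KASP calls before filtering.
* loci with no genotyped individual in the HWE population carry no
  evidence against equilibrium and are retained.

The cascade is idempotent, and tightening the MAPQ, missingness, MAF or
HWE thresholds can only shrink the surviving set. Tightening the *depth*
threshold is not formally monotone: extra masking changes the post-mask
allele frequencies, and in contrived cases a locus can cross the MAF
boundary in either direction. The per-stage report telescopes exactly
(each stage's entering count is the previous stage's surviving count).

## Assay design

`primer_properties()` computes length, GC fraction, and melting temperature
from nearest-neighbor duplex thermodynamics (the standard unified
dinucleotide parameter set with terminal initiation corrections), a
monovalent-salt entropy correction of 0.368 cal mol⁻¹ K⁻¹ per phosphate,
and the two-state formula at 200 nM primer / 50 mM Na⁺. The model is
isolated behind this one function; assays validate against the constraint
windows (Tm 58–62 °C, GC 40–60% inclusive at both ends, length 20–30 nt)
under this model, not against any external predictor.

`design_kasp()` screens for two allele-specific primers that terminate on
the variant base (SNPs) or span the InDel junction (ending two bases into
the allele-specific sequence), plus one common primer on the opposite side
within 120 bp. Both strands are screened. Ranking is by worst
allele-primer |Tm − 60|, then common-primer |Tm − 60|, then length and
distance to the variant — all mirror-invariant quantities — with exact
configuration ties broken toward the input's forward strand. As a result
the design is deterministic and strand-symmetric: designing on the
reverse-complemented flank returns the same physical primer molecules with
the strand label flipped. The commercial universal fluorescent tails are
proprietary and are not appended; assays carry a dye map (target allele →
HEX, alternative → FAM) instead.

`design_scar()` supports both gel-assay geometries. Codominant: both
primers outside the InDel, both alleles amplify, sizes differ by the InDel
length, which must be ≥ 20 bp for unambiguous separation on agarose.
Dominant: the reverse primer sits inside the insertion-specific segment,
so the deletion allele yields no product at all — the geometry that gives
the target species a diagnostic *null* (no-band) phenotype.

## Calling

`call_kasp()` uses a fixed allele-ratio rule rather than clustering: wells
below a total-intensity floor (default 0.30) are no-calls; otherwise the
HEX fraction r = HEX/(FAM+HEX) maps to target homozygote (r ≥ 0.80),
alternative homozygote (r ≤ 0.20), heterozygote (0.35 ≤ r ≤ 0.65), and
no-call in the gaps. A deterministic rule is auditable and sufficient for
endpoint clusters as well separated as validated assays produce; a
clustering-based caller is deliberately out of scope. All thresholds are
configurable (`kasp_thresholds()`).

`kasp_species_call()` aggregates assays conservatively: any heterozygous
assay flags a hybrid; conflicting homozygote calls are ambiguous; a
no-call among otherwise consistent assays yields the consistent call
flagged low-confidence.

The merged two-locus SCAR rule (`combined_scar_classify()`) encodes the
validated combined-pattern table: with the dominant marker's band absent
(X) or present (O) and the codominant marker read as 516-type, 537-type or
both, the target patterns are X:516, X:516/537 and O:516; O:537 is
non-target and O:516/537 a heterozygous hybrid. Two notes:

* the validated table lists O:516 (dominant band present, codominant
  target-size) as a *target* pattern even though the dominant band
  otherwise indicates non-target; it is encoded as validated.
* every combination outside the table — notably a lane with no
  amplification anywhere (X:none) — returns `ambiguous`, never `target`.
  For a conservation screen the fail-safe direction is to withhold a
  purebred certificate, not to issue one.

Band sizes are matched within ±5 bp (default); the 516/537 pair (21 bp
apart) remains unambiguous at that tolerance.

## Scoring

`score_panel()` implements two scoring conventions and refuses to default
silently, because they answer different questions. Under the
*morphological* convention a call is concordant when it matches the field
label (with hybrid calls counting as non-target); this measures agreement
with pre-classification, and is the convention under which a cryptic
hybrid among the morphological purebreds appears as a discordance. Under
the *genetic* convention calls are matched against the simulated (or
otherwise known) genetic truth; this measures diagnostic accuracy proper.
Sensitivity is always computed over the genetically confirmed purebreds and
specificity over the genetic non-targets (hybrids included), under the
chosen convention.

Confidence intervals are Wilson score intervals without continuity
correction at the exact normal quantile (1.959964…). For 62/64 the
interval is 89.3–99.1% and for 63/64 the upper bound is 99.7%, matching
the conventional presentation of such panels; the 63/64 *lower* bound
computes to 91.7% at one decimal under this formula (some published
presentations print 91.6; no Wilson variant we are aware of reproduces
that figure, and the package does not chase it).

`hybrid_index()` is the standard allele-proportion index over diagnostic
loci: 1 for pure target, exactly 0.5 for an F1 (obligate heterozygote at
every fixed difference), 0.75 in expectation for a first backcross to the
target, converging to 1 − 2^−(k+1) for the k-th backcross.

## The panel simulator

`simulate_panel()` generates the statistical structure every stage
assumes, so the pipeline is testable end to end with no external data. Two
diverged diploid populations share a genome of mostly-SNP loci; a planted
subset of fixed-difference loci separates them absolutely; background
allele frequencies are Beta-distributed per population (shape 0.8/0.8, a
mildly U-shaped spectrum typical of diverged taxa) with genotypes in
Hardy–Weinberg proportions. Sample classes cover purebreds, atypical
variants (genetically non-target at diagnostic loci — the reading under
which stage-2 mining, which places them in the contrast, is consistent),
a cryptic F1 labelled morphologically as target, non-target species, F1
hybrids, and first backcrosses (heterozygous at each fixed difference
independently with probability 1/2). Background loci are redrawn if they
fix between the pools by sampling accident, so the planted loci are
*exactly* the panel's diagnostic fixed differences and perfect-recovery
statements are well defined.

Contamination is applied after genotype assignment: per-genotype depth is
negative-binomial (mean 90, dispersion 8, emulating the ~94× average of a
typical GBS run), a stated fraction of genotypes (default 2%) is resampled
to depth < 3, a fraction (default 2%) set missing outright, and a fraction
of sites (default 5%) assigned MAPQ below 20.

Endpoint fluorescence is class-conditional Gaussian: target homozygote at
(FAM 0.10, HEX 1.00), alternative at (1.00, 0.10), heterozygote at
(0.55, 0.55), no-template control at (0.05, 0.05), isotropic noise with
default sd 0.03 in normalized units — the tight, well-separated cluster
geometry that validated endpoint assays display. The smallest
between-class mean separation (0.64) exceeds six noise sd by an order of
magnitude, which guarantees ≥ 99% class recovery by the ratio caller; this
margin is asserted in the test suite.

The named scenarios fix the study conditions. **S1** (KASP validation):
32 purebreds + 1 cryptic F1 (labelled target, so 33 morphological
targets) + 3 variants + 16 non-target species + 12 F1 hybrids = 64
samples, three KASP assays (two SNP, one InDel; the InDel locus doubles as
the dominant SCAR locus, mirroring the dual use of such loci in practice).
**S2** (SCAR validation): the same panel read with the two SCAR assays, in
which the cryptic F1 genuinely produces the heterozygous combined pattern
and one designated purebred's lanes are overridden to the same pattern,
emulating incomplete lineage sorting at a single assay locus. On these
scenarios the pipeline reproduces, deterministically at any seed: KASP
concordance 63/64 (98.4%) with the cryptic F1 the single morphological
discordance, sensitivity 32/32, morphological specificity 31/32 (96.9%);
merged-SCAR concordance 62/64 (96.9%) with two discordances and genetic
specificity 32/32.

What the simulator does **not** emulate: linkage between loci, allele
surfing or drift within populations, backcross generations beyond BC1,
sequence-level read artifacts (the VCF is synthesized at genotype level),
plate-position effects or signal drift in fluorescence, and partial gel
failures other than the designed null patterns. Passing tests on this
panel therefore demonstrate the correctness of the algorithms under their
stated assumptions, not robustness to every artifact of real GBS or PCR
data.

## Numerical and scale choices

* Exact HWE p-values are computed in log-space and normalised; the
  "no more probable than observed" comparison uses a 1 + 10⁻⁹ relative
  tolerance so ties are included platform-independently.
* Wilson intervals clamp to [0, 1]; the degenerate all-success upper bound
  is exactly 1.
* Percentages are displayed rounded half away from zero to one decimal;
  all stored values are unrounded.
* Test and validation panels use 64 samples × 500 loci with 40 planted
  diagnostic loci; property tests use hundreds of 8–12 sample × 30–60
  locus panels. These sizes exercise every code path while keeping the
  default suite fast; all are set in one place (`simulation_config()`)
  and scale freely.
* Ties in primer ranking are broken by mirror-invariant criteria, making
  design reproducible across strand conventions; see the design section.

## Known limitations

* Multi-allelic VCF records are rejected, not split; the fixed-allele
  definition is biallelic and no principled splitting rule exists for it.
* The Tm model is a standard nearest-neighbor implementation, not a full
  thermodynamic screen: hairpins, dimers and mispriming are out of scope,
  so designed primers are candidates for, not replacements of, a final
  in-silico check.
* The dominant/codominant SCAR geometries assume simple InDels; complex
  rearrangements are not modelled.
* Scoring treats `ambiguous` and `no_call` as discordant with every
  expectation; panels with many failed wells will therefore look worse
  than a repeat-and-rescore workflow would report.
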