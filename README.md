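# markermine

Tools for developing and validating **species-diagnostic molecular
markers** from genotyping-by-sequencing (GBS) panels of hybridizing taxa —
the workflow used to certify purebred individuals of an endangered species
that forms natural hybrid swarms with sympatric relatives, where morphology
alone misclassifies cryptic hybrids.

The package covers the full path from a genotype matrix to a validated
assay report:

* **QC cascade** — per-genotype depth masking (depth ≥ 3), site MAPQ ≥ 20,
  per-locus missingness < 30%, folded MAF > 5%, and an exact
  Hardy–Weinberg test within the purebred population (excluding loci with
  p < 0.001).
* **Fixed-allele mining** — a locus is diagnostic iff 100% of confirmed
  purebreds are homozygous for one allele and that allele has frequency
  exactly 0 (heterozygotes included) in the contrast set; two-stage
  training refinement removes cryptic hybrids exposed by assay validation.
* **Assay design** — KASP (two allele-specific primers terminating on the
  variant plus a common primer; nearest-neighbor Tm, GC and length
  windows) and SCAR (codominant size-difference ≥ 20 bp, or dominant with
  a null allele) primer screening over flanking sequence.
* **Calling** — endpoint FAM/HEX fluorescence → genotype class via an
  allele-ratio rule; gel band patterns → a merged two-locus
  dominant + codominant decision table; per-sample species calls.
* **Diagnostics** — concordance, sensitivity, specificity with Wilson
  score intervals; hybrid indices (1 purebred, 0.5 F1, 0.75 BC1).
* **Panel simulator** — two diverged diploid populations, planted
  fixed-difference loci, F1/BC1 hybrids, one cryptic F1, atypical
  variants, missingness/depth/MAPQ contamination, class-conditional
  fluorescence and band patterns; the whole pipeline runs with no
  external data.

The central statistic is the Wilson score interval for a binomial
proportion p̂ = x/n:

    ( p̂ + z²/2n ± z √( p̂(1−p̂)/n + z²/4n² ) ) / ( 1 + z²/n )

and the fixed-allele rule for a candidate locus ℓ with reference set R and
contrast set C:

    ∀ r ∈ R: g(r, ℓ) = AA   and   count(A in C at ℓ) = 0,  no missing g.

## Worked example

Simulate the 64-sample KASP validation scenario (32 purebreds, one cryptic
F1 carrying the morphological target label, 3 variants, 16 non-target
species, 12 F1 hybrids), call species from the endpoint fluorescence, and
score against the field classification:

```r
library(markermine)

sc <- simulate_scenario("S1", seed = 1)
calls <- call_kasp_panel(subset(sc$fluorescence, sample %in% sc$sheet$id))
score_panel(calls, sc$sheet, "morphological")
#> diagnostic report (morphological convention, n = 64)
#>   concordance: 98.4% (63/64) (95% CI: 91.7-99.7%)
#>   sensitivity: 100.0% (32/32)
#>   specificity: 96.9% (31/32)
#>   discordant samples: S36
```

Sample S36 is the cryptic F1: heterozygous at every diagnostic locus, it
produces dual FAM+HEX fluorescence on all three assays and cannot match
its (morphologically assigned) purebred label — exactly the individual the
markers exist to catch. Under the genetic convention its hybrid call is
correct and the panel scores 64/64.

The full pipeline (filter → two-stage mining → optional primer design →
KASP and merged-SCAR calling → scoring under both conventions) runs from
files:

```r
p <- run_simulate("S2", seed = 1, out_dir = "panel")
res <- run_full(p$vcf, p$sheet, p$fluorescence, p$bands, "run")
res$reports$scar_morphological
#> diagnostic report (morphological convention, n = 64)
#>   concordance: 96.9% (62/64) (95% CI: 89.3-99.1%)
#>   sensitivity: 96.9% (31/32)
#>   specificity: 96.9% (31/32)
#>   discordant samples: S32, S36
```

A thin command-line wrapper with `simulate` and `full` subcommands is
installed at `inst/cli/markermine.R`.

## Package layout

| Area | Files |
|---|---|
| Data model, VCF/TSV I/O | `R/genotype-matrix.R`, `R/sample-sheet.R`, `R/vcf-io.R` |
| Simulator and scenarios | `R/simulate.R`, `R/scenario.R` |
| QC filters and exact HWE | `R/filters.R` |
| Fixed-allele mining | `R/mine.R` |
| Primer design (Tm, KASP, SCAR) | `R/design.R` |
| Calling (fluorescence, bands, merged rule) | `R/call.R` |
| Diagnostics (Wilson, scoring, hybrid index) | `R/diagnostics.R` |
| Orchestration | `R/pipeline.R`, `inst/cli/markermine.R` |

See `vignettes/marker-pipeline.Rmd` for the model, parameter defaults and
design rationale.
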