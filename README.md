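# haplorefine

Haplotype-sharing genotype refinement for whole-genome sequenced cohorts
that are also chip-typed and long-range phased, plus the variant-processing
machinery around it: hard site-quality filtering with simple-repeat masking,
ancestral-state polarization of SNPs and indels, consequence-impact
classification with transition/transversion summaries, imputation-accuracy
metrics, and a deterministic cohort simulator so everything runs end-to-end
with no external data.

## Who it is for

Statistical-genetics and sequencing-informatics developers who need a
tested, inspectable implementation of likelihood + haplotype-sharing
genotype refinement — for method study, for simulation experiments, or as a
reference against production pipelines.

## The model

Each haplotype *h* in the phased scaffold pool *H* is modelled as a mosaic
copy of the others (a Li & Stephens / IMPUTE-style HMM). With mismatch
penalty λ, the copying state *z<sub>i</sub>* emits the proband allele with
probability 1−λ (match) or λ (mismatch), and between markers stays on its
donor with probability e<sup>−ρ_i/N</sup> + (1−e<sup>−ρ_i/N</sup>)/N, where
ρ_i = 4N<sub>e</sub>r<sub>i</sub>, r<sub>i</sub> is the genetic distance in
Morgans and N the donor count. Forward–backward gives copying posteriors
γ<sub>h,k,i</sub> = P(z<sub>i</sub> = k | all markers), sparsified at 10⁻⁶
of each marker's maximum.

To refine a variant with genotype likelihoods (L0, L1, L2) per individual,
every haplotype carries θ<sub>h</sub> = P(h bears the alternative allele),
initialised as (L2 + ½L1)/(L0+L1+L2). Iterate until max |Δθ| < ε:

    τ_h  = Σ_l γ_{h,l} θ_l                       (sharing prediction)
    P00  = (1−τ_h)(1−τ_k) L0      P10 = τ_h(1−τ_k) ½L1
    P01  = (1−τ_h)τ_k ½L1         P11 = τ_h τ_k L2
    θ_h' = (P10+P11)/ΣP           θ_k' = (P01+P11)/ΣP

Defaults: λ = 10⁻⁷, N<sub>e</sub> = 7000, ε = 10⁻⁷, sparsification 10⁻⁶.
The result is phased genotype posteriors, hard calls, an allele-frequency
estimate and an information score per site.

## Worked example

Simulate a 200-diploid cohort (100 scaffold markers over ~5 cM, target MAF
0.05) sequenced at a shallow 2× and refine the planted variant:

```r
library(haplorefine)

ev <- evaluate_refinement(sim_config(depth = 2, seed = 1))
ev$summary
#>   maf_realized  info concordance_refined concordance_likelihood r2_refined r2_likelihood
#> 1        0.055 0.863               0.975                  0.895      0.849         0.229

ev$refined
#> <refined_variant> 200 individuals, freq 0.0408, info 0.863, 84 iterations

head(tidy(ev$refined))
#>   individual     P00      P01      P10      P11   dosage gt
#> 1          1 0.00673 9.93e-01 1.75e-05 4.10e-04 9.94e-01 0|1
#> 2          2 1.00000 3.06e-07 1.25e-07 9.53e-18 4.32e-07 0|0
#> ...
```

At 2× depth the likelihood-only calls reach 89.5% concordance with the
truth and a dosage r² of 0.23; fusing in haplotype sharing lifts them to
97.5% and 0.85. Individual 1 is a heterozygote whose refined posterior
(P01 ≈ 0.99) also phases the alternative allele onto its second haplotype.
`autoplot()` on a refined variant, on copying posteriors, or on a
`concordance_report()` draws the standard diagnostics; `tidy()`/`glance()`
return tibbles for downstream work.

Site filtering, polarization and annotation are tibble-in/tibble-out:

```r
sites <- read_vcf("calls.vcf") |> classify_sites(repeat_mask = mask)
sites |> classify_impacts() |> tstv_ratio(by = "impact")
```

A thin CLI over the same functions lives at `inst/cli/haplorefine.R` with
`refine`, `filter`, `polarize`, `annotate`, `simulate` and `metrics`
subcommands.

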