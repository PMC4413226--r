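---
title: "Genotype refinement by haplotype sharing: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype refinement by haplotype sharing: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplorefine)
```

## The problem

Genotype calls made from sequence reads alone err at a rate set by depth: an
individual who is truly heterozygous but happened to draw one alternative
read out of eight will, on the likelihoods alone, be called homozygous for
the reference allele. In a cohort where every sequenced individual is also
chip-typed and long-range phased, haplotype sharing carries the missing
information: if the ambiguous individual shares a chip-defined haplotype with
someone who is confidently heterozygous, the ambiguous genotype should move
toward heterozygous. haplorefine implements this fusion — a haplotype-copying
hidden Markov model over the phased scaffold plus an iterative
per-haplotype allele-probability update — together with the surrounding
variant-processing machinery (hard site filters with repeat masking,
ancestral-state polarization, impact classification and Ts/Tv summaries,
accuracy metrics) and a cohort simulator that makes the whole chain testable
without any external data.

## The copying model

Each proband haplotype $h$ in the scaffold pool $H$ is modelled as an
imperfect mosaic copy of the other haplotypes. The latent copying state
$z_i \in H \setminus \{h\}$ at marker $i$ emits the proband's allele with
probability $1-\lambda$ on a match and $\lambda$ on a mismatch; between
markers the chain stays on its donor with probability
$e^{-\rho_i/N} + (1 - e^{-\rho_i/N})/N$ and switches to each specific other
donor with probability $(1-e^{-\rho_i/N})/N$, where $\rho_i = 4 N_e r_i$,
$r_i$ is the genetic distance in Morgans between markers $i-1$ and $i$, and
$N$ is the donor count. `copying_posteriors()` runs forward–backward to get
$\gamma_{h,k,i} = P(z_i = k \mid \text{all markers})$ for all donors at once.

Defaults, with units and origin:

* `lambda = 1e-7` — mismatch penalty (probability). Scaffold genotypes are
  chip calls with very low error, so mismatches are heavily penalised.
* `ne = 7000` — effective number of haplotypes in the population feeding
  $\rho_i$. Appropriate for a large, relatively homogeneous founder
  population; configurable for others.
* `sparsify = 1e-6` — per-marker storage threshold relative to that marker's
  largest $\gamma$; ties at the cutoff are kept, so at every marker the
  retained mass is at least $1 - N \times \text{threshold}$.
* $N$ is recomputed from the actual pool as $|H\setminus\{h\}| = 2(n-1)$ for
  $n$ diploids.

Numerical choices: the forward pass starts uniform over donors (the model is
silent on initialisation and the posterior is insensitive to it at
equilibrium-scale $\rho$); both passes are rescaled to sum to one at each
marker, which leaves the posteriors unchanged while preventing underflow;
results are asserted (in the tests) to equal exhaustive path enumeration to
$10^{-10}$ on small pools.

A practical regime note: what matters for persistence of copying states is
$\rho_i / N$. With chip-density markers and thousands of donors this is
$\ll 1$ and sharing is informative across many markers; in very small toy
pools the same genetic spacing makes switching dominant, which is why the
worked fixtures in the tests use proportionally denser maps.

## Refinement of a target variant

A target variant between scaffold markers gets donor weights by linear
interpolation of the flanking markers' $\gamma$ in genetic distance
(`interpolate_gamma()`; outside the span the nearest marker is used, and
weights are renormalised over the stored donors). Each haplotype carries
$\theta_h$, the probability that it bears the alternative allele,
initialised for both haplotypes of an individual from its genotype
likelihoods as $(L_2 + \tfrac12 L_1)/(L_0+L_1+L_2)$. Iteratively:

1. predict $\tau_h = \sum_l \gamma_{h,l}\,\theta_l$ for every haplotype
   (the haplotype-sharing expectation of its allele);
2. for each individual with haplotypes $h, k$, combine with the likelihoods
   into unnormalised phased probabilities
   $P_{00} = (1-\tau_h)(1-\tau_k)L_0$,
   $P_{10} = \tau_h(1-\tau_k)\tfrac12 L_1$,
   $P_{01} = (1-\tau_h)\tau_k \tfrac12 L_1$,
   $P_{11} = \tau_h\tau_k L_2$, and update
   $\theta_h' = (P_{10}+P_{11})/\Sigma P$,
   $\theta_k' = (P_{01}+P_{11})/\Sigma P$;
3. stop when $\max_h |\theta_h' - \theta_h| < \varepsilon$ (default
   $10^{-7}$), or flag non-convergence at `max_iter` (default 1000 — the
   procedure has no stated bound, and in practice converges in tens of
   iterations).

Design points that were genuinely open:

* **Update schedule.** All $\tau$ are computed from the previous iteration's
  $\theta$ and all $\theta$ updated afterwards (synchronous). This makes the
  result independent of individual ordering; a sequential sweep would bias
  results by position in the file.
* **Donor set.** The update formulas exclude only $h$ itself from the donor
  pool, so an individual's other haplotype can serve as its own donor.
  `exclude_self_individual = TRUE` removes the partner haplotype as well
  (with weight renormalisation, falling back to the population mean of
  $\theta$ if nothing remains); the default follows the formulas literally.
* **Hard calls.** The phased call is the argmax of the posterior quadruple.
  An exact $P_{01} = P_{10}$ tie is emitted as an unphased heterozygote
  (`0/1`) unless the donor-weight support $\tau$ breaks it — an arbitrary
  phase would be false precision.
* **Information score.** The filtering bounds refer to a genotype
  information statistic whose exact formula is not fixed by the method
  description; `info_score()` uses the standard imputation information,
  $1 - \overline{\mathrm{Var}(g)} / (2f(1-f))$, which lives on the right
  scale (0 for posteriors at Hardy–Weinberg priors, 1 for delta posteriors,
  above 1 when observed dosage variance exceeds binomial expectation, which
  is what an upper filter bound of 1.4 implies). Its numerical values on
  real data may differ from any other implementation of a similarly named
  score; the filter honours the bounds syntactically.

## Site filters

`classify_sites()` applies strict-inequality hard thresholds per variant
type: SNPs fail on QD < 2, MQ < 40, FS > 60, HaplotypeScore > 13,
MQRankSum < −12.5 or ReadPosRankSum < −8; indels on QD < 2, FS > 200 or
ReadPosRankSum < −20; both types on DP > 110,000, AN < 4,200, HW < 10⁻⁷,
SI > 1.4, or SI below 0.6 (SNPs) / 0.9 (indels). A value exactly at a
threshold passes, and a missing annotation cannot fail its rule — filters
ought not punish absent evidence. Rules are evaluated independently, so the
failed-rule set is order-invariant. The repeat mask is the merged union of
tandem-repeat intervals and homopolymer runs of six or more bases; a variant
is masked if any base of its reference span `POS..POS+len(ref)−1` touches
the mask (indel left-alignment is assumed done upstream).

The Hardy–Weinberg test is the exact conditional test (probability of the
heterozygote count given allele counts, two-sided by summing configurations
no more probable than the observed one) rather than a chi-square
approximation: the filter compares p-values down to $10^{-7}$, far outside
the asymptotic regime for rare variants. The tests verify it against a
sequential-pairing dynamic program for every configuration of up to 20
individuals.

## Polarization

SNPs are polarized by direct comparison with the ancestor base: ancestor
equal to the reference means the alternative allele is derived, and vice
versa; an N, gap or third base leaves the state undetermined. Ancestor FASTA
case often encodes confidence; both cases are accepted by default and
`high_confidence_only` restricts to uppercase.

Indels are polarized from aligned ancestor/human windows spanning 5 bp plus
the indel length on each side. Equal base counts with at most one mismatch
mean the reference allele is ancestral; a base-count difference equal to the
indel length with at most one flanking mismatch means the alternative is
ancestral, with insertions additionally required to show the exact inserted
bases in the ancestor. Everything else — including base-count differences
that are nonzero but unequal to the indel length — is undetermined.
Mismatches are counted only at columns where both sequences have a base, so
the indel site itself never counts; an ancestral N at a compared column
counts as a mismatch (unknown is not a match). The package consumes one
pre-selected ancestor sequence per window via a small tab-separated exchange
format; tree traversal over full multiple-alignment archives is out of
scope and is emulated by the simulator.

## Annotation and metrics

Consequence terms map to four severity-ordered impact classes (LoF >
MODERATE > LOW > OTHER); a variant with several terms takes the most severe,
unrecognised terms fall back to OTHER with a once-per-term warning, and a
variant affecting no transcript is intergenic, hence OTHER. Initiator-codon
changes are grouped with LoF, matching the grouping convention this package
follows even though some annotation tools rank them lower. Transitions are
exactly the A↔G and C↔T substitutions; `tstv_ratio()` reports per-stratum
counts and returns `Inf` with both counts shown when a stratum (such as
stop-retained changes, which are obligate transitions) has no
transversions. `dosage_r2()` uses the posterior dosage
$P_{01}+P_{10}+2P_{11}$, the standard imputation-accuracy statistic, and
flags monomorphic truth as undefined rather than returning 0. Catalogue
overlap matches on chromosome, position and alleles after trimming shared
allele context so redundant indel spellings match.

## The simulator: what it does and does not emulate

`simulate_cohort()` generates the structure the refinement model assumes:
founder haplotypes with independent alleles, pool haplotypes as founder
mosaics with exponential segment lengths in genetic distance, a target
variant planted on founder lineages so it is perfectly tagged by local
haplotype background, and read counts that are Poisson in depth with
binomially distributed alternative-allele counts (error rate per read).
Defaults: 200 diploids, 100 markers spaced 0.05 cM (about a 5 cM scaffold
window at the usual 1 cM/Mb), 20 founders, switch rate 0.1/cM, target MAF
0.05, depth 20, error 0.01. These sizes keep a full
simulate–refine–measure chain in seconds on one core while leaving the
sharing signal strong; the founder count matches the default MAF so a
single lineage can carry the variant.

What the generator does *not* emulate: mapping artefacts, indel realignment
noise, depth heterogeneity along the genome, chip genotyping error in the
scaffold, relatedness structure beyond founder mosaics, and annotation
values computed from reads (fixture annotations are set directly). Passing
parameter-recovery tests therefore show that the implementation is faithful
to its own generative assumptions — the regime where haplotype sharing is
maximally informative — not that real cohorts will reach the same accuracy.
A misspecification mode (`shared_structure = FALSE`) draws haplotypes
independently so that sharing carries no information; refinement then has
nothing to propagate and degrades toward likelihood-only calling, which the
accuracy comparison makes visible.

```{r example}
cfg <- sim_config(n_individuals = 60, n_markers = 60, depth = 2, seed = 42)
ev <- evaluate_refinement(cfg)
ev$summary[, c("maf_realized", "info", "concordance_refined",
               "concordance_likelihood", "r2_refined", "r2_likelihood")]
```

## Degenerate inputs and tie-breaks

* Zero reads give a flat likelihood triple; a site where every individual is
  flat is written with missing genotypes and information score 0.
* Likelihoods are scale-invariant and renormalised on input; an all-zero
  triple is an error, as is a combination of predictions and likelihoods
  with zero total posterior mass (reported with the individual).
* A single-marker map is valid (no intervals); zero genetic distance means
  no switching, and a target outside the scaffold span takes the nearest
  marker's donor weights.
* Requested MAFs the founder lineages cannot represent are rounded to the
  closest achievable carrier count and reported.
* Multi-allelic records and indels over 60 bp are outside the model and are
  skipped with counted warnings, not errors.

## Known limitations

* Per-variant refinement only: no joint multi-variant haplotype estimation,
  no trio awareness, no X/Y handling.
* The information score is this package's own standard formulation (see
  above) — bounds tuned elsewhere for a differently defined score may need
  recalibration.
* The exact HW test enumerates heterozygote configurations; it is exact for
  cohort-scale counts but assumes a single well-mixed population.
* Catalogue overlap trims allele context but does not left-align against a
  reference; inputs are expected to be left-aligned already.
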