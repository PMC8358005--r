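---
title: "Detecting parent-of-origin allelic imbalance in reciprocal-cross F1 RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parent-of-origin allelic imbalance in reciprocal-cross F1 RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recipase)
```

## The design and the model

A reciprocal cross produces two F1 subgroups that are genetically
identical: in subgroup A the father carries the non-reference strain
genome, in subgroup B the mother does. At a transcribed heterozygous SNP,
let $p$ be the reference-allele fraction of the RNA-seq reads. Three
hypotheses separate cleanly:

* **Null**: $p_A = p_B = 0.5$ — both alleles expressed equally.
* **Cis strain effect**: $p_A = p_B \neq 0.5$ — a strain-specific
  regulatory variant biases expression identically in both crosses.
* **Parent-of-origin effect**: $p_A \neq p_B$ — the same allele behaves
  differently depending on which parent contributed it. A paternally
  expressed gene pushes $p_A$ down (the father's copy is the non-reference
  allele in A) and $p_B$ up; maternal expression mirrors this. We define
  $\Delta = p_A - p_B$, so paternal expression gives $\Delta < 0$ and
  maternal expression $\Delta > 0$.

`recipase` works on subgroup-summed allele depths: per (SNP, subgroup),
read depths are summed over all samples, which is the resolution at which
the downstream tests operate. Tissues are always separate strata.

## The inference chain

1. **Filter.** Per subgroup: summed depth $\geq 20$ with $\geq 2$ reads
   per allele. Both subgroups must pass for a SNP to enter the
   differential test — the filter's unit is the aggregated count because
   that is what the tests consume. The filter is monotone in depth.
2. **Subgroup AIE.** Exact binomial test of the summed counts against
   $p_0 = 0.5$, two-sided by the minimum-likelihood rule (at $p_0 = 0.5$
   this equals the doubled tail capped at 1). BH FDR within each
   (tissue, subgroup) family; AIE at $q < 0.05$.
3. **Differential AIE.** Pooled two-sample proportion $z$-test of
   $\hat p_A$ vs $\hat p_B$, two-tailed, no continuity correction by
   default (a Yates flag exists for parity with other software; whether
   the original analyses used one is not stated, so both modes are
   exposed and the default is documented). BH within tissue. A SNP
   qualifies only when $q < 0.05$ **and** $|\Delta| > 0.1$: the
   effect-size gate keeps statistically significant but biologically
   trivial imbalances out, and — usefully — also absorbs mild
   extra-binomial variance that the pooled $z$-test does not model.
4. **Imprinting screen.** $|\Delta| > 0.7$ flags the rare, nearly
   monoallelic parent-of-origin switches characteristic of classical
   imprinted genes (Snrpn, Ube3a, Trappc9 in the motivating system).
5. **Gene level.** A gene inherits the category of its best qualifying
   assigned SNP: minimum $q$, ties by larger $|\Delta|$, then
   lexicographic SNP id — a deterministic rule so outputs are
   reproducible byte-for-byte.
6. **Enrichment.** Two-sided Fisher's exact tests (hypergeometric
   minimum-likelihood enumeration) within an *explicit* expressed-gene
   universe, never silently the whole annotation. Fold enrichment is
   $(a/(a+b)) / ((a+c)/N)$; reported folds are rounded half away from
   zero to one decimal, internal arithmetic never is. BH across each
   battery.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_depth` | 20 | reads per subgroup | below this the binomial test has no power and fractions are unstable |
| `min_allele_depth` | 2 | reads per allele | guards against genotyping artefacts appearing monoallelic |
| `fdr` | 0.05 | — | conventional BH level |
| `min_delta` | 0.1 | fraction | effect-size gate for differential AIE |
| `strong_delta` | 0.7 | fraction | near-monoallelic switch, the imprinting screen |
| `de_p` | 0.05 | nominal p | relaxed DE cut-off used for overlap/correlation analyses |
| `flank_bp` | 0 | bp | SNP→gene assignment is gene-body by default |

SNP-to-gene assignment: the upstream analyses that motivated this package
used a 100 kb gene window for GWAS gene intervals but never state the AIE
assignment rule, so the default here is the conservative gene body
(flank 0) with `flank_bp` available when a window is wanted. Multi-allelic
sites are dropped, not decomposed; strand is carried but ignored (allele
counts are unstranded). Coordinates are 1-based inclusive internally;
BED converts at the boundary. The "reference allele" is whichever allele
matches the reference genome build — in a cross where the reference
derives from one parental strain, that strain's copy.

## What the simulator states, and what it does not

`simulate_allele_counts()` draws, per SNP per sample, a total depth from
a negative binomial (mean 60, size 5 — the depth distribution is our
choice; nothing upstream specifies one) and a reference depth from a
beta-binomial with intra-class correlation $\rho$
($\alpha = \theta(1-\rho)/\rho$, $\beta = (1-\theta)(1-\rho)/\rho$;
$\rho = 0$ degenerates to the binomial). Defaults: $n = 8$ samples per
subgroup (matching the motivating experiment), $\rho = 0.02$ (mild
replicate-level overdispersion typical of well-behaved ASE data), 5%
paternally imprinted, 5% maternally imprinted, 10% cis genes,
`imprint_delta` 0.3, `cis_delta` 0.2, mapping bias 0. Effect classes are
assigned per gene so SNPs within a gene share a signal. These choices
were made once as the stated world and are not tuned against test
outcomes.

The generator emulates: subgroup-structured allele counts, planted
imprinting with correct sign convention, cis effects, global additive
mapping bias, and naturally occurring below-filter depths. It does **not**
emulate: per-site mapping bias, haplotype phase, correlated SNPs beyond
gene-level class sharing, sample-specific library-size effects, or raw
reads/alignments. A green recovery test therefore establishes that the
statistics behave correctly under the stated sampling model — not that
real-data artefacts (reference bias beyond a global shift, genotyping
error) are handled; the N-masking utility exists precisely because real
data need that mitigation upstream.

## Numerical choices

* Two-sided exact p-values (binomial, Fisher) sum point probabilities
  $\leq$ the observed one with a $1 + 10^{-7}$ relative tolerance to
  absorb floating-point ties — the same guard R's own exact tests use.
* p-values are floored at `.Machine$double.xmin` so they stay in $(0,1]$.
* A degenerate pooled proportion (0 or 1 in both groups together) gives
  $z = 0$, $p = 1$: two fully concordant groups carry no evidence of
  difference.
* `log2FC == 0` maps to direction "up" by convention and is reported via
  a message; such genes are excluded from direction-stratified
  enrichment only by their p-values, never silently.
* Outlier exclusion in correlations is explicit-by-id only; no automatic
  outlier detection exists anywhere in the package.
* BH is the FDR procedure throughout (the upstream description says only
  "FDR"); families are (tissue, subgroup) for binomial AIE and tissue for
  differential AIE, matching per-region reporting.
* All orderings (outputs, tie-breaks) are deterministic, and every
  random draw flows from a single user-supplied seed, so reruns are
  bit-identical.

## Known limitations

* The pooled $z$-test treats subgroup sums as binomial; with strong
  replicate overdispersion its p-values are anti-conservative, mitigated
  but not removed by the $|\Delta| > 0.1$ gate. A beta-binomial inference
  mode is deliberately out of scope (the simulator, not the tests, models
  overdispersion).
* Per-sample mixed-model AIE, haplotype phasing, and indels are out of
  scope.
* The CLI reports exit codes 0 (success) and 1 (user error); the
  documented code 2 for internal errors is currently unreachable because
  all anticipated failures are classified as user errors.
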