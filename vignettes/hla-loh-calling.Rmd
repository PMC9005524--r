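---
title: "Calling allele-specific HLA LOH: model, features, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling allele-specific HLA LOH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The calling model

`hlaloh` decides, per heterozygous HLA class I locus, whether the tumor has
somatically lost one of the two inherited alleles. The decision combines a
gradient-boosted classifier over seven per-locus features with deterministic
post-hoc rules. The underlying signal model is simple: if a fraction
*e = purity × clonality* of the sampled cells carry a deletion of allele *b*,
then at every position where the two homologous alleles differ, the expected
tumor depth of *b* scales by (1 − *e*) while allele *a* is unchanged, and the
tumor B-allele frequency shifts away from its normal-sample value. All
allele-specific features are computed only at these mismatch sites, because
every other position receives reads from both alleles and is uninformative.

Assumptions worth stating explicitly:

* allele-specific probe-capture bias is multiplicative and identical in tumor
  and normal, so dividing tumor BAF by normal BAF cancels it;
* exome-wide read totals (`r_t`, `r_n`) are valid proxies for sequencing
  mass, so `(D_T/D_N)·(R_N/R_T)` is 1 under copy neutrality;
* purity, ploidy, and allele-specific copy-number segments come from an
  upstream caller and are treated as inputs, never re-estimated;
* duplicate reads were removed upstream of depth computation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| bin width | 150 | bp | aggregates site noise while tracking within-gene structure; all four allele-specific features summarise per-bin medians |
| homozygosity floor | 5 | sites | below five informative positions, allele-specific depth cannot be measured; the locus is excluded |
| soft-clip cap | 20 | % of read length | reads clipped beyond this are likely mismapped across alleles; exactly 20% is retained |
| mismatch cap | 0 (1 with somatic mutation) | mismatches | cross-allele mismapping produces mismatches; a known somatic mutation legitimately adds one |
| site usability floor | 10 | normal reads | the adjusted BAF divides by the normal BAF; low-depth or fixed (0/1) normal BAFs are capture artifacts |
| flank window | 10,000 | bp | most HLA LOH events are deletions far larger than the gene; a b-allele-zero segment within 10 kb is strong evidence |
| probability threshold | 0.5 | — | no threshold is canonical for the classifier's probability; 0.5 is the default and exposed in `loh_config()` |
| secondary checks | ratio < 0.98, adjusted BAF > 0.02 | — | protect specificity at low purity: a confident probability cannot stand without at least minimal allelic imbalance |
| bi-allelic rule | ratio < 0.5 in ≥ 25% of bins | — | when even the "retained" allele is strongly depleted, both alleles are labeled deleted |
| XGBoost | depth 5, eta 0.3, subsample 0.5, min_child_weight 2, 100 rounds | — | deliberately conservative; no hyperparameter search is performed |

## Numerical and design choices

**Adjusted BAF: deviation from 1.** The per-bin summary is
`|median(BAF_T/BAF_N) − 1|`. A literal absolute value of the ratio itself
cannot be anchored at zero for copy-neutral loci (a balanced locus gives 1,
not 0), and the 0.02 secondary check is only meaningful for a feature that
vanishes at no change; the deviation-from-1 form has both properties. The
literal form remains available via `adjusted_baf(..., literal = TRUE)`.

**Pairwise alignment.** Mismatch sites come from a global alignment with
match +1, mismatch −1, gap open −5, gap extend −1. The affine penalties keep
indels contiguous, which makes "one site per indel, at its first position"
well defined; the parameters are a package choice, not a published constant.
A gap in allele 1 (an insertion in allele 2) has no natural allele-1
coordinate, so it is anchored at the preceding allele-1 base (0 at the
start).

**Coordinate frame.** All bins and site coordinates live on allele 1
(0-based); allele-2 coordinates are carried alongside from the alignment so
each allele's depth is read off its own reference.

**Consistency uses tumor depth only.** The bin vote compares the two
alleles' median *tumor* depths. Normal-normalized votes are a defensible
alternative; raw tumor depth was chosen because the feature is meant to
capture within-tumor consistency of the deficit, and the capture bias that
normalization would remove affects both bins and votes coherently. A side
effect is that strong capture bias alone can push the feature toward 1; the
classifier compensates because the same bias appears in LOH-negative
training loci.

**Bin eligibility.** For the ratio features a bin contributes only when both
alleles have at least one usable site in it; bins with no usable sites are
skipped for BAF/ratio features but count as 0.5-vote ties for consistency.

**Degenerate inputs.** A locus whose sites are all filtered yields `NA`
features and an explicit `"no-call"` status — NaNs never propagate into the
classifier. Ties in consistency votes give both alleles 0.5. Secondary
checks can only revoke an LOH call, never create one.

**Allele-swap symmetry.** Relabeling the two alleles leaves the depth-ratio
and consistency features exactly unchanged. The adjusted BAF is exactly
swap-symmetric only at a balanced normal BAF (the deviation |ΔBAF|/BAF_N
changes denominator under relabeling); in practice the bin medians make the
difference negligible, and the zero point (no shift) is preserved exactly.

## What the synthetic generator emulates — and what it does not

`simulate_locus()`/`simulate_cohort()` produce truth-labeled loci with the
statistical structure the caller relies on: 30–80 mismatch sites over a
3,200-bp allele, an allele-1 capture fraction drawn around 0.5 (σ = 0.08,
truncated to [0.25, 0.75]), negative-binomial site coverage (mean 500×,
dispersion 0.1) with a binomial allele split, LOH prevalence 19.6%, flanking
deletions for 73% of LOH events, uniform purity in [0.15, 1], 70% of events
clonal with subclonal clonality uniform in [0.3, 1], and ploidy an integer
in 1–4 concentrated at 2. The site-total-then-split construction keeps each
allele's marginal depth negative-binomial at the stated dispersion while
giving BAFs binomial sampling noise conditional on site depth, which is how
read counting actually behaves; drawing the two allele depths independently
would inflate BAF noise far beyond what deep exome data shows.

The generator does not emulate: alignment and mapping artifacts (reads are
born assigned to the correct allele), basecall errors and quality strings,
position-correlated capture structure along the gene, contamination,
germline CNVs, or mis-estimated purity/ploidy inputs. Green tests on these
fixtures therefore validate the *computational* pipeline and its statistical
behavior under the stated noise model — they do not certify performance on
real capture chemistry, where mapping bias and purity mis-estimation are the
dominant failure modes.

The in-silico mixture framework operates on depth profiles by binomial
thinning rather than on raw FASTQ reads. At the depth level the two are
distributionally equivalent, and thinning keeps the experiment desk-scale;
the cost is that read-level artifacts (duplicates, fragment-length
structure) cannot resurface in the mixture. Expected sequencing mass is
conserved by construction for the exome slot and the retained allele; the
lost allele's mass genuinely varies with the mixing fraction, which is the
signal itself.

## Problem sizes

The shipped evaluation uses, per run: a training cohort of 720 loci (19.6%
prevalence) generated from a seed disjoint from all evaluation seeds; a
clonal sensitivity row over purities 0.3–1.0 (step 0.1) with 10 replicates ×
5 loci per cell; specificity controls at 10 stated-purity levels × 100 loci;
a full 8 × 8 purity × clonality grid with 10 replicates × 5 loci per cell;
and 100 pooled negative controls per grid cell. These sizes give binomial
standard errors of 1–2 percentage points per cell and run in a couple of
minutes on one CPU; they are the package's chosen evaluation scale, and all
of them are recomputed — never cached — by `scripts/acceptance.R`.

## Known limitations

* Class II genes are out of scope; the reference machinery is class I only.
* The MSA dialect is a documented simplification of IMGT alignment releases:
  the reference row is gap-free, so insertions relative to the MSA reference
  are not representable; real IMGT files need conversion.
* HLA typing, somatic mutation calls, purity/ploidy and segments are inputs;
  errors in them propagate directly into the features.
* The heuristic annotator (`annotate_locus_heuristic()`) encodes manual
  labeling criteria for auditing synthetic truth; it is deliberately not a
  calling path and should never be used as ground truth.
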