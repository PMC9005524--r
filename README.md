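# hlaloh

Allele-specific calling of HLA loss of heterozygosity (LOH) from paired
tumor–normal exome sequencing.

## The problem

Tumors can escape T-cell surveillance by somatically deleting one of the two
inherited HLA class I alleles (HLA-A, -B, -C): the peptides presented only by
the lost allele disappear from the cell surface, which matters for
immunotherapy and neoantigen-based treatment selection. Generic copy-number
callers struggle in the HLA region — the genes are short, highly polymorphic,
and probe capture differs between the two alleles of the same patient — so
detecting which allele is lost requires allele-aware machinery.

`hlaloh` implements that machinery end to end:

1. **Patient-specific reference.** An IMGT-style allele database (cDNA + gDNA
   multiple sequence alignments) is parsed, incompletely sequenced alleles
   are completed by imputation (donor with the same 4-digit protein name,
   then the same 2-digit group, then the first allele listed in the MSA), and
   the patient's typed alleles are assembled into a per-gene reference pair.
2. **Mismatch sites and depth.** The two homologous alleles are globally
   aligned; every SNV column and the first position of every indel becomes an
   informative site (pairs with fewer than 5 sites are effectively
   homozygous and excluded). Reads mapped to the patient reference are kept
   only with ≤ 20% soft-clipping and zero mismatches (one mismatch if a
   somatic HLA mutation is known), and per-position allele depth is computed.
3. **Seven features per heterozygous locus.** With `A`/`B` the allele
   depths, `T`/`N` tumor/normal, `R` exome-wide read totals, and 150-bp bins
   along the allele:
   - *adjusted BAF*: `median_bins |median_sites(BAF_T / BAF_N) − 1|`, where
     `BAF = B/(A+B)` — dividing by the normal BAF cancels allele-specific
     capture bias; 0 means no allelic shift;
   - *allele-specific depth ratio*:
     `median_bins min_allele median_sites((D_T/D_N)·(R_N/R_T))` — 1 when
     copy-neutral, → 0 as one allele is lost;
   - *consistency of depth*: each bin votes for the allele with higher
     median tumor depth (0.5 each on ties/empty bins); the feature is the
     larger per-allele mean vote, in [0.5, 1];
   - *total depth ratio*: per-bin sum of the two allele medians, median over
     bins — 2 when copy-neutral, distinguishes deletion from amplification
     of the other allele;
   - *tumor purity* (clipped to [0.1, 1]) and *tumor ploidy* (integer ≥ 1),
     taken from upstream copy-number estimation (e.g. Sequenza);
   - *flanking deletion*: 0 if any segment with b-allele copy number 0 lies
     within 10 kb of the gene — most HLA LOH events are megabase-scale
     deletions.
4. **Classifier + decision rules.** An XGBoost binary-logistic model
   (max_depth 5, eta 0.3, subsample 0.5, min_child_weight 2, 100 rounds)
   produces a probability; a locus is called LOH only if the probability
   reaches the threshold **and** the allele-specific ratio is < 0.98 **and**
   the adjusted BAF is > 0.02. The allele with the lower normalized depth is
   labeled deleted; if the retained allele's per-bin ratio is < 0.5 in ≥ 25%
   of bins, both alleles are labeled deleted.
5. **Limit-of-detection machinery.** Depth-level binomial thinning mixes a
   pure-tumor profile with independent normal replicates at any tumor purity
   × clonality, reproducing in-silico cell-line mixture experiments and
   sensitivity/specificity grids; a synthetic fixture generator provides
   truth-labeled cohorts with realistic capture bias and overdispersed
   coverage.

## Worked example

```r
library(hlaloh)

# truth-labeled synthetic cohort: 720 heterozygous loci, ~20% with planted LOH
cohort <- simulate_cohort(fixture_params(n_loci = 720, seed = 101))
fit <- loh_model(loh ~ ., data = cohort$features, seed = 1)
fit
#> Gradient-boosted HLA LOH classifier
#>   trained on 720 loci (prevalence 17.8%), 7 features, 100 rounds
#>   features: adjusted_baf, as_depth_ratio, consistency, total_depth_ratio, purity, ploidy, flank_deletion

cross_validate(cohort$features, k = 10, seed = 2)
#> 10-fold cross-validation over 720 loci (pooled held-out):
#>   sensitivity 0.969  specificity 0.998  F1 0.980  AUROC 1.000  AUPRC 0.999

# a clonal LOH event at 40% tumor purity
lc <- simulate_locus(fixture_params(), seed = 7, loh = TRUE,
                     purity = 0.4, clonality = 1, deleted = 2)
call_locus(fit, lc)
#> <loh_call> HLA-A: LOH (p = 0.991); deleted: A*02:01
```

The feature vector behind that call was
`adjusted_baf = 0.301, as_depth_ratio = 0.599, consistency = 1.0,
total_depth_ratio = 1.598, purity = 0.4, ploidy = 4, flank_deletion = 0`:
at 40% purity the lost allele retains 60% of its depth (ratio 0.6, BAF shift
0.3), the deficit is consistent across every bin, and the flanking segment
table shows a b-allele deletion — jointly unambiguous for the model
(probability 0.991), and the secondary checks (0.599 < 0.98, 0.301 > 0.02)
concur. Gain-based importances put `adjusted_baf` first (0.87) followed by
`flank_deletion` (0.11).

Calling real data end to end goes through `loh_pipeline()` (database MSAs →
patient reference → SAM/BAM depth → features → calls), or the equivalent CLI
in `inst/cli/hlaloh` (`call`, `train`, `cv`, `simulate`, `lod`
subcommands with a YAML run config). `inst/extdata/` ships a small
synthetic allele database in the package's documented MSA dialect
(`synthetic_*.msa`) for format reference; it is generated, not derived from
the licensed IMGT/HLA distribution.

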