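# StrokeSexPatterns

Sex-specific lesion-pattern effects on 3-month functional outcome after
acute ischaemic stroke, as a tested, reusable R pipeline.

Growing evidence suggests that male and female brains respond differently
to ischaemic damage in particular locations: the *spatial pattern* of a
stroke lesion may carry sex-specific prognostic information beyond lesion
volume. This package is for neuroimaging statisticians who want to estimate
such effects — and probe their stability — on cohorts of spatially
normalized lesion segmentations with 3-month modified Rankin Scale (mRS)
outcomes.

## What it computes

1. **Parcellation** — binary lesion masks are counted against a three-layer
   atlas (94 cortical + 15 subcortical regions + 20 white-matter tracts),
   giving 129 lesioned-voxel counts per patient and total lesion volume.
2. **Lesion patterns** — non-negative matrix factorization (multiplicative
   updates, NNDSVD initialization) reduces the count matrix to `k = 10`
   patterns `X ≈ W H`, with max-normalized basis rows.
3. **Hierarchical outcome model** — unfavourable outcome (mRS > 2) is
   modelled as

   ```
   y_i ~ Bernoulli(logit⁻¹(α + Σ_j β_{j,sex(i)} W_ij + γᵀ x_i))
   β_{j,s} ~ N(μ_j, τ_j),  μ_j ~ N(0,1),  τ_j ~ HalfNormal(1)
   ```

   with covariates age, age², sex, six cardiovascular risk factors and
   lesion volume, sampled by a built-in No-U-Turn Sampler (Rcpp). Effects
   are *substantial* when the 90% highest-posterior-density interval
   (HPDI) excludes zero; sex differences are posterior draws of
   `β_male − β_female`; performance is posterior-predictive AUC.
4. **Sensitivity** — 20 repetitions of majority-class downsampling
   (favourable-outcome men sampled down to the favourable-outcome women
   count) with full refits.
5. **Lesion network mapping** — 100 region-subset variants per pattern
   seed functional-connectivity t-maps against male- and female-specific
   normative connectomes (global signal regression, Fisher z, one-sample
   t); positive/negative t sums within 14 hemisphere-specific cortical
   networks are contrasted between sexes with BH-FDR over 140 tests per
   sign.

Synthetic-data generators with known ground truth (`simulateCohort()`,
`simulateAtlas()`, `simulateLesionMasks()`, `simulateConnectomes()`) cover
every input, so the full pipeline runs and is tested without any patient
data.

## Worked example

```r
library(StrokeSexPatterns)

# a synthetic cohort with a female-specific effect of pattern 5
sim <- simulateCohort(cohortConfig(
  nPatients = 822, seed = 7,
  coefFemale = c(0, 0, 0, 0, 0.8, 0, 0, 0, 0, 0)
))
cfg <- pipelineConfig(
  lesions = sim$lesions, cohort = sim$cohort,
  k = 10, draws = 1000, chains = 2, warmup = 500,
  sensitivityReps = 5, seed = 7
)
bundle <- runPipeline(cfg)
bundle
#> StrokeSexPatterns result bundle
#>   parcellation  skipped (matrix supplied)
#>   patterns      done
#>   baseline      done
#>   model         done
#>   sensitivity   done
#>   lnm           skipped
#>   posterior-predictive AUC: 0.679
#>   substantial sex differences (men - women): pattern 10

subset(bundle$effects, pattern == 10)
#>    pattern   quantity       mean hpdi_lower hpdi_upper substantial
#> 28      10       male  0.2113077 -0.1362270  0.5529582       FALSE
#> 29      10     female  1.1440549  0.7056366  1.6394558        TRUE
#> 30      10 difference -0.9327472 -1.2973104 -0.5617454        TRUE
```

The factorization relabels patterns (generator pattern 5 is fitted
pattern 10 here; `matchPatterns()` maps them, matched cosines > 0.998).
The difference rows read as the study this emulates reports: the pattern
matters in women (posterior mean 1.14, 90% HPDI 0.71–1.64) but not in men
(HPDI spans zero), and the men-minus-women difference is substantially
negative (−0.93, 90% HPDI −1.30 to −0.56). The sensitivity summary
(`bundle$sensitivity$summary`) tallies how often each pattern's difference
survives downsampled refits — 5 of 5 repetitions for the planted pattern
in this run.

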