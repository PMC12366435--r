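# taglm

Bootstrap discovery of lexicogrammatical discriminators from tagged
speech corpora.

## The problem

Clinicians and corpus linguists studying autism spectrum disorder (ASD)
annotate transcribed speech with systemic-functional lexicogrammatical
tags — clause complexing, logico-semantic relations, appraisal, modality,
Japanese negotiating particles, and so on — and ask which of those
resources are used differently by ASD and non-ASD speakers.  The data are
awkward: roughly as many tag features (~135) as speakers (64 ASD + 71
non-ASD), wildly varying speech lengths, and sparse counts for rare tags.
`taglm` implements the interpretable analysis route for this setting: the
**Tag Linear Model**, a logistic regression over per-word tag frequencies
whose coefficients are made testable by bootstrap resampling.

## The method

For speaker *i* with word total *w<sub>i</sub>* and count
*c<sub>ij</sub>* of tag *j*, the feature is the per-word rate
*x<sub>ij</sub> = c<sub>ij</sub> / w<sub>i</sub>*.  The group label
*y<sub>i</sub>* (ASD = 1) is modeled as

> logit P(y<sub>i</sub> = 1) = β₀ + Σ<sub>j</sub> β<sub>j</sub> x<sub>ij</sub>,

fit by penalized maximum likelihood (ridge penalty (λ/2)‖β‖², intercept
unpenalized, Newton iteration with step-halving).  Over *B* bootstrap
resamples of speakers the model is refit and, for each tag, the mean and
standard deviation of β<sub>j</sub> across resamples give a two-sided
normal-approximation p-value

> p<sub>j</sub> = 2 (1 − Φ(|mean<sub>j</sub>| / sd<sub>j</sub>)).

Tags with p < α are the discriminators; they can be narrowed to the
clause/phrase level and grouped into seven cognitive-functional domains
(working memory, inferential ability, mental space construction, joint
attention, weak central coherence, self/other differentiation and agency,
restricted and repetitive behaviors).  A stratified k-fold
cross-validation reports accuracy, precision, sensitivity and
specificity of the fitted classifier.

Because the underlying clinical corpus is not publicly deposited, the
package ships a synthetic corpus generator (`generate_corpus()`,
`table1_preset()`) that emulates the study conditions — group sizes
64/71, log-normal word totals, Poisson or negative-binomial tag counts
with group-dependent log-linear rates — so the whole pipeline is testable
end to end.

## Worked example

```r
library(taglm)

scheme  <- default_tag_scheme()                  # 135 tags, 15 categories
corpus  <- generate_corpus(table1_preset(scheme, effect_size = 0.8, seed = 42))
corpus
#> Speaker-by-tag counts: 135 speakers x 135 tags
#>   groups: ASD=64, non-ASD=71 (positive class: ASD)

features <- normalize_features(corpus)
boot <- bootstrap_coefficients(features, B = 2000, lambda = 1, seed = 42)
sum(boot$significant)
#> [1] 46

sel <- select_discriminators(boot, alpha = 0.05)
head(sel[, c("tag", "mean", "p_value")], 3)
#>                        tag        mean      p_value
#> 1 Process type/existential  0.04619850 1.557702e-13
#> 2              Filler/unto  0.08583574 9.103774e-12
#> 3 Evidentiality/appearance -0.03399258 8.375481e-11

core <- filter_structural_level(sel, scheme, level = "clause_phrase")
map_to_domains(core$tag, scheme)[["working memory"]]
#> [1] "Clause complexes-noun clauses"
#> [2] "Clause complexes-reported clauses"
#> [3] "Clause complexes-adnominal clauses"
#> [4] "Logico-semantic relation/projection-embedding"

cross_validate(features, k = 5, seed = 43)
#> Confusion: TP=62 FP=1 TN=70 FN=2
#> accuracy 0.978 | precision 0.984 | sensitivity 0.969 | specificity 0.986
```

Here 46 of 135 tags come out significant: the generator planted effects
on exactly the 46 packaged discriminator items (4 with increased, 42
with decreased use in the ASD group), and the bootstrap recovers them
with the planted signs.  The sign of `mean` says which group uses the
tag more (positive = more in ASD); `p_value` is the moments-based
normal approximation above.  `run_pipeline()` wraps all of these stages
and writes a stamped, byte-reproducible report bundle;
`inst/cli/taglm.R` exposes the same steps as shell subcommands
(`simulate`, `bootstrap`, `evaluate`, `report`, `run`).

The published discriminator table that anchors the packaged tag scheme
is available as data via `table1_discriminators()`, and
`pvalue_from_moments()` reproduces its printed p-values from its printed
mean/SD columns up to printed rounding.

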