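# audlearn

Analysis of rule-based auditory category-learning experiments: latent
performance states, task-design effects, and early prediction of who will
learn the rule.

In the task this package models, participants hear frequency-modulated tones
varying in duration, pitch direction, loudness, frequency band and
modulation speed (160 distinct tones), and must discover by trial and error
which duration x direction conjunction is the "target" category, pressing a
target or non-target button on each of 240 trials. The package is written
for researchers analysing such experiments: it turns per-trial logs into
block-level performance coefficients, models the population's latent
performance states, quantifies design confounds, and asks how early learners
(`L`) can be told apart from non-learners (`notL`). Because such behavioural
data is usually available only on request, a design-faithful synthetic
cohort generator (balanced schedules, the 76-participant allocation over 4
configurations x 2 buttons, Markov performance-state dynamics) makes the
whole pipeline runnable and testable out of the box.

## The models at the core

**Performance coefficients.** For a trial block $b$:

$$\text{blockSensitivity}_b = \frac{\#\{\text{target trials answered with the target button}\}_b}{\#\{\text{target trials}\}_b},$$

and analogously blockSpecificity for correct rejections of non-targets;
cumulative versions at trial $i$ use the strict prefix $1..i{-}1$.

**Latent performance states.** Pooled block coefficients are fitted with a
univariate $K$-component Gaussian mixture by EM (variance-floored, multiple
restarts), $p(x)=\sum_k w_k\,\mathcal N(x;\mu_k,\sigma_k^2)$, with the
number of components judged by $\mathrm{BIC}=\ln(n)\,3K-2\ln\hat\Lambda$.
With $K=3$ the components are labelled high/med/low by mean, and each block
is assigned to its maximum-posterior state.

**Design effects.** Per-participant counts of high-performance blocks are
compared across response buttons and between all configuration pairs with
Mann-Whitney U tests (midranks; exact for small tie-free samples, otherwise
tie- and continuity-corrected normal approximation; uncorrected two-sided
p-values banded at 0.05 and 0.2).

**Early classification.** Block-40 sensitivity/specificity features plus
configuration and button feed a class-weighted gradient-boosted tree
ensemble over nested feature subspaces (`upto_40` ... `complete`),
evaluated by stratified 5-fold cross-validation with balanced accuracy
$\tfrac12(\mathrm{sens}+\mathrm{spec})$, with per-feature split-gain
importances normalised to 100.

## Worked example

```r
library(audlearn)

cohort <- generate_cohort(master_seed = 42)   # 76 participants, 18240 trials
blocks <- block_series_table(cohort$trials, "sensitivity", block_size = 10)
fit <- gmm1d(blocks$value, K = 3, seed = 1)
summary(fit)
#> Gaussian mixture (1-D), K = 3
#>
#>           low   high    med
#> weight 0.0877 0.6524 0.2599
#> mean   0.0000 1.0000 0.5207
#> sd     0.0010 0.0010 0.1285
#>
#> log-likelihood: 6848.63   BIC(n = n_obs): -13629.7
#> converged: TRUE after 47 iterations
```

The three states: an atom at perfect block sensitivity (the high state,
weight 0.65), a mid-level state around 0.52, and a small at-chance-or-below
state. Assign states, count high blocks, and test the design effects:

```r
labels <- label_components(fit)
states <- data.frame(participant_id = blocks$participant_id,
                     block = blocks$block,
                     state = labels[assign_states(fit, blocks$value)])
counts <- high_block_counts(states, cohort$participants)

button_effect_test(counts)
#> Mann-Whitney U test (normal_tie_corrected, two_sided)
#>   U = 798.50  (n1 = 35, n2 = 41),  p = 0.3987

pairwise_config_tests(counts, "total")
#> Pairwise configuration comparisons (total)
#>   config_a config_b     U        p    category
#> 1        1        2 224.0 0.342951        n.s.
#> 2        1        3 108.0 0.035383 significant
#> 3        1        4 174.5 0.671214        n.s.
#> 4        2        3  79.0 0.005096 significant
#> 5        2        4 134.5 0.181264    marginal
#> 6        3        4 214.5 0.188297    marginal
```

At this seed, configuration 3 (long/up — the configuration the generator
boosts by default) collects significantly more high-performance blocks than
configurations 1 and 2 and marginally more than 4; the button effect is not
significant in this particular cohort. Finally, how well do early features
separate learners from non-learners?

```r
features <- build_feature_table(cohort)
stratified_cv(features, "complete", seed = 1)
#> Subspace complete: balanced accuracy 80.1% (+/- 17.0%)
#> fold scores: 0.667 0.962 0.667 0.792 0.917
#> top features:
#>           feature score
#> 1 sens_161_to_200  40.1
#> 2 spec_201_to_240  25.9
#> 3  spec_81_to_120  14.5
```

Hit rates late in the session (trials 161-200) dominate the ranking. A
single call runs every stage and writes checksummed CSV/JSON outputs:

```r
manifest <- run_pipeline(run_config(seed = 42, out_dir = "run1"))
```

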