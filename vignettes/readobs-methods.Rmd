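---
title: "Models and methods behind readobs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind readobs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

During natural reading the eyes skip many words entirely and linger on
others for very different times. Three broad explanations compete:
*linguistic prediction* (how well the next word can be anticipated from
context), *parafoveal preview* (how well its identity can already be
discerned from low-acuity peripheral vision), and *low-level oculomotor
factors* (word length, distance from the prior fixation, landing position).
`readobs` quantifies each explanation per word token in a common
information-theoretic currency, regresses skipping and gaze durations on
them per participant, and partitions the cross-validated explained
variation into unique and shared components.

## The ideal observer of parafoveal preview

Word identification from the parafovea is modelled as Bayesian inference
over a vocabulary of letter-vector encodings. Each word is a concatenation
of 26-dimensional one-hot letter vectors padded to the longest word
(`d = 26 l_max`). Visual evidence arrives as samples from a multivariate
Gaussian centred on the true word's encoding with diagonal covariance
`lambda(eps)^e I` per letter slot (default `e = -1/2` as printed in the
source formalism; the Bayesian-Reader lineage's precision convention
`e = -1` is available via `perceptual_span(noise_exponent = -1)`).

Sensory quality is the Gaussian perceptual-span integral over the letter's
unit-width bounding box,

```
lambda(eps) = Lambda * [Phi((eps + 0.5)/sigma) - Phi((eps - 0.5)/sigma)],
```

with defaults `sigma = 3`, `Lambda = 1`. Slot `j` (0-based) of a word
previewed at launch distance `L` sits at eccentricity `L + j`; padding
slots are sampled too (true value zero), so word length is itself inferred
noisily from the zero blocks.

Beliefs are `V - 1` log-odds against an arbitrary reference word (the last
word of the input order; results are invariant to the choice, and the test
suite checks this). Each sample adds the log-odds likelihood, a linear
function of the percept. Because the update is additive and the covariance
fixed per token, a chain of `T` samples depends on the percepts only
through their sum, whose distribution is known in closed form; the
implementation draws that sufficient statistic directly. This is an exact
algebraic collapse, not an approximation — the test suite verifies that
chaining `T` explicit updates gives bit-identical posteriors, and that both
match brute-force Bayes with explicit Gaussian densities on small
vocabularies.

Per token we run `repeats = 3` independent chains of `T = 50` samples and
average the posterior entropies; information gained from the preview is
prior entropy minus posterior entropy (bits). `T` is a fixed budget: no
adaptive stopping.

**Numerical choices.** `lambda` is floored at `1e-12` before
exponentiation so variances stay finite; posterior probabilities use
max-subtracted softmax; probabilities are clipped at `1e-12` in the
McFadden loss. One RNG stream per (participant, token, repeat) is derived
from a master seed by stable string hashing, making observer outputs
reproducible and order-independent — and identical between the synthetic
generator and a re-analysis run with the same master seed.

## Contextual priors from truncated next-word distributions

The contextual observer replaces the frequency prior with one built from a
next-word probability distribution: keep the smallest "nucleus" of top
predictions reaching cumulative mass 0.95 (ties broken lexicographically),
treat the rest of the vocabulary as a flat tail with pseudocount 1, and
convert nucleus probabilities to implied pseudofrequencies
`P_i (V - k) / (1 - sum P)`. Nucleus words missing from the observer
lexicon are dropped into the tail without renormalizing the retained
probabilities (the literal construction; the alternative of renormalizing
is a design choice we did not take). Predictive entropy uses the same
nucleus-plus-flat-tail support, keeping the prediction features and the
contextual prior consistent.

## Corpus measures and filters

First-pass measures follow the standard definitions: a token is first-pass
skipped if the eyes first cross it without fixating it while no later word
has been fixated; gaze duration sums the maximal initial run of fixations
on a token; launch distance is the token's first character minus the prior
fixation coordinate; landing offset is measured from the word centre
(`(L-1)/2`, 0-based), negative meaning left. Tokens first crossed by a
line-crossing saccade (return sweep) are left unscored. Filters: tokens
with non-alphabetic characters, blink-adjacent tokens, absolute launch
distance above 24 characters, and (duration analysis only) gaze durations
outside 70–900 ms. The launch cap is applied to the magnitude; the filter
log counts each rule independently.

## Regression, scoring and partitioning

Per participant, skipping is modelled by maximum-likelihood logistic
regression and gaze durations by OLS, both with intercepts and no
regularization, on predictors z-scored within participant (population SD;
`word_class` expands to indicator contrasts). Scores are 10-fold
cross-validated with pooled held-out losses: `R^2 = 1 - SS_res/SS_tot`
against each training fold's mean, and McFadden
`R^2 = 1 - L_M/L_null` against intercept-only fits. Folds are assigned at
random by row (stratified by outcome for logistic fits) from a fixed seed;
the seven models feeding a three-way partition share fold assignments, so
partition differences reflect predictors, not folds. Partitions follow
inclusion–exclusion on the seven scores; under cross-validation individual
partitions can be negative and are reported as-is with a flag.

Group-level inference uses equal-tail bootstrap t-tests: the null is built
by mean-centering, p is twice the smaller tail probability of the observed
t under resampling (no symmetry assumption), and CIs are percentile
intervals of the resampled mean.

## Effect sizes

The preview benefit is the expected gaze-duration difference between a
preview of average informativeness and no preview at all (posterior
entropy equal to the prior entropy), computed on the participant's
z-scale for parafoveal entropy and multiplied by the regression weight.
The predictability benefit applies cloze cutoffs (low < 0.02,
high > 0.25, i.e. surprisal above 5.64 or below 2 bits) to the surprisal
distribution and multiplies the mean z-surprisal difference between bins
by the current-word surprisal weight only (not the spillover lags; the
source is ambiguous and we chose the current-word reading). Both benefits
are invariant to the standardization (tested).

## The synthetic world

The generator emulates the statistical structure the analysis assumes:

* **Lexicon**: `V` random letter strings, frequencies Zipfian
  (`rank^-1`), lengths 2–8 growing noisily with rank so longer words are
  rarer.
* **Provider**: a bigram table with Dirichlet rows centred on the text's
  unigram distribution; smaller concentration gives more informative
  contexts. The realized text unigram deviates log-normally
  (`text_freq_log_sd = 1`) from the lexicon's reference frequencies,
  because real frequency norms (film subtitles, say) never match a
  specific text's statistics.
* **Reader**: a strictly left-to-right pass. Each upcoming word is skipped
  with probability `plogis` of a linear form in its length and launch
  distance (optionally its predictive and parafoveal entropies); fixated
  words land Gaussian around 40% of word length (left of centre) with
  launch-dependent scatter; gaze durations are linear in surprisal (lags
  0–2), parafoveal entropy, log-frequency (lags 0–2), word-class offsets
  and absolute landing offset, plus Gaussian noise resampled (not
  clipped) into 70–900 ms so the plausibility filter does not truncate
  the noise distribution. Skipped words are later refixated regressively
  with probability increasing in their pre-skip parafoveal entropy
  (the compensation mechanism). The final text word is always fixated so
  every token is crossed during the pass and compensation fixations are
  unambiguous regressions.

What a green test establishes: the pipeline recovers implanted
coefficients, classifies first-pass events exactly, and reproduces the
qualitative partition structure. What it does not establish: anything
about real orthography (random strings have sparse neighborhoods), real
syntax (bigram contexts), multi-line layout, or return-sweep handling.

## Why the contextual observer can extract *fewer* bits in a matched world

With context `C`, word `W` and percept `E` forming the Markov chain
`C -> W -> E`, the expected information a matched contextual observer
extracts is `I(W;E|C) = I(W;E) - I(C;E) <= I(W;E)`: conditioning on
context can only reduce the expected information the percept delivers
about the word. The often-reported opposite direction (contextual
observers extracting more bits) therefore requires misspecification — in
practice, a frequency prior estimated from a different corpus than the
text being read, and a vocabulary large enough that identification stays
incomplete at typical eccentricities. The synthetic world models the
first ingredient (`text_freq_log_sd = 1`); the second is outside desk
scale (tens of thousands of orthographically dense words). At desk-scale
vocabularies identification is essentially complete at typical launch
distances, so the corpus-mean difference is dominated by the
prior-entropy deficit; with reference mismatch its sign at larger
eccentricities fluctuates with the realized mismatch rather than
stabilizing in the printed direction. The acceptance suite asserts the
data-processing bound in the matched world (stable, green) and states the
corpus-mean criterion literally (red at desk scale, with this analysis in
the decisions ledger).

Similarly, the three-way skipping partition under oculomotor-only
generation assigns essentially the whole joint score to the oculomotor
*set*, but its *unique* partition cannot reach 90% of the joint: parafoveal
entropy is by definition driven by length and eccentricity, so the
preview/oculomotor overlap is structural (about 17% of the joint in the
stated world).

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `sigma` | 3 | perceptual-span width, characters |
| `Lambda` | 1 | sensory-quality scale |
| `noise_exponent` | -1/2 | variance = `lambda^e` |
| `T_samples` | 50 | visual samples per run |
| `repeats` | 3 | runs averaged per token |
| `nucleus mass` | 0.95 | contextual truncation |
| `k_folds` | 10 | cross-validation folds |
| `n_boot` | 10^4 | bootstrap resamples |
| `max_launch` | 24 | launch-distance cap, characters |
| `gaze_window` | 70–900 | plausible gaze durations, ms |

## Known limitations

Single-line synthetic texts only; no modelling of preview from fixations
earlier than the last; no letter-similarity structure; corpus-specific raw
formats must be converted to the canonical TSV schema by the user;
fold assignment is by row (configurable in code but not blocked by text).
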