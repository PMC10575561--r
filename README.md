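# readobs

Model-based analysis of eye movements in natural reading: how much of the
variation in **word skipping** and **gaze durations** is explained by
*linguistic prediction*, *parafoveal preview*, and *low-level oculomotor
factors*?

`readobs` is for reading researchers and computational psycholinguists who
have word-by-word fixation reports and want the full model-based pipeline:

* a **Bayesian ideal observer** of parafoveal word identification —
  eccentricity-dependent noisy letter sampling over a Gaussian perceptual
  span (`λ(ε) = Λ[Φ((ε+½)/σ) − Φ((ε−½)/σ)]`, defaults σ = 3, Λ = 1),
  log-odds belief updating, and per-token posterior entropy in bits;
* **contextual priors** built from any next-word probability provider via
  nucleus truncation (mass 0.95) and implied pseudofrequencies with a flat
  pseudocount-1 tail;
* **first-pass measure extraction** (skips, gaze durations, launch
  distance, landing position) and the standard data-selection filters
  (non-alphabetic tokens, blinks, |launch| > 24 chars, gaze outside
  70–900 ms, return sweeps);
* per-participant **cross-validated regression** (logistic for skipping
  scored by McFadden R², OLS for durations scored by R², 10 folds, pooled
  held-out losses);
* **variation partitioning** of 2 or 3 explanation sets by
  inclusion–exclusion over the 3 (7) model combinations on shared folds;
* **equal-tail bootstrap t-tests**, model-derived **preview and
  predictability benefits** in ms, and the contextual-vs-non-contextual
  observer comparison;
* a **synthetic reading-corpus generator** with known ground truth, so the
  whole pipeline is verifiable end to end without any licensed corpus or
  pretrained language model.

## Worked example

```r
library(readobs)

study <- generate_study(generator_params(
  n_participants = 4, words_per_participant = 600, V = 150,
  master_seed = 42))
report <- run_pipeline(study$corpus, study$lexicon, study$lm_features,
                       pipeline_config(master_seed = 42, n_boot = 2000,
                                       compare_priors = FALSE))

aggregate(value ~ partition, report$partitions$skipping, mean)
#>                        partition     value
#> 1                    oculomotor*  5.42e-02
#> 2 prediction:oculomotor\\preview  1.96e-03
#> 3  prediction:preview:oculomotor  1.51e-03
#> 4 prediction:preview\\oculomotor -1.04e-05
#> 5                    prediction* -2.11e-03
#> 6 preview:oculomotor\\prediction  1.21e-02
#> 7                       preview* -3.86e-03

report$bootstrap$skipping[["oculomotor*"]]
#> <bootstrap t-test> mean 0.05423 (t = 14.526, n = 4), 95% CI [0.04837, 0.0601], p = 0
```

The generator's default skip rule uses only word length and launch
distance, and the partitions recover exactly that structure: the
oculomotor unique partition dominates, the preview–oculomotor overlap is
the only other sizable component (parafoveal identifiability is itself a
function of length and eccentricity), and the lexical unique partitions
are indistinguishable from zero.

```r
report$effect_sizes
#>   participant preview_benefit_ms predictability_benefit_ms
#> 1         p01               24.0                      13.9
#> 2         p02               33.2                      13.5
#> 3         p03               37.4                      13.3
#> 4         p04               23.4                      13.2
```

Per-participant preview benefits (expected gaze-duration saving of an
average preview versus none) and predictability benefits (high- versus
low-cloze words) in milliseconds, derived from the standardized duration
model and the stored z-moments.

Single tokens work too:

```r
lex <- build_lexicon(c("the","that","then","this","them","they",
                       "she","he","her","there"),
                     c(10,8,6,5,5,5,4,4,3,3))
preview_entropy("the", 2, frequency_prior_logodds(lex), lex,
                config = observer_config(seed = 1))
#> <observer output> 'the' at 2.00 chars: prior 3.217 -> posterior 0.468 bits (gain 2.749)
```

## Real corpora

Convert your eye-tracking report to the canonical TSV pair documented in
`?read_corpus` (`words.tsv`: participant, text_id, line_id, word_index,
word, first_char, word_class; `fixations.tsv`: participant, text_id,
line_id, order, x_char, duration_ms, blink_adjacent), supply a
word-frequency TSV (`?read_lexicon`) and per-token next-word nuclei as
JSON lines (`?read_nucleus`), then:

```sh
exec/readobs all --corpus my_corpus_dir --out results --seed 1
```

or from R via `run_pipeline()`. A full natural-reading corpus with a large
vocabulary takes hours (observer sampling dominates); the synthetic
workflow above is the desk-scale path.

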