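# onconotes

Computer-aided screening of free-text psycho-oncology patient notes.

Patients treated for head–neck or upper-gastrointestinal cancers — many of
them enterally fed — are at high risk of disturbed body image, low
self-esteem and mood deterioration, while psycho-oncological staff time is
scarce. `onconotes` implements a structured NLP screening pipeline over
short notes in which patients describe how they perceive their body, for
psychologists, psychiatrists and researchers who want a fast, auditable
first pass over such narratives.

For each note the pipeline produces:

* **Word-class statistics** — adjectives split by polarity, verb tenses
  ("to be" vs others), the possessive *my* in a body context, and the
  adjective *saturation* `100 · n_adj / L` of note length `L`, summarised
  per treatment stage (diagnosis, treatment, palliative).
* **Sentiment polarity** `y ∈ {−1, 0, +1}` from a hybrid score
  `c = α·s_lex + (1−α)·s_model`, where
  `s_lex = (n₊ − n₋)/n_matched` comes from a polarity lexicon and
  `s_model` from a small recurrent sequence classifier over token
  embeddings; `y = 0` iff `|c| ≤` the neutral band.
* **Areas of difficulty** (body image, self-esteem, pain): a bag-of-words
  term–document matrix is reduced by truncated SVD (latent semantic
  analysis); a note's affiliation to a topic in its negative and positive
  contexts is the clipped cosine between the projection of its
  topic-related vocabulary and the centroid of the topic's negative /
  positive term vectors. With relative difference
  `rd = 100·|a⁻ − a⁺| / max(a⁻, a⁺)`, the outcome is ABSENT
  (`a⁻ = a⁺ = 0`), NEGATIVE (`a⁻ > a⁺`, `rd > 20%`), POSITIVE
  (mirrored), else MIXED. Pain is dictionary membership (raised or not).
* **Emotion profiles** — intensities in `[0, 1]` for happiness, sadness,
  anger, disgust, fear. An affective lexicon (word → five intensities) is
  expanded over the corpus: emotion *centres* are mean embeddings of
  dominant-emotion lexicon words; an out-of-lexicon word is assigned to
  its most cosine-similar centre and receives intensities
  `Σₖ s_k·w_k` from its k Euclidean-nearest lexicon words with
  normalised inverse-distance weights. The note-level intensity for
  emotion *e* is `(Σ_{w∈D_e} s_w(e)) / L` over the tokens `D_e` dominated
  by *e*.
* **Method-vs-expert agreement** — Cohen's kappa with full confusion
  matrices, per-stage agreement breakdowns, and pain / no-pain group mean
  profiles.

Clinical corpora of this kind cannot be shipped, so the package includes a
first-class synthetic-study generator (`corpus_spec()`,
`generate_study()`) with exact planted ground truth — stages, sentiment,
topic contexts, pain, word-class counts, emotion clusters — used by the
entire test suite.

## Worked example

Generate a 50-note synthetic study, run the main analyses, and compare
with the expert flags (all numbers below are the actual output):

```r
library(onconotes)

st    <- generate_study(corpus_spec(seed = 1))
notes <- preprocess_notes(st$notes, stopwords = st$lexicons$stopwords)

# sentiment per treatment stage
sent <- hybrid_sentiment(notes, st$lexicons$polarity)
stage_sentiment_breakdown(sent, notes)
#> # A tibble: 3 × 5
#>   stage          n pct_positive pct_neutral pct_negative
#> 1 I             11         9.09        27.3         63.6
#> 2 II            32        28.1         18.8         53.1
#> 3 palliative     7        14.3         28.6         57.1
```

Stage I notes are predominantly negative (63.6%), with positivity peaking
during treatment — the per-stage proportions the generator planted, and
exactly what the lexicon route recovers.

```r
# body-image context per note, via LSA affiliation
space <- fit_lsa(term_document_matrix(notes))
ctx <- topic_affiliation(notes, st$topics$body_image, space) |>
  classify_topic_context()
ctx[1:4, ]
#>   id       negative positive relative_difference_pct context   flag
#> 1 note0001    0.434   0                        100   NEGATIVE    -1
#> 2 note0002    0.118   0.414                     71.4 POSITIVE     1
#> 3 note0003    0.315   0.351                     10.3 MIXED        2
#> 4 note0004    0.430   0.0647                    84.9 NEGATIVE    -1

# agreement with the expert flags
cohens_kappa(ctx$context, flag_to_context(st$notes$flag_body_image))
#> <agreement_report> n = 50
#>   kappa = 0.9665 (po = 0.98, pe = 0.4028)
```

Note 1 mentions body image only in negative terms (affiliation 0.434 vs
0), note 3 mixes contexts (relative difference 10.3% < 20% → MIXED); 49 of
50 notes match the expert flag, a chance-corrected kappa of 0.97.

```r
# five-emotion profiles from the expanded lexicon
expanded <- expand_lexicon(unique(unlist(notes$tokens)),
                           st$lexicons$affective, st$embeddings)
prof <- note_emotion_profiles(notes, expanded)
stage_emotion_profiles(prof, notes)
#> # A tibble: 3 × 7
#>   stage          n happiness sadness  anger disgust    fear
#> 1 I             11    0.0129  0.0215 0.0147  0.0122 0.0179
#> 2 II            32    0.0164  0.0163 0.0224  0.0157 0.0106
#> 3 palliative     7    0.0267  0.0229 0.0108  0.0102 0.00997
```

Sadness and fear dominate at diagnosis, anger peaks during treatment, and
happiness is highest under palliative care — the stage-wise emotion
mixture the generator planted. `plot_stage_emotion_profiles()`,
`plot_stage_sentiment()` and `plot_adjective_saturation()` render these
tables; `run_pipeline(pipeline_config(...))` executes all of the above
end-to-end with versioned outputs, and `inst/cli/onconotes.R` wraps
`synth` and `run` for shell use.

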