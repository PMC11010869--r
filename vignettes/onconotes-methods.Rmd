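---
title: "Methods: screening psycho-oncology notes with lexicon and embedding NLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening psycho-oncology notes with lexicon and embedding NLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onconotes)
```

## The screening problem

Patients treated for head–neck or upper-gastrointestinal cancers — many of
them enterally fed — are at high risk of disturbed body image and mood
deterioration, and psycho-oncological resources are scarce. `onconotes`
implements a structured NLP screening pipeline over short free-text notes in
which patients describe how they perceive their body. For each note it
produces:

1. **Word-class statistics** — adjective counts split by polarity, verb
   tenses ("to be" vs other verbs), and the possessive *my* in a body
   context, summarised as per-stage adjective-saturation percentages.
2. **Sentiment polarity** in three classes \{−1, 0, +1\}, from a hybrid of
   a polarity lexicon and a small recurrent sequence classifier.
3. **Areas of difficulty** — body image, self-esteem (four-outcome context
   classification) and pain (present/absent), via latent semantic analysis.
4. **Emotion profiles** — intensities in \[0, 1\] for happiness, sadness,
   anger, disgust and fear, after expanding an affective lexicon over the
   corpus vocabulary with embedding geometry.
5. **Agreement statistics** (Cohen's kappa, per-stage breakdowns) against
   expert flags, when those are available.

Clinical free-text corpora of this kind cannot be redistributed, so the
package ships a first-class synthetic-study generator with exact ground
truth; all validation is property-based and recovery-based on those
corpora.

## Lexicons and preprocessing

The **affective lexicon** follows the schema of normed affect word lists
(one word, a polarity in \{−1, 0, +1\}, and five emotion intensities in
\[0, 1\]); the shipped content is always synthetic — licensing of normed
lexicons forbids redistribution, and nothing in the pipeline depends on the
real entries. The **polarity lexicon** is a flat word→polarity table in the
tradition of general sentiment dictionaries, kept separate from the
affective lexicon: the affective lexicon drives the emotion machinery,
while the polarity lexicon drives sentiment and the adjective split. The
**topic dictionaries** hold positive and negative word lists for body image
and self-esteem, and a single list for pain, which is only ever detected as
raised-or-not.

Preprocessing lowercases, strips punctuation (it does not split on it, so
the token count never exceeds the raw whitespace count), removes stopwords,
and stems. The stemmer is an injected function with identity as the
default: morphology is language-specific (the motivating application is
Polish) and deliberately outside the correctness surface of this package —
a real tagger or stemmer plugs in through the same contract. The note
length *L* used by every per-length statistic is the post-preprocessing
token count; with raw or sentence counts the emotion quotient below would
not be bounded by construction.

## Word-class statistics

A tag lexicon (word → part of speech, tense, "to be" flag, "my" flag)
stands in for a full POS tagger so that counting is deterministic and
testable. Adjectives are split by their polarity-lexicon sign; adjectives
matching neither sign are "other". Negative (positive) adjective saturation
of a note is `100 · n_neg / L`; stage summaries are unweighted per-note
means, because each note is one patient utterance and short notes should
not be down-weighted. The possessive *my* is counted only when a
body-related term occurs in the same note (whole-note window — the
narratives are only a few sentences long, so a tighter window would mostly
split sentences arbitrarily).

## Hybrid sentiment

The lexicon route scores a note as
`(positive matches − negative matches) / matched tokens` ∈ \[−1, 1\].
The model route is a stacked Elman recurrent network over the sequence of
token embeddings (tanh units, sigmoid read-out of the final hidden state,
full backpropagation through time, Adam). It is a deliberately scaled-down
stand-in for the large LSTM sentiment models used in production: the
weights are not the contribution here, the interface and the hybrid
combination are. Defaults: 2 recurrent layers of width 8, 30 epochs,
learning rate 0.02; all of it configurable, and the seed is recorded in the
fitted model so training is reproducible. Training labels are binary
(−1/+1); neutrality is produced downstream by the band, not learned.

The hybrid score is the convex combination
`alpha · lexicon + (1 − alpha) · model` with `alpha = 0.5` by default —
with no stated weighting scheme in the literature for this combination, the
symmetric choice is the only non-arbitrary one — and `alpha` is forced to 1
when no model is supplied. The label is 0 when `|combined| ≤ 0.1` (the
neutral band) and `sign(combined)` otherwise. A fourth "ambivalent"
sentiment class is intentionally not emitted: mixed positive–negative
content is the business of the difficulty module's MIXED outcome.

## Areas of difficulty

Notes are turned into a bag-of-words term–document matrix (terms sorted in
the C locale for determinism) and reduced by truncated SVD. Raw counts are
the default weighting, with `log` and `tfidf` behind a flag; on corpora
with planted structure raw counts were sufficient and make the matrix
easiest to reason about. The default rank is `min(50, min(dim) − 1)`.

**Topic affiliation.** Term coordinates are the rows of `U_r·D_r`. A
note's affiliation to a topic in the negative (positive) context is the
cosine similarity — clipped below at zero — between the projection of the
note's *topic-related vocabulary* (its tokens that belong to the topic
dictionary, with multiplicity, folded in through `U_r`) and the centroid of
the topic's negative (positive) term vectors. Restricting the query to the
theme's own vocabulary is a deliberate design decision: projecting the full
note vector lets shared off-topic co-occurrence (fillers, function words)
dominate both cosines, and in experiments on planted corpora the
negative/positive contrast collapsed below the 20% threshold for most
notes (≈37% recovery at 500 notes, versus 100% with the restricted query).
The restriction also makes the ABSENT rule exact: a note with no topic
vocabulary has a zero query vector and therefore affiliation exactly 0 in
both contexts.

**Four-outcome rule.** With negative affiliation `a⁻`, positive `a⁺`, and
relative difference `rd = 100·|a⁻ − a⁺| / max(a⁻, a⁺)` (0 when both are 0):

* ABSENT when `a⁻ = a⁺ = 0`;
* NEGATIVE when `a⁻ > a⁺` and `rd > 20`;
* POSITIVE when `a⁺ > a⁻` and `rd > 20`;
* MIXED otherwise.

The max denominator is chosen because it is total (no division by zero for
non-degenerate pairs), scale-free (jointly rescaling both affiliations
never changes the label), and makes the 20% boundary reachable from both
sides. A relative difference of exactly 20% yields MIXED, since the
one-sided rules demand strict excess. Pain is plain set membership against
the pain list — fully deterministic, which is why pain agreement with any
membership-consistent annotation is always 100%.

## Emotion measurement

The five-emotion algorithm has three geometric steps over the embedding
table (GloVe text format, 100-dimensional by default):

1. **Centres** — the centre of emotion *e* is the per-dimension mean of
   the embeddings of lexicon words whose dominant emotion is *e* (dominant
   = argmax of the five intensities; ties broken in the fixed order
   happiness, sadness, anger, disgust, fear; all-zero rows map to a
   `none` sentinel and never feed a centre).
2. **Assignment** — an out-of-lexicon word joins the centre with maximal
   cosine similarity. Zero vectors have no direction and are skipped with
   a warning.
3. **Intensities** — the word's intensity for each emotion is the weighted
   sum `Σ s_k·w_k` over its k Euclidean-nearest lexicon words, with
   normalised inverse-distance weights
   `w_k = (1/(d_k+ε)) / Σ_j 1/(d_j+ε)`, `ε = 1e-9`, `k = 5` by default.
   Normalising the weights to sum to one keeps every combined intensity
   inside \[0, 1\]; the ε guard makes a coincident neighbour dominate
   smoothly instead of dividing by zero. Ties at the k-th distance break
   lexicographically, so the neighbour set is a pure function of the
   inputs. A `uniform` scheme (plain mean) is available.

Expansion gives every embeddable out-of-lexicon corpus stem an entry with
its dominant emotion from step 2 and intensities from step 3 — the centroid
decides the label, the neighbours supply the magnitudes — with polarity 0
and `source = "expanded"`; seed entries are never modified.

**Note profiles.** For emotion *e*, with `D_e` the note's tokens whose
lexicon dominant emotion is *e*, the profile value is `(Σ_{w∈D_e} s_w(e)) / L`.
The product form `(Σ s)·n_e/L` — a literal transcription of a "sum times
count over length" quotient — can exceed 1 for emotion-dense notes,
contradicting the stated \[0, 1\] range of emotion intensity; the
implemented quotient equals `(mean s)·(n_e/L)`, is bounded by construction,
and the product form remains available behind `literal = TRUE` for
comparison. A defensive clamp to \[0, 1\] is applied either way.

## Agreement statistics

Cohen's unweighted kappa is computed over the union of observed categories
(4-category context alphabet for the difficulty topics, 3-category for
sentiment), with the full confusion matrix retained; when both raters are
constant and identical, chance agreement is 1 and kappa is defined as 1
with a degeneracy flag. Per-stage breakdowns report exact-match agreement
plus, in `mixed_lenient` mode, a separate "advantage" discrepancy class:
the expert rated MIXED but the method favoured one context. Between-group
comparisons are descriptive means only; no significance testing is
performed.

## The synthetic-study generator

`corpus_spec()` fixes the study conditions; `generate_study()` derives the
lexicons, embeddings, topic dictionaries and annotated corpus from the
spec and a single seed. Defaults encode the cohort the method targets:

* 50 notes of 10–200 tokens across three treatment stages at 22% / 64% /
  14% (diagnosis, treatment, palliative);
* per-stage sentiment splits of 9/27/64, 29/18/53 and 14/29/57 percent
  (positive/neutral/negative) and per-stage polar-adjective rates of
  16.3%, 11.1% and 15.3% of note length, matching published per-stage
  summaries of this population;
* four-outcome topic-context proportions dominated by negative contexts;
  pain planted in half the notes (no published prevalence exists for this
  exact quantity; one half maximises the information in the pain-group
  comparison);
* a 250-word seed affective lexicon in five planted clusters
  (dominant-emotion intensity Uniform(0.6, 1), others Uniform(0, 0.3), so
  the planted cluster is always the dominant label), 100 extra
  out-of-lexicon cluster words as expansion targets, 100-dimensional
  embeddings with cluster centres at mutual distance 10σ;
* roughly 10% of each note's tokens drawn from emotion clusters — the
  coverage ratio reported for affective lexicons over clinical corpora —
  with at least 3 dominant-cluster words per note and 80% purity;
* quota (exact-count) sampling for every categorical plant, so
  bookkeeping targets are exact at any corpus size; "to be" and other-verb
  tense draws follow the published tense ratios (7:89:9 and 25:140).

Every realised count is recorded at composition time; the ground-truth
table is the oracle for the aggregate tests. All generator outputs are
pure functions of (spec, seed).

What the generator does **not** emulate: natural-language syntax and
morphology (words are generated strings, the stemmer is identity),
embedding coverage of non-affective vocabulary (topic terms, adjectives
and fillers deliberately carry no vectors, isolating the emotion machinery
from them — in real GloVe spaces nearly every token is embedded and
expansion will also assign emotions to neutral words, a noise source absent
here), correlations between sentiment, topic context and emotions beyond
the planted marginals, and annotator noise (expert flags equal the planted
truth). Passing recovery tests therefore demonstrates correctness of the
pipeline's mechanics under its stated assumptions, not clinical validity
on real notes.

## Numerical choices and degenerate inputs

* Duplicate lexicon words: error in strict mode, last-wins with a message
  otherwise. Lexicon CSV is UTF-8, comma-separated, dot decimal;
  intensities are written with 17 significant digits and parsed with
  correctly-rounded base-R conversion so write→read round-trips are
  bit-exact.
* Empty raw text is an error; a note emptied by stopword removal is
  retained (flagged) but excluded from length-normalised statistics, which
  are undefined at L = 0.
* Term order in the term–document matrix and all tie-breaks use C-locale
  radix ordering; together with seed-threaded RNG this makes the full
  pipeline rerun byte-identical (verified by content hashes; only the
  manifest carries a timestamp).
* SVD comes from base R (LAPACK); the truncated reconstruction error
  equals the discarded singular-value tail energy to ~1e-14 in tests.
* The recurrent classifier clips gradients at global norm 5 and is
  validated against numerical differentiation to 1e-6.

## Problem sizes used in validation

The shipped validation suite exercises: the exhaustive 21×21 affiliation
grid; 200 random kNN instances with lexicons up to 500 words and k ≤ 10
against an exhaustive-scan oracle (agreement to 1e-12); a 1,000-note
corpus for the intensity-range invariant; a 500-note corpus at separation
10σ for dominant-emotion recovery (≥95% required) and topic-context
recovery (≥90% of non-MIXED notes; pain 100%); closed-form kappa values
and a 10,000-pair independence null; and double pipeline runs on the
default 50-note study for determinism. These sizes keep every quantity
statistically sharp while the whole suite runs in about a minute.

## Known limitations

* Real-language preprocessing (Polish morphology, real POS tagging) is a
  plug-in contract, not an implementation.
* The classifier is a small Elman network, not a production LSTM; it
  demonstrates the hybrid interface and trains reliably on separable
  corpora, nothing more.
* Reported per-stage percentages, kappas and profile values from any
  particular clinical study depend on that study's (non-distributable)
  corpus and are not reproduced by this package; the package reproduces
  the *method* and validates it on planted structure.
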