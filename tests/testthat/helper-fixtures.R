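# In-code fixtures shared across the suite. Everything is built
# programmatically; the small_study object is generated once per test run.

make_affective <- function(words, intensities, polarity = 0L,
                           source = "seed") {
  stopifnot(ncol(intensities) == 5)
  colnames(intensities) <- emotion_labels()
  lex <- tibble::tibble(word = words,
                        polarity = rep_len(as.integer(polarity),
                                           length(words)))
  for (e in emotion_labels()) lex[[e]] <- intensities[, e]
  lex$source <- rep_len(source, length(words))
  lex$dominant <- dominant_emotion(lex)
  lex
}

make_notes <- function(token_list, stage = "I", ids = NULL) {
  n <- length(token_list)
  tibble::tibble(
    id = ids %||% sprintf("n%03d", seq_len(n)),
    stage = rep_len(stage, n),
    text = vapply(token_list, paste, character(1), collapse = " "),
    tokens = token_list,
    n_tokens = lengths(token_list)
  )
}

# a small but complete synthetic study, shared across files (cheap dims)
small_spec <- function(seed = 42L, n_notes = 40L) {
  corpus_spec(n_notes = n_notes, note_length_range = c(20L, 60L),
              lexicon_size = 50L, oov_words_per_emotion = 6L,
              embedding_dim = 16L, n_filler_words = 40L,
              n_polar_adjectives = 12L, n_other_adjectives = 8L,
              seed = seed)
}

cached_small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- generate_study(small_spec())
      st$prep <- preprocess_notes(st$notes,
                                  stopwords = st$lexicons$stopwords)
      cache <<- st
    }
    cache
  }
})

# literal restatement of the four-outcome relative-difference rule, used as
# the independent oracle for classify_topic_context
rule_oracle <- function(neg, pos, thr = 20) {
  if (neg == 0 && pos == 0) return("ABSENT")
  rd <- 100 * abs(neg - pos) / max(neg, pos)
  if (neg > pos && rd > thr) return("NEGATIVE")
  if (pos > neg && rd > thr) return("POSITIVE")
  "MIXED"
}

# largest-remainder allocation, restated independently of the generator
quota_counts_oracle <- function(n, props) {
  k <- floor(n * props)
  frac <- n * props - k
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(-frac, seq_along(props))[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  as.integer(k)
}

# exhaustive-scan kNN oracle: loops over lexicon words, sorts by distance
# (ties by word), applies the weight formula directly
knn_oracle <- function(vec, lexicon, embeddings, k, scheme = "inverse_distance",
                       eps = 1e-9) {
  words <- lexicon$word[lexicon$word %in% rownames(embeddings)]
  d <- vapply(words, function(w) sqrt(sum((vec - embeddings[w, ])^2)),
              numeric(1))
  ord <- order(d, words, method = "radix")[seq_len(k)]
  nb_w <- words[ord]
  nb_d <- d[ord]
  w <- if (scheme == "uniform") rep(1 / k, k) else {
    raw <- 1 / (nb_d + eps)
    raw / sum(raw)
  }
  s <- as.matrix(lexicon[match(nb_w, lexicon$word), emotion_labels()])
  list(words = nb_w, intensity = drop(w %*% s))
}
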