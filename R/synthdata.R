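# Synthetic study generator: affective/polarity/tag lexicons with planted
# emotion clusters, clustered word embeddings, topic dictionaries, and
# annotated note corpora whose ground truth (stages, sentiment, contexts,
# pain, word-class counts) is recorded exactly at composition time. All
# outputs are pure functions of (spec, seed); categorical plants use quota
# (exact-count) sampling so bookkeeping targets are exact.

#' Specification of a synthetic study
#'
#' Defaults emulate the kind of cohort the method targets: 50 notes split
#' across three treatment stages (22% / 64% / 14%), per-stage sentiment
#' splits and adjective-saturation rates matching published per-stage
#' summaries, four-outcome topic contexts for body image and self-esteem,
#' pain in half the notes, 100-dimensional clustered embeddings, and an
#' affective-lexicon coverage of roughly 10% of each note's tokens.
#'
#' @param n_notes number of notes.
#' @param note_length_range target token-count range per note (very short
#'   notes are stretched minimally when their planted structure needs more
#'   slots).
#' @param stage_proportions named proportions over `I`, `II`, `palliative`.
#' @param sentiment_by_stage 3 x 3 matrix (stages x positive/neutral/
#'   negative) of per-stage sentiment proportions.
#' @param emotion_mix_by_stage 3 x 5 matrix (stages x emotions) of dominant-
#'   emotion proportions per stage.
#' @param adjective_rate_by_stage named per-stage fraction of tokens that
#'   are polar adjectives.
#' @param topic_context_proportions named list (`body_image`, `self_esteem`)
#'   of proportions over `ABSENT`, `NEGATIVE`, `POSITIVE`, `MIXED`.
#' @param pain_prevalence fraction of notes mentioning pain.
#' @param lexicon_size number of seed affective-lexicon words (at least 25).
#' @param oov_words_per_emotion out-of-lexicon emotion-cluster words per
#'   emotion (expansion targets).
#' @param embedding_dim embedding dimension (at least 5).
#' @param cluster_separation mutual distance between emotion-cluster
#'   centres, in units of the within-cluster standard deviation (sigma = 1).
#' @param emotion_token_rate fraction of each note's tokens drawn from
#'   emotion clusters (at least 3 words per note).
#' @param emotion_purity fraction of a note's emotion words drawn from its
#'   dominant cluster.
#' @param topic_token_rate fraction of tokens from each present topic's
#'   dictionary.
#' @param stopword_rate stopwords added per content token.
#' @param n_topic_terms,n_pain_terms,n_polar_adjectives,n_other_adjectives,
#'   n_filler_words,n_stopwords vocabulary sizes of the remaining classes.
#' @param seed master RNG seed; every generator derives its stream from it.
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(
    n_notes = 50L,
    note_length_range = c(10L, 200L),
    stage_proportions = c(I = 0.22, II = 0.64, palliative = 0.14),
    sentiment_by_stage = rbind(
      I = c(positive = 0.09, neutral = 0.27, negative = 0.64),
      II = c(positive = 0.29, neutral = 0.18, negative = 0.53),
      palliative = c(positive = 0.14, neutral = 0.29, negative = 0.57)
    ),
    emotion_mix_by_stage = rbind(
      I = c(happiness = 0.10, sadness = 0.30, anger = 0.15,
            disgust = 0.20, fear = 0.25),
      II = c(happiness = 0.15, sadness = 0.20, anger = 0.30,
             disgust = 0.20, fear = 0.15),
      palliative = c(happiness = 0.35, sadness = 0.25, anger = 0.10,
                     disgust = 0.10, fear = 0.20)
    ),
    adjective_rate_by_stage = c(I = 0.1628, II = 0.1111, palliative = 0.1526),
    topic_context_proportions = list(
      body_image = c(ABSENT = 0.04, NEGATIVE = 0.46, POSITIVE = 0.42,
                     MIXED = 0.08),
      self_esteem = c(ABSENT = 0.04, NEGATIVE = 0.46, POSITIVE = 0.36,
                      MIXED = 0.14)
    ),
    pain_prevalence = 0.5,
    lexicon_size = 250L,
    oov_words_per_emotion = 20L,
    embedding_dim = 100L,
    cluster_separation = 10,
    emotion_token_rate = 0.10,
    emotion_purity = 0.8,
    topic_token_rate = 0.06,
    stopword_rate = 0.2,
    n_topic_terms = 12L,
    n_pain_terms = 10L,
    n_polar_adjectives = 30L,
    n_other_adjectives = 20L,
    n_filler_words = 150L,
    n_stopwords = 10L,
    seed = 1L) {
  spec <- list(
    n_notes = as.integer(n_notes),
    note_length_range = as.integer(note_length_range),
    stage_proportions = stage_proportions,
    sentiment_by_stage = sentiment_by_stage,
    emotion_mix_by_stage = emotion_mix_by_stage,
    adjective_rate_by_stage = adjective_rate_by_stage,
    topic_context_proportions = topic_context_proportions,
    pain_prevalence = pain_prevalence,
    lexicon_size = as.integer(lexicon_size),
    oov_words_per_emotion = as.integer(oov_words_per_emotion),
    embedding_dim = as.integer(embedding_dim),
    cluster_separation = cluster_separation,
    emotion_token_rate = emotion_token_rate,
    emotion_purity = emotion_purity,
    topic_token_rate = topic_token_rate,
    stopword_rate = stopword_rate,
    n_topic_terms = as.integer(n_topic_terms),
    n_pain_terms = as.integer(n_pain_terms),
    n_polar_adjectives = as.integer(n_polar_adjectives),
    n_other_adjectives = as.integer(n_other_adjectives),
    n_filler_words = as.integer(n_filler_words),
    n_stopwords = as.integer(n_stopwords),
    seed = as.integer(seed)
  )
  check_props <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0("`", what, "` must be non-negative and sum to 1."),
            class = "onconotes_parameter_error")
    }
  }
  check_props(spec$stage_proportions, "stage_proportions")
  for (s in stage_levels()) {
    check_props(spec$sentiment_by_stage[s, ], paste0("sentiment_by_stage[", s, ",]"))
    check_props(spec$emotion_mix_by_stage[s, ], paste0("emotion_mix_by_stage[", s, ",]"))
  }
  for (t in names(spec$topic_context_proportions)) {
    check_props(spec$topic_context_proportions[[t]], t)
  }
  if (spec$lexicon_size < 25L) {
    abort("`lexicon_size` must be at least 5 words per emotion (25).",
          class = "onconotes_parameter_error")
  }
  if (spec$embedding_dim < 5L) {
    abort("`embedding_dim` must be at least 5 to host five cluster centres.",
          class = "onconotes_parameter_error")
  }
  if (spec$cluster_separation < 0 || spec$pain_prevalence < 0 ||
      spec$pain_prevalence > 1) {
    abort("`cluster_separation` must be >= 0 and `pain_prevalence` in [0, 1].",
          class = "onconotes_parameter_error")
  }
  if (any(spec$note_length_range < 1L) ||
      spec$note_length_range[1] > spec$note_length_range[2]) {
    abort("`note_length_range` must be an increasing pair of positive counts.",
          class = "onconotes_parameter_error")
  }
  if (spec$seed >= 2^31 - 1000) {
    abort("`seed` too large.", class = "onconotes_parameter_error")
  }
  structure(spec, class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("<corpus_spec> ", x$n_notes, " notes, lexicon ", x$lexicon_size,
      " words, dim ", x$embedding_dim, ", separation ", x$cluster_separation,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# exact-count (quota) allocation of n items over named proportions
quota_counts <- function(n, props) {
  k <- floor(n * props)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- n * props - k
    add <- order(-frac, seq_along(props))[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  setNames(as.integer(k), names(props))
}

# quota allocation followed by a seeded shuffle
quota_assign <- function(n, props) {
  k <- quota_counts(n, props)
  sample(rep(names(k), k))
}

#' Generate synthetic lexicons
#'
#' Builds the seed affective lexicon (words partitioned across the five
#' emotion clusters; dominant-emotion intensity Uniform(0.6, 1), other
#' emotions Uniform(0, 0.3), so the planted cluster is always dominant),
#' out-of-lexicon emotion words (expansion targets), the polarity lexicon
#' (positive and negative adjectives), and the tag lexicon covering every
#' generated word class (adjectives, "to be" and other verbs with tenses,
#' the possessive "my", fillers, stopwords). Deterministic given the spec
#' seed.
#'
#' @param spec a [corpus_spec()].
#' @return an object of class `synthetic_lexicons`: `affective`, `polarity`,
#'   `tags` tibbles, `oov` (word/cluster tibble), token `pools`, `stopwords`.
#' @export
generate_lexicon <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  labs <- emotion_labels()
  withr::with_seed(spec$seed + 101L, {
    counts <- quota_counts(spec$lexicon_size,
                           setNames(rep(0.2, 5), labs))
    cluster <- rep(labs, counts)
    words <- sprintf("w%04d", seq_len(spec$lexicon_size))
    smat <- matrix(runif(spec$lexicon_size * 5, 0, 0.3),
                   ncol = 5, dimnames = list(NULL, labs))
    smat[cbind(seq_len(spec$lexicon_size), match(cluster, labs))] <-
      runif(spec$lexicon_size, 0.6, 1)
    affective <- tibble::tibble(word = words,
                                polarity = ifelse(cluster == "happiness",
                                                  1L, -1L))
    for (e in labs) affective[[e]] <- unname(smat[, e])
    affective$source <- "seed"
    affective$dominant <- cluster

    oov <- tibble::tibble(
      word = sprintf("x%04d", seq_len(5 * spec$oov_words_per_emotion)),
      cluster = rep(labs, each = spec$oov_words_per_emotion)
    )

    pools <- list(
      padj = sprintf("padj%03d", seq_len(spec$n_polar_adjectives)),
      nadj = sprintf("nadj%03d", seq_len(spec$n_polar_adjectives)),
      oadj = sprintf("oadj%03d", seq_len(spec$n_other_adjectives)),
      tb_past = sprintf("tbpast%02d", 1:3),
      tb_present = sprintf("tbpres%02d", 1:3),
      tb_future = sprintf("tbfut%02d", 1:2),
      v_past = sprintf("vpast%02d", 1:8),
      v_present = sprintf("vpres%02d", 1:12),
      my = "my",
      filler = sprintf("fill%04d", seq_len(spec$n_filler_words))
    )
    stopwords <- sprintf("stop%02d", seq_len(spec$n_stopwords))

    polarity <- tibble::tibble(
      word = c(pools$padj, pools$nadj),
      polarity = rep(c(1L, -1L), c(length(pools$padj), length(pools$nadj)))
    )

    tag_row <- function(word, pos, tense = "n/a", tobe = FALSE, my = FALSE) {
      tibble::tibble(word = word, pos = pos, tense = tense,
                     is_to_be = tobe, is_my = my)
    }
    tags <- dplyr::bind_rows(
      tag_row(pools$padj, "adjective"),
      tag_row(pools$nadj, "adjective"),
      tag_row(pools$oadj, "adjective"),
      tag_row(pools$tb_past, "verb", "past", tobe = TRUE),
      tag_row(pools$tb_present, "verb", "present", tobe = TRUE),
      tag_row(pools$tb_future, "verb", "future", tobe = TRUE),
      tag_row(pools$v_past, "verb", "past"),
      tag_row(pools$v_present, "verb", "present"),
      tag_row(pools$my, "other", my = TRUE),
      tag_row(c(words, oov$word, pools$filler), "other")
    )
    structure(list(affective = affective, polarity = polarity, tags = tags,
                   oov = oov, pools = pools, stopwords = stopwords),
              class = "synthetic_lexicons")
  })
}

# five cluster centres at mutual distance `sep`: regular-simplex vertices
# (e_i - 1/5 over the first five coordinates) rescaled, zero-padded to dim
cluster_centers <- function(dim, sep) {
  base <- diag(5) - 1 / 5          # pairwise distance sqrt(2)
  base <- base * (sep / sqrt(2))
  cbind(base, matrix(0, 5, dim - 5))
}

#' Generate clustered word embeddings
#'
#' Embeds every affective word (seed and out-of-lexicon) as its planted
#' cluster centre plus isotropic Gaussian noise (sigma = 1). Centres sit at
#' mutual distance `cluster_separation * sigma`. Words outside the affective
#' vocabulary (topic terms, adjectives, fillers) carry no vector: the table
#' deliberately models partial embedding coverage of a corpus. Deterministic
#' given the spec seed.
#'
#' @param lexicons a [generate_lexicon()] result.
#' @param spec the matching [corpus_spec()].
#' @return embedding matrix (words x dim) with the planted `centers`
#'   (5 x dim matrix) attached as an attribute.
#' @export
generate_embeddings <- function(lexicons, spec) {
  stopifnot(inherits(lexicons, "synthetic_lexicons"),
            inherits(spec, "corpus_spec"))
  withr::with_seed(spec$seed + 202L, {
    centers <- cluster_centers(spec$embedding_dim, spec$cluster_separation)
    rownames(centers) <- emotion_labels()
    words <- c(lexicons$affective$word, lexicons$oov$word)
    cluster <- c(lexicons$affective$dominant, lexicons$oov$cluster)
    noise <- matrix(rnorm(length(words) * spec$embedding_dim),
                    nrow = length(words))
    mat <- centers[cluster, , drop = FALSE] + noise
    rownames(mat) <- words
    attr(mat, "centers") <- centers
    mat
  })
}

#' Generate topic dictionaries
#'
#' Fixed synthetic term lists for body image and self-esteem (positive and
#' negative) and pain (single list). No randomness: vocabulary sizes come
#' from the spec.
#'
#' @param spec a [corpus_spec()].
#' @return a named list of [topic_dictionary()] objects.
#' @export
generate_topic_dictionaries <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  k <- spec$n_topic_terms
  list(
    body_image = topic_dictionary("body_image",
                                  positive = sprintf("bipos%02d", seq_len(k)),
                                  negative = sprintf("bineg%02d", seq_len(k))),
    self_esteem = topic_dictionary("self_esteem",
                                   positive = sprintf("sepos%02d", seq_len(k)),
                                   negative = sprintf("seneg%02d", seq_len(k))),
    pain = topic_dictionary("pain",
                            positive = sprintf("pain%02d",
                                               seq_len(spec$n_pain_terms)))
  )
}

# token counts realising a planted topic context at target size n_t:
# NEGATIVE at >= 3:1 negative:positive, POSITIVE mirrored, MIXED 1:1
context_counts <- function(context, n_t) {
  switch(context,
    ABSENT = c(neg = 0L, pos = 0L),
    NEGATIVE = {
      pos <- n_t %/% 4L
      c(neg = n_t - pos, pos = pos)
    },
    POSITIVE = {
      neg <- n_t %/% 4L
      c(neg = neg, pos = n_t - neg)
    },
    MIXED = {
      half <- (n_t + n_t %% 2L) %/% 2L
      c(neg = half, pos = half)
    }
  )
}

#' Generate an annotated synthetic corpus
#'
#' Composes each note from planted parts: emotion-cluster words (at least
#' three from the dominant cluster; roughly `emotion_token_rate` of the
#' tokens, a share `1 - emotion_purity` spread over the other clusters),
#' polar adjectives realising the planted sentiment label, topic terms
#' realising the planted body-image and self-esteem contexts, pain terms
#' when pain is planted, "my" tokens when the body-image topic is present,
#' "to be" and other verbs with tense draws, and filler words up to the
#' target length. Stopwords are interspersed and removed again by
#' preprocessing. Expert flags equal the planted labels, and every
#' realised count is recorded in the ground-truth table at composition time.
#'
#' @param lexicons a [generate_lexicon()] result.
#' @param embeddings matching [generate_embeddings()] matrix (unused in
#'   composition; accepted for interface symmetry).
#' @param topics a [generate_topic_dictionaries()] list.
#' @param spec the matching [corpus_spec()].
#' @return a list with `notes` (corpus tibble as from [read_notes()]) and
#'   `truth` (per-note ground truth and realised counts).
#' @export
generate_corpus <- function(lexicons, embeddings, topics, spec) {
  stopifnot(inherits(lexicons, "synthetic_lexicons"),
            inherits(spec, "corpus_spec"))
  labs <- emotion_labels()
  pools <- lexicons$pools
  cluster_pool <- lapply(setNames(labs, labs), function(e) {
    c(lexicons$affective$word[lexicons$affective$dominant == e],
      lexicons$oov$word[lexicons$oov$cluster == e])
  })
  withr::with_seed(spec$seed + 303L, {
    n <- spec$n_notes
    stage <- quota_assign(n, spec$stage_proportions)
    sentiment <- integer(n)
    dominant <- character(n)
    for (s in stage_levels()) {
      idx <- which(stage == s)
      if (length(idx) == 0) next
      sent_lab <- quota_assign(length(idx), spec$sentiment_by_stage[s, ])
      sentiment[idx] <- c(positive = 1L, neutral = 0L,
                          negative = -1L)[sent_lab]
      dominant[idx] <- quota_assign(length(idx),
                                    spec$emotion_mix_by_stage[s, ])
    }
    body_ctx <- quota_assign(n, spec$topic_context_proportions$body_image)
    se_ctx <- quota_assign(n, spec$topic_context_proportions$self_esteem)
    pain <- as.integer(quota_assign(
      n, c(`1` = spec$pain_prevalence, `0` = 1 - spec$pain_prevalence)))
    rng <- spec$note_length_range
    L_target <- if (rng[1] == rng[2]) rep(rng[1], n) else
      sample(seq(rng[1], rng[2]), n, replace = TRUE)

    notes <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      L <- L_target[i]
      # emotion words: dominant cluster plus a spread over the others
      n_emo <- max(3L, round(spec$emotion_token_rate * L))
      n_off <- min(n_emo - 3L, round((1 - spec$emotion_purity) * n_emo))
      n_dom <- n_emo - n_off
      emo_tokens <- sample(cluster_pool[[dominant[i]]], n_dom, replace = TRUE)
      if (n_off > 0) {
        others <- setdiff(labs, dominant[i])
        off_cl <- rep_len(others, n_off)
        emo_tokens <- c(emo_tokens, vapply(off_cl, function(e) {
          sample(cluster_pool[[e]], 1)
        }, character(1)))
      }
      # polar adjectives realising the sentiment label
      n_adj <- max(2L, round(spec$adjective_rate_by_stage[stage[i]] * L))
      if (sentiment[i] == 0L) {
        n_adj <- n_adj - n_adj %% 2L
        n_pos_adj <- n_adj %/% 2L
      } else if (sentiment[i] == 1L) {
        n_pos_adj <- as.integer(ceiling(0.8 * n_adj))
      } else {
        n_pos_adj <- n_adj - as.integer(ceiling(0.8 * n_adj))
      }
      n_neg_adj <- n_adj - n_pos_adj
      adj_tokens <- c(sample(pools$padj, n_pos_adj, replace = TRUE),
                      sample(pools$nadj, n_neg_adj, replace = TRUE))
      # topic terms realising the planted contexts
      n_t <- max(3L, round(spec$topic_token_rate * L))
      bi <- context_counts(body_ctx[i], n_t)
      se <- context_counts(se_ctx[i], n_t)
      topic_tokens <- c(
        sample(topics$body_image$negative, bi["neg"], replace = TRUE),
        sample(topics$body_image$positive, bi["pos"], replace = TRUE),
        sample(topics$self_esteem$negative, se["neg"], replace = TRUE),
        sample(topics$self_esteem$positive, se["pos"], replace = TRUE)
      )
      pain_tokens <- if (pain[i] == 1L) {
        sample(topics$pain$positive, sample(1:3, 1), replace = TRUE)
      } else character(0)
      n_my <- if (body_ctx[i] != "ABSENT") sample(1:2, 1) else 0L
      my_tokens <- rep(pools$my, n_my)
      # verbs with tense draws
      n_tb <- max(1L, round(0.03 * L))
      tb_tense <- sample(c("past", "present", "future"), n_tb,
                         replace = TRUE, prob = c(7, 89, 9) / 105)
      tb_tokens <- vapply(tb_tense, function(tn) {
        sample(pools[[paste0("tb_", tn)]], 1)
      }, character(1))
      n_ov <- max(1L, round(0.04 * L))
      ov_tense <- sample(c("past", "present"), n_ov, replace = TRUE,
                         prob = c(25, 140) / 165)
      ov_tokens <- vapply(ov_tense, function(tn) {
        sample(pools[[paste0("v_", tn)]], 1)
      }, character(1))
      structural <- c(emo_tokens, adj_tokens, topic_tokens, pain_tokens,
                      my_tokens, tb_tokens, ov_tokens)
      n_fill <- max(0L, L - length(structural))
      # a slice of filler is the "other" adjective class
      n_oadj <- round(0.1 * n_fill)
      fill_tokens <- c(sample(pools$oadj, n_oadj, replace = TRUE),
                       sample(pools$filler, n_fill - n_oadj, replace = TRUE))
      content <- sample(c(structural, fill_tokens))
      L_final <- length(content)
      stops <- sample(lexicons$stopwords,
                      round(spec$stopword_rate * L_final), replace = TRUE)
      text_tokens <- sample(c(content, stops))
      notes[[i]] <- tibble::tibble(
        id = sprintf("note%04d", i),
        stage = stage[i],
        text = paste0(paste(text_tokens, collapse = " "), "."),
        flag_body_image = context_to_flag(body_ctx[i]),
        flag_self_esteem = context_to_flag(se_ctx[i]),
        flag_pain = pain[i],
        flag_sentiment = sentiment[i]
      )
      truth[[i]] <- tibble::tibble(
        id = sprintf("note%04d", i),
        stage = stage[i],
        sentiment = sentiment[i],
        dominant_emotion = dominant[i],
        body_image = body_ctx[i],
        self_esteem = se_ctx[i],
        pain = pain[i],
        note_length = L_final,
        n_emotion_words = n_emo,
        n_dominant_words = n_dom,
        n_pos_adj = n_pos_adj,
        n_neg_adj = n_neg_adj,
        n_other_adj = n_oadj,
        to_be_past = sum(tb_tense == "past"),
        to_be_present = sum(tb_tense == "present"),
        to_be_future = sum(tb_tense == "future"),
        other_past = sum(ov_tense == "past"),
        other_present = sum(ov_tense == "present"),
        verbs_total = n_tb + n_ov,
        my_count = n_my,
        lexicon_score = if (n_adj > 0) (n_pos_adj - n_neg_adj) / n_adj else 0
      )
    }
    list(notes = dplyr::bind_rows(notes), truth = dplyr::bind_rows(truth))
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_lexicon()],
#' [generate_embeddings()], [generate_topic_dictionaries()] and
#' [generate_corpus()]; optionally writes every artefact to a directory
#' (notes JSONL, lexicon CSVs, vectors in GloVe text format, topic JSONs,
#' stopword list, ground-truth CSV).
#'
#' @param spec a [corpus_spec()].
#' @param dir optional output directory (created if missing).
#' @return a list with `spec`, `lexicons`, `embeddings`, `topics`, `notes`,
#'   `truth`, and (when written) `paths`.
#' @export
generate_study <- function(spec = corpus_spec(), dir = NULL) {
  lexicons <- generate_lexicon(spec)
  embeddings <- generate_embeddings(lexicons, spec)
  topics <- generate_topic_dictionaries(spec)
  corpus <- generate_corpus(lexicons, embeddings, topics, spec)
  out <- list(spec = spec, lexicons = lexicons, embeddings = embeddings,
              topics = topics, notes = corpus$notes, truth = corpus$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      notes = file.path(dir, "notes.jsonl"),
      affective = file.path(dir, "affective_lexicon.csv"),
      polarity = file.path(dir, "polarity_lexicon.csv"),
      tags = file.path(dir, "tag_lexicon.csv"),
      vectors = file.path(dir, "vectors.txt"),
      body_image = file.path(dir, "topic_body_image.json"),
      self_esteem = file.path(dir, "topic_self_esteem.json"),
      pain = file.path(dir, "topic_pain.json"),
      stopwords = file.path(dir, "stopwords.txt"),
      truth = file.path(dir, "truth.csv")
    )
    write_notes(out$notes, paths$notes)
    write_affective_lexicon(lexicons$affective, paths$affective)
    write_polarity_lexicon(lexicons$polarity, paths$polarity)
    write_tag_lexicon(lexicons$tags, paths$tags)
    write_embeddings(embeddings, paths$vectors)
    write_topic_dictionary(topics$body_image, paths$body_image)
    write_topic_dictionary(topics$self_esteem, paths$self_esteem)
    write_topic_dictionary(topics$pain, paths$pain)
    writeLines(lexicons$stopwords, paths$stopwords)
    readr::write_csv(out$truth, paths$truth, progress = FALSE)
    out$paths <- paths
  }
  out
}

#' Generate a labelled corpus for sentiment-classifier training
#'
#' A linearly separable toy problem: two word clusters (positive and
#' negative) in embedding space; each note draws a share `purity` of its
#' tokens from its own class's cluster and the rest from the other. Labels
#' are balanced by quota.
#'
#' @param n number of notes.
#' @param embedding_dim embedding dimension.
#' @param separation distance between the two cluster centres (sigma = 1).
#' @param length_range note length range.
#' @param vocab_per_class words per polarity cluster.
#' @param purity own-cluster token share.
#' @param seed RNG seed.
#' @return a list with `notes` (preprocessed tibble with `sentiment` labels
#'   in \{-1, +1\}) and `embeddings`.
#' @export
generate_sentiment_corpus <- function(n = 200L, embedding_dim = 10L,
                                      separation = 6, length_range = c(8L, 30L),
                                      vocab_per_class = 40L, purity = 0.85,
                                      seed = 1L) {
  withr::with_seed(as.integer(seed), {
    words_pos <- sprintf("pw%03d", seq_len(vocab_per_class))
    words_neg <- sprintf("nw%03d", seq_len(vocab_per_class))
    center <- c(separation / 2, rep(0, embedding_dim - 1))
    emb <- rbind(
      matrix(rnorm(vocab_per_class * embedding_dim), vocab_per_class) +
        rep(center, each = vocab_per_class),
      matrix(rnorm(vocab_per_class * embedding_dim), vocab_per_class) -
        rep(center, each = vocab_per_class)
    )
    rownames(emb) <- c(words_pos, words_neg)
    label <- as.integer(quota_assign(n, c(`1` = 0.5, `-1` = 0.5)))
    lens <- if (length_range[1] == length_range[2]) {
      rep(length_range[1], n)
    } else {
      sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    }
    tokens <- lapply(seq_len(n), function(i) {
      own <- if (label[i] == 1L) words_pos else words_neg
      other <- if (label[i] == 1L) words_neg else words_pos
      n_own <- round(purity * lens[i])
      sample(c(sample(own, n_own, replace = TRUE),
               sample(other, lens[i] - n_own, replace = TRUE)))
    })
    notes <- tibble::tibble(
      id = sprintf("s%04d", seq_len(n)),
      stage = "I",
      text = vapply(tokens, paste, character(1), collapse = " "),
      tokens = tokens,
      n_tokens = lengths(tokens),
      sentiment = label
    )
    list(notes = notes, embeddings = emb)
  })
}
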