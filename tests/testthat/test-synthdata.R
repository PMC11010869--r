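test_that("generators are pure functions of (spec, seed)", {
  spec <- small_spec(seed = 9L, n_notes = 15L)
  a <- generate_study(spec)
  b <- generate_study(spec)
  expect_identical(a$notes, b$notes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$lexicons$affective, b$lexicons$affective)
  expect_identical(unclass(a$embeddings), unclass(b$embeddings))

  c_ <- generate_study(small_spec(seed = 10L, n_notes = 15L))
  expect_false(identical(a$notes$text, c_$notes$text))
})

test_that("the synthetic affective lexicon realises its planted structure", {
  spec <- small_spec()
  lex <- generate_lexicon(spec)$affective
  expect_equal(nrow(lex), spec$lexicon_size)
  expect_equal(length(unique(lex$word)), spec$lexicon_size)
  cl_counts <- table(lex$dominant)
  expect_true(all(abs(cl_counts - spec$lexicon_size / 5) <= 1))
  ints <- as.matrix(lex[emotion_labels()])
  expect_true(all(ints >= 0 & ints <= 1))
  # dominant intensity drawn high, off-emotions low -> argmax = cluster
  expect_true(all(apply(ints, 1, max) >= 0.6))
  expect_identical(lex$dominant, dominant_emotion(lex))
})

test_that("categorical plants use exact quota counts", {
  spec <- corpus_spec(n_notes = 200L, pain_prevalence = 0.3,
                      note_length_range = c(20L, 40L), lexicon_size = 50L,
                      oov_words_per_emotion = 5L, embedding_dim = 8L,
                      n_filler_words = 30L, seed = 3L)
  st <- generate_study(spec)
  expect_equal(sum(st$truth$pain), 60L)   # 0.3 * 200 exactly
  expect_equal(as.integer(table(st$truth$stage)[stage_levels()]),
               quota_counts_oracle(200, spec$stage_proportions))
  bi <- table(factor(st$truth$body_image, levels = context_levels()))
  expect_equal(as.integer(bi),
               quota_counts_oracle(
                 200, spec$topic_context_proportions$body_image))
})

test_that("embedding clusters are recoverable at high separation and at
           chance when separation is zero", {
  spec10 <- small_spec()
  lx <- generate_lexicon(spec10)
  emb <- generate_embeddings(lx, spec10)
  centers <- attr(emb, "centers")
  planted <- c(lx$affective$dominant, lx$oov$cluster)
  nearest <- apply(emb, 1, function(v) {
    emotion_labels()[which.min(colSums((t(centers) - v)^2))]
  })
  expect_gte(mean(nearest == planted), 0.99)

  spec0 <- small_spec()
  spec0$cluster_separation <- 0
  emb0 <- generate_embeddings(lx, spec0)
  centers0 <- attr(emb0, "centers")
  nearest0 <- apply(emb0, 1, function(v) {
    d <- colSums((t(centers0) - v)^2)
    emotion_labels()[which(d == min(d))[1]]
  })
  acc0 <- mean(nearest0 == planted)
  expect_lt(abs(acc0 - 0.2), 0.1)   # chance of five
})

test_that("ground truth is internally consistent with the emitted notes", {
  st <- cached_small_study()
  # planted topic-context words are present at the stated ratios
  for (i in seq_len(nrow(st$prep))) {
    tk <- st$prep$tokens[[i]]
    ctx <- st$truth$body_image[i]
    n_neg <- sum(tk %in% st$topics$body_image$negative)
    n_pos <- sum(tk %in% st$topics$body_image$positive)
    if (ctx == "ABSENT") {
      expect_equal(n_neg + n_pos, 0L)
    } else if (ctx == "NEGATIVE") {
      expect_gte(n_neg, 3 * n_pos)
    } else if (ctx == "POSITIVE") {
      expect_gte(n_pos, 3 * n_neg)
    } else {
      expect_equal(n_neg, n_pos)
    }
    # pain words iff the pain flag, dominant-cluster words at least 3
    expect_equal(any(tk %in% st$topics$pain$positive),
                 st$truth$pain[i] == 1L)
    pool <- c(
      st$lexicons$affective$word[
        st$lexicons$affective$dominant == st$truth$dominant_emotion[i]],
      st$lexicons$oov$word[
        st$lexicons$oov$cluster == st$truth$dominant_emotion[i]])
    expect_gte(sum(tk %in% pool), 3)
  }
  # expert flags equal the planted labels
  expect_identical(st$notes$flag_body_image,
                   context_to_flag(st$truth$body_image))
  expect_identical(st$notes$flag_pain, st$truth$pain)
  expect_identical(st$notes$flag_sentiment, st$truth$sentiment)
})

test_that("written study artefacts are loadable and reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- small_spec(seed = 4L, n_notes = 10L)
  st1 <- generate_study(spec, dir = dir1)
  generate_study(spec, dir = dir2)
  for (f in c("notes.jsonl", "affective_lexicon.csv", "vectors.txt",
              "topic_body_image.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  notes <- read_notes(file.path(dir1, "notes.jsonl"))
  expect_identical(notes, st1$notes)
  lex <- read_affective_lexicon(file.path(dir1, "affective_lexicon.csv"))
  expect_equal(lex$word, st1$lexicons$affective$word)
  emb <- read_embeddings(file.path(dir1, "vectors.txt"))
  expect_equal(dim(emb), dim(st1$embeddings))
})

test_that("the sentiment training corpus is balanced and within its length
           range", {
  sc <- generate_sentiment_corpus(n = 60, length_range = c(5L, 12L),
                                  seed = 8)
  expect_equal(sum(sc$notes$sentiment == 1L), 30L)
  expect_true(all(sc$notes$n_tokens >= 5 & sc$notes$n_tokens <= 12))
  expect_true(all(unlist(sc$notes$tokens) %in% rownames(sc$embeddings)))
})
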