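test_that("emotion centres are per-dimension means of the dominant words", {
  # one word per emotion: each centre equals that word's vector
  emb1 <- matrix(rnorm(25), 5, 5,
                 dimnames = list(sprintf("w%d", 1:5), NULL))
  ints <- diag(5) * 0.9
  lex1 <- make_affective(sprintf("w%d", 1:5), ints)
  ctr <- emotion_centers(lex1, emb1)
  for (i in 1:5) {
    expect_equal(unname(ctr[lex1$dominant[i], ]), unname(emb1[i, ]))
  }

  # two sadness words at (0,0,...) and (2,4,...): centre (1,2,...)
  emb2 <- rbind(s1 = c(0, 0, 0, 0, 0), s2 = c(2, 4, 0, 0, 0),
                h = c(1, 1, 1, 1, 1), a = 2:6, d = 3:7, f = 4:8)
  ints2 <- matrix(0.1, 6, 5)
  ints2[1:2, 2] <- 0.9; ints2[3, 1] <- 0.9; ints2[4, 3] <- 0.9
  ints2[5, 4] <- 0.9; ints2[6, 5] <- 0.9
  lex2 <- make_affective(rownames(emb2), ints2)
  ctr2 <- emotion_centers(lex2, emb2)
  expect_equal(unname(ctr2["sadness", ]), c(1, 2, 0, 0, 0))

  # brute-force mean oracle on a random lexicon
  set.seed(51)
  n <- 60
  embr <- matrix(rnorm(n * 8), n, 8, dimnames = list(sprintf("r%02d", 1:n),
                                                     NULL))
  intsr <- matrix(runif(n * 5, 0, 0.3), n, 5)
  cl <- sample(1:5, n, replace = TRUE)
  intsr[cbind(1:n, cl)] <- runif(n, 0.6, 1)
  lexr <- make_affective(rownames(embr), intsr)
  ctrr <- emotion_centers(lexr, embr)
  for (e in seq_along(emotion_labels())) {
    oracle <- colMeans(embr[cl == e, , drop = FALSE])
    expect_equal(unname(ctrr[emotion_labels()[e], ]), oracle,
                 tolerance = 1e-12)
  }

  # an emotion with no embeddable word is a coverage error naming it
  lex_missing <- lexr[lexr$dominant != "fear", ]
  expect_error(emotion_centers(lex_missing, embr), regexp = "fear",
               class = "onconotes_coverage_error")
})

test_that("centre assignment maximises cosine similarity, is scale
           invariant, and rejects zero vectors", {
  set.seed(52)
  centers <- matrix(rnorm(25), 5, 5, dimnames = list(emotion_labels(), NULL))
  expect_identical(assign_word_to_center(centers["fear", ], centers), "fear")
  expect_identical(assign_word_to_center(3 * centers["anger", ], centers),
                   "anger")

  # orthogonal geometry: vector orthogonal to all centres but one
  ortho <- diag(5)
  rownames(ortho) <- emotion_labels()
  v <- c(0, 0, 1, 0, 0)
  expect_identical(assign_word_to_center(v, ortho), "anger")

  expect_error(assign_word_to_center(numeric(5), centers),
               class = "onconotes_zero_vector_error")

  # brute-force cosine oracle on random vectors
  for (i in 1:20) {
    v <- rnorm(5)
    sims <- apply(centers, 1, function(ct)
      sum(v * ct) / sqrt(sum(v^2) * sum(ct^2)))
    expect_identical(assign_word_to_center(v, centers),
                     emotion_labels()[which.max(sims)])
  }
})

test_that("kNN intensities follow the weight formula exactly", {
  # geometry on a line: lexicon words at 0, 1, 3 with known intensities
  emb <- rbind(a = c(0, 0), b = c(1, 0), c = c(3, 0))
  ints <- matrix(0.1, 3, 5)
  ints[, 2] <- c(0.9, 0.8, 0.4)   # sadness column
  lex <- make_affective(rownames(emb), ints)

  # k = 1: exactly the nearest neighbour's intensities
  got1 <- knn_word_intensity(c(0.1, 0), lex, emb, knn_config(k = 1))
  expect_equal(unname(got1[1, ]), unname(as.matrix(lex[1, emotion_labels()])[1, ]))

  # k = 2 at equal distances: symmetric weights -> mean (0.8+0.4)/2
  got2 <- knn_word_intensity(c(2, 0), lex, emb, knn_config(k = 2))
  expect_equal(unname(got2[1, "sadness"]), 0.6, tolerance = 1e-6)

  # k = 2 at distances 1 and 3: weights 0.75/0.25 -> 0.75*0.8 + 0.25*0.4
  got3 <- knn_word_intensity(c(2, 0) * 0 + c(0, 0), lex[2:3, ], emb,
                             knn_config(k = 2))
  expect_equal(unname(got3[1, "sadness"]), 0.75 * 0.8 + 0.25 * 0.4,
               tolerance = 1e-6)

  # fewer embeddable words than k is a parameter error
  expect_error(knn_word_intensity(c(0, 0), lex, emb, knn_config(k = 4)),
               class = "onconotes_parameter_error")
})

test_that("kNN agrees with the exhaustive-scan oracle, uniform weights give
           the plain mean, and ties break lexicographically", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    d <- sample(3:6, 1)
    emb <- matrix(rnorm(n * d), n, d,
                  dimnames = list(sprintf("w%03d", sample.int(999, n)), NULL))
    ints <- matrix(runif(n * 5), n, 5)
    lex <- make_affective(rownames(emb), ints)
    k <- sample(1:8, 1)
    q <- rnorm(d)
    nb <- knn_neighbors(matrix(q, 1), lex, emb, knn_config(k = k))[[1]]
    got <- knn_word_intensity(matrix(q, 1), lex, emb, knn_config(k = k))
    oracle <- knn_oracle(q, lex, emb, k)
    expect_identical(nb$word, oracle$words)
    expect_equal(unname(got[1, ]), unname(oracle$intensity),
                 tolerance = 1e-12)
    gotu <- knn_word_intensity(matrix(q, 1), lex, emb,
                               knn_config(k = k, weight_scheme = "uniform"))
    mean_oracle <- colMeans(as.matrix(
      lex[match(oracle$words, lex$word), emotion_labels()]))
    expect_equal(unname(gotu[1, ]), unname(mean_oracle), tolerance = 1e-12)
  }

  # exact distance ties resolved by word order
  emb <- rbind(zz = c(1, 0), aa = c(-1, 0), mm = c(0, 5))
  lex <- make_affective(rownames(emb), matrix(runif(15), 3, 5))
  nb <- knn_neighbors(c(0, 0), lex, emb, knn_config(k = 1))[[1]]
  expect_identical(nb$word, "aa")
})

test_that("lexicon expansion is a no-op on covered vocabulary, inherits a
           coincident seed word, and never alters seed entries", {
  emb <- rbind(a = c(0, 0), b = c(1, 0), c = c(3, 0), new = c(1, 0))
  ints <- matrix(0.1, 3, 5); ints[, 2] <- c(0.9, 0.8, 0.4)
  lex <- make_affective(c("a", "b", "c"), ints)
  # complete the five emotions so centres exist
  emb5 <- rbind(emb, h = c(0, 1), an = c(0, 2), d = c(0, 3), f = c(0, 4))
  ints5 <- rbind(ints, diag(5)[c(1, 3, 4, 5), ] * 0.9)
  lex5 <- make_affective(c("a", "b", "c", "h", "an", "d", "f"), ints5)

  expect_warning(same <- expand_lexicon(c("a", "b"), lex5, emb5),
                 regexp = "unchanged")
  expect_identical(same, lex5)

  out <- expand_lexicon(c("a", "new"), lex5, emb5, knn_config(k = 1))
  expect_identical(out[seq_len(nrow(lex5)), ], lex5)   # seed untouched
  new_row <- out[out$word == "new", ]
  expect_identical(new_row$source, "expanded")
  # coincident with seed word b -> inherits b's intensities exactly
  expect_equal(as.numeric(new_row[emotion_labels()]),
               as.numeric(lex5[lex5$word == "b", emotion_labels()]))
})

test_that("expansion recovers planted clusters and is byte-for-byte
           deterministic", {
  st <- cached_small_study()
  vocab <- unique(unlist(st$prep$tokens))
  exp1 <- expand_lexicon(vocab, st$lexicons$affective, st$embeddings)
  exp2 <- expand_lexicon(vocab, st$lexicons$affective, st$embeddings)
  expect_identical(exp1, exp2)

  ov <- st$lexicons$oov
  got <- exp1$dominant[match(ov$word, exp1$word)]
  seen <- !is.na(got)
  expect_gte(mean(got[seen] == ov$cluster[seen]), 0.95)
})

test_that("note emotion profiles implement the bounded quotient with the
           literal product form behind a flag", {
  ints <- matrix(0.05, 4, 5)
  ints[1, 2] <- 0.6; ints[2, 2] <- 0.8       # two sadness-dominant words
  ints[3, 1] <- 1;   ints[4, 1] <- 1         # happiness at full intensity
  lex <- make_affective(c("s1", "s2", "h1", "h2"), ints)

  # no covered tokens -> all zeros
  p0 <- note_emotion_profiles(make_notes(list(c("x", "y"))), lex)
  expect_true(all(as.matrix(p0[emotion_labels()]) == 0))

  # L = 10, sadness words 0.6 + 0.8 -> 1.4 / 10 = 0.14
  toks <- c("s1", "s2", sprintf("f%d", 1:8))
  p1 <- note_emotion_profiles(make_notes(list(toks)), lex)
  expect_equal(p1$sadness, 0.14)
  # literal reading multiplies by n_e = 2
  p1l <- note_emotion_profiles(make_notes(list(toks)), lex, literal = TRUE)
  expect_equal(p1l$sadness, 0.28)

  # all tokens dominant-happiness at s = 1 attains the upper bound
  p2 <- note_emotion_profiles(make_notes(list(rep(c("h1", "h2"), 5))), lex)
  expect_equal(p2$happiness, 1)

  expect_error(note_emotion_profiles(make_notes(list(character(0))), lex),
               class = "onconotes_empty_note_error")
})

test_that("profiles stay inside [0, 1] and the planted dominant emotion is
           recovered on the synthetic corpus", {
  st <- cached_small_study()
  vocab <- unique(unlist(st$prep$tokens))
  expanded <- expand_lexicon(vocab, st$lexicons$affective, st$embeddings)
  prof <- note_emotion_profiles(st$prep, expanded)
  pm <- as.matrix(prof[emotion_labels()])
  expect_true(all(pm >= 0 & pm <= 1))
  dom <- emotion_labels()[max.col(pm, ties.method = "first")]
  eligible <- st$truth$n_dominant_words >= 3
  expect_gte(mean(dom[eligible] == st$truth$dominant_emotion[eligible]),
             0.95)
})

test_that("stage profiles are arithmetic means with degenerate cases intact", {
  prof <- tibble::tibble(id = c("a", "b", "c"),
                         happiness = c(0.2, 0.4, 0), sadness = c(0.1, 0.3, 0),
                         anger = 0, disgust = 0, fear = 0)
  notes <- tibble::tibble(id = c("a", "b", "c"),
                          stage = c("I", "I", "II"))
  m <- suppressWarnings(stage_emotion_profiles(prof, notes))
  expect_equal(m$happiness[m$stage == "I"], 0.3)
  expect_equal(m$happiness[m$stage == "II"], 0)   # single note = its profile
  expect_true(all(as.matrix(m[m$stage == "II", emotion_labels()]) == 0))
})
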