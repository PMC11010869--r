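pol <- tibble::tibble(word = c("good", "fine", "nice", "bad", "awful"),
                      polarity = c(1L, 1L, 1L, -1L, -1L))

test_that("lexicon sentiment is the signed fraction of matched tokens", {
  notes <- make_notes(list(
    c("good", "fine", "nice"),                  # all positive -> +1
    c("zz", "yy"),                              # no matches -> 0
    c("good", "fine", "nice", "bad"),           # 3 pos, 1 neg of 4 -> 0.5
    c("awful", "bad", "zz")                     # 0 pos, 2 neg -> -1
  ))
  sc <- lexicon_sentiment(notes, pol)
  expect_equal(sc$lexicon_score, c(1, 0, 0.5, -1))
  expect_equal(sc$n_matched, c(3L, 0L, 4L, 2L))
})

test_that("negating every matched polarity negates the score exactly", {
  set.seed(14)
  for (i in 1:20) {
    toks <- sample(c(pol$word, "zz", "qq"), 12, replace = TRUE)
    notes <- make_notes(list(toks))
    flipped <- dplyr::mutate(pol, polarity = -polarity)
    expect_identical(lexicon_sentiment(notes, flipped)$lexicon_score,
                     -lexicon_sentiment(notes, pol)$lexicon_score)
  }
})

test_that("hybrid combination, neutral band and parameter validation follow
           the contract", {
  notes <- make_notes(list(c("good", "fine", "nice", "bad", "awful")))
  # alpha = 1 reduces to the lexicon score
  r <- hybrid_sentiment(notes, pol, alpha = 1)
  expect_equal(r$combined_score, r$lexicon_score)
  # |combined| <= band -> neutral
  r0 <- hybrid_sentiment(make_notes(list(c("good", "bad"))), pol,
                         neutral_band = 0.1)
  expect_equal(r0$combined_score, 0)
  expect_equal(r0$label, 0L)
  expect_error(hybrid_sentiment(notes, pol, alpha = 1.2),
               class = "onconotes_parameter_error")
})

test_that("the hybrid score is the convex combination of lexicon and model
           routes (0.8 and -0.2 at alpha 0.5 -> 0.3, label +1)", {
  # arithmetic of the combination rule
  combined <- 0.5 * 0.8 + 0.5 * (-0.2)
  expect_equal(combined, 0.3)
  expect_equal(as.integer(sign(combined)) * (abs(combined) > 0.1), 1L)

  # and the code path with a real (cheaply trained) model
  sc <- generate_sentiment_corpus(n = 40, length_range = c(6L, 10L), seed = 2)
  m <- train_sentiment_model(sc$notes, sc$embeddings,
                             sentiment_config(epochs = 2, hidden_size = 4,
                                              seed = 1))
  polarity <- tibble::tibble(word = c("pw001", "nw001"),
                             polarity = c(1L, -1L))
  h <- hybrid_sentiment(sc$notes, polarity, model = m,
                        embeddings = sc$embeddings, alpha = 0.3)
  expect_equal(h$combined_score,
               0.3 * h$lexicon_score + 0.7 * h$model_score)
  expect_true(all(h$label %in% c(-1L, 0L, 1L)))
  expect_true(all(h$label[abs(h$combined_score) <= 0.1] == 0L))
})

test_that("BPTT gradients match numerical differentiation", {
  set.seed(1)
  cfg <- sentiment_config(recurrent_layers = 2, hidden_size = 4)
  P <- onconotes:::rnn_init(3, cfg)
  X <- matrix(rnorm(15), 3, 5)
  g <- onconotes:::rnn_loss_grad(P, X, 1, 2)$grad
  h <- 1e-6
  worst <- 0
  for (nm in names(P)) {
    for (i in seq_along(P[[nm]])) {
      Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + h
      Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - h
      num <- (onconotes:::rnn_loss_grad(Pp, X, 1, 2)$loss -
                onconotes:::rnn_loss_grad(Pm, X, 1, 2)$loss) / (2 * h)
      worst <- max(worst, abs(g[[nm]][i] - num))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the classifier separates a linearly separable corpus, trains
           deterministically, and rejects single-class input", {
  sc <- generate_sentiment_corpus(n = 200, seed = 3)
  cfg <- sentiment_config(seed = 5)
  m <- train_sentiment_model(sc$notes, sc$embeddings, cfg)
  expect_gte(m$train_accuracy, 0.95)
  # loss non-increasing over epoch checkpoints (small tolerance for Adam)
  expect_lte(max(diff(m$loss_history)), 0.05)
  expect_lte(m$loss_history[length(m$loss_history)], m$loss_history[1])

  m2 <- train_sentiment_model(sc$notes, sc$embeddings, cfg)
  expect_identical(predict(m, sc$notes, sc$embeddings),
                   predict(m2, sc$notes, sc$embeddings))

  mono <- dplyr::mutate(sc$notes, sentiment = 1L)
  expect_error(train_sentiment_model(mono, sc$embeddings, cfg),
               class = "onconotes_training_error")

  g <- glance(m)
  expect_equal(g$seed, 5L)
  expect_s3_class(tidy(m), "tbl_df")
})

test_that("label shuffling destroys held-out accuracy (permutation null)", {
  sc <- generate_sentiment_corpus(n = 200, seed = 3)
  shuf <- sc$notes
  withr::with_seed(99, shuf$sentiment <- sample(shuf$sentiment))
  m <- train_sentiment_model(shuf[1:140, ], sc$embeddings,
                             sentiment_config(seed = 5))
  p <- predict(m, shuf[141:200, ], sc$embeddings)
  acc <- mean(sign(p$model_score) == shuf$sentiment[141:200])
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("stage breakdown percentages are exact and sum to 100", {
  notes <- tibble::tibble(id = sprintf("n%d", 1:4),
                          stage = rep("I", 4))
  sent <- tibble::tibble(id = notes$id, label = c(1L, -1L, -1L, 0L))
  b <- suppressWarnings(stage_sentiment_breakdown(sent, notes))
  expect_equal(b$pct_positive, 25)
  expect_equal(b$pct_neutral, 25)
  expect_equal(b$pct_negative, 50)
  expect_equal(b$pct_positive + b$pct_neutral + b$pct_negative, 100,
               tolerance = 0.01)

  all_neg <- dplyr::mutate(sent, label = -1L)
  b2 <- suppressWarnings(stage_sentiment_breakdown(all_neg, notes))
  expect_equal(b2$pct_negative, 100)
})

test_that("planted sentiment labels and per-stage proportions are recovered
           exactly from the synthetic corpus", {
  st <- cached_small_study()
  sent <- hybrid_sentiment(st$prep, st$lexicons$polarity)
  expect_identical(sent$label, st$truth$sentiment)
  expect_equal(sent$lexicon_score,
               st$truth$lexicon_score[match(sent$id, st$truth$id)])
  b <- suppressWarnings(stage_sentiment_breakdown(sent, st$prep))
  for (s in b$stage) {
    planted <- st$truth$sentiment[st$truth$stage == s]
    expect_equal(b$pct_negative[b$stage == s], 100 * mean(planted == -1L))
  }
})
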