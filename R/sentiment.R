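# Three-class note sentiment: a lexicon polarity score, a small recurrent
# (stacked Elman) sequence classifier trained on embedded token streams, and
# the hybrid convex combination of the two with a neutral band.

#' Lexicon-based sentiment score
#'
#' For each note: `(positive matches - negative matches) / matched tokens`,
#' where matches are tokens found in the polarity lexicon; 0 when no token
#' matches. The score lies in \[-1, 1\] and negating every matched entry's
#' polarity negates it exactly.
#'
#' @param notes preprocessed notes tibble.
#' @param polarity polarity lexicon tibble.
#' @return a tibble with columns `id`, `lexicon_score`, `n_matched`.
#' @export
lexicon_sentiment <- function(notes, polarity) {
  assert_preprocessed(notes)
  score_one <- function(tokens) {
    pol <- polarity$polarity[match(tokens, polarity$word)]
    pol <- pol[!is.na(pol)]
    if (length(pol) == 0) return(c(0, 0))
    c((sum(pol == 1L) - sum(pol == -1L)) / length(pol), length(pol))
  }
  sc <- vapply(notes$tokens, score_one, numeric(2))
  tibble::tibble(id = notes$id, lexicon_score = sc[1, ],
                 n_matched = as.integer(sc[2, ]))
}

#' Configuration of the recurrent sentiment classifier
#'
#' A deliberately small stacked Elman recurrent network stands in for the
#' large LSTM used in production settings; depth, width, and training length
#' are all configurable and the seed is recorded in the fitted model.
#'
#' @param recurrent_layers number of stacked recurrent layers (default 2).
#' @param hidden_size hidden state width per layer.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param seed RNG seed governing initialisation and epoch shuffling.
#' @return an object of class `sentiment_config`.
#' @export
sentiment_config <- function(recurrent_layers = 2L, hidden_size = 8L,
                             epochs = 30L, learning_rate = 0.02, seed = 1L) {
  vals <- c(recurrent_layers, hidden_size, epochs, learning_rate, seed)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All sentiment_config fields must be positive.",
          class = "onconotes_parameter_error")
  }
  structure(list(recurrent_layers = as.integer(recurrent_layers),
                 hidden_size = as.integer(hidden_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "sentiment_config")
}

# ---- internal recurrent network ------------------------------------------

rnn_init <- function(dim, config) {
  L <- config$recurrent_layers
  h <- config$hidden_size
  P <- list()
  for (l in seq_len(L)) {
    nin <- if (l == 1) dim else h
    rW <- sqrt(6 / (nin + h))
    P[[paste0("W", l)]] <- matrix(runif(h * nin, -rW, rW), h, nin)
    rU <- sqrt(6 / (2 * h))
    P[[paste0("U", l)]] <- matrix(runif(h * h, -rU, rU), h, h)
    P[[paste0("b", l)]] <- numeric(h)
  }
  P$wo <- runif(h, -0.5, 0.5)
  P$bo <- 0
  P
}

rnn_forward <- function(P, X, L) {
  Tn <- ncol(X)
  h <- length(P$wo)
  H <- vector("list", L)
  inp <- X
  for (l in seq_len(L)) {
    W <- P[[paste0("W", l)]]; U <- P[[paste0("U", l)]]; b <- P[[paste0("b", l)]]
    Hl <- matrix(0, h, Tn)
    hp <- numeric(h)
    for (t in seq_len(Tn)) {
      hp <- tanh(W %*% inp[, t] + U %*% hp + b)[, 1]
      Hl[, t] <- hp
    }
    H[[l]] <- Hl
    inp <- Hl
  }
  logit <- sum(P$wo * H[[L]][, Tn]) + P$bo
  yhat <- 1 / (1 + exp(-logit))
  list(H = H, yhat = yhat)
}

rnn_loss_grad <- function(P, X, y, L) {
  fw <- rnn_forward(P, X, L)
  H <- fw$H
  Tn <- ncol(X)
  h <- length(P$wo)
  eps <- 1e-12
  loss <- -(y * log(fw$yhat + eps) + (1 - y) * log(1 - fw$yhat + eps))
  G <- lapply(P, function(p) p * 0)
  d_out <- fw$yhat - y
  G$wo <- H[[L]][, Tn] * d_out
  G$bo <- d_out
  dH <- lapply(H, function(m) m * 0)
  dH[[L]][, Tn] <- dH[[L]][, Tn] + P$wo * d_out
  for (l in rev(seq_len(L))) {
    W <- P[[paste0("W", l)]]; U <- P[[paste0("U", l)]]
    inp <- if (l == 1) X else H[[l - 1]]
    dh_carry <- numeric(h)
    for (t in rev(seq_len(Tn))) {
      dh <- dH[[l]][, t] + dh_carry
      dz <- dh * (1 - H[[l]][, t]^2)
      G[[paste0("W", l)]] <- G[[paste0("W", l)]] + dz %o% inp[, t]
      if (t > 1) {
        G[[paste0("U", l)]] <- G[[paste0("U", l)]] + dz %o% H[[l]][, t - 1]
      }
      G[[paste0("b", l)]] <- G[[paste0("b", l)]] + dz
      dh_carry <- drop(crossprod(U, dz))
      if (l > 1) dH[[l - 1]][, t] <- dH[[l - 1]][, t] + drop(crossprod(W, dz))
    }
  }
  list(loss = loss, grad = G)
}

clip_grads <- function(G, max_norm = 5) {
  nrm <- sqrt(sum(vapply(G, function(g) sum(g^2), numeric(1))))
  if (nrm > max_norm) G <- lapply(G, function(g) g * (max_norm / nrm))
  G
}

#' Train the recurrent sentiment classifier
#'
#' Fits a small stacked Elman recurrent network (tanh units, sigmoid output
#' on the final hidden state, Adam optimiser, backpropagation through time)
#' on notes with binary sentiment labels in \{-1, +1\}. Each note is
#' represented by the sequence of embeddings of its in-vocabulary tokens.
#' Training is deterministic given `config$seed`.
#'
#' @param notes preprocessed notes tibble carrying the label column.
#' @param embeddings embedding matrix (words as rownames).
#' @param config a [sentiment_config()].
#' @param label_col name of the label column (values in \{-1, +1\}).
#' @return an object of class `sentiment_model` with the fitted weights, the
#'   config (seed included), per-epoch `loss_history`, and training accuracy.
#' @seealso [predict.sentiment_model()], [hybrid_sentiment()]
#' @export
train_sentiment_model <- function(notes, embeddings,
                                  config = sentiment_config(),
                                  label_col = "sentiment") {
  assert_preprocessed(notes)
  assert_embeddings(embeddings)
  stopifnot(inherits(config, "sentiment_config"))
  if (!label_col %in% names(notes)) {
    abort(paste0("Label column `", label_col, "` not found."),
          class = "onconotes_input_error")
  }
  labels <- notes[[label_col]]
  if (!all(labels %in% c(-1, 1))) {
    abort("Training labels must be -1 or +1 (neutral is produced by the band).",
          class = "onconotes_training_error")
  }
  if (length(unique(labels)) < 2) {
    abort("Training corpus contains a single class.",
          class = "onconotes_training_error")
  }
  seqs <- lapply(notes$tokens, function(tk) t(embed_tokens(tk, embeddings)))
  empty <- vapply(seqs, ncol, integer(1)) == 0
  if (any(empty)) {
    abort(paste0("Note(s) with no embeddable tokens: ",
                 paste(head(notes$id[empty], 5), collapse = ", ")),
          class = "onconotes_training_error")
  }
  y <- as.integer(labels == 1)
  n <- length(seqs)
  L <- config$recurrent_layers
  lr <- config$learning_rate
  loss_history <- numeric(config$epochs)
  P <- NULL
  withr::with_seed(config$seed, {
    P <- rnn_init(ncol(embeddings), config)
    m <- lapply(P, function(p) p * 0)
    v <- lapply(P, function(p) p * 0)
    step <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (i in ord) {
        lg <- rnn_loss_grad(P, seqs[[i]], y[i], L)
        tot <- tot + lg$loss
        G <- clip_grads(lg$grad)
        step <- step + 1
        for (nm in names(P)) {
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * G[[nm]]
          v[[nm]] <- 0.999 * v[[nm]] + 0.001 * G[[nm]]^2
          mh <- m[[nm]] / (1 - 0.9^step)
          vh <- v[[nm]] / (1 - 0.999^step)
          P[[nm]] <- P[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
        }
      }
      loss_history[ep] <- tot / n
    }
  })
  model <- structure(list(params = P, config = config, dim = ncol(embeddings),
                          loss_history = loss_history, n_train = n),
                     class = "sentiment_model")
  preds <- predict(model, notes, embeddings)
  model$train_accuracy <- mean(sign(preds$model_score) == labels)
  model
}

#' Predict sentiment scores from a fitted recurrent classifier
#'
#' @param object a `sentiment_model`.
#' @param notes preprocessed notes tibble.
#' @param embeddings embedding matrix used at training time.
#' @param ... unused.
#' @return a tibble with columns `id` and `model_score` in (-1, 1). Notes
#'   with no embeddable tokens receive a score of 0.
#' @export
predict.sentiment_model <- function(object, notes, embeddings, ...) {
  assert_preprocessed(notes)
  assert_embeddings(embeddings)
  L <- object$config$recurrent_layers
  scores <- vapply(notes$tokens, function(tk) {
    X <- t(embed_tokens(tk, embeddings))
    if (ncol(X) == 0) return(0)
    2 * rnn_forward(object$params, X, L)$yhat - 1
  }, numeric(1))
  tibble::tibble(id = notes$id, model_score = scores)
}

#' @export
print.sentiment_model <- function(x, ...) {
  cat("<sentiment_model> stacked Elman recurrent classifier\n",
      "  layers: ", x$config$recurrent_layers,
      ", hidden: ", x$config$hidden_size,
      ", input dim: ", x$dim, "\n",
      "  epochs: ", x$config$epochs,
      ", final loss: ", signif(x$loss_history[length(x$loss_history)], 4),
      ", train accuracy: ", signif(x$train_accuracy, 4), "\n",
      "  seed: ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sentiment_model <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    rows = vapply(x$params, NROW, integer(1)),
    cols = vapply(x$params, NCOL, integer(1)),
    n_values = vapply(x$params, length, integer(1)),
    l2_norm = vapply(x$params, function(p) sqrt(sum(p^2)), numeric(1))
  )
}

#' @export
glance.sentiment_model <- function(x, ...) {
  tibble::tibble(
    recurrent_layers = x$config$recurrent_layers,
    hidden_size = x$config$hidden_size,
    epochs = x$config$epochs,
    n_train = x$n_train,
    final_loss = x$loss_history[length(x$loss_history)],
    train_accuracy = x$train_accuracy,
    seed = x$config$seed
  )
}

#' Hybrid sentiment of notes
#'
#' Combines the lexicon score and the recurrent classifier score as
#' `combined = alpha * lexicon + (1 - alpha) * model`; when no model is
#' supplied, `alpha` is forced to 1 and the lexicon score stands alone. The
#' three-class label is 0 when `|combined| <= neutral_band` and
#' `sign(combined)` otherwise.
#'
#' @param notes preprocessed notes tibble.
#' @param polarity polarity lexicon tibble.
#' @param model optional fitted `sentiment_model`.
#' @param embeddings embedding matrix (required when `model` is supplied).
#' @param alpha lexicon weight in \[0, 1\] (default 0.5).
#' @param neutral_band half-width of the neutral zone (default 0.1).
#' @return a tibble with columns `id`, `lexicon_score`, `model_score`
#'   (`NA` without a model), `combined_score`, `label`.
#' @export
hybrid_sentiment <- function(notes, polarity, model = NULL, embeddings = NULL,
                             alpha = 0.5, neutral_band = 0.1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single value in [0, 1].",
          class = "onconotes_parameter_error")
  }
  if (!is.numeric(neutral_band) || neutral_band < 0) {
    abort("`neutral_band` must be non-negative.",
          class = "onconotes_parameter_error")
  }
  lex <- lexicon_sentiment(notes, polarity)
  if (is.null(model)) {
    alpha <- 1
    model_score <- rep(NA_real_, nrow(lex))
    combined <- lex$lexicon_score
  } else {
    if (is.null(embeddings)) {
      abort("`embeddings` required when a model is supplied.",
            class = "onconotes_parameter_error")
    }
    model_score <- predict(model, notes, embeddings)$model_score
    combined <- alpha * lex$lexicon_score + (1 - alpha) * model_score
  }
  label <- ifelse(abs(combined) <= neutral_band, 0L, as.integer(sign(combined)))
  tibble::tibble(id = lex$id, lexicon_score = lex$lexicon_score,
                 model_score = model_score, combined_score = combined,
                 label = label)
}

#' Sentiment breakdown by treatment stage
#'
#' Percentage of positive (+1), neutral (0) and negative (-1) notes within
#' each treatment stage. Percentages sum to 100 per stage; empty stages are
#' omitted with a warning.
#'
#' @param sentiment tibble with `id` and `label` (see [hybrid_sentiment()]).
#' @param notes notes tibble supplying the `stage` of each id.
#' @return a tibble with columns `stage`, `n`, `pct_positive`, `pct_neutral`,
#'   `pct_negative`.
#' @export
stage_sentiment_breakdown <- function(sentiment, notes) {
  df <- dplyr::inner_join(sentiment, notes[c("id", "stage")], by = "id")
  warn_empty_stages(df$stage)
  df |>
    dplyr::mutate(stage = factor(.data$stage, levels = stage_levels())) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_positive = 100 * mean(.data$label == 1L),
      pct_neutral = 100 * mean(.data$label == 0L),
      pct_negative = 100 * mean(.data$label == -1L),
      .groups = "drop"
    ) |>
    dplyr::mutate(stage = as.character(.data$stage))
}
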