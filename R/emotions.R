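# Five-emotion measurement: emotion centres from the affective lexicon,
# cosine assignment of out-of-lexicon words, kNN intensity estimation with
# distance-based weights, lexicon expansion over the corpus vocabulary, and
# note-level emotion profiles.

#' Configuration of kNN intensity estimation
#'
#' @param k number of nearest lexicon neighbours (Euclidean distance).
#' @param weight_scheme `inverse_distance` (default): weights proportional
#'   to `1 / (distance + epsilon)`, normalised to sum to 1 so the weighted
#'   intensity stays inside \[0, 1\]; or `uniform`: the plain mean.
#' @param epsilon small positive guard against zero distances.
#' @return an object of class `knn_config`.
#' @export
knn_config <- function(k = 5L, weight_scheme = c("inverse_distance", "uniform"),
                       epsilon = 1e-9) {
  weight_scheme <- match.arg(weight_scheme)
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort("`k` must be a positive integer.", class = "onconotes_parameter_error")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    abort("`epsilon` must be positive.", class = "onconotes_parameter_error")
  }
  structure(list(k = as.integer(k), weight_scheme = weight_scheme,
                 epsilon = epsilon),
            class = "knn_config")
}

#' Emotion centres of an affective lexicon
#'
#' The centre of each emotion is the per-dimension arithmetic mean of the
#' embeddings of all lexicon words whose dominant emotion is that label.
#' Every emotion must be represented by at least one embeddable word.
#'
#' @param lexicon affective lexicon tibble (with `dominant` column, see
#'   [read_affective_lexicon()]).
#' @param embeddings embedding matrix (words as rownames).
#' @return a 5 x d numeric matrix with emotion labels as rownames.
#' @export
emotion_centers <- function(lexicon, embeddings) {
  assert_embeddings(embeddings)
  if (!"dominant" %in% names(lexicon)) {
    lexicon$dominant <- dominant_emotion(lexicon)
  }
  lex <- lexicon[lexicon$word %in% rownames(embeddings) &
                   lexicon$dominant %in% emotion_labels(), ]
  centers <- matrix(NA_real_, nrow = 5, ncol = ncol(embeddings),
                    dimnames = list(emotion_labels(), NULL))
  for (e in emotion_labels()) {
    words <- lex$word[lex$dominant == e]
    if (length(words) == 0) {
      abort(paste0("No embeddable lexicon word with dominant emotion '", e,
                   "'."),
            class = "onconotes_coverage_error")
    }
    centers[e, ] <- colMeans(embeddings[words, , drop = FALSE])
  }
  centers
}

#' Assign word vectors to the most similar emotion centre
#'
#' Cosine similarity between each vector and the five emotion centres; the
#' label of the maximal similarity wins, ties broken by the canonical label
#' order. Cosine is scale-invariant, so any positive rescaling of a vector
#' keeps its assignment. Zero vectors have no direction and are an error
#' (callers skip them upstream with a warning). A zero centre contributes
#' similarity 0.
#'
#' @param vectors a numeric matrix (one vector per row) or a single vector.
#' @param centers emotion-centre matrix (see [emotion_centers()]).
#' @return character vector of emotion labels, one per input vector.
#' @export
assign_word_to_center <- function(vectors, centers) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  nv <- sqrt(rowSums(vectors^2))
  if (any(nv == 0)) {
    abort("Zero vector has undefined direction; cannot assign an emotion.",
          class = "onconotes_zero_vector_error")
  }
  nc <- sqrt(rowSums(centers^2))
  sims <- vectors %*% t(centers)
  sims <- sims / nv
  sims <- sweep(sims, 2, ifelse(nc == 0, Inf, nc), "/")  # zero centre -> 0
  sims[, nc == 0] <- 0
  colnames(sims) <- rownames(centers)
  emotion_labels()[max.col(sims[, emotion_labels(), drop = FALSE],
                           ties.method = "first")]
}

# embeddable subset of the lexicon, with its embedding rows
lexicon_embeddable <- function(lexicon, embeddings) {
  words <- lexicon$word[lexicon$word %in% rownames(embeddings)]
  list(lexicon = lexicon[match(words, lexicon$word), , drop = FALSE],
       mat = embeddings[words, , drop = FALSE])
}

#' Nearest lexicon neighbours of word vectors
#'
#' The k Euclidean-nearest embeddable lexicon words for each query vector,
#' with distances. Ties at the k-th distance are broken by lexicographic
#' word order (C locale), making the neighbour set deterministic.
#'
#' @param vectors query vectors (matrix, one per row, rownames optional).
#' @param lexicon affective lexicon tibble.
#' @param embeddings embedding matrix.
#' @param config a [knn_config()].
#' @return a list (one element per query) of tibbles with columns `word`,
#'   `distance`, ordered nearest first.
#' @export
knn_neighbors <- function(vectors, lexicon, embeddings, config = knn_config()) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  le <- lexicon_embeddable(lexicon, embeddings)
  if (nrow(le$mat) < config$k) {
    abort(paste0("Only ", nrow(le$mat), " embeddable lexicon words; k = ",
                 config$k, " not satisfiable."),
          class = "onconotes_parameter_error")
  }
  d2 <- outer(rowSums(vectors^2), rowSums(le$mat^2), "+") -
    2 * vectors %*% t(le$mat)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  words <- le$lexicon$word
  lapply(seq_len(nrow(vectors)), function(i) {
    ord <- order(dmat[i, ], words, method = "radix")[seq_len(config$k)]
    tibble::tibble(word = words[ord], distance = dmat[i, ord])
  })
}

#' kNN emotion intensities of word vectors
#'
#' For each query vector, the weighted combination of the emotion
#' intensities of its k nearest lexicon words:
#' `intensity_e = sum_k s_k(e) * w_k`, where `s_k(e)` is neighbour k's
#' intensity for emotion e and the weights `w_k` are normalised inverse
#' distances (`1 / (d_k + epsilon)`, summing to 1) or uniform (`1/k`).
#' With normalised weights every intensity stays inside \[0, 1\]; with
#' `k = 1` the output equals the nearest neighbour's intensities exactly.
#'
#' @inheritParams knn_neighbors
#' @return a numeric matrix, one row per query, columns the five emotions.
#' @export
knn_word_intensity <- function(vectors, lexicon, embeddings,
                               config = knn_config()) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  nb <- knn_neighbors(vectors, lexicon, embeddings, config)
  labs <- emotion_labels()
  smat <- as.matrix(lexicon[labs])
  rownames(smat) <- lexicon$word
  out <- t(vapply(nb, function(tb) {
    w <- if (config$weight_scheme == "uniform") {
      rep(1 / nrow(tb), nrow(tb))
    } else {
      raw <- 1 / (tb$distance + config$epsilon)
      raw / sum(raw)
    }
    drop(w %*% smat[tb$word, , drop = FALSE])
  }, numeric(5)))
  colnames(out) <- labs
  rownames(out) <- rownames(vectors)
  out
}

#' Expand an affective lexicon over a corpus vocabulary
#'
#' Every embeddable corpus stem absent from the seed lexicon gains an entry:
#' its dominant emotion comes from the nearest emotion centre (cosine), its
#' intensities from the kNN weighted combination of its nearest lexicon
#' words, its polarity is 0, and its `source` is `"expanded"`. Seed entries
#' are never modified. Words with a zero embedding vector are skipped with a
#' warning (their direction is undefined); if no out-of-lexicon word is
#' embeddable, the seed lexicon is returned unchanged with a warning. The
#' expansion is a pure function of its inputs.
#'
#' @param vocabulary character vector of corpus stems.
#' @param lexicon seed affective lexicon tibble.
#' @param embeddings embedding matrix.
#' @param config a [knn_config()].
#' @return the expanded affective lexicon tibble (seed rows first, expanded
#'   rows in lexicographic word order).
#' @export
expand_lexicon <- function(vocabulary, lexicon, embeddings,
                           config = knn_config()) {
  assert_embeddings(embeddings)
  oov <- setdiff(unique(vocabulary), lexicon$word)
  oov <- sort(oov[oov %in% rownames(embeddings)], method = "radix")
  if (length(oov) > 0) {
    vecs <- embeddings[oov, , drop = FALSE]
    zero <- rowSums(vecs^2) == 0
    if (any(zero)) {
      warn(paste0("Skipping ", sum(zero),
                  " word(s) with zero embedding vectors."))
      oov <- oov[!zero]
      vecs <- vecs[!zero, , drop = FALSE]
    }
  }
  if (length(oov) == 0) {
    warn("No embeddable out-of-lexicon words; lexicon returned unchanged.")
    return(lexicon)
  }
  centers <- emotion_centers(lexicon, embeddings)
  dominant <- assign_word_to_center(vecs, centers)
  intens <- knn_word_intensity(vecs, lexicon, embeddings, config)
  new <- tibble::tibble(word = oov, polarity = 0L)
  for (e in emotion_labels()) new[[e]] <- unname(intens[, e])
  new$source <- "expanded"
  new$dominant <- dominant
  dplyr::bind_rows(lexicon, new)
}

#' Note-level emotion profiles
#'
#' For each note of length L (post-preprocessing token count) and each
#' emotion e, let `D_e` be the note's tokens whose lexicon dominant emotion
#' is e. The profile intensity is `sum of s_w(e) over D_e, divided by L`
#' (each token contributes its own dominant-emotion intensity), which is 0
#' when no token carries the emotion and reaches 1 only when every token is
#' dominated by e at full intensity. Values are defensively clamped to
#' \[0, 1\]. The literal product form `(sum s) * n_e / L`, which can exceed
#' 1, is available for comparison via `literal = TRUE`.
#'
#' @param notes preprocessed notes tibble; every note must have L > 0.
#' @param lexicon (expanded) affective lexicon tibble with a `dominant`
#'   column.
#' @param literal use the unbounded product form (then clamped).
#' @return a tibble with columns `id` and the five emotions.
#' @export
note_emotion_profiles <- function(notes, lexicon, literal = FALSE) {
  assert_preprocessed(notes)
  if (!"dominant" %in% names(lexicon)) {
    lexicon$dominant <- dominant_emotion(lexicon)
  }
  zero <- lengths(notes$tokens) == 0
  if (any(zero)) {
    abort(paste0("Emotion profile undefined for empty note(s): ",
                 paste(head(notes$id[zero], 5), collapse = ", ")),
          class = "onconotes_empty_note_error")
  }
  labs <- emotion_labels()
  smat <- as.matrix(lexicon[labs])
  prof <- t(vapply(notes$tokens, function(tk) {
    L <- length(tk)
    idx <- match(tk, lexicon$word)
    hit <- !is.na(idx)
    out <- setNames(numeric(5), labs)
    if (any(hit)) {
      dom <- lexicon$dominant[idx[hit]]
      keep <- dom %in% labs
      dom <- dom[keep]
      rows <- idx[hit][keep]
      if (length(rows) > 0) {
        s_own <- smat[cbind(rows, match(dom, labs))]
        sums <- tapply(s_own, factor(dom, levels = labs), sum, default = 0)
        out[labs] <- as.numeric(sums) / L
        if (literal) {
          n_e <- tabulate(factor(dom, levels = labs), nbins = 5)
          out[labs] <- out[labs] * n_e
        }
      }
    }
    pmin(pmax(out, 0), 1)
  }, numeric(5)))
  colnames(prof) <- labs
  dplyr::bind_cols(tibble::tibble(id = notes$id), tibble::as_tibble(prof))
}

#' Mean emotion profiles by treatment stage
#'
#' Arithmetic mean of each emotion intensity within each stage; empty
#' stages are omitted with a warning.
#'
#' @param profiles output of [note_emotion_profiles()].
#' @param notes notes tibble supplying the `stage` of each id.
#' @return a tibble with `stage`, `n`, and the five mean intensities.
#' @export
stage_emotion_profiles <- function(profiles, notes) {
  df <- dplyr::inner_join(profiles, notes[c("id", "stage")], by = "id")
  warn_empty_stages(df$stage)
  df |>
    dplyr::mutate(stage = factor(.data$stage, levels = stage_levels())) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(emotion_labels()), mean),
                     .groups = "drop") |>
    dplyr::mutate(stage = as.character(.data$stage))
}
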