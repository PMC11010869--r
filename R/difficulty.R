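# Area-of-difficulty identification: bag-of-words term-document matrix,
# latent semantic analysis via truncated SVD, positive/negative topic
# affiliation in the reduced space, the four-outcome 20% relative-difference
# rule, and dictionary-based pain detection.

#' Term-document frequency matrix
#'
#' Bag-of-words counts over a preprocessed corpus: rows are terms (sorted
#' lexicographically, C locale), columns are documents in corpus order, and
#' entry (i, j) is the number of occurrences of term i in note j.
#'
#' @param notes preprocessed notes tibble; at least one note must have a
#'   token.
#' @return an integer matrix with terms as rownames and note ids as colnames.
#' @export
term_document_matrix <- function(notes) {
  assert_preprocessed(notes)
  if (all(lengths(notes$tokens) == 0)) {
    abort("All notes are empty; cannot build a term-document matrix.",
          class = "onconotes_empty_matrix_error")
  }
  terms <- sort(unique(unlist(notes$tokens)), method = "radix")
  mat <- matrix(0L, nrow = length(terms), ncol = nrow(notes),
                dimnames = list(terms, notes$id))
  for (j in seq_len(nrow(notes))) {
    tb <- table(notes$tokens[[j]])
    if (length(tb) > 0) {
      mat[match(names(tb), terms), j] <- as.integer(tb)
    }
  }
  mat
}

weight_tdm <- function(mat, weighting, idf = NULL) {
  switch(weighting,
    raw = mat * 1.0,
    log = log1p(mat),
    tfidf = {
      if (is.null(idf)) {
        df <- rowSums(mat > 0)
        idf <- log(ncol(mat) / pmax(df, 1))
      }
      mat * idf
    }
  )
}

#' Fit a latent semantic analysis space
#'
#' Truncated singular value decomposition of the (optionally weighted)
#' term-document matrix. The retained term coordinates are `U_r * D_r`
#' (rows of `u` scaled by the singular values) and new documents are folded
#' in by projecting their weighted count vector onto `U_r`. The squared
#' Frobenius reconstruction error at rank r equals the energy of the
#' discarded singular values.
#'
#' @param tdm term-document matrix (see [term_document_matrix()]).
#' @param rank number of retained dimensions; default
#'   `min(50, min(dim(tdm)) - 1)` (but at least 1).
#' @param weighting count weighting before the SVD: `raw` counts (default),
#'   `log` (`log(1 + count)`), or `tfidf`.
#' @return an object of class `lsa_space` with elements `u`, `d` (retained
#'   singular values), `v`, `singular_values` (all of them, non-increasing),
#'   `rank`, `terms`, `weighting`, `idf`.
#' @export
fit_lsa <- function(tdm, rank = NULL, weighting = c("raw", "log", "tfidf")) {
  weighting <- match.arg(weighting)
  if (!is.matrix(tdm) || is.null(rownames(tdm))) {
    abort("`tdm` must be a matrix with terms as rownames.",
          class = "onconotes_input_error")
  }
  maxr <- min(dim(tdm))
  if (is.null(rank)) rank <- max(1L, min(50L, maxr - 1L))
  if (!is.numeric(rank) || length(rank) != 1 || rank < 1 || rank > maxr) {
    abort(paste0("`rank` must lie in [1, ", maxr, "]."),
          class = "onconotes_parameter_error")
  }
  rank <- as.integer(rank)
  idf <- NULL
  if (weighting == "tfidf") {
    df <- rowSums(tdm > 0)
    idf <- log(ncol(tdm) / pmax(df, 1))
  }
  X <- weight_tdm(tdm, weighting, idf)
  sv <- svd(X)
  structure(list(
    u = sv$u[, seq_len(rank), drop = FALSE],
    d = sv$d[seq_len(rank)],
    v = sv$v[, seq_len(rank), drop = FALSE],
    singular_values = sv$d,
    rank = rank,
    terms = rownames(tdm),
    weighting = weighting,
    idf = idf
  ), class = "lsa_space")
}

#' @export
print.lsa_space <- function(x, ...) {
  cat("<lsa_space> rank ", x$rank, " over ", length(x$terms), " terms (",
      x$weighting, " weighting)\n", sep = "")
  cat("  leading singular values: ",
      paste(signif(head(x$singular_values, 5), 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.lsa_space <- function(x, ...) {
  d <- x$singular_values
  tibble::tibble(
    component = seq_along(d),
    singular_value = d,
    energy_share = d^2 / sum(d^2),
    retained = seq_along(d) <= x$rank
  )
}

#' @export
glance.lsa_space <- function(x, ...) {
  d <- x$singular_values
  tibble::tibble(
    rank = x$rank,
    n_terms = length(x$terms),
    weighting = x$weighting,
    total_energy = sum(d^2),
    retained_energy_share = sum(d[seq_len(x$rank)]^2) / sum(d^2)
  )
}

# project a token multiset into the LSA space (fold-in onto U_r)
project_tokens <- function(tokens, space) {
  q <- numeric(length(space$terms))
  tb <- table(tokens[tokens %in% space$terms])
  if (length(tb) > 0) q[match(names(tb), space$terms)] <- as.numeric(tb)
  if (space$weighting == "log") q <- log1p(q)
  if (space$weighting == "tfidf") q <- q * space$idf
  drop(crossprod(space$u, q))
}

cosine_clip <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  max(0, sum(a * b) / (na * nb))
}

#' Topic affiliation of notes in LSA space
#'
#' For each note, the affiliation to a topic in its negative and positive
#' contexts: the note's theme-related vocabulary (its tokens that belong to
#' the topic dictionary, with multiplicity) is folded into the reduced
#' space, and the affiliation is the cosine similarity (clipped below at
#' zero) between that projection and the centroid of the topic's negative
#' (resp. positive) term vectors. Restricting the query to the theme's own
#' vocabulary keeps the contrast between the two contexts from being washed
#' out by off-topic co-occurrence, while the LSA projection still smooths
#' across related terms. A note sharing no vocabulary with the topic
#' dictionary, or none with the LSA space, has both affiliations exactly
#' 0 — the condition under which the topic is declared absent.
#'
#' @param notes preprocessed notes tibble.
#' @param topic a [topic_dictionary()]. For pain-style single-list topics
#'   use [detect_pain()] instead.
#' @param space a fitted [fit_lsa()] space whose vocabulary contains at
#'   least one term from each of the topic's lists.
#' @return a tibble with columns `id`, `negative`, `positive`,
#'   `relative_difference_pct` (relative difference on the max-denominator
#'   scale, in percent).
#' @export
topic_affiliation <- function(notes, topic, space) {
  assert_preprocessed(notes)
  stopifnot(inherits(topic, "topic_dictionary"), inherits(space, "lsa_space"))
  term_mat <- space$u * space$d[col(space$u)]  # U_r scaled by singular values
  rownames(term_mat) <- space$terms
  centroid <- function(terms) {
    hit <- intersect(terms, space$terms)
    if (length(hit) == 0) {
      abort(paste0("No '", topic$topic, "' dictionary terms present in the ",
                   "LSA vocabulary."),
            class = "onconotes_degenerate_topic_error")
    }
    colMeans(term_mat[hit, , drop = FALSE])
  }
  neg_centroid <- if (length(topic$negative) > 0) centroid(topic$negative) else NULL
  pos_centroid <- centroid(topic$positive)
  all_terms <- topic_terms(topic)
  res <- vapply(notes$tokens, function(tk) {
    tk <- tk[tk %in% all_terms]
    if (length(tk) == 0) return(c(0, 0))
    p <- project_tokens(tk, space)
    if (all(p == 0)) return(c(0, 0))
    neg <- if (is.null(neg_centroid)) 0 else cosine_clip(p, neg_centroid)
    pos <- cosine_clip(p, pos_centroid)
    c(neg, pos)
  }, numeric(2))
  out <- tibble::tibble(id = notes$id, negative = res[1, ], positive = res[2, ])
  out$relative_difference_pct <- relative_difference_pct(out$negative,
                                                         out$positive)
  out
}

#' Relative difference between context affiliations
#'
#' `100 * |negative - positive| / max(negative, positive)` when the maximum
#' is positive, 0 otherwise. The max denominator keeps the quantity total,
#' scale-free, and symmetric in the two contexts.
#'
#' @param negative,positive non-negative affiliation values.
#' @return numeric vector of percentages in \[0, 100\].
#' @export
relative_difference_pct <- function(negative, positive) {
  mx <- pmax(negative, positive)
  ifelse(mx > 0, 100 * abs(negative - positive) / mx, 0)
}

#' Four-outcome topic-context classification
#'
#' Applies the relative-difference rule to each affiliation pair:
#' * `ABSENT` when both affiliations equal 0;
#' * `NEGATIVE` when the negative affiliation exceeds the positive one and
#'   the relative difference is greater than `threshold_pct`;
#' * `POSITIVE` symmetrically;
#' * `MIXED` otherwise (including a relative difference of exactly
#'   `threshold_pct`, since the one-sided rules require strict excess).
#'
#' The rules are total and mutually exclusive, and scaling both affiliations
#' by a positive constant never changes the label.
#'
#' @param affiliation a tibble with `negative` and `positive` columns (see
#'   [topic_affiliation()]); values must be non-negative.
#' @param threshold_pct relative-difference threshold in percent (default 20).
#' @return `affiliation` with `context` (label) and `flag` (expert code:
#'   0 absent, -1 negative, 1 positive, 2 mixed) columns added.
#' @export
classify_topic_context <- function(affiliation, threshold_pct = 20) {
  if (!all(c("negative", "positive") %in% names(affiliation))) {
    abort("`affiliation` needs `negative` and `positive` columns.",
          class = "onconotes_input_error")
  }
  neg <- affiliation$negative
  pos <- affiliation$positive
  if (any(!is.finite(neg)) || any(!is.finite(pos)) ||
      any(neg < 0) || any(pos < 0)) {
    abort("Affiliation values must be finite and non-negative.",
          class = "onconotes_contract_error")
  }
  rd <- relative_difference_pct(neg, pos)
  label <- rep("MIXED", length(neg))
  label[neg == 0 & pos == 0] <- "ABSENT"
  label[neg > pos & rd > threshold_pct] <- "NEGATIVE"
  label[pos > neg & rd > threshold_pct] <- "POSITIVE"
  affiliation$relative_difference_pct <- rd
  affiliation$context <- label
  affiliation$flag <- context_to_flag(label)
  affiliation
}

#' Binary pain detection
#'
#' A note raises the topic of pain if and only if any of its stems belongs
#' to the pain dictionary — plain set membership, fully deterministic.
#'
#' @param notes preprocessed notes tibble.
#' @param pain_dict a [topic_dictionary()] with topic `"pain"`.
#' @return a tibble with columns `id` and `pain` (0/1).
#' @export
detect_pain <- function(notes, pain_dict) {
  assert_preprocessed(notes)
  stopifnot(inherits(pain_dict, "topic_dictionary"))
  if (pain_dict$topic != "pain") {
    abort("`pain_dict` must carry topic 'pain'.",
          class = "onconotes_input_error")
  }
  tibble::tibble(
    id = notes$id,
    pain = vapply(notes$tokens,
                  function(tk) as.integer(any(tk %in% pain_dict$positive)),
                  integer(1))
  )
}
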