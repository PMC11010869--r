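test_that("the term-document matrix holds exact bag-of-words counts", {
  notes <- make_notes(list(c("a", "b", "a"), c("b", "c")))
  tdm <- term_document_matrix(notes)
  expect_identical(rownames(tdm), c("a", "b", "c"))
  expect_equal(unname(tdm["a", ]), c(2L, 0L))
  expect_equal(unname(tdm["b", ]), c(1L, 1L))
  expect_equal(unname(tdm["c", ]), c(0L, 1L))

  single <- make_notes(list(c("x", "y", "x", "z")))
  expect_equal(unname(colSums(term_document_matrix(single))), 4L)

  dup <- make_notes(list(c("a", "b"), c("a", "b")), ids = c("d1", "d2"))
  tdup <- term_document_matrix(dup)
  expect_equal(unname(tdup[, 1]), unname(tdup[, 2]))

  empty <- make_notes(list(character(0)))
  expect_error(term_document_matrix(empty),
               class = "onconotes_empty_matrix_error")
})

test_that("truncated SVD reconstruction error equals the discarded
           singular-value tail energy", {
  set.seed(77)
  # exact decomposition at full rank, and on a rank-1 matrix
  full <- matrix(rpois(50, 3), 10, 5, dimnames = list(letters[1:10], NULL))
  sp <- fit_lsa(full, rank = 5)
  recon <- sp$u %*% diag(sp$d) %*% t(sp$v)
  expect_lt(sqrt(sum((full - recon)^2)), 1e-8)

  r1 <- outer(1:6, c(2, 1, 3)) * 1L
  rownames(r1) <- paste0("t", 1:6)
  sp1 <- fit_lsa(r1, rank = 1)
  expect_lt(sqrt(sum((r1 - sp1$u %*% (sp1$d * t(sp1$v)))^2)), 1e-8)

  # random 20 x 10 matrices vs the dense-SVD oracle tail identity
  for (i in 1:5) {
    X <- matrix(rpois(200, 2), 20, 10, dimnames = list(sprintf("t%02d", 1:20),
                                                       NULL))
    r <- sample(1:9, 1)
    sp <- fit_lsa(X, rank = r)
    recon <- sp$u %*% (sp$d * t(sp$v))
    tail_energy <- sum(svd(X)$d[-seq_len(r)]^2)
    expect_equal(sqrt(sum((X - recon)^2)), sqrt(tail_energy),
                 tolerance = 1e-8)
    expect_true(all(diff(sp$singular_values) <= 1e-12))
  }

  expect_error(fit_lsa(full, rank = 11),
               class = "onconotes_parameter_error")
})

test_that("lsa_space broom methods summarise the decomposition", {
  X <- matrix(rpois(50, 3), 10, 5, dimnames = list(letters[1:10], NULL))
  sp <- fit_lsa(X, rank = 3)
  td <- tidy(sp)
  expect_equal(sum(td$energy_share), 1)
  expect_equal(sum(td$retained), 3L)
  expect_equal(glance(sp)$rank, 3L)
})

test_that("the four-outcome rule matches its literal restatement on the
           exhaustive affiliation grid", {
  grid <- expand.grid(negative = seq(0, 1, by = 0.05),
                      positive = seq(0, 1, by = 0.05))
  got <- classify_topic_context(tibble::as_tibble(grid))$context
  want <- mapply(rule_oracle, grid$negative, grid$positive)
  expect_equal(mean(got == want), 1)   # 100% agreement on all 441 pairs
})

test_that("rule boundary and degenerate cases behave as specified", {
  pairs <- tibble::tibble(negative = c(0, 0.5, 0.6, 0.5, 0.4),
                          positive = c(0, 0.5, 0.4, 0.4, 0.5))
  out <- classify_topic_context(pairs)
  expect_identical(out$context,
                   c("ABSENT", "MIXED", "NEGATIVE", "MIXED", "MIXED"))
  # (0.6, 0.4): rel diff 100*|0.2|/0.6 = 33.3% with the max denominator
  expect_equal(out$relative_difference_pct[3], 100 * 0.2 / 0.6)
  # (0.5, 0.4): rel diff exactly 20% -> MIXED (rules require strict excess)
  expect_equal(out$relative_difference_pct[4], 20)
  expect_identical(out$flag, c(0L, 2L, -1L, 2L, 2L))

  expect_error(classify_topic_context(
    tibble::tibble(negative = -0.1, positive = 0.5)),
    class = "onconotes_contract_error")
})

test_that("the label is invariant under joint positive rescaling of the
           affiliations", {
  set.seed(12)
  for (i in 1:50) {
    neg <- runif(1); pos <- runif(1); k <- runif(1, 0.01, 40)
    a <- classify_topic_context(tibble::tibble(negative = neg,
                                               positive = pos))$context
    b <- classify_topic_context(tibble::tibble(negative = k * neg,
                                               positive = k * pos))$context
    expect_identical(a, b)
  }
})

test_that("topic affiliation separates planted contexts and is exactly zero
           without topic vocabulary", {
  st <- cached_small_study()
  sp <- fit_lsa(term_document_matrix(st$prep))
  aff <- topic_affiliation(st$prep, st$topics$body_image, sp)
  tr <- st$truth

  neg_notes <- tr$body_image == "NEGATIVE"
  expect_true(all(aff$negative[neg_notes] > aff$positive[neg_notes]))
  absent <- tr$body_image == "ABSENT"
  expect_true(any(absent))
  expect_true(all(aff$negative[absent] == 0 & aff$positive[absent] == 0))

  # determinism: identical call twice
  expect_identical(aff, topic_affiliation(st$prep, st$topics$body_image, sp))

  bogus <- topic_dictionary("body_image", positive = "neverseenpos",
                            negative = "neverseenneg")
  expect_error(topic_affiliation(st$prep, bogus, sp),
               class = "onconotes_degenerate_topic_error")
})

test_that("pain detection equals set membership on every note", {
  pain <- topic_dictionary("pain", positive = c("ache", "sore"))
  notes <- make_notes(list(c("body", "ache"), c("calm", "word")))
  expect_equal(detect_pain(notes, pain)$pain, c(1L, 0L))

  st <- cached_small_study()
  got <- detect_pain(st$prep, st$topics$pain)$pain
  oracle <- vapply(st$prep$tokens,
                   function(tk) as.integer(any(tk %in% st$topics$pain$positive)),
                   integer(1))
  expect_equal(mean(got == oracle), 1)
  expect_equal(got, st$truth$pain)
})
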