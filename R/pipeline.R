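# End-to-end orchestration: preprocess -> word statistics -> sentiment ->
# areas of difficulty -> emotions -> evaluation, with versioned, rerunnable
# outputs and a manifest recording every effective parameter.

#' Pipeline configuration
#'
#' Paths to every input artefact plus all tunable parameters, fully
#' defaulted. The effective configuration is serialised next to the outputs
#' so every run is auditable.
#'
#' @param notes,affective_lexicon,polarity_lexicon,tag_lexicon,vectors file
#'   paths to the corpus and lexicons.
#' @param topics named list of topic-dictionary JSON paths; must include
#'   `body_image`, `self_esteem`, `pain`.
#' @param out_dir output directory for the run.
#' @param stopwords optional path to a stopword list (one word per line).
#' @param rank LSA rank (`NULL`: automatic, see [fit_lsa()]).
#' @param weighting LSA count weighting (`raw`, `log`, `tfidf`).
#' @param threshold_pct relative-difference threshold for topic contexts.
#' @param alpha,neutral_band hybrid-sentiment parameters.
#' @param knn a [knn_config()] for lexicon expansion.
#' @param agreement_mode `strict` or `mixed_lenient` breakdowns.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed governs optional model training).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(notes, affective_lexicon, polarity_lexicon,
                            tag_lexicon, vectors, topics, out_dir,
                            stopwords = NULL, rank = NULL,
                            weighting = "raw", threshold_pct = 20,
                            alpha = 0.5, neutral_band = 0.1,
                            knn = knn_config(),
                            agreement_mode = "mixed_lenient", seed = 1L) {
  need <- c("body_image", "self_esteem", "pain")
  if (!is.list(topics) || !all(need %in% names(topics))) {
    abort("`topics` must name body_image, self_esteem and pain paths.",
          class = "onconotes_parameter_error")
  }
  structure(list(notes = notes, affective_lexicon = affective_lexicon,
                 polarity_lexicon = polarity_lexicon,
                 tag_lexicon = tag_lexicon, vectors = vectors,
                 topics = topics, out_dir = out_dir, stopwords = stopwords,
                 rank = rank, weighting = weighting,
                 threshold_pct = threshold_pct, alpha = alpha,
                 neutral_band = neutral_band, knn = unclass(knn),
                 agreement_mode = agreement_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                digits = 10, na = "null"), con)
  }
  invisible(path)
}

#' Run the full screening pipeline
#'
#' Reads every input, preprocesses the corpus, and emits into the run
#' directory: `wordstats.csv` (per-note word-class counts and saturations),
#' `sentiment.jsonl`, `difficulty.jsonl` (per note and topic: affiliations,
#' relative difference, context, flag code), `profiles.jsonl` (five-emotion
#' profiles from the expanded lexicon), `expanded_lexicon.csv`,
#' `report.json` (stage summaries plus, when expert flags are present,
#' kappa and agreement breakdowns), `config.json`, and `manifest.json`
#' with content hashes. Rerunning on identical inputs reproduces every
#' output byte-for-byte (the timestamp lives only in the manifest). On any
#' stage failure a `FAILED` marker naming the error is left in the run
#' directory and the error is re-raised.
#'
#' @param config a [pipeline_config()].
#' @param stemmer optional stemming function applied to every artefact.
#' @return (invisibly) a list with every intermediate result and the output
#'   paths.
#' @export
run_pipeline <- function(config, stemmer = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  tryCatch(
    run_pipeline_impl(config, stemmer),
    error = function(e) {
      writeLines(conditionMessage(e), fail_marker)
      abort(paste0("Pipeline failed: ", conditionMessage(e)),
            class = "onconotes_pipeline_error", parent = e)
    }
  )
}

run_pipeline_impl <- function(config, stemmer) {
  out <- config$out_dir
  stopwords <- if (is.null(config$stopwords)) character() else
    readLines(config$stopwords, warn = FALSE)
  notes <- read_notes(config$notes)
  notes <- preprocess_notes(notes, stopwords = stopwords, stemmer = stemmer)
  affective <- read_affective_lexicon(config$affective_lexicon,
                                      stemmer = stemmer)
  polarity <- read_polarity_lexicon(config$polarity_lexicon,
                                    stemmer = stemmer)
  tags <- read_tag_lexicon(config$tag_lexicon, stemmer = stemmer)
  embeddings <- read_embeddings(config$vectors)
  topics <- lapply(config$topics, read_topic_dictionary, stemmer = stemmer)

  # word statistics (possessive "my" gated on body-image vocabulary)
  counts <- count_word_classes(notes, tags, polarity,
                               body_terms = topic_terms(topics$body_image))
  nonempty <- notes[lengths(notes$tokens) > 0, , drop = FALSE]
  saturation <- adjective_saturation(
    counts[counts$note_length > 0, , drop = FALSE])
  stage_adj <- stage_adjective_means(saturation)
  readr::write_csv(saturation, file.path(out, "wordstats.csv"),
                   progress = FALSE)

  # sentiment (lexicon route; a trained model can be combined via
  # hybrid_sentiment() outside the standard run)
  sentiment <- hybrid_sentiment(notes, polarity, alpha = config$alpha,
                                neutral_band = config$neutral_band)
  write_jsonl(sentiment, file.path(out, "sentiment.jsonl"))
  stage_sent <- stage_sentiment_breakdown(sentiment, notes)

  # areas of difficulty in a shared LSA space
  tdm <- term_document_matrix(nonempty)
  space <- fit_lsa(tdm, rank = config$rank, weighting = config$weighting)
  difficulty <- dplyr::bind_rows(lapply(c("body_image", "self_esteem"),
    function(tp) {
      aff <- topic_affiliation(nonempty, topics[[tp]], space)
      aff <- classify_topic_context(aff, threshold_pct = config$threshold_pct)
      dplyr::mutate(aff, topic = tp, .after = "id")
    }))
  pain <- detect_pain(notes, topics$pain)
  write_jsonl(difficulty, file.path(out, "difficulty.jsonl"))

  # emotions from the expanded lexicon
  vocab <- unique(unlist(notes$tokens))
  knn <- do.call(knn_config, config$knn)
  expanded <- expand_lexicon(vocab, affective, embeddings, knn)
  write_affective_lexicon(expanded, file.path(out, "expanded_lexicon.csv"))
  profiles <- note_emotion_profiles(nonempty, expanded)
  write_jsonl(profiles, file.path(out, "profiles.jsonl"))
  stage_prof <- stage_emotion_profiles(profiles, notes)

  # evaluation against expert flags, when present
  report <- list(
    n_notes = nrow(notes),
    stage_adjective_means = stage_adj,
    stage_sentiment = stage_sent,
    stage_emotion_profiles = stage_prof
  )
  has_flags <- !all(is.na(notes$flag_body_image)) ||
    !all(is.na(notes$flag_sentiment))
  if (has_flags) {
    for (tp in c("body_image", "self_esteem")) {
      flags <- notes[[paste0("flag_", tp)]]
      d <- difficulty[difficulty$topic == tp, ]
      keep <- !is.na(flags[match(d$id, notes$id)])
      if (any(keep)) {
        d <- d[keep, ]
        expert <- flag_to_context(flags[match(d$id, notes$id)])
        report[[paste0("kappa_", tp)]] <-
          glance(cohens_kappa(d$context, expert))
        report[[paste0("agreement_", tp)]] <- agreement_breakdown(
          tibble::tibble(stage = notes$stage[match(d$id, notes$id)],
                         method = d$context, expert = expert),
          mode = config$agreement_mode)
      }
    }
    keep <- !is.na(notes$flag_sentiment)
    if (any(keep)) {
      lab <- sentiment$label[match(notes$id[keep], sentiment$id)]
      report$kappa_sentiment <-
        glance(cohens_kappa(lab, notes$flag_sentiment[keep]))
    }
    keep <- !is.na(notes$flag_pain)
    if (any(keep)) {
      report$pain_agreement_pct <- 100 *
        mean(pain$pain[match(notes$id[keep], pain$id)] ==
               notes$flag_pain[keep])
      pain_grp <- tibble::tibble(
        id = nonempty$id,
        pain = pain$pain[match(nonempty$id, pain$id)]
      )
      grp <- dplyr::inner_join(profiles, pain_grp, by = "id")
      report$pain_group_means <- group_mean_profiles(grp, pain)
    }
  } else {
    warn("Corpus carries no expert flags; agreement sections omitted.")
  }
  report_path <- file.path(out, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", pretty = TRUE)

  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  outputs <- c("wordstats.csv", "sentiment.jsonl", "difficulty.jsonl",
               "profiles.jsonl", "expanded_lexicon.csv", "report.json",
               "config.json")
  manifest <- list(
    tool = "onconotes",
    version = as.character(utils::packageVersion("onconotes")),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    hashes = as.list(tools::md5sum(file.path(out, outputs)))
  )
  names(manifest$hashes) <- outputs
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = out, outputs = file.path(out, outputs),
                 counts = counts, saturation = saturation,
                 stage_adjective_means = stage_adj, sentiment = sentiment,
                 stage_sentiment = stage_sent, difficulty = difficulty,
                 pain = pain, profiles = profiles,
                 stage_emotion_profiles = stage_prof,
                 expanded_lexicon = expanded, report = report))
}
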