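# one shared small corpus and model for the whole file (training is the
# expensive step; the corpus is regenerated deterministically)
crf_fixture <- local({
  corpus <- gen_corpus(n_docs = 40, seed = 101)
  n <- nrow(corpus$documents)
  idx <- seq_len(round(0.8 * n))
  train_docs <- corpus$documents[idx, , drop = FALSE]
  test_docs <- corpus$documents[-idx, , drop = FALSE]
  model <- train_tagger(
    train_docs,
    corpus$gold[corpus$gold$doc_id %in% train_docs$doc_id, ],
    map = corpus$cluster_map, gazetteers = list(corpus$gazetteer),
    training = training_config(max_iterations = 150L),
    verbose = FALSE
  )
  list(corpus = corpus, model = model, train_docs = train_docs,
       test_docs = test_docs)
})

test_that("training rejects invalid inputs", {
  corpus <- crf_fixture$corpus
  expect_error(
    train_tagger(corpus$documents[1, ],
                 data.frame(doc_id = "nope", section = "A", start = 0L,
                            end = 3L, text = "x", entity_type = NA),
                 verbose = FALSE),
    "unknown document"
  )
  # all annotations misaligned -> zero B labels -> error
  docs <- data.frame(doc_id = "d1", title = "Methanol reacts quickly.",
                     abstract = "")
  bad_ann <- data.frame(doc_id = "d1", section = "T", start = 1L, end = 4L,
                        text = "eth", entity_type = NA)
  expect_error(
    suppressWarnings(train_tagger(docs, bad_ann, verbose = FALSE)),
    "zero aligned B"
  )
  expect_error(train_tagger(docs, bad_ann, config = list(bogus = 1)),
               "feature_config")
  expect_error(training_config(max_iterations = 0), "max_iterations")
})

test_that("the tagger learns the planted chemical vocabulary", {
  fx <- crf_fixture
  gold <- fx$corpus$gold[fx$corpus$gold$doc_id %in% fx$test_docs$doc_id, ]
  pred <- tag_corpus(fx$model, fx$test_docs)
  ev <- evaluate_cem(gold, pred)
  expect_gt(ev$f1, 0.85)
})

test_that("tagged mentions are valid spans with in-range confidences", {
  fx <- crf_fixture
  pred <- tag_corpus(fx$model, fx$test_docs)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
  docs <- fx$test_docs
  text <- ifelse(pred$section == "T",
                 docs$title[match(pred$doc_id, docs$doc_id)],
                 docs$abstract[match(pred$doc_id, docs$doc_id)])
  expect_equal(substring(text, pred$start + 1L, pred$end), pred$text)
  # BIO decoding cannot produce overlapping spans within a section
  by_sec <- split(pred, paste(pred$doc_id, pred$section))
  for (grp in by_sec) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) > 1L) {
      expect_true(all(grp$start[-1L] >= grp$end[-nrow(grp)]))
    }
  }
})

test_that("tagging is deterministic and the empty document yields nothing", {
  fx <- crf_fixture
  d <- fx$test_docs[1, , drop = FALSE]
  expect_identical(tag_document(fx$model, d), tag_document(fx$model, d))
  empty <- tag_document(fx$model,
                        data.frame(doc_id = "e", title = "", abstract = ""))
  expect_equal(nrow(empty), 0L)
  expect_error(tag_document(list(), d), "not a trained")
})

test_that("two trainings with identical inputs give identical predictions", {
  corpus <- gen_corpus(n_docs = 12, seed = 7)
  args <- list(corpus$documents, corpus$gold, map = corpus$cluster_map,
               gazetteers = list(corpus$gazetteer),
               training = training_config(max_iterations = 60L),
               verbose = FALSE)
  m1 <- do.call(train_tagger, args)
  m2 <- do.call(train_tagger, args)
  expect_identical(tag_corpus(m1, corpus$documents),
                   tag_corpus(m2, corpus$documents))
})

test_that("model save/load round-trips predictions exactly", {
  fx <- crf_fixture
  path <- tempfile(fileext = ".rds")
  save_tagger(fx$model, path)
  reloaded <- load_tagger(path)
  expect_identical(tag_corpus(reloaded, fx$test_docs),
                   tag_corpus(fx$model, fx$test_docs))

  truncated <- tempfile()
  writeBin(readBin(path, "raw", n = 50L), truncated)
  expect_error(load_tagger(truncated), "cannot load")
  not_model <- tempfile()
  saveRDS(list(a = 1), not_model)
  expect_error(load_tagger(not_model), "compatible")
})

test_that("the blacklist filter drops exact surface matches only", {
  fx <- crf_fixture
  pred <- tag_corpus(fx$model, fx$test_docs)
  skip_if(nrow(pred) == 0L)
  victim <- pred$text[1]
  filtered <- tag_corpus(fx$model, fx$test_docs, blacklist = victim)
  expect_false(victim %in% filtered$text)
  expect_equal(nrow(filtered), sum(pred$text != victim))
})

test_that("removing a planted signal family does not help the tagger", {
  # directional ablation on a small benchmark: the full feature set
  # must not lose to the no-cluster configuration by more than noise
  f1_of <- function(cfg, seed) {
    corpus <- gen_corpus(n_docs = 30, seed = seed)
    n <- nrow(corpus$documents)
    idx <- seq_len(round(0.8 * n))
    tr <- corpus$documents[idx, ]
    te <- corpus$documents[-idx, ]
    m <- train_tagger(tr, corpus$gold[corpus$gold$doc_id %in% tr$doc_id, ],
                      config = cfg, map = corpus$cluster_map,
                      gazetteers = list(corpus$gazetteer),
                      training = training_config(max_iterations = 80L),
                      verbose = FALSE)
    evaluate_cem(corpus$gold[corpus$gold$doc_id %in% te$doc_id, ],
                 tag_corpus(m, te))$f1
  }
  seeds <- 201:203
  full <- vapply(seeds, function(s) f1_of(feature_config(), s), numeric(1))
  now2v <- vapply(seeds, function(s) {
    f1_of(feature_config(use_word2vec = FALSE), s)
  }, numeric(1))
  expect_gte(mean(full), mean(now2v) - 0.02)
})
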