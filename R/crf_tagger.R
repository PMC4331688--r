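## Training and application of the first-order linear-chain CRF tagger:
## sentence detection -> tokenization -> feature assembly -> L-BFGS
## training / Viterbi decoding -> BIO span decoding with confidences.

.bio_labels <- c("B", "I", "O")
.model_version <- 1L

#' Training configuration for the CRF tagger
#'
#' The model is always a first-order linear chain trained with L-BFGS;
#' `l2_penalty` is the coefficient of the squared-norm penalty on the
#' weights, and `seed` is recorded for reproducibility (optimization
#' starts from zero weights and is deterministic given the data).
#'
#' @param max_iterations Maximum L-BFGS iterations (>= 1).
#' @param l2_penalty Non-negative L2 regularization strength.
#' @param seed Integer seed recorded with the model.
#' @return A list of class `training_config`.
#' @export
training_config <- function(max_iterations = 200L, l2_penalty = 1.0,
                            seed = 1L) {
  if (!is.numeric(max_iterations) || max_iterations < 1) {
    stop("max_iterations must be >= 1")
  }
  if (!is.numeric(l2_penalty) || l2_penalty < 0) {
    stop("l2_penalty must be non-negative")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 l2_penalty = as.numeric(l2_penalty),
                 optimizer = "L-BFGS", seed = as.integer(seed)),
            class = "training_config")
}

section_text <- function(document, section) {
  if (section == "T") document$title else document$abstract
}

## Shared pipeline front end: sentences -> tokens -> features for one
## document section.  Returns a list of per-sentence lists with tokens
## (section offsets) and feature sets.
section_sentences <- function(text, tokenizer, config, map, gazetteers) {
  sents <- split_sentences(text)
  out <- list()
  for (j in seq_len(nrow(sents))) {
    sl <- substr(text, sents$start[j] + 1L, sents$end[j])
    tok <- tokenize(sl, tokenizer)
    if (nrow(tok) == 0L) next
    tok$start <- tok$start + sents$start[j]
    tok$end <- tok$end + sents$start[j]
    feats <- assemble_features(tok, config = config, map = map,
                               gazetteers = gazetteers,
                               sentence_start = TRUE)
    out[[length(out) + 1L]] <- list(tokens = tok, features = feats)
  }
  out
}

#' Train the CRF chemical entity tagger
#'
#' Runs the full pipeline on the training corpus -- sentence detection,
#' tokenization with the chosen tokenizer, BIO labeling against the
#' gold annotations, windowed feature assembly -- and fits a
#' first-order linear-chain CRF by L-BFGS.  Gold mentions that do not
#' align with token boundaries are skipped (and counted); training
#' requires at least one aligned mention.
#'
#' @param documents Data frame as from [read_abstracts()].
#' @param annotations Gold mentions as from [read_annotations()].
#' @param config A [feature_config()].
#' @param training A [training_config()].
#' @param map Optional [cluster_map()] (stored in the model).
#' @param gazetteers List of [gazetteer()] objects (stored in the model).
#' @param tokenizer Tokenizer registry name (stored in the model).
#' @param verbose Emit a training log via `message()`.
#' @return An object of class `chem_tagger`.
#' @export
train_tagger <- function(documents, annotations,
                         config = feature_config(),
                         training = training_config(),
                         map = NULL, gazetteers = list(),
                         tokenizer = "chem", verbose = TRUE) {
  if (!inherits(config, "feature_config")) {
    stop("config must be created with feature_config()")
  }
  if (!inherits(training, "training_config")) {
    stop("training must be created with training_config()")
  }
  unknown <- setdiff(unique(annotations$doc_id), documents$doc_id)
  if (length(unknown) > 0L) {
    stop("annotations refer to unknown document(s): ",
         paste(head(unknown, 3L), collapse = ", "))
  }
  sentences <- list()
  misaligned <- 0L
  for (i in seq_len(nrow(documents))) {
    doc <- documents[i, , drop = FALSE]
    for (section in c("T", "A")) {
      text <- section_text(doc, section)
      ann <- annotations[annotations$doc_id == doc$doc_id &
                           annotations$section == section, , drop = FALSE]
      for (sent in section_sentences(text, tokenizer, config, map,
                                     gazetteers)) {
        labels <- withCallingHandlers(
          label_bio(sent$tokens, ann[ann$start >= min(sent$tokens$start) &
                                       ann$end <= max(sent$tokens$end), ,
                                     drop = FALSE]),
          warning = function(w) invokeRestart("muffleWarning")
        )
        misaligned <- misaligned + attr(labels, "misaligned")
        sentences[[length(sentences) + 1L]] <-
          list(features = sent$features, labels = labels)
      }
    }
  }
  n_b <- sum(vapply(sentences, function(s) sum(s$labels == "B"), integer(1)))
  if (length(sentences) == 0L || n_b == 0L) {
    stop("no usable training sentences: zero aligned B labels")
  }
  all_feats <- unique(unlist(lapply(sentences, `[[`, "features"),
                             use.names = FALSE))
  fit <- crf_fit(sentences, all_feats, training)
  if (verbose) {
    message(sprintf(
      "CRF training: %d sentences, %d features, %d misaligned mention(s), %s",
      length(sentences), length(all_feats), misaligned,
      fit$convergence_note))
  }
  structure(list(theta = fit$theta, feature_index = all_feats,
                 feature_config = config, training_config = training,
                 tokenizer = tokenizer, cluster_map = map,
                 gazetteers = gazetteers, labels = .bio_labels,
                 misaligned = misaligned, n_features = length(all_feats),
                 version = .model_version),
            class = "chem_tagger")
}

## flatten sentences into the index layout the C++ core expects;
## features absent from the index (unseen at training time) are dropped
flatten_sentences <- function(feature_sets_by_sentence, feature_index,
                              labels_by_sentence = NULL) {
  n_tok_per_sent <- vapply(feature_sets_by_sentence, length, integer(1))
  per_token <- unlist(feature_sets_by_sentence, recursive = FALSE,
                      use.names = FALSE)
  n_tok <- length(per_token)
  per_tok_len <- lengths(per_token)
  m <- match(unlist(per_token, use.names = FALSE), feature_index)
  keep <- !is.na(m)
  tok_of <- rep.int(seq_len(n_tok), per_tok_len)
  counts <- tabulate(tok_of[keep], nbins = n_tok)
  labels <- integer()
  if (!is.null(labels_by_sentence)) {
    labels <- match(unlist(labels_by_sentence, use.names = FALSE),
                    .bio_labels) - 1L
  }
  list(feat = as.integer(m[keep] - 1L),
       tok_ptr = as.integer(c(0L, cumsum(counts))),
       sent_ptr = as.integer(c(0L, cumsum(n_tok_per_sent))),
       labels = as.integer(labels))
}

crf_fit <- function(sentences, feature_index, training) {
  flat <- flatten_sentences(lapply(sentences, `[[`, "features"),
                            feature_index,
                            lapply(sentences, `[[`, "labels"))
  L <- length(.bio_labels)
  nf <- length(feature_index)
  np <- nf * L + L * L
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (is.null(cache$par) || !identical(par, cache$par)) {
      r <- crf_nll_grad(par, flat$feat, flat$tok_ptr, flat$sent_ptr,
                        flat$labels, L, nf, training$l2_penalty)
      cache$par <- par
      cache$nll <- r$nll
      cache$grad <- r$grad
    }
    invisible(NULL)
  }
  res <- stats::optim(
    par = rep(0, np),
    fn = function(par) { evaluate(par); cache$nll },
    gr = function(par) { evaluate(par); cache$grad },
    method = "L-BFGS-B",
    control = list(maxit = training$max_iterations, factr = 1e7)
  )
  note <- if (res$convergence == 0L) {
    "converged"
  } else {
    sprintf("stopped (optim code %d)", res$convergence)
  }
  list(theta = res$par, convergence_note = note)
}

#' Tag a document with a trained model
#'
#' Applies the model's full pipeline (sentence detection, the
#' training-time tokenizer and feature configuration, Viterbi decoding,
#' BIO span decoding) to the title and abstract of one document.  The
#' confidence of each mention is the product of the per-token marginal
#' probabilities of its decoded labels.  No post-processing or
#' abbreviation matching is performed; optionally, mentions whose
#' surface matches a blacklist entry exactly are dropped (off by
#' default).
#'
#' @param model A `chem_tagger` from [train_tagger()].
#' @param document One-row data frame with `doc_id`, `title`,
#'   `abstract`.
#' @param blacklist Optional character vector of surface forms to
#'   filter out.
#' @return Data frame of entity mentions with a `confidence` column.
#' @export
tag_document <- function(model, document, blacklist = NULL) {
  if (!inherits(model, "chem_tagger") || is.null(model$theta)) {
    stop("model is not a trained chem_tagger")
  }
  L <- length(model$labels)
  nf <- model$n_features
  out <- list()
  for (section in c("T", "A")) {
    text <- section_text(document, section)
    if (is.na(text) || !nzchar(text)) next
    sents <- section_sentences(text, model$tokenizer, model$feature_config,
                               model$cluster_map, model$gazetteers)
    for (sent in sents) {
      flat <- flatten_sentences(list(sent$features), model$feature_index)
      dec <- crf_decode(model$theta, flat$feat, flat$tok_ptr, flat$sent_ptr,
                        L, nf)
      labels <- model$labels[dec$path + 1L]
      mentions <- decode_bio(sent$tokens, labels, text = text,
                             doc_id = document$doc_id, section = section)
      if (nrow(mentions) == 0L) next
      ## per-entity confidence: product of decoded-label marginals
      conf <- numeric(nrow(mentions))
      run_start <- match(mentions$start, sent$tokens$start)
      run_end <- match(mentions$end, sent$tokens$end)
      for (k in seq_len(nrow(mentions))) {
        idx <- run_start[k]:run_end[k]
        p <- dec$marginals[cbind(idx, dec$path[idx] + 1L)]
        conf[k] <- min(max(prod(p), 0), 1)
      }
      mentions$confidence <- conf
      out[[length(out) + 1L]] <- mentions
    }
  }
  if (length(out) == 0L) {
    res <- empty_mentions()
    res$confidence <- numeric()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(blacklist)) {
    res <- res[!res$text %in% blacklist, , drop = FALSE]
  }
  res
}

#' @rdname tag_document
#' @param documents Data frame of documents; mentions are concatenated.
#' @export
tag_corpus <- function(model, documents, blacklist = NULL) {
  out <- lapply(seq_len(nrow(documents)), function(i) {
    tag_document(model, documents[i, , drop = FALSE], blacklist = blacklist)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- empty_mentions()
    res$confidence <- numeric()
  }
  rownames(res) <- NULL
  res
}

#' Persist and restore a trained tagger
#'
#' The serialized file carries a format version; loading a file that is
#' corrupt, truncated, or of a different version fails with an error.
#' A round-tripped model produces identical predictions.
#'
#' @param model A `chem_tagger`.
#' @param path File path.
#' @return `save_tagger` invisibly returns `path`; `load_tagger`
#'   returns the model.
#' @export
save_tagger <- function(model, path) {
  stopifnot(inherits(model, "chem_tagger"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot load tagger model from '", path, "': ", conditionMessage(e))
  })
  if (!inherits(model, "chem_tagger") ||
      !identical(model$version, .model_version)) {
    stop("file '", path, "' does not contain a compatible tagger model")
  }
  model
}

#' @export
print.chem_tagger <- function(x, ...) {
  cat(sprintf(paste0("First-order linear-chain CRF tagger: %d features, ",
                     "tokenizer '%s', soundex length %d\n"),
              x$n_features, x$tokenizer, x$feature_config$soundex_len))
  invisible(x)
}
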