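## Seeded synthetic data: corpora with planted chemical-like mentions,
## cluster maps, gazetteers, and simulated extractor outputs with a
## known conditional-precision structure.  Everything is reproducible
## from an explicit seed and nothing touches the caller's RNG state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## fragment grammar for chemical-like surface forms
.chem_stems <- c("meth", "eth", "prop", "but", "pent", "hex", "hept", "oct")
.chem_suffixes <- c("ane", "anol", "ylene", "oate", "anal", "anoic")
.chem_heads <- c("acid", "chloride", "oxide", "ester")
.filler_words <- c(
  "the", "reaction", "was", "measured", "in", "aqueous", "samples", "we",
  "observed", "strong", "binding", "of", "to", "receptor", "cells", "after",
  "treatment", "with", "solution", "at", "room", "temperature", "for",
  "hours", "and", "then", "analyzed", "by", "spectroscopy", "results",
  "indicate", "that", "levels", "increased", "during", "incubation",
  "control", "group", "showed", "no", "significant", "change")
.sentence_openers <- c("The", "We", "Samples", "Results", "Analysis",
                       "Treatment", "Incubation", "Measurements")

chem_formula_pool <- function() {
  simple <- c("CO2", "H2O", "H2O2", "NH3", "CH4", "SO2", "NaCl", "KCl",
              "CaCO3", "C2H5OH", "H2SO4", "HNO3", "NaOH", "FeO", "MgO")
  combos <- as.vector(outer(2:6, 4:9, function(i, j) {
    paste0("C", i, "H", j)
  }))
  unique(c(simple, combos, paste0(combos[seq_len(10)], "O")))
}

#' Generator configuration for synthetic corpora
#'
#' Defaults describe a small but learnable world: documents of a title
#' plus a few abstract sentences, on average `mention_rate` planted
#' chemical mentions per sentence, with a fifth of the chemical
#' vocabulary multi-word and a quarter formula-like.
#'
#' @param n_docs Number of documents (>= 1).
#' @param seed Integer seed.
#' @param vocab_size Number of distinct chemical surface forms.
#' @param mention_rate Mean mentions per sentence (Poisson).
#' @param multiword_fraction Fraction of the chemical vocabulary that
#'   is multi-word.
#' @param formula_fraction Fraction that is formula-like.
#' @param gazetteer_fraction Fraction of the chemical vocabulary listed
#'   in the generated gazetteer.
#' @param k_clusters Cluster count of the generated cluster map.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_docs, seed = 1L, vocab_size = 40L,
                             mention_rate = 1.2, multiword_fraction = 0.2,
                             formula_fraction = 0.25,
                             gazetteer_fraction = 0.7, k_clusters = 40L) {
  if (!is.numeric(n_docs) || n_docs < 1) stop("n_docs must be >= 1")
  props <- c(multiword_fraction, formula_fraction, gazetteer_fraction)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (mention_rate < 0) stop("mention_rate must be non-negative")
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 vocab_size = as.integer(vocab_size),
                 mention_rate = mention_rate,
                 multiword_fraction = multiword_fraction,
                 formula_fraction = formula_fraction,
                 gazetteer_fraction = gazetteer_fraction,
                 k_clusters = as.integer(k_clusters)),
            class = "generator_config")
}

build_chem_vocab <- function(config) {
  n_multi <- round(config$vocab_size * config$multiword_fraction)
  n_formula <- round(config$vocab_size * config$formula_fraction)
  n_single <- max(config$vocab_size - n_multi - n_formula, 0L)
  names_pool <- as.vector(outer(.chem_stems, .chem_suffixes, paste0))
  singles <- sample(names_pool, min(n_single, length(names_pool)))
  formulas <- sample(chem_formula_pool(), n_formula)
  multi_base <- sample(setdiff(names_pool, singles),
                       min(n_multi, length(names_pool) - length(singles)))
  multis <- paste(multi_base, sample(.chem_heads, length(multi_base),
                                     replace = TRUE))
  list(terms = c(singles, formulas, multis),
       type = c(rep("SYSTEMATIC", length(singles)),
                rep("FORMULA", length(formulas)),
                rep("MULTIPLE", length(multis))))
}

## build one sentence; returns its text and the mentions planted in it
## (offsets relative to the sentence start)
gen_sentence <- function(vocab, mention_rate) {
  n_fill <- sample(4:9, 1L)
  fillers <- sample(.filler_words, n_fill, replace = TRUE)
  n_ment <- min(stats::rpois(1L, mention_rate), n_fill)
  words <- c(sample(.sentence_openers, 1L), fillers)
  is_mention <- logical(length(words))
  types <- character(length(words))
  if (n_ment > 0L) {
    pick <- sample.int(length(vocab$terms), n_ment, replace = TRUE)
    pos <- sort(sample(2:length(words), n_ment))
    words[pos] <- vocab$terms[pick]
    is_mention[pos] <- TRUE
    types[pos] <- vocab$type[pick]
  }
  offsets <- cumsum(c(0L, nchar(words) + 1L))[seq_along(words)]
  text <- paste0(paste(words, collapse = " "), ".")
  mentions <- data.frame(
    start = offsets[is_mention],
    end = offsets[is_mention] + nchar(words[is_mention]),
    text = words[is_mention],
    entity_type = types[is_mention],
    stringsAsFactors = FALSE
  )
  list(text = text, mentions = mentions)
}

#' Generate a synthetic annotated corpus
#'
#' Builds documents whose sentences are filler words with chemical-like
#' surface forms planted at exact, whitespace-delimited positions, so
#' that every gold mention is token-aligned under the default
#' tokenizer.  Also returns a cluster map concentrating chemical tokens
#' in dedicated clusters (strong embedding signal), and a gazetteer
#' covering a configurable fraction of the chemical vocabulary.
#'
#' @param config A [generator_config()], or `NULL` to build one from
#'   `...`.
#' @param ... Passed to [generator_config()] when `config` is `NULL`.
#' @return A list with `documents`, `gold`, `cluster_map`, `gazetteer`,
#'   and `vocab` (the chemical term list with types).
#' @export
#' @examples
#' corpus <- gen_corpus(n_docs = 3, seed = 42)
#' head(corpus$gold)
gen_corpus <- function(config = NULL, ...) {
  if (is.null(config)) config <- generator_config(...)
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    vocab <- build_chem_vocab(config)
    docs <- vector("list", config$n_docs)
    gold <- vector("list", config$n_docs)
    for (i in seq_len(config$n_docs)) {
      doc_id <- sprintf("SYN%05d", i)
      sections <- list(T = 1L, A = sample(2:4, 1L))
      texts <- c(T = "", A = "")
      doc_mentions <- list()
      for (section in c("T", "A")) {
        parts <- character()
        cursor <- 0L
        for (s in seq_len(sections[[section]])) {
          sent <- gen_sentence(vocab, config$mention_rate)
          if (nrow(sent$mentions) > 0L) {
            m <- sent$mentions
            m$start <- m$start + cursor
            m$end <- m$end + cursor
            m$doc_id <- doc_id
            m$section <- section
            doc_mentions[[length(doc_mentions) + 1L]] <- m
          }
          parts <- c(parts, sent$text)
          cursor <- cursor + nchar(sent$text) + 1L  # joining space
        }
        texts[[section]] <- paste(parts, collapse = " ")
      }
      docs[[i]] <- data.frame(doc_id = doc_id, title = texts[["T"]],
                              abstract = texts[["A"]],
                              stringsAsFactors = FALSE)
      gold[[i]] <- if (length(doc_mentions) > 0L) {
        do.call(rbind, doc_mentions)
      } else {
        NULL
      }
    }
    documents <- do.call(rbind, docs)
    gold <- do.call(rbind, gold)
    if (is.null(gold)) gold <- empty_mentions()
    gold <- gold[, c("doc_id", "section", "start", "end", "text",
                     "entity_type")]
    rownames(gold) <- NULL
    chem_tokens <- unique(unlist(strsplit(vocab$terms, " ", fixed = TRUE)))
    map <- gen_cluster_map(
      vocab = c(chem_tokens, .filler_words, tolower(.sentence_openers)),
      k = config$k_clusters,
      seed = config$seed + 1L,
      chem_terms = chem_tokens
    )
    n_gaz <- round(config$gazetteer_fraction * length(vocab$terms))
    gaz <- if (n_gaz > 0L) {
      gazetteer("main", sample(vocab$terms, n_gaz), match_mode = "token")
    } else {
      NULL
    }
    list(documents = documents, gold = gold, cluster_map = map,
         gazetteer = gaz, vocab = vocab, config = config)
  })
}

#' Seeded cluster-map assignment
#'
#' Emulates the result of clustering word-embedding vectors: chemical
#' terms are concentrated in a small set of dedicated cluster ids and
#' all other terms are spread over the rest.  Deterministic for a given
#' seed.
#'
#' @param vocab Character vector of terms to map.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param chem_terms Terms to place in the dedicated chemical clusters.
#' @param n_chem_clusters How many cluster ids are reserved for
#'   chemical terms.
#' @return A [cluster_map()].
#' @export
gen_cluster_map <- function(vocab, k, seed = 1L, chem_terms = character(),
                            n_chem_clusters = max(1L, k %/% 8L)) {
  if (!is.numeric(k) || k < 2) stop("k must be >= 2")
  k <- as.integer(k)
  n_chem_clusters <- min(as.integer(n_chem_clusters), k - 1L)
  with_seed(seed, {
    vocab <- unique(vocab)
    is_chem <- vocab %in% chem_terms
    ids <- integer(length(vocab))
    ids[is_chem] <- sample.int(n_chem_clusters, sum(is_chem),
                               replace = TRUE) - 1L
    if (any(!is_chem)) {
      ids[!is_chem] <- sample(seq.int(n_chem_clusters, k - 1L),
                              sum(!is_chem), replace = TRUE)
    }
    cluster_map(stats::setNames(ids, vocab), k = k)
  })
}

#' Simulation specification for extractor outputs
#'
#' The generative twin of the conditional-precision table: for each
#' non-zero signature, how many candidate spans to fabricate and which
#' fraction of them are true entities.
#'
#' @param extractor_names Character vector of extractor names (length
#'   n).
#' @param cells Data frame with columns `signature` (bit strings of
#'   length n, no all-zero row), `candidates` (counts >= 1) and
#'   `true_fraction` (in \[0, 1\]).
#' @param mode `"exact"` plants `round(q * count)` gold spans per
#'   cell; `"stochastic"` marks each span gold independently with
#'   probability q.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(extractor_names, cells,
                            mode = c("exact", "stochastic")) {
  mode <- match.arg(mode)
  n <- length(extractor_names)
  stopifnot(n >= 1L, is.data.frame(cells), nrow(cells) >= 1L,
            all(c("signature", "candidates", "true_fraction") %in%
                  names(cells)))
  if (any(nchar(cells$signature) != n) ||
      any(!grepl("^[01]+$", cells$signature)) ||
      any(cells$signature == strrep("0", n))) {
    stop("cell signatures must be non-zero bit strings of length ", n)
  }
  if (anyDuplicated(cells$signature)) stop("duplicate cell signatures")
  if (any(cells$candidates < 1)) stop("cell candidate counts must be >= 1")
  if (any(cells$true_fraction < 0 | cells$true_fraction > 1)) {
    stop("true_fraction must lie in [0, 1]")
  }
  structure(list(extractor_names = extractor_names, mode = mode,
                 cells = cells),
            class = "simulation_spec")
}

#' Simulate extractor outputs with known conditional precisions
#'
#' Fabricates distinct spans cell by cell, assigns each span to exactly
#' the extractors whose signature bit is set, and marks spans as gold
#' according to the cell's true fraction (deterministically in exact
#' mode, by independent coin flips in stochastic mode).  The realized
#' table -- the exact per-cell precision of the fabricated world -- is
#' returned alongside the outputs.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (used in stochastic mode).
#' @return A list with `outputs` (named list of span data frames),
#'   `gold` (span data frame) and `table` (the realized
#'   `conditional_table`).
#' @export
simulate_extractors <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- length(spec$extractor_names)
  with_seed(seed, {
    total <- sum(spec$cells$candidates)
    idx <- seq_len(total)
    spans <- data.frame(
      doc_id = sprintf("SIM%05d", 1L + (idx - 1L) %/% 25L),
      section = "A",
      start = ((idx - 1L) %% 25L) * 10L,
      end = ((idx - 1L) %% 25L) * 10L + 5L,
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(span_key(spans))) {
      stop("internal error: duplicate fabricated spans")
    }
    cell_of <- rep.int(seq_len(nrow(spec$cells)), spec$cells$candidates)
    gold_mask <- logical(total)
    hits <- integer(nrow(spec$cells))
    for (c_i in seq_len(nrow(spec$cells))) {
      rows <- which(cell_of == c_i)
      q <- spec$cells$true_fraction[c_i]
      if (spec$mode == "exact") {
        n_gold <- round(q * length(rows))
        if (n_gold > 0L) gold_mask[rows[seq_len(n_gold)]] <- TRUE
        hits[c_i] <- n_gold
      } else {
        mask <- stats::runif(length(rows)) < q
        gold_mask[rows[mask]] <- TRUE
        hits[c_i] <- sum(mask)
      }
    }
    bits <- strsplit(spec$cells$signature, "")
    outputs <- stats::setNames(lapply(seq_len(n), function(i) {
      in_i <- vapply(bits, function(b) b[i] == "1", logical(1))
      spans[cell_of %in% which(in_i), , drop = FALSE]
    }), spec$extractor_names)
    sig <- all_signatures(n)
    cells <- data.frame(
      signature = sig,
      candidates = as.integer(spec$cells$candidates[
        match(sig, spec$cells$signature)]),
      hits = hits[match(sig, spec$cells$signature)],
      stringsAsFactors = FALSE
    )
    cells$candidates[is.na(cells$candidates)] <- 0L
    cells$hits[is.na(cells$hits)] <- 0L
    cells$probability <- ifelse(cells$candidates > 0L,
                                cells$hits / pmax(cells$candidates, 1L),
                                NA_real_)
    rownames(cells) <- NULL
    list(outputs = outputs, gold = spans[gold_mask, , drop = FALSE],
         table = new_conditional_table(spec$extractor_names, cells))
  })
}

#' Emulated embedding training on a small corpus
#'
#' A light-weight stand-in for word2vec + K-means for integration
#' testing of the cluster-feature pipeline: builds a token
#' co-occurrence matrix over a symmetric window, weights it by positive
#' pointwise mutual information, embeds terms with a truncated SVD and
#' clusters the embeddings with K-means.
#'
#' @param documents Data frame of documents.
#' @param k Number of clusters (>= 2).
#' @param dim Embedding dimensionality.
#' @param window Symmetric co-occurrence window in tokens.
#' @param seed Integer seed (K-means initialization).
#' @param tokenizer Tokenizer registry name.
#' @return A [cluster_map()].
#' @export
train_cluster_map <- function(documents, k = 40L, dim = 20L, window = 2L,
                              seed = 1L, tokenizer = "chem") {
  if (k < 2) stop("k must be >= 2")
  toks <- tokenize_corpus(documents, tokenizer)
  terms <- tolower(toks$surface)
  vocab <- sort(unique(terms))
  v <- length(vocab)
  if (v < k) stop("vocabulary smaller than k")
  ids <- match(terms, vocab)
  cooc <- matrix(0, v, v)
  ## sections are contiguous runs in tokenize_corpus output
  run <- paste(toks$doc_id, toks$section, sep = "\r")
  for (start in which(!duplicated(run))) {
    end <- start
    while (end < length(run) && run[end + 1L] == run[start]) end <- end + 1L
    seq_ids <- ids[start:end]
    for (d in seq_len(window)) {
      if (length(seq_ids) <= d) next
      a <- seq_ids[seq_len(length(seq_ids) - d)]
      b <- seq_ids[-seq_len(d)]
      for (j in seq_along(a)) {
        cooc[a[j], b[j]] <- cooc[a[j], b[j]] + 1
        cooc[b[j], a[j]] <- cooc[b[j], a[j]] + 1
      }
    }
  }
  total <- sum(cooc)
  rowp <- pmax(rowSums(cooc), 1) / total
  pmi <- log(pmax(cooc / total, 1e-12) / outer(rowp, rowp))
  pmi[pmi < 0] <- 0
  sv <- svd(pmi, nu = min(dim, v), nv = 0)
  emb <- sv$u * rep(sqrt(pmax(sv$d[seq_len(ncol(sv$u))], 1e-12)),
                    each = nrow(sv$u))
  with_seed(seed, {
    km <- stats::kmeans(emb, centers = k, nstart = 3L, iter.max = 50L)
    cluster_map(stats::setNames(km$cluster - 1L, vocab), k = k)
  })
}
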