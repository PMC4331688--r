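## The tagger's feature battery: Soundex phonetic codes, word-class
## shapes, token-shape predicates, character n-grams, the formula
## heuristic, embedding-cluster lookups, gazetteer lookups, and the
## window assembly that turns per-token features into CRF observations.

#' Soundex phonetic code of a word
#'
#' American Soundex generalized to a configurable number of digits.
#' Non-alphabetic characters are stripped first; a word with no ASCII
#' letters gets the sentinel code `"#"`.  The code is the uppercased
#' first letter followed by consonant-class digits (B,F,P,V = 1;
#' C,G,J,K,Q,S,X,Z = 2; D,T = 3; L = 4; M,N = 5; R = 6; vowels and
#' H, W, Y carry no code).  Adjacent letters with the same digit
#' collapse, including across H or W; a letter repeating the first
#' letter's class immediately after it is skipped; vowels (and Y) act
#' as separators.  Digits beyond `max_digits` are ignored and codes are
#' never zero-padded, so `"carbon"` and `"carbonate"` share the code
#' `C615` at the default-census length of 3.
#'
#' @param word Character scalar.
#' @param max_digits Maximum number of digits to emit (>= 1); the
#'   tagger's default configuration uses 7.
#' @return Character scalar code.
#' @export
#' @examples
#' soundex("carbon", 3)      # "C615"
#' soundex("carbonate", 7)   # "C6153"
soundex <- function(word, max_digits = 7) {
  if (!is.numeric(max_digits) || length(max_digits) != 1L || max_digits < 1) {
    stop("max_digits must be a single number >= 1")
  }
  letters_only <- toupper(gsub("[^A-Za-z]+", "", word))
  if (!nzchar(letters_only)) return("#")
  chars <- strsplit(letters_only, "", fixed = TRUE)[[1L]]
  code_of <- function(ch) {
    switch(ch,
           B = , F = , P = , V = 1L,
           C = , G = , J = , K = , Q = , S = , X = , Z = 2L,
           D = , T = 3L,
           L = 4L,
           M = , N = 5L,
           R = 6L,
           0L)  # A E I O U H W Y
  }
  digits <- integer()
  prev <- code_of(chars[1L])
  for (ch in chars[-1L]) {
    if (ch %in% c("H", "W")) next          # transparent: do not reset prev
    code <- code_of(ch)
    if (code == 0L) {                      # vowel or Y: separator
      prev <- 0L
      next
    }
    if (code != prev) digits <- c(digits, code)
    prev <- code
  }
  if (length(digits) > max_digits) digits <- digits[seq_len(max_digits)]
  paste0(chars[1L], paste(digits, collapse = ""))
}

#' Word-class (shape) conversion
#'
#' Maps each character to a class symbol: uppercase letter to `A`,
#' lowercase letter to `a`, digit to `0`, anything else to `x`.  The
#' brief form collapses runs of identical class symbols.
#'
#' @param word Character scalar.
#' @return Named character vector with elements `full` and `brief`.
#' @export
#' @examples
#' word_class("Ca(2+)")  # full "Aax0xx", brief "Aax0x"
word_class <- function(word) {
  full <- gsub("\\p{Lu}", "A", word, perl = TRUE)
  full <- gsub("\\p{Ll}", "a", full, perl = TRUE)
  full <- gsub("\\p{Nd}", "0", full, perl = TRUE)
  full <- gsub("[^Aa0]", "x", full, perl = TRUE)
  brief <- gsub("(.)\\1+", "\\1", full, perl = TRUE)
  c(full = full, brief = brief)
}

#' Feature extraction configuration
#'
#' Collects the ablation switches and window widths of the tagger.
#' `use_nlp` controls the word-class (and optional lemma) features,
#' `use_word2vec` the embedding-cluster feature, `use_soundex` the
#' Soundex feature whose length is `soundex_len` (the ablation study
#' varies it over 3, 5, 7 and 100).  `windows` maps feature families to
#' the neighbor window width used when assembling per-token CRF
#' observations; families absent from the list default to 0 (no
#' neighbor copies).
#'
#' @param use_nlp,use_word2vec,use_soundex Logical ablation switches.
#' @param soundex_len Maximum Soundex digits (>= 1).
#' @param windows Named list of integer window widths per family.
#' @param lemmatizer Optional function mapping a surface to its lemma;
#'   `NULL` (the default) omits the lemma feature.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(use_nlp = TRUE, use_word2vec = TRUE,
                           use_soundex = TRUE, soundex_len = 7,
                           windows = default_windows(),
                           lemmatizer = NULL) {
  stopifnot(is.logical(use_nlp), is.logical(use_word2vec),
            is.logical(use_soundex))
  if (!is.numeric(soundex_len) || soundex_len < 1) {
    stop("soundex_len must be >= 1")
  }
  if (!is.null(lemmatizer) && !is.function(lemmatizer)) {
    stop("lemmatizer must be NULL or a function")
  }
  structure(list(use_nlp = isTRUE(use_nlp),
                 use_word2vec = isTRUE(use_word2vec),
                 use_soundex = isTRUE(use_soundex),
                 soundex_len = as.integer(soundex_len),
                 windows = windows, lemmatizer = lemmatizer),
            class = "feature_config")
}

#' @rdname feature_config
#' @export
default_windows <- function() {
  ## high-cardinality families (word, lower) get the wide window;
  ## categorical shape-ish families get +-1; soundex and n-grams stay
  ## local to keep the parameter count in check
  list(word = 2L, lower = 2L, shape = 1L, wc = 1L, wcb = 1L,
       cluster = 1L, gaz = 1L, lemma = 1L,
       soundex = 0L, ng2 = 0L, ng3 = 0L, ng4 = 0L, bos = 0L)
}

#' Per-token surface features
#'
#' Emits the general token-derived features for one surface form: the
#' word itself and its lowercase form, shape predicates (contains a
#' digit, starts with a capital, all capitals, all lowercase, mixed
#' case, ends in a sign, ends in a number, contains a dash, starts with
#' a number), character 2/3/4-grams, the chemical-formula heuristic
#' (set when no two consecutive characters are lowercase letters), a
#' sentence-start marker, and -- per the configuration -- word-class
#' and Soundex features.
#'
#' @param surface Character scalar token surface.
#' @param sentence_start Logical: is this the first token of a sentence?
#' @param config A [feature_config()].
#' @return Character vector of feature keys (`family=value` or bare
#'   presence keys).
#' @export
token_features <- function(surface, sentence_start = FALSE,
                           config = feature_config()) {
  feats <- c(paste0("word=", surface), paste0("lower=", tolower(surface)))
  has_upper <- grepl("\\p{Lu}", surface, perl = TRUE)
  has_lower <- grepl("\\p{Ll}", surface, perl = TRUE)
  has_letter <- grepl("\\p{L}", surface, perl = TRUE)
  shapes <- character()
  if (grepl("\\p{Nd}", surface, perl = TRUE)) shapes <- c(shapes, "digit")
  if (grepl("^\\p{Lu}", surface, perl = TRUE)) shapes <- c(shapes, "initcap")
  if (has_letter && !has_lower) shapes <- c(shapes, "allcaps")
  if (has_letter && !has_upper) shapes <- c(shapes, "allsmall")
  if (has_upper && has_lower) shapes <- c(shapes, "mixed")
  if (grepl("[+±=*/%-]$", surface, perl = TRUE)) shapes <- c(shapes, "endsign")
  if (grepl("\\p{Nd}$", surface, perl = TRUE)) shapes <- c(shapes, "enddigit")
  if (grepl("-", surface, fixed = TRUE)) shapes <- c(shapes, "dash")
  if (grepl("^\\p{Nd}", surface, perl = TRUE)) shapes <- c(shapes, "startdigit")
  if (!grepl("\\p{Ll}\\p{Ll}", surface, perl = TRUE)) {
    shapes <- c(shapes, "formula")
  }
  if (length(shapes) > 0L) feats <- c(feats, paste0("shape=", shapes))
  nc <- nchar(surface)
  for (n in 2:4) {
    if (nc >= n) {
      grams <- substring(surface, seq_len(nc - n + 1L), seq.int(n, nc))
      feats <- c(feats, paste0("ng", n, "=", unique(grams)))
    }
  }
  if (sentence_start) feats <- c(feats, "bos")
  if (config$use_nlp) {
    wc <- word_class(surface)
    feats <- c(feats, paste0("wc=", wc[["full"]]), paste0("wcb=", wc[["brief"]]))
    if (!is.null(config$lemmatizer)) {
      feats <- c(feats, paste0("lemma=", config$lemmatizer(surface)))
    }
  }
  if (config$use_soundex) {
    feats <- c(feats, paste0("soundex=", soundex(surface, config$soundex_len)))
  }
  unique(feats)
}

#' Construct a cluster map
#'
#' A cluster map associates terms with the identifier of the embedding
#' cluster they fall into (integers in `[0, k)`); terms absent from the
#' map have no cluster and yield no feature.
#'
#' @param ids Named integer vector: names are terms, values cluster ids.
#' @param k Number of clusters.
#' @return An object of class `cluster_map`.
#' @export
cluster_map <- function(ids, k) {
  stopifnot(is.numeric(ids), !is.null(names(ids)), k >= 1)
  ids <- stats::setNames(as.integer(ids), names(ids))
  if (any(ids < 0L) || any(ids >= k)) {
    stop("cluster ids must lie in [0, k)")
  }
  structure(list(map = ids, k = as.integer(k)), class = "cluster_map")
}

#' @rdname cluster_map
#' @param path Two-column tab-separated file: term, cluster id.
#' @export
read_cluster_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           col.names = c("term", "id"),
                           colClasses = c("character", "integer"),
                           fileEncoding = "UTF-8")
  ids <- stats::setNames(tab$id, tab$term)
  cluster_map(ids, k = max(tab$id) + 1L)
}

#' @rdname cluster_map
#' @param map A `cluster_map`.
#' @param term Character scalar.
#' @export
cluster_lookup <- function(map, term) {
  id <- unname(map$map[match(term, names(map$map))])
  if (is.na(id)) id <- unname(map$map[match(tolower(term), names(map$map))])
  if (is.na(id)) NULL else id
}

#' Embedding-cluster feature for a word
#'
#' Looks the word up in the cluster map (exact form first, then the
#' lowercased form) and, when found, returns the feature
#' `cluster=<id>`; a word never seen in the embedding corpus yields no
#' feature rather than a default id.
#'
#' @param word Character scalar.
#' @param map A [cluster_map()].
#' @return Character vector of length 0 or 1.
#' @export
cluster_feature <- function(word, map) {
  if (is.null(map)) return(character())
  id <- cluster_lookup(map, word)
  if (is.null(id)) character() else paste0("cluster=", id)
}

#' Construct a gazetteer
#'
#' @param name Short identifier used in feature keys.
#' @param terms Character vector of dictionary terms (possibly
#'   multi-word).
#' @param match_mode `"token"` (entries are tokenized and matched
#'   against token runs), `"prefix"` or `"suffix"` (entries are matched
#'   as surface affixes).
#' @param tokenizer Tokenizer used to pre-tokenize multi-word entries.
#' @param boost When `TRUE` the gazetteer emits the bare `boost`
#'   feature instead of `in_<name>` features (a boost-term list).
#' @return An object of class `gazetteer`.
#' @export
gazetteer <- function(name, terms, match_mode = c("token", "prefix", "suffix"),
                      tokenizer = "chem", boost = FALSE) {
  match_mode <- match.arg(match_mode)
  terms <- unique(terms[nzchar(terms)])
  if (length(terms) == 0L) stop("gazetteer '", name, "' has no entries")
  entries <- if (match_mode == "token") {
    lapply(terms, function(t) tokenize(t, tokenizer)$surface)
  } else {
    as.list(terms)
  }
  structure(list(name = name, entries = entries, match_mode = match_mode,
                 member_tokens = unique(unlist(entries)),
                 full_keys = vapply(entries, paste, character(1),
                                    collapse = "\r"),
                 boost = isTRUE(boost)),
            class = "gazetteer")
}

#' @rdname gazetteer
#' @param path Plain-text UTF-8 file, one term per line.
#' @param ... Passed on to `gazetteer()`.
#' @export
read_gazetteer <- function(path, name, ...) {
  terms <- readLines(path, encoding = "UTF-8", warn = FALSE)
  gazetteer(name, terms[nzchar(trimws(terms))], ...)
}

#' Gazetteer lookup features for one token position
#'
#' For a token-mode gazetteer, emits `in_<name>` when the token at
#' `index` occurs anywhere in any entry, and `in_<name>_full` when a
#' contiguous token run covering `index` equals an entire entry.
#' Prefix/suffix gazetteers test entries as surface affixes
#' (`pfx_<name>` / `sfx_<name>`).  A boost gazetteer emits the bare
#' `boost` feature.
#'
#' @param surfaces Character vector of the sentence's token surfaces.
#' @param index Position (1-based) of the token of interest.
#' @param gazetteers List of [gazetteer()] objects.
#' @return Character vector of feature keys.
#' @export
gazetteer_features <- function(surfaces, index, gazetteers) {
  if (index < 1L || index > length(surfaces)) {
    stop("index out of range")
  }
  feats <- character()
  for (g in gazetteers) {
    if (g$match_mode == "token") {
      if (surfaces[index] %in% g$member_tokens) {
        feats <- c(feats, if (g$boost) "boost" else paste0("in_", g$name))
        lens <- unique(lengths(g$entries))
        full <- FALSE
        for (len in lens) {
          for (off in max(1L, index - len + 1L):index) {
            if (off + len - 1L > length(surfaces)) next
            run <- paste(surfaces[off:(off + len - 1L)], collapse = "\r")
            if (run %in% g$full_keys) {
              full <- TRUE
              break
            }
          }
          if (full) break
        }
        if (full && !g$boost) feats <- c(feats, paste0("in_", g$name, "_full"))
      }
    } else if (g$match_mode == "prefix") {
      hit <- any(vapply(g$entries, function(e) {
        startsWith(surfaces[index], e)
      }, logical(1)))
      if (hit) feats <- c(feats, paste0("pfx_", g$name))
    } else {
      hit <- any(vapply(g$entries, function(e) {
        endsWith(surfaces[index], e)
      }, logical(1)))
      if (hit) feats <- c(feats, paste0("sfx_", g$name))
    }
  }
  unique(feats)
}

## family of a feature key, for window lookup
feature_family <- function(keys) {
  fam <- sub("=.*$", "", keys)
  fam[startsWith(keys, "in_") | startsWith(keys, "pfx_") |
        startsWith(keys, "sfx_") | keys == "boost"] <- "gaz"
  fam
}

#' Assemble windowed feature sets for a sentence
#'
#' Computes the per-token features (surface, cluster and gazetteer
#' families) and then copies each neighbor's features into the current
#' token's set, re-keyed with the relative offset (`word[-1]=...`),
#' out to the per-family window width of the configuration.  Positions
#' near the sentence boundary simply omit out-of-range neighbors.
#'
#' @param tokens Data frame of tokens (column `surface` is used).
#' @param config A [feature_config()].
#' @param map Optional [cluster_map()].
#' @param gazetteers List of [gazetteer()] objects.
#' @param sentence_start Logical: does the sentence start a document
#'   sentence (first token gets the `bos` feature)?
#' @return List of character vectors, one feature set per token.
#' @export
assemble_features <- function(tokens, config = feature_config(), map = NULL,
                              gazetteers = list(), sentence_start = TRUE) {
  n <- nrow(tokens)
  if (n == 0L) return(list())
  surfaces <- tokens$surface
  own <- vector("list", n)
  for (i in seq_len(n)) {
    f <- token_features(surfaces[i],
                        sentence_start = sentence_start && i == 1L,
                        config = config)
    if (config$use_word2vec && !is.null(map)) {
      f <- c(f, cluster_feature(surfaces[i], map))
    }
    if (length(gazetteers) > 0L) {
      f <- c(f, gazetteer_features(surfaces, i, gazetteers))
    }
    own[[i]] <- f
  }
  wv <- unlist(config$windows)
  wv <- stats::setNames(as.integer(wv), names(wv))
  ## per-token vector of window widths, one entry per feature key;
  ## families without a configured width get 0 (never copied)
  famw <- lapply(own, function(f) {
    w <- wv[feature_family(f)]
    w[is.na(w)] <- 0L
    unname(w)
  })
  wmax <- if (length(wv) > 0L) max(wv, 0L) else 0L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fs <- own[[i]]
    if (wmax > 0L) {
      for (d in setdiff(seq.int(-wmax, wmax), 0L)) {
        j <- i + d
        if (j < 1L || j > n) next
        keep <- famw[[j]] >= abs(d)
        if (!any(keep)) next
        keys <- own[[j]][keep]
        tagged <- sub("^([^=\\[]+)", sprintf("\\1[%+d]", d), keys, perl = TRUE)
        fs <- c(fs, tagged)
      }
    }
    out[[i]] <- unique(fs)
  }
  out
}

#' Label tokens with the BIO scheme from gold mentions
#'
#' A token whose span starts a gold mention gets `B`; following tokens
#' inside the same mention get `I`; everything else gets `O`.  A
#' mention whose boundaries do not coincide with token boundaries is
#' skipped and counted in the `misaligned` attribute (with a warning),
#' keeping the labels faithful to the gold offsets.  Overlapping gold
#' mentions are rejected.
#'
#' @param tokens Data frame of tokens with `start`, `end` offsets in
#'   the same section as the mentions.
#' @param mentions Data frame of gold mentions (`start`, `end` used).
#' @return Character vector of labels `B`/`I`/`O`, with attribute
#'   `misaligned` counting skipped mentions.
#' @export
label_bio <- function(tokens, mentions) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  misaligned <- 0L
  if (nrow(mentions) > 0L) {
    m <- mentions[order(mentions$start), , drop = FALSE]
    if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)])) {
      stop("overlapping gold mentions")
    }
    for (i in seq_len(nrow(m))) {
      inside <- which(tokens$start >= m$start[i] & tokens$end <= m$end[i])
      aligned <- length(inside) > 0L &&
        tokens$start[inside[1L]] == m$start[i] &&
        tokens$end[inside[length(inside)]] == m$end[i] &&
        all(diff(inside) == 1L)
      if (!aligned) {
        misaligned <- misaligned + 1L
        next
      }
      labels[inside[1L]] <- "B"
      if (length(inside) > 1L) labels[inside[-1L]] <- "I"
    }
  }
  if (misaligned > 0L) {
    warning(sprintf("%d gold mention(s) not aligned to token boundaries; skipped",
                    misaligned))
  }
  attr(labels, "misaligned") <- misaligned
  labels
}

#' Decode a BIO label sequence into entity mentions
#'
#' Maximal runs matching `B I*` become mentions spanning the first
#' token's start to the last token's end.  An `I` not preceded by `B`
#' or `I` (as a model may emit) is treated as `B`.
#'
#' @param tokens Data frame of tokens with `start`, `end`.
#' @param labels Character vector of `B`/`I`/`O`, same length.
#' @param text Optional source section text; when given, mention text
#'   is the exact source slice, otherwise token surfaces joined by a
#'   single space.
#' @param doc_id,section Carried into the output columns.
#' @return Data frame of entity mentions.
#' @export
decode_bio <- function(tokens, labels, text = NULL,
                       doc_id = NA_character_, section = NA_character_) {
  if (nrow(tokens) != length(labels)) {
    stop("tokens and labels have different lengths")
  }
  runs <- list()
  cur <- NULL
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "B" || (lab == "I" && is.null(cur))) {
      if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- c(i, i)
    } else if (lab == "I") {
      cur[2L] <- i
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  if (length(runs) == 0L) return(empty_mentions())
  starts <- vapply(runs, function(r) tokens$start[r[1L]], integer(1))
  ends <- vapply(runs, function(r) tokens$end[r[2L]], integer(1))
  texts <- if (!is.null(text)) {
    substring(text, starts + 1L, ends)
  } else {
    vapply(runs, function(r) {
      paste(tokens$surface[r[1L]:r[2L]], collapse = " ")
    }, character(1))
  }
  data.frame(doc_id = doc_id, section = section, start = starts, end = ends,
             text = texts, entity_type = NA_character_,
             stringsAsFactors = FALSE)
}
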