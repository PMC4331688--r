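## Sentence splitting and tokenization behind a pluggable registry,
## plus the tokenizer-boundary benchmark against gold entity spans.

.tokenizers <- new.env(parent = emptyenv())

#' Register a tokenizer under a name
#'
#' A tokenizer is a function taking a character scalar and returning a
#' data frame with columns `surface`, `start`, `end` (0-based,
#' end-exclusive character offsets into its input).  Three tokenizers
#' ship with the package: `"chem"` (the default, chemistry-aware),
#' `"whitespace"` and `"simple-punct"`.
#'
#' @param name Registry key.
#' @param fn Tokenizer function.
#' @return Invisibly, `name`.
#' @export
register_tokenizer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fn))
  assign(name, fn, envir = .tokenizers)
  invisible(name)
}

#' @rdname register_tokenizer
#' @export
list_tokenizers <- function() sort(ls(.tokenizers))

get_tokenizer <- function(name) {
  if (!exists(name, envir = .tokenizers, inherits = FALSE)) {
    stop(sprintf("unknown tokenizer '%s'; available: %s",
                 name, paste(list_tokenizers(), collapse = ", ")))
  }
  get(name, envir = .tokenizers, inherits = FALSE)
}

## word characters: letters (incl. Greek), decimal digits, and the
## Unicode sub-/superscript digits that occur in chemical text
.word_char_re <- "^[\\p{L}\\p{Nd}²³¹⁰-₟]$"

.open_brackets <- c("(", "[", "{")
.close_brackets <- c(")", "]", "}")

empty_tokens <- function() {
  data.frame(surface = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Split text into sentence spans
#'
#' A sentence ends at `.`, `!` or `?` that is followed by whitespace and
#' an uppercase letter, or that is the last non-whitespace character of
#' the text.  Returned spans are 0-based, end-exclusive, trimmed of
#' surrounding whitespace, and jointly cover every non-whitespace
#' character.
#'
#' @param text Character scalar.
#' @return Data frame with integer columns `start`, `end`.
#' @export
#' @examples
#' split_sentences("Calcium binds. Magnesium does not.")
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- data.frame(start = integer(), end = integer())
  if (is.na(text) || !grepl("\\S", text, perl = TRUE)) return(out)
  n <- nchar(text)
  ## candidate terminators: punct followed by whitespace+uppercase,
  ## or punct followed only by whitespace to end of text
  m <- gregexpr("[.!?](?=\\s+\\p{Lu})|[.!?](?=\\s*$)", text, perl = TRUE)[[1L]]
  ends <- if (m[1L] == -1L) integer() else as.integer(m)
  if (length(ends) == 0L || ends[length(ends)] < n) {
    ## text without a recognized terminator: the tail is one sentence
    ends <- c(ends, n)
  }
  start <- 1L
  spans <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    seg <- substr(text, start, ends[i])
    lead <- regexpr("\\S", seg, perl = TRUE)
    if (lead > 0L) {
      last <- regexpr("\\S\\s*$", seg, perl = TRUE)
      spans[[i]] <- c(start + lead - 2L, start + last - 1L)
    }
    start <- ends[i] + 1L
  }
  spans <- spans[!vapply(spans, is.null, logical(1))]
  if (length(spans) == 0L) return(out)
  data.frame(start = vapply(spans, `[[`, integer(1), 1L),
             end = vapply(spans, `[[`, integer(1), 2L))
}

#' Tokenize text with a registered tokenizer
#'
#' The default `"chem"` tokenizer splits on whitespace and then peels
#' leading and trailing punctuation off each fragment, with exceptions
#' tuned to chemical nomenclature: internal hyphens and internal commas
#' (as in `1,2-dichloroethane`) are preserved, a bracket at the edge of
#' a fragment stays attached when its pair is balanced within the
#' fragment (as in `Ca(2+)`), and a trailing sentence period is always
#' split off.  `"whitespace"` splits on whitespace only;
#' `"simple-punct"` peels every leading/trailing punctuation character
#' with no exceptions.
#'
#' @param text Character scalar.
#' @param tokenizer Registry name of the tokenizer to apply.
#' @return Data frame with columns `surface`, `start`, `end`; tokens
#'   are non-overlapping, sorted by `start`, and each `surface` equals
#'   the source slice at its offsets.
#' @export
#' @examples
#' tokenize("CO2 and H2O.")
#' tokenize("1,2-dichloroethane")
tokenize <- function(text, tokenizer = "chem") {
  get_tokenizer(tokenizer)(text)
}

## locate whitespace-separated fragments with 0-based offsets
find_fragments <- function(text) {
  m <- gregexpr("\\S+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(NULL)
  list(start = as.integer(m) - 1L,
       len = attr(m, "match.length"))
}

tokenize_whitespace <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty_tokens())
  fr <- find_fragments(text)
  if (is.null(fr)) return(empty_tokens())
  end <- fr$start + fr$len
  data.frame(surface = substring(text, fr$start + 1L, end),
             start = fr$start, end = end, stringsAsFactors = FALSE)
}

## shared peeling core over one whitespace-free fragment starting at
## 0-based offset `base`; `chem` enables the bracket-balance and
## trailing-period exceptions
peel_fragment <- function(chars, base, chem) {
  is_word <- grepl(.word_char_re, chars, perl = TRUE)
  m <- length(chars)
  lo <- 1L
  hi <- m
  starts <- integer()
  ends <- integer()
  balanced_here <- function(br) {
    i <- match(br, c(.open_brackets, .close_brackets))
    pair_open <- .open_brackets[(i - 1L) %% 3L + 1L]
    pair_close <- .close_brackets[(i - 1L) %% 3L + 1L]
    window <- chars[lo:hi]
    sum(window == pair_open) == sum(window == pair_close)
  }
  while (lo < hi && !is_word[lo]) {
    if (chem && chars[lo] %in% .open_brackets && balanced_here(chars[lo])) break
    starts <- c(starts, lo)
    ends <- c(ends, lo)
    lo <- lo + 1L
  }
  tail_starts <- integer()
  while (hi >= lo && !is_word[hi]) {
    if (chem && chars[hi] %in% .close_brackets && balanced_here(chars[hi])) {
      break
    }
    tail_starts <- c(hi, tail_starts)
    hi <- hi - 1L
    if (hi < lo) break
  }
  if (lo <= hi) {
    starts <- c(starts, lo)
    ends <- c(ends, hi)
  }
  if (length(tail_starts) > 0L) {
    starts <- c(starts, tail_starts)
    ends <- c(ends, tail_starts)
  }
  data.frame(start = base + starts - 1L, end = base + ends,
             stringsAsFactors = FALSE)
}
## (starts/ends are 1-based indices within the fragment)

tokenize_peeling <- function(text, chem) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty_tokens())
  fr <- find_fragments(text)
  if (is.null(fr)) return(empty_tokens())
  pieces <- vector("list", length(fr$start))
  for (i in seq_along(fr$start)) {
    frag <- substring(text, fr$start[i] + 1L, fr$start[i] + fr$len[i])
    chars <- strsplit(frag, "", fixed = TRUE)[[1L]]
    pieces[[i]] <- peel_fragment(chars, fr$start[i], chem = chem)
  }
  spans <- do.call(rbind, pieces)
  spans <- spans[order(spans$start), , drop = FALSE]
  data.frame(surface = substring(text, spans$start + 1L, spans$end),
             start = spans$start, end = spans$end,
             stringsAsFactors = FALSE, row.names = NULL)
}

register_tokenizer("chem", function(text) tokenize_peeling(text, chem = TRUE))
register_tokenizer("simple-punct",
                   function(text) tokenize_peeling(text, chem = FALSE))
register_tokenizer("whitespace", tokenize_whitespace)

#' Tokenize every section of a corpus
#'
#' Applies sentence splitting and then the chosen tokenizer to the
#' title (`T`) and abstract (`A`) of every document, reporting tokens
#' with document-section character offsets.
#'
#' @param documents Data frame as returned by [read_abstracts()].
#' @param tokenizer Registry name.
#' @return Data frame with columns `doc_id`, `section`, `surface`,
#'   `start`, `end`.
#' @export
tokenize_corpus <- function(documents, tokenizer = "chem") {
  tok <- get_tokenizer(tokenizer)
  rows <- list()
  for (i in seq_len(nrow(documents))) {
    for (section in c("T", "A")) {
      text <- if (section == "T") documents$title[i] else documents$abstract[i]
      sents <- split_sentences(text)
      for (j in seq_len(nrow(sents))) {
        sl <- substr(text, sents$start[j] + 1L, sents$end[j])
        t <- tok(sl)
        if (nrow(t) == 0L) next
        t$start <- t$start + sents$start[j]
        t$end <- t$end + sents$start[j]
        t$doc_id <- documents$doc_id[i]
        t$section <- section
        rows[[length(rows) + 1L]] <- t
      }
    }
  }
  if (length(rows) == 0L) {
    return(cbind(data.frame(doc_id = character(), section = character()),
                 empty_tokens()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("doc_id", "section", "surface", "start", "end")]
}

#' Benchmark a tokenization against gold entity boundaries
#'
#' A gold mention containing no space is *correct* when a single token
#' matches its span exactly.  A mention containing spaces (space being
#' the only admitted word separator) is *split correct* when every
#' space-separated word of the mention is matched exactly by a single
#' token.  Everything else is *incorrect*.  Accuracy is the percentage
#' of correct plus split-correct mentions.
#'
#' @param gold Data frame of gold entity mentions.
#' @param tokens Data frame of tokens with document-section offsets, as
#'   returned by [tokenize_corpus()].
#' @return An object of class `tokenizer_report`: counts `correct`,
#'   `split_correct`, `total_correct`, `incorrect` and percentage
#'   `accuracy`.
#' @export
evaluate_tokenizer <- function(gold, tokens) {
  key <- function(doc, sec, s, e) paste(doc, sec, s, e, sep = "\r")
  tok_keys <- key(tokens$doc_id, tokens$section, tokens$start, tokens$end)
  covered <- unique(paste(tokens$doc_id, tokens$section, sep = "\r"))
  correct <- 0L
  split_correct <- 0L
  incorrect <- 0L
  for (i in seq_len(nrow(gold))) {
    sec_key <- paste(gold$doc_id[i], gold$section[i], sep = "\r")
    if (!sec_key %in% covered) {
      stop(sprintf("no tokens available for document '%s' section %s",
                   gold$doc_id[i], gold$section[i]))
    }
    text <- gold$text[i]
    if (!grepl(" ", text, fixed = TRUE)) {
      hit <- key(gold$doc_id[i], gold$section[i], gold$start[i], gold$end[i]) %in%
        tok_keys
      if (hit) correct <- correct + 1L else incorrect <- incorrect + 1L
    } else {
      words <- strsplit(text, " ", fixed = TRUE)[[1L]]
      offs <- cumsum(c(0L, nchar(head(words, -1L)) + 1L))
      ok <- nzchar(words)
      word_keys <- key(gold$doc_id[i], gold$section[i],
                       gold$start[i] + offs[ok],
                       gold$start[i] + offs[ok] + nchar(words[ok]))
      if (all(ok) && all(word_keys %in% tok_keys)) {
        split_correct <- split_correct + 1L
      } else {
        incorrect <- incorrect + 1L
      }
    }
  }
  total_correct <- correct + split_correct
  denom <- total_correct + incorrect
  structure(
    list(correct = correct, split_correct = split_correct,
         total_correct = total_correct, incorrect = incorrect,
         accuracy = if (denom == 0L) 0 else 100 * total_correct / denom),
    class = "tokenizer_report"
  )
}

#' @export
print.tokenizer_report <- function(x, ...) {
  cat(sprintf(paste0("Tokenizer benchmark: correct=%d split_correct=%d ",
                     "total_correct=%d incorrect=%d accuracy=%.2f%%\n"),
              x$correct, x$split_correct, x$total_correct, x$incorrect,
              x$accuracy))
  invisible(x)
}
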