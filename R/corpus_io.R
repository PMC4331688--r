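## Corpus, annotation and prediction I/O in the tab-separated dialect used
## by community chemical-NER evaluations, plus exact-span CEM scoring.

#' Read abstracts from a tab-separated corpus file
#'
#' Each non-empty line carries three tab-separated fields: document
#' identifier, title, abstract.  Title and abstract may be empty strings
#' but the fields must be present.  Duplicate document identifiers are
#' rejected.
#'
#' @param path Path to a UTF-8 text file.
#' @return A data frame with character columns `doc_id`, `title`,
#'   `abstract`, one row per input line, in file order.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines("12345\tCalcium study\tWe measured Ca levels.", tf)
#' read_abstracts(tf)
read_abstracts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(data.frame(doc_id = character(), title = character(),
                      abstract = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  ## strsplit drops trailing empty fields: pad lines with an empty
  ## title/abstract back to width 3
  bad <- which(n_fields < 1L | n_fields > 3L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected 3 tab-separated fields, found %d",
                 keep[bad[1L]], n_fields[bad[1L]]))
  }
  parts <- lapply(parts, function(p) c(p, character(3L - length(p))))
  docs <- data.frame(
    doc_id   = vapply(parts, `[[`, character(1), 1L),
    title    = vapply(parts, `[[`, character(1), 2L),
    abstract = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(docs$doc_id))) {
    stop(sprintf("line %d: empty document identifier",
                 keep[which(!nzchar(docs$doc_id))[1L]]))
  }
  dup <- duplicated(docs$doc_id)
  if (any(dup)) {
    stop(sprintf("duplicate doc_id '%s' (line %d)",
                 docs$doc_id[which(dup)[1L]], keep[which(dup)[1L]]))
  }
  docs
}

#' Read gold annotations or extractor predictions as entity mentions
#'
#' Each line carries at least five tab-separated fields: document
#' identifier, section code (`T` for title, `A` for abstract), start
#' offset, end offset, mention text, and optionally an entity type.
#' Offsets are 0-based, end-exclusive, counted in characters within the
#' section string.
#'
#' @param path Path to a UTF-8 text file.
#' @return A data frame with columns `doc_id`, `section`, `start`,
#'   `end`, `text`, `entity_type` (`NA` when absent), in file order.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) return(empty_mentions())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 5L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected at least 5 tab-separated fields, found %d",
                 keep[bad[1L]], n_fields[bad[1L]]))
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  section <- get(2L)
  if (any(!section %in% c("T", "A"))) {
    i <- which(!section %in% c("T", "A"))[1L]
    stop(sprintf("line %d: unknown section code '%s' (expected T or A)",
                 keep[i], section[i]))
  }
  start <- suppressWarnings(as.integer(get(3L)))
  end <- suppressWarnings(as.integer(get(4L)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1L]
    stop(sprintf("line %d: non-integer offsets", keep[i]))
  }
  if (any(start < 0L | start >= end)) {
    i <- which(start < 0L | start >= end)[1L]
    stop(sprintf("line %d: invalid span [%d, %d)", keep[i], start[i], end[i]))
  }
  entity_type <- if (all(n_fields >= 6L)) {
    vapply(parts, function(p) if (length(p) >= 6L) p[[6L]] else NA_character_,
           character(1))
  } else {
    vapply(parts, function(p) if (length(p) >= 6L) p[[6L]] else NA_character_,
           character(1))
  }
  data.frame(doc_id = get(1L), section = section, start = start, end = end,
             text = get(5L), entity_type = entity_type,
             stringsAsFactors = FALSE)
}

empty_mentions <- function() {
  data.frame(doc_id = character(), section = character(),
             start = integer(), end = integer(),
             text = character(), entity_type = character(),
             stringsAsFactors = FALSE)
}

#' Write ranked predictions with confidences
#'
#' Produces the submission dialect: one line per mention with fields
#' `doc_id`, `section:start:end`, a 1-based per-document rank in
#' descending confidence (ties broken by section, start, end), and the
#' confidence printed with five decimal places.
#'
#' @param mentions Data frame with columns `doc_id`, `section`, `start`,
#'   `end` and `confidence` (in \[0, 1\]).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(mentions, path) {
  required <- c("doc_id", "section", "start", "end", "confidence")
  missing_cols <- setdiff(required, names(mentions))
  if (length(missing_cols) > 0L) {
    stop("mentions is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(mentions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  conf <- mentions$confidence
  if (any(is.na(conf)) || any(conf < 0 | conf > 1)) {
    stop("confidences must lie in [0, 1]")
  }
  ord <- order(mentions$doc_id, -conf, mentions$section,
               mentions$start, mentions$end)
  m <- mentions[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(m)), m$doc_id, FUN = seq_along)
  lines <- sprintf("%s\t%s:%d:%d\t%d\t%.5f",
                   m$doc_id, m$section, m$start, m$end, rank, m$confidence)
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

## exact-span key used everywhere spans are compared as sets
span_key <- function(x) {
  paste(x$doc_id, x$section, x$start, x$end, sep = "\r")
}

#' Exact-span micro-averaged evaluation (CEM scoring)
#'
#' Gold and predicted mentions are compared on the key
#' (`doc_id`, `section`, `start`, `end`); entity types are ignored and
#' duplicates within either collection are collapsed.  Precision,
#' recall and F1 are micro-averaged with the 0/0 = 0 convention.
#'
#' @param gold,predicted Data frames of entity mentions (any data frame
#'   with `doc_id`, `section`, `start`, `end` columns).
#' @return An object of class `cem_evaluation`: a list with counts
#'   `true_positives`, `false_positives`, `false_negatives` and
#'   proportions `precision`, `recall`, `f1`.
#' @export
#' @examples
#' g <- data.frame(doc_id = "d", section = "A",
#'                 start = c(0L, 5L, 9L), end = c(3L, 8L, 12L))
#' evaluate_cem(g, g)$f1
evaluate_cem <- function(gold, predicted) {
  gk <- unique(span_key(gold))
  pk <- unique(span_key(predicted))
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  precision <- safe_ratio(tp, tp + fp)
  recall <- safe_ratio(tp, tp + fn)
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  structure(
    list(true_positives = tp, false_positives = fp, false_negatives = fn,
         precision = precision, recall = recall, f1 = f1),
    class = "cem_evaluation"
  )
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' @export
print.cem_evaluation <- function(x, ...) {
  cat(sprintf("CEM evaluation: TP=%d FP=%d FN=%d  P=%.5f R=%.5f F1=%.5f\n",
              x$true_positives, x$false_positives, x$false_negatives,
              x$precision, x$recall, x$f1))
  invisible(x)
}
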