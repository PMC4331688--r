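## The probabilistic ensemble combiner: pool span candidates from n
## extractors, estimate the 2^n - 1 conditional-precision parameters
## P(entity | E_1 .. E_n) on an annotated corpus, score candidates with
## them, threshold, and trace precision-recall curves.

#' Pool candidate spans from several extractors
#'
#' The candidate set is the union of all extractors' spans, compared on
#' the exact key (`doc_id`, `section`, `start`, `end`); overlapping but
#' unequal spans remain distinct candidates.  Each candidate carries a
#' signature: the vector of indicator bits, one per extractor, with bit
#' i set when extractor i predicted exactly that span.
#'
#' @param outputs Named list of span data frames (columns `doc_id`,
#'   `section`, `start`, `end`), one per extractor; the list order
#'   fixes the extractor order.
#' @return Data frame of candidates with a `signature` column (a bit
#'   string such as `"110"`), with attribute `extractors`.
#' @export
pool_candidates <- function(outputs) {
  if (length(outputs) == 0L) stop("at least one extractor output is required")
  if (is.null(names(outputs)) || any(!nzchar(names(outputs))) ||
      anyDuplicated(names(outputs))) {
    stop("outputs must be a named list with unique extractor names")
  }
  keys_by_ex <- lapply(outputs, function(o) unique(span_key(o)))
  all_keys <- unique(unlist(keys_by_ex, use.names = FALSE))
  spans <- do.call(rbind, lapply(outputs, function(o) {
    o[, c("doc_id", "section", "start", "end"), drop = FALSE]
  }))
  spans <- spans[!duplicated(span_key(spans)), , drop = FALSE]
  spans <- spans[match(all_keys, span_key(spans)), , drop = FALSE]
  bits <- vapply(keys_by_ex, function(k) as.integer(all_keys %in% k),
                 integer(length(all_keys)))
  bits <- matrix(bits, nrow = length(all_keys))
  signature <- if (length(all_keys) == 0L) {
    character()
  } else {
    apply(bits, 1L, paste, collapse = "")
  }
  out <- cbind(spans, data.frame(signature = signature,
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "extractors") <- names(outputs)
  out
}

all_signatures <- function(n) {
  grid <- expand.grid(rep(list(0:1), n))[-1L, rev(seq_len(n)), drop = FALSE]
  unname(apply(grid, 1L, paste, collapse = ""))
}

new_conditional_table <- function(extractors, cells) {
  structure(list(n = length(extractors), extractors = extractors,
                 cells = cells),
            class = "conditional_table")
}

#' Estimate the conditional-precision table from an annotated corpus
#'
#' For each of the 2^n - 1 non-zero signatures s, the probability that
#' a candidate with that signature is a true entity is estimated as the
#' precision of the derived extractor whose output is the intersection
#' of the firing extractors' span sets minus the union of the
#' non-firing ones: cells hold the candidate count, the gold-hit count,
#' and their ratio.  Signatures never realized on the corpus are kept
#' as cells with a missing probability.
#'
#' @param outputs Named list of extractor span data frames.
#' @param gold Gold span data frame.
#' @param smoothing Apply add-one smoothing `(hits + 1) / (candidates
#'   + 2)` to realized cells (off by default; raw precisions are
#'   reported).
#' @return An object of class `conditional_table`.
#' @export
estimate_table <- function(outputs, gold, smoothing = FALSE) {
  cands <- pool_candidates(outputs)
  if (nrow(cands) == 0L) stop("empty candidate pool: no extractor predicted anything")
  gk <- unique(span_key(gold))
  hit <- span_key(cands) %in% gk
  sig <- all_signatures(length(outputs))
  sig_f <- factor(cands$signature, levels = sig)
  candidates <- as.integer(table(sig_f))
  hits <- as.integer(tapply(as.integer(hit), sig_f, sum, default = 0L))
  probability <- ifelse(candidates > 0L,
                        if (smoothing) (hits + 1) / (candidates + 2)
                        else hits / pmax(candidates, 1L),
                        NA_real_)
  cells <- data.frame(signature = sig, candidates = candidates, hits = hits,
                      probability = probability, stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  new_conditional_table(names(outputs), cells)
}

#' @export
print.conditional_table <- function(x, ...) {
  cat(sprintf("Conditional-precision table over %d extractor(s) (%s): %d cells\n",
              x$n, paste(x$extractors, collapse = ", "), nrow(x$cells)))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Serialize a conditional table as tab-separated text
#'
#' One row per signature: one 0/1 column per extractor (named after
#' it), then `candidates`, `hits`, `probability` (empty for unrealized
#' cells).
#'
#' @param table A `conditional_table`.
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_conditional_table <- function(table, path) {
  stopifnot(inherits(table, "conditional_table"))
  bits <- do.call(rbind, strsplit(table$cells$signature, ""))
  df <- as.data.frame(apply(bits, 2L, as.integer, simplify = FALSE))
  names(df) <- table$extractors
  df$candidates <- table$cells$candidates
  df$hits <- table$cells$hits
  df$probability <- table$cells$probability
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_conditional_table
#' @export
read_conditional_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                          fileEncoding = "UTF-8")
  fixed <- c("candidates", "hits", "probability")
  extractors <- setdiff(names(df), fixed)
  if (length(extractors) == 0L || !all(fixed %in% names(df))) {
    stop("not a conditional-table file: ", path)
  }
  signature <- apply(df[, extractors, drop = FALSE], 1L, paste, collapse = "")
  cells <- data.frame(signature = signature,
                      candidates = as.integer(df$candidates),
                      hits = as.integer(df$hits),
                      probability = ifelse(df$candidates > 0L,
                                           df$hits / pmax(df$candidates, 1L),
                                           NA_real_),
                      stringsAsFactors = FALSE)
  new_conditional_table(extractors, cells)
}

#' Score pooled candidates with a conditional table
#'
#' Each candidate's confidence is the table probability of its
#' signature.  When the signature was never realized during estimation
#' the fallback policy applies: `"mean-single"` (the default) takes the
#' unweighted mean of the single-extractor probabilities of the firing
#' extractors, `"zero"` scores 0, `"error"` fails.
#'
#' @param candidates Data frame from [pool_candidates()] (its
#'   `extractors` attribute must match the table's extractor order).
#' @param table A `conditional_table`.
#' @param fallback Missing-cell policy.
#' @return The candidates with a `confidence` column.
#' @export
score_candidates <- function(candidates, table,
                             fallback = c("mean-single", "zero", "error")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(table, "conditional_table"))
  ex <- attr(candidates, "extractors")
  if (!identical(ex, table$extractors)) {
    stop("extractor order mismatch: candidates have (",
         paste(ex, collapse = ", "), "), table has (",
         paste(table$extractors, collapse = ", "), ")")
  }
  idx <- match(candidates$signature, table$cells$signature)
  conf <- table$cells$probability[idx]
  missing <- which(is.na(conf))
  if (length(missing) > 0L) {
    if (fallback == "error") {
      stop("signature ", candidates$signature[missing[1L]],
           " has no estimated probability")
    }
    if (fallback == "zero") {
      conf[missing] <- 0
    } else {
      single_sig <- vapply(seq_len(table$n), function(i) {
        bits <- rep("0", table$n)
        bits[i] <- "1"
        paste(bits, collapse = "")
      }, character(1))
      single_p <- table$cells$probability[match(single_sig,
                                                table$cells$signature)]
      for (k in missing) {
        firing <- which(strsplit(candidates$signature[k], "")[[1L]] == "1")
        p <- single_p[firing]
        p <- p[!is.na(p)]
        conf[k] <- if (length(p) > 0L) mean(p) else 0
      }
    }
  }
  candidates$confidence <- conf
  attr(candidates, "extractors") <- ex
  candidates
}

#' @rdname score_candidates
#' @param outputs Named list of extractor span data frames; pooled and
#'   scored in one step.
#' @export
ensemble_score <- function(outputs, table,
                           fallback = c("mean-single", "zero", "error")) {
  score_candidates(pool_candidates(outputs), table, fallback = fallback)
}

#' Retain candidates at or above a confidence threshold
#'
#' @param scored Data frame with a `confidence` column.
#' @param tau Threshold in \[0, 1\].
#' @return The retained rows.
#' @export
apply_threshold <- function(scored, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau > 1) {
    stop("tau must be a single number in [0, 1]")
  }
  out <- scored[scored$confidence >= tau, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision-recall curve over confidence thresholds
#'
#' Evaluates [apply_threshold()] at every distinct confidence value
#' plus 0 and 1, scoring each retained set against the gold spans with
#' exact-span micro-averaged precision/recall/F1.
#'
#' @param scored Scored candidates.
#' @param gold Gold span data frame.
#' @return Data frame with columns `tau`, `retained`, `precision`,
#'   `recall`, `f1`, sorted by `tau` ascending.
#' @export
pr_curve <- function(scored, gold) {
  taus <- sort(unique(c(0, 1, scored$confidence)))
  rows <- lapply(taus, function(tau) {
    kept <- apply_threshold(scored, tau)
    ev <- evaluate_cem(gold, kept)
    data.frame(tau = tau, retained = nrow(kept), precision = ev$precision,
               recall = ev$recall, f1 = ev$f1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
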