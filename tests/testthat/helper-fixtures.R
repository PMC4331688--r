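# shared fixture builders: everything is generated in code, nothing on disk

make_spans <- function(starts, doc_id = "d", section = "A", len = 1L) {
  data.frame(doc_id = doc_id, section = section,
             start = as.integer(starts), end = as.integer(starts) + len,
             stringsAsFactors = FALSE)
}

write_lines_tmp <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf, useBytes = TRUE)
  tf
}

# random small ensemble instance for oracle cross-checks: up to
# `max_extractors` extractors over a universe of `n_spans` spans
random_ensemble_instance <- function(max_extractors = 4L, n_spans = 50L) {
  n_ex <- sample(seq_len(max_extractors), 1L)
  universe <- make_spans(seq_len(n_spans) * 3L)
  outputs <- stats::setNames(lapply(seq_len(n_ex), function(i) {
    keep <- runif(n_spans) < runif(1L, 0.2, 0.8)
    universe[keep, , drop = FALSE]
  }), paste0("ex", seq_len(n_ex)))
  # guarantee a non-empty pool
  if (all(vapply(outputs, nrow, integer(1)) == 0L)) {
    outputs[[1L]] <- universe[1L, , drop = FALSE]
  }
  gold <- universe[runif(n_spans) < 0.5, , drop = FALSE]
  list(outputs = outputs, gold = gold)
}

# independent brute-force oracle: for signature s, materialize the
# derived extractor Y by explicit set intersection/difference and
# compute its precision on the gold set
oracle_cell_precision <- function(outputs, gold, signature) {
  keys <- lapply(outputs, function(o) {
    unique(paste(o$doc_id, o$section, o$start, o$end, sep = "\r"))
  })
  bits <- strsplit(signature, "")[[1L]] == "1"
  y <- Reduce(intersect, keys[bits])
  for (k in keys[!bits]) y <- setdiff(y, k)
  if (length(y) == 0L) return(NA_real_)
  gk <- unique(paste(gold$doc_id, gold$section, gold$start, gold$end,
                     sep = "\r"))
  mean(y %in% gk)
}
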