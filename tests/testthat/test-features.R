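test_that("soundex encodes the classic chemical family", {
  expect_equal(soundex("carbon", 3), "C615")
  expect_equal(soundex("carbonate", 7), "C6153")
  expect_equal(soundex("A", 7), "A")
  expect_equal(soundex("123"), "#")
  expect_equal(soundex(""), "#")
  expect_error(soundex("carbon", 0), "max_digits")

  # H/W transparency and adjacent-code collapse
  expect_equal(soundex("Ashcraft", 3), "A261")   # S and C collapse across H
  expect_equal(soundex("Pfister", 4), "P236")    # P/F collapse at word start
  expect_equal(soundex("Tymczak", 4), "T522")    # vowel separation keeps Z, K
})

test_that("soundex is case-insensitive and shape-constrained", {
  set.seed(31)
  for (i in 1:200) {
    w <- paste(sample(c(letters, LETTERS), sample(1:12, 1), replace = TRUE),
               collapse = "")
    code <- soundex(w)
    expect_identical(code, soundex(toupper(w)))
    expect_match(code, "^([A-Z][1-6]{0,7}|#)$")
  }
})

test_that("soundex codes are invariant to H/W deletion after the first letter", {
  set.seed(32)
  for (i in 1:200) {
    w <- paste(sample(letters, sample(3:10, 1), replace = TRUE), collapse = "")
    stripped <- paste0(substr(w, 1, 1), gsub("[hw]", "", substr(w, 2, nchar(w))))
    expect_identical(soundex(w), soundex(stripped))
  }
})

test_that("word_class maps characters and collapses runs idempotently", {
  expect_equal(unname(word_class("Ca(2+)")), c("Aax0xx", "Aax0x"))
  expect_equal(unname(word_class("carbon")), c("aaaaaa", "a"))
  expect_equal(unname(word_class("")), c("", ""))
  set.seed(33)
  for (i in 1:50) {
    w <- paste(sample(c(letters, LETTERS, 0:9, "+", "-", "("),
                      sample(1:10, 1), replace = TRUE), collapse = "")
    brief <- word_class(w)[["brief"]]
    expect_identical(gsub("(.)\\1+", "\\1", brief), brief)
  }
})

test_that("token_features emits the documented shape and n-gram keys", {
  f <- token_features("CO2")
  expect_true("shape=formula" %in% f)   # no two consecutive lowercase
  expect_true("shape=digit" %in% f)
  expect_true("shape=allcaps" %in% f)
  expect_true(all(c("ng2=CO", "ng2=O2") %in% f))
  expect_true("word=CO2" %in% f)
  expect_true("lower=co2" %in% f)
  expect_false("bos" %in% f)

  f <- token_features("Methanol")
  expect_false("shape=formula" %in% f)  # "th" is two consecutive lowercase
  expect_true("shape=initcap" %in% f)
  expect_true("shape=mixed" %in% f)

  f <- token_features("carbon", sentence_start = TRUE)
  expect_true("bos" %in% f)
  expect_true("lower=carbon" %in% f)
  expect_true("soundex=C615" %in% f)    # default length 7 gives C615 here too

  # ablations remove their families
  f <- token_features("carbon", config = feature_config(use_soundex = FALSE,
                                                        use_nlp = FALSE))
  expect_false(any(startsWith(f, "soundex=")))
  expect_false(any(startsWith(f, "wc")))

  # determinism
  expect_identical(token_features("Ca(2+)"), token_features("Ca(2+)"))
})

test_that("cluster features fire only for mapped terms", {
  map <- cluster_map(c(Tetralinoleoyl = 8L, methanol = 3L), k = 1000L)
  expect_equal(cluster_feature("Tetralinoleoyl", map), "cluster=8")
  expect_equal(cluster_feature("Methanol", map), "cluster=3")  # lowercase fallback
  expect_length(cluster_feature("xyzzy", map), 0L)
  empty <- cluster_map(stats::setNames(integer(), character()), k = 10L)
  expect_length(cluster_feature("anything", empty), 0L)

  tf <- tempfile()
  writeLines(c("Tetralinoleoyl\t8", "thiophosphocholine\t8", "Vav\t10"), tf)
  m2 <- read_cluster_map(tf)
  expect_equal(cluster_feature("Vav", m2), "cluster=10")
})

test_that("gazetteer lookups cover token, full-run, affix and boost modes", {
  g <- gazetteer("main", c("acetic acid", "methanol"))
  f <- gazetteer_features(c("acetic", "acid"), 1L, list(g))
  expect_setequal(f, c("in_main", "in_main_full"))
  f <- gazetteer_features(c("acetic", "salt"), 1L, list(g))
  expect_equal(f, "in_main")   # token member but no full entry run
  expect_length(gazetteer_features("xyzzy", 1L, list(g)), 0L)

  sfx <- gazetteer("suff", c("yl", "ane"), match_mode = "suffix")
  expect_equal(gazetteer_features("methyl", 1L, list(sfx)), "sfx_suff")
  pfx <- gazetteer("pref", "meth", match_mode = "prefix")
  expect_equal(gazetteer_features("methyl", 1L, list(pfx)), "pfx_pref")

  boost <- gazetteer("boost", "CO2", boost = TRUE)
  expect_equal(gazetteer_features("CO2", 1L, list(boost)), "boost")

  expect_error(gazetteer("empty", character()), "no entries")
  expect_error(gazetteer_features(c("a", "b"), 3L, list(g)), "range")
})

test_that("assemble_features windows neighbor families by configured width", {
  toks <- data.frame(surface = c("We", "measured", "CO2"),
                     start = c(0L, 3L, 12L), end = c(2L, 11L, 15L))
  fs <- assemble_features(toks)
  # middle token: word family has width 2 but only offsets -1/+1 exist
  expect_true("word[-1]=We" %in% fs[[2]])
  expect_true("word[+1]=CO2" %in% fs[[2]])
  expect_true("word[+2]=CO2" %in% fs[[1]])
  # soundex has window 0: never offset-tagged
  expect_false(any(grepl("^soundex\\[", unlist(fs))))
  # first token of the sentence carries bos, neighbors do not inherit it
  expect_true("bos" %in% fs[[1]])
  expect_false(any(grepl("^bos\\[", unlist(fs))))

  one <- assemble_features(toks[1, ])
  expect_false(any(grepl("\\[", one[[1]])))

  cfg <- feature_config(windows = list(word = 0L))
  fs0 <- assemble_features(toks, config = cfg)
  expect_false(any(grepl("\\[", unlist(fs0))))
})

test_that("BIO labeling and decoding honor alignment and round-trip", {
  toks <- data.frame(surface = c("acetic", "acid", "reacts"),
                     start = c(0L, 7L, 12L), end = c(6L, 11L, 18L))
  m <- data.frame(start = 0L, end = 11L)
  labels <- label_bio(toks, m)
  expect_equal(as.vector(labels), c("B", "I", "O"))

  expect_equal(as.vector(label_bio(toks, m[0, ])), c("O", "O", "O"))

  # mention cutting a token in half is skipped and counted
  bad <- data.frame(start = 0L, end = 3L)
  expect_warning(labels <- label_bio(toks, bad), "not aligned")
  expect_equal(as.vector(labels), c("O", "O", "O"))
  expect_equal(attr(labels, "misaligned"), 1L)

  expect_error(label_bio(toks, data.frame(start = c(0L, 5L),
                                          end = c(11L, 18L))),
               "overlapping")

  text <- "acetic acid reacts"
  dec <- decode_bio(toks, c("B", "I", "O"), text = text)
  expect_equal(dec$text, "acetic acid")
  expect_equal(dec$start, 0L)
  expect_equal(dec$end, 11L)
  # stray I is promoted to B
  dec <- decode_bio(toks, c("O", "I", "O"), text = text)
  expect_equal(dec$text, "acid")
  expect_equal(nrow(decode_bio(toks, c("O", "O", "O"))), 0L)
  expect_error(decode_bio(toks, c("O", "O")), "length")
})

test_that("decode_bio(label_bio(.)) reproduces aligned gold spans", {
  for (seed in 1:5) {
    corpus <- gen_corpus(n_docs = 4, seed = seed)
    docs <- corpus$documents
    for (i in seq_len(nrow(docs))) {
      for (section in c("T", "A")) {
        text <- if (section == "T") docs$title[i] else docs$abstract[i]
        toks <- tokenize(text)
        gold <- corpus$gold[corpus$gold$doc_id == docs$doc_id[i] &
                              corpus$gold$section == section, ]
        labels <- label_bio(toks, gold)
        expect_equal(attr(labels, "misaligned"), 0L)
        dec <- decode_bio(toks, as.vector(labels), text = text)
        expect_setequal(paste(dec$start, dec$end),
                        paste(gold$start, gold$end))
        if (nrow(gold) > 0L) {
          expect_setequal(dec$text, gold$text)
        }
      }
    }
  }
})
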