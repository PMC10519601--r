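test_that("tokenizer applies the stated rules", {
  expect_equal(tokenize("I love it!"), c("i", "love", "it"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("Don't worry — I'm fine."),
               c("don't", "worry", "i'm", "fine"))
  expect_equal(tokenize("I counted 42 things"), c("i", "counted", "42", "things"))
  expect_equal(tokenize("... !!! ---"), character(0))
})

test_that("score_text computes category percentages with wildcard matching", {
  lex <- default_lexicon()
  s <- score_text("I am worried", lex)
  expect_equal(s$wc, 3L)
  expect_equal(s$anxiety, 100 / 3, tolerance = 1e-12)
  expect_equal(s$i, 100 / 3, tolerance = 1e-12)
  expect_equal(s$posemo + s$anger + s$sadness, 0)

  # 200-token text with posemo words at exactly 25 positions
  toks <- rep("the", 200)
  toks[seq(1, 200, by = 8)] <- "sweet"
  s <- score_text(paste(toks, collapse = " "), lex)
  expect_equal(s$wc, 200L)
  expect_equal(s$posemo, 12.5)

  # no dictionary tokens
  s0 <- score_text("table chair window", lex)
  expect_equal(unlist(s0[c("posemo", "anxiety", "anger", "sadness", "i")]),
               c(posemo = 0, anxiety = 0, anger = 0, sadness = 0, i = 0))
  # empty text: wc 0, all scores 0
  se <- score_text("", lex)
  expect_equal(se$wc, 0L)
  expect_equal(se$posemo, 0)
})

test_that("a token may hit several categories but once per category", {
  lex <- affect_lexicon(list(posemo = c("bittersweet"), anxiety = c("bitter*"),
                             anger = c("x"), sadness = c("bittersweet", "bitter*"),
                             i = c("i")), version = "overlap")
  s <- score_text("bittersweet", lex)
  expect_equal(s$posemo, 100)
  expect_equal(s$anxiety, 100)
  expect_equal(s$sadness, 100) # two matching entries, counted once
})

test_that("concatenation score is the wc-weighted mean of part scores", {
  lex <- default_lexicon()
  set.seed(11)
  for (rep in 1:20) {
    a <- random_text(sample(5:60, 1))
    b <- random_text(sample(5:60, 1))
    sa <- score_text(a, lex); sb <- score_text(b, lex)
    sc <- score_text(paste(a, b), lex)
    expect_equal(sc$wc, sa$wc + sb$wc)
    for (cat in c("posemo", "anxiety", "anger", "sadness", "i")) {
      expect_equal(sc[[cat]],
                   (sa[[cat]] * sa$wc + sb[[cat]] * sb$wc) / (sa$wc + sb$wc),
                   tolerance = 1e-12)
    }
  }
})

test_that("scorer agrees exactly with the brute-force matcher", {
  lex <- default_lexicon()
  set.seed(23)
  for (rep in 1:200) {
    txt <- random_text(50)
    fast <- score_text(txt, lex)
    slow <- brute_force_score(txt, lex)
    expect_identical(fast$wc, as.integer(slow$wc))
    for (cat in c("posemo", "anxiety", "anger", "sadness", "i")) {
      expect_identical(fast[[cat]], slow[[cat]])
    }
  }
})

test_that("word-count filter keeps exactly the >= 25-word posts", {
  scored <- tibble::tibble(id = c("a", "b", "c"), wc = c(25L, 24L, 400L))
  kept <- filter_min_words(scored)
  expect_equal(kept$id, c("a", "c"))
  expect_equal(nrow(filter_min_words(scored[0, ])), 0L)
})

test_that("read_dic parses the %-delimited dialect", {
  f <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tposemo", "2\tanx", "3\tanger", "4\tsad", "5\ti",
               "%", "happy\t1", "worri*\t2", "hate\t3", "sad\t4", "i\t5",
               "me\t5"), f)
  lex <- read_dic(f)
  expect_s3_class(lex, "affect_lexicon")
  expect_equal(lex$entries$anxiety, "worri*")
  expect_equal(sort(lex$entries$i), c("i", "me"))
  s <- score_text("I am worried", lex)
  expect_equal(s$anxiety, 100 / 3, tolerance = 1e-12)

  # extra categories are ignored with a message
  g <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tposemo", "2\tanx", "3\tanger", "4\tsad", "5\ti",
               "99\tcogproc", "%", "happy\t1\t99", "worri*\t2", "hate\t3",
               "sad\t4", "i\t5", "think\t99"), g)
  expect_message(lex2 <- read_dic(g), "ignoring")
  expect_equal(lex2$entries$posemo, "happy")

  # undeclared id is an error
  h <- withr::local_tempfile(fileext = ".dic")
  writeLines(c("%", "1\tposemo", "2\tanx", "3\tanger", "4\tsad", "5\ti",
               "%", "happy\t99", "worri*\t2", "hate\t3", "sad\t4", "i\t5"), h)
  expect_error(read_dic(h), "undeclared")
})

test_that("lexicon constructor enforces its invariants", {
  expect_error(affect_lexicon(list(posemo = "good")), "missing")
  expect_error(affect_lexicon(list(posemo = "Good", anxiety = "a", anger = "b",
                                   sadness = "c", i = "i")), "lower-case")
  expect_error(affect_lexicon(list(posemo = "go*od", anxiety = "a", anger = "b",
                                   sadness = "c", i = "i")), "final position")
})
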