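test_that("bracketed tree files read record by record, skipping empties", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("(S (NP Mary) (VP eats))", "", "(X a)"), f)
  trees <- read_bracketed_trees(f)
  expect_length(trees, 2L)
  expect_equal(tree_terminals(trees[[1]]), c("Mary", "eats"))
  expect_equal(tree_terminals(trees[[2]]), "a")
})

test_that("a record may span several lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("(S (NP Mary)", "   (VP eats))", "(X a)"), f)
  trees <- read_bracketed_trees(f)
  expect_length(trees, 2L)
  expect_equal(tree_length(trees[[1]]), 2L)
})

test_that("unbalanced records raise an error naming the record", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("(S (NP Mary) (VP eats))", "((S a)"), f)
  expect_error(read_bracketed_trees(f), "record 2")
})

test_that("tree write/read round-trips through files", {
  corpus <- random_corpus(20)
  f <- withr::local_tempfile(fileext = ".txt")
  write_bracketed_trees(corpus$trees, f)
  back <- read_bracketed_trees(f)
  expect_length(back, 20L)
  for (i in seq_along(back)) {
    expect_identical(tree_nodes(back[[i]]), tree_nodes(corpus$trees[[i]]))
  }
})

test_that("CoNLL-U reading keeps heads, ignores comments and ranges", {
  f <- withr::local_tempfile(fileext = ".conllu")
  writeLines(c(
    "# sent_id = 1",
    "1\tMary\t_\t_\t_\t_\t2\tnsubj\t_\t_",
    "2\teats\t_\t_\t_\t_\t0\troot\t_\t_",
    "2-3\teats.apples\t_\t_\t_\t_\t_\t_\t_\t_",
    "3\tapples\t_\t_\t_\t_\t2\tobj\t_\t_",
    "4\tdaily\t_\t_\t_\t_\t2\tadvmod\t_\t_",
    ""), f)
  deps <- read_dependency(f)
  expect_length(deps, 1L)
  expect_equal(deps[[1]]$head, c(2L, 0L, 2L, 2L))
  expect_equal(dependency_heads(deps[[1]]), 1L)  # 0-based: "eats"
})

test_that("dependency format errors are caught", {
  f <- withr::local_tempfile(fileext = ".conllu")
  writeLines(c("1\ta\t_\t_\t_\t_\t0\troot\t_\t_",
               "2\tb\t_\t_\t_\t_\t0\troot\t_\t_", ""), f)
  expect_error(read_dependency(f), "exactly one root")
  writeLines(c("1\ta\t_\t_\t_\t_\t1\tdep\t_\t_", ""), f)
  expect_error(read_dependency(f), "own head")
  writeLines(c("1\ta\t_\t_\t_\t_\t5\tdep\t_\t_", ""), f)
  expect_error(read_dependency(f), "out of range")
})

test_that("dependency write/read round-trips", {
  corpus <- random_corpus(15)
  f <- withr::local_tempfile(fileext = ".conllu")
  write_dependency(corpus$deps, f)
  back <- read_dependency(f)
  expect_length(back, 15L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$head, corpus$deps[[i]]$head)
    expect_equal(back[[i]]$form, corpus$deps[[i]]$form)
  }
})

test_that("timing tables validate and order rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tonset\toffset", "so\t12.10\t12.31", "then\t13.0\t13.2"), f)
  tt <- read_word_timings(f)
  expect_equal(tt$onset, c(12.10, 13.0))
  expect_equal(tt$word, c("so", "then"))

  writeLines(c("word\tonset\toffset", "b\t13.0\t13.2", "a\t12.1\t12.3"), f)
  expect_warning(tt <- read_word_timings(f), "reordered")
  expect_equal(tt$word, c("a", "b"))

  writeLines(c("word\tonset\toffset", "a\t12.1\t11.9"), f)
  expect_error(read_word_timings(f), "offset < onset")

  writeLines(c("word\tonset", "a\t12.1"), f)
  expect_error(read_word_timings(f), "missing column")
})

test_that("pause-based segmentation inserts a boundary at a long pause", {
  # a 2.6 s silence after "because" splits the sentence at threshold 1.0
  tt <- data.frame(
    word = c("suspicious", "because", "they're", "they", "have"),
    onset = c(10.0, 10.6, 13.8, 15.1, 15.4),
    offset = c(10.5, 11.2, 14.2, 15.3, 15.6),
    sentence_id = 0L, recall_id = "r1")
  seg <- segment_sentences(tt, pause_threshold = 1.0)
  expect_equal(seg$sentence_id, c(0L, 0L, 1L, 1L, 1L))
  # "they" follows a 0.9 s pause: below threshold, no extra boundary
  seg05 <- segment_sentences(tt, pause_threshold = 0.5)
  expect_equal(seg05$sentence_id, c(0L, 0L, 1L, 2L, 2L))
})

test_that("segmentation preserves existing boundaries and is idempotent", {
  tt <- data.frame(word = letters[1:6],
                   onset = c(0, 0.4, 0.8, 1.2, 1.6, 2.0),
                   offset = c(0.3, 0.7, 1.1, 1.5, 1.9, 2.3),
                   sentence_id = c(0L, 0L, 0L, 1L, 1L, 1L),
                   recall_id = "r1")
  seg <- segment_sentences(tt, pause_threshold = 1.0)
  expect_equal(seg$sentence_id, tt$sentence_id)  # gaps all 0.1 s
  expect_equal(segment_sentences(seg, 1.0)$sentence_id, seg$sentence_id)
  # without respecting prior ids, all six words fuse into one sentence
  expect_equal(segment_sentences(tt, 1.0, respect_existing = FALSE)$sentence_id,
               rep(0L, 6))
})

test_that("segmentation sentence count matches a brute-force gap scan", {
  set.seed(11)
  cfg <- simulation_config()
  corpus <- random_corpus(40)
  tm <- simulate_timings(corpus, cfg)
  for (thr in c(0.05, 0.3, 1.0)) {
    seg <- segment_sentences(tm, thr, respect_existing = FALSE)
    gaps <- tm$onset[-1] - tm$offset[-nrow(tm)]
    expect_equal(max(seg$sentence_id) + 1L, 1L + sum(gaps >= thr))
  }
})

test_that("empty timing input segments to empty output", {
  tt <- data.frame(word = character(0), onset = numeric(0),
                   offset = numeric(0))
  expect_equal(nrow(segment_sentences(tt, 1.0)), 0L)
})

test_that("ROI timeseries reading enforces integrity", {
  f <- withr::local_tempfile(fileext = ".tsv")
  base <- expand.grid(participant = c("p1", "p2"), roi = c("BA44", "BA45"),
                      tr_index = 0:9, stringsAsFactors = FALSE)
  base$value <- seq_len(nrow(base)) * 0.1
  utils::write.table(base, f, sep = "\t", quote = FALSE, row.names = FALSE)
  x <- read_roi_timeseries(f)
  expect_equal(nrow(x), 40L)
  expect_equal(attr(x, "tr"), 1.5)

  utils::write.table(rbind(base, base[1, ]), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_roi_timeseries(f), "duplicated")

  utils::write.table(base[base$tr_index != 5, ], f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_roi_timeseries(f), "gap")

  bad <- base; bad$value <- "x"
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_roi_timeseries(f), "numeric")
})
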