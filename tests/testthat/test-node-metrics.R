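test_that("the worked four-word sentence yields the published count vectors", {
  tr <- t1_tree()
  expect_equal(as.integer(top_down_counts(tr)), c(2L, 2L, 1L, 1L))
  expect_equal(as.integer(bottom_up_counts(tr)), c(1L, 0L, 2L, 3L))
  expect_equal(as.integer(left_corner_counts(tr)), c(2L, 1L, 2L, 1L))
  expect_equal(as.integer(open_node_counts(tr)), c(1L, 3L, 2L, 0L))
  expect_equal(as.integer(early_top_down_counts(tr)), c(4L, 1L, 1L, 0L))
  expect_equal(as.integer(chunked_counts(tr, t1_dep())), c(4L, 2L, 0L, 0L))
})

test_that("top-down counts the node dominating 'daily' already at 'eats'", {
  # the outer VP spans eats..daily; its top-down attribution is word 1
  nodes <- countable_nodes(t1_tree())
  vp_outer <- nodes[nodes$label == "VP" & nodes$end == 4L, ]
  expect_equal(vp_outer$start, 1L)
  td <- top_down_counts(t1_tree())
  expect_gte(td[2L], 2L)  # eats opens both VPs
})

test_that("countable nodes honour the POS-layer convention", {
  expect_equal(nrow(countable_nodes(t1_tree(), FALSE)), 6L)
  expect_equal(nrow(countable_nodes(t1_tree(), TRUE)), 6L)
  pos <- parse_bracketed(t1_pos_bracketing)
  expect_equal(nrow(countable_nodes(pos, FALSE)), 6L)
  expect_equal(nrow(countable_nodes(pos, TRUE)), 10L)
  # degenerate single-terminal tree: the root counts even though it is
  # preterminal-shaped
  expect_equal(nrow(countable_nodes(parse_bracketed("(X a)"), FALSE)), 1L)
})

test_that("branching chains follow the closed-form count patterns", {
  n <- 7L
  rc <- right_chain(n)  # (X1 w1 (X2 w2 (... wn)))
  td_r <- as.integer(top_down_counts(rc))
  # right-branching: one new node opens per word, nothing at the last word
  expect_equal(td_r, c(rep(1L, n - 1L), 0L))
  bu_r <- as.integer(bottom_up_counts(rc))
  # and every node closes only at the last word
  expect_equal(bu_r, c(rep(0L, n - 1L), n - 1L))

  lc <- left_chain(n)
  td_l <- as.integer(top_down_counts(lc))
  # left-branching: every span starts at word 0
  expect_equal(td_l, c(n - 1L, rep(0L, n - 1L)))
  bu_l <- as.integer(bottom_up_counts(lc))
  expect_equal(bu_l, c(0L, rep(1L, n - 1L)))
})

test_that("branching direction shapes where node-building mass falls", {
  for (n in c(3L, 5L, 9L, 15L)) {
    # left-branching opens everything at once: cumulative top-down mass
    # dominates; right-branching defers all closures to the sentence end,
    # so its open-nodes load dominates
    cum_l <- cumsum(top_down_counts(left_chain(n)))
    cum_r <- cumsum(top_down_counts(right_chain(n)))
    expect_true(all(cum_l >= cum_r))
    expect_gt(sum(cum_l - cum_r), 0)
    # both chains carry the same total open-node load, but right-branching
    # accumulates it toward the end while left-branching unwinds from a
    # front-loaded peak
    open_r <- as.integer(open_node_counts(right_chain(n)))
    open_l <- as.integer(open_node_counts(left_chain(n)))
    expect_equal(sum(open_r), sum(open_l))
    expect_true(all(diff(open_r[-n]) >= 0L))
    expect_true(all(diff(open_l) <= 0L))
    expect_equal(max(open_l), open_l[1L])
  }
})

test_that("all strategies conserve the countable-node total", {
  corpus <- random_corpus(200)
  for (i in seq_along(corpus$trees)) {
    tr <- corpus$trees[[i]]
    total <- nrow(countable_nodes(tr))
    expect_equal(sum(top_down_counts(tr)), total)
    expect_equal(sum(bottom_up_counts(tr)), total)
    expect_equal(sum(left_corner_counts(tr)), total)
    expect_equal(sum(early_top_down_counts(tr)), total)
    expect_equal(sum(chunked_counts(tr, corpus$deps[[i]])), total)
  }
})

test_that("incremental implementations match the span oracle", {
  corpus <- random_corpus(200)
  for (tr in corpus$trees) {
    expect_equal(as.integer(top_down_counts(tr)), span_oracle(tr, "top_down"))
    expect_equal(as.integer(bottom_up_counts(tr)), span_oracle(tr, "bottom_up"))
    expect_equal(as.integer(left_corner_counts(tr)),
                 span_oracle(tr, "left_corner"))
  }
  # and with preterminals counted, on POS-layered trees
  pos <- parse_bracketed(t1_pos_bracketing)
  for (s in c("top_down", "bottom_up", "left_corner")) {
    f <- switch(s, top_down = top_down_counts, bottom_up = bottom_up_counts,
                left_corner = left_corner_counts)
    expect_equal(as.integer(f(pos, TRUE)), span_oracle(pos, s, TRUE))
  }
})

test_that("open nodes equal cumulative opened minus closed and end at zero", {
  corpus <- random_corpus(200)
  for (tr in corpus$trees) {
    op <- as.integer(open_node_counts(tr))
    td <- cumsum(top_down_counts(tr))
    bu <- cumsum(bottom_up_counts(tr))
    expect_equal(op, as.integer(td - bu))
    expect_true(all(op >= 0L))
    expect_equal(op[length(op)], 0L)
  }
})

test_that("open nodes before closure differ by the closures at the word", {
  tr <- t1_tree()
  after <- as.integer(open_node_counts(tr, timing = "after"))
  before <- as.integer(open_node_counts(tr, timing = "before"))
  expect_equal(before - after, as.integer(bottom_up_counts(tr)))
})

test_that("early top-down shifts counts one word earlier and conserves mass", {
  corpus <- random_corpus(100)
  for (tr in corpus$trees) {
    td <- as.integer(top_down_counts(tr))
    etd <- as.integer(early_top_down_counts(tr))
    n <- length(td)
    expect_equal(sum(etd), sum(td))
    expect_equal(etd[n], 0L)
    if (n > 1L) expect_equal(etd[1L], td[1L] + td[2L])
    if (n > 2L) expect_equal(etd[2:(n - 1L)], td[3:n])
  }
  single <- parse_bracketed("(S (X a))")
  expect_equal(as.integer(early_top_down_counts(single)),
               as.integer(top_down_counts(single)))
})

test_that("chunked counts live only on the first word and heads", {
  corpus <- random_corpus(100)
  for (i in seq_along(corpus$trees)) {
    tr <- corpus$trees[[i]]
    dep <- corpus$deps[[i]]
    v <- as.integer(chunked_counts(tr, dep))
    allowed <- unique(c(0L, dependency_heads(dep)))
    expect_true(all((which(v > 0L) - 1L) %in% allowed))
    # sentence-final word carries 0 unless it is itself word 0 or a head
    n <- length(v)
    if (!((n - 1L) %in% allowed)) expect_equal(v[n], 0L)
  }
})

test_that("chunked counting handles degenerate head layouts", {
  # complete POS layer: only the root S is countable, total mass 1
  tr <- parse_bracketed("(S (X a) (Y b) (Z c))")
  # token 1 ("a") heads the other two -> head set {0}; all mass at word 0
  dep_a <- list(form = c("a", "b", "c"), head = c(0L, 1L, 1L),
                relation = c("root", "dep", "dep"))
  expect_equal(as.integer(chunked_counts(tr, dep_a)), c(1L, 0L, 0L))
  # no heads at all (each token a root-chain with no dependents modelled):
  # everything folds to word 0
  dep_none <- list(form = c("a", "b", "c"), head = c(0L, 0L, 0L),
                   relation = c("root", "root", "root"))
  expect_equal(as.integer(chunked_counts(tr, dep_none)), c(1L, 0L, 0L))
  # without the POS layer all four nodes count and land on word 0
  tr2 <- parse_bracketed("(S (X a b) (Y c))")
  expect_equal(sum(chunked_counts(tr2, dep_none)), 3L)
  # token-count mismatch is an alignment error
  expect_error(chunked_counts(tr, t1_dep()), "mismatch")
})

test_that("node_count_table aggregates all strategies per word", {
  corpus <- random_corpus(25)
  tab <- node_count_table(corpus$trees, corpus$deps)
  expect_equal(nrow(tab), sum(vapply(corpus$trees, tree_length, numeric(1))))
  for (i in seq_along(corpus$trees)) {
    sub <- tab[tab$sentence_id == i - 1L, ]
    expect_equal(sub$top_down, as.integer(top_down_counts(corpus$trees[[i]])))
    expect_equal(sub$chunked,
                 as.integer(chunked_counts(corpus$trees[[i]], corpus$deps[[i]])))
    expect_equal(sub$open_nodes,
                 as.integer(open_node_counts(corpus$trees[[i]])))
    expect_equal(sub$early_top_down,
                 as.integer(early_top_down_counts(corpus$trees[[i]])))
    expect_equal(sub$left_corner,
                 as.integer(left_corner_counts(corpus$trees[[i]])))
  }
  expect_error(node_count_table(corpus$trees, NULL, strategies = "chunked"),
               "requires dependency")
})
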