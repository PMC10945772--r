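#' Countable nodes of a parse tree
#'
#' Enumerates the nonterminal nodes that the incremental complexity metrics
#' count. By default part-of-speech-level nodes are excluded: when the tree
#' has a complete POS layer (every terminal wrapped in a unary preterminal,
#' as in standard treebank output), those unary wrappers are dropped; the
#' root is always kept. Trees without a full POS layer — e.g. bracketings
#' that attach words directly to phrasal nodes — have no POS layer to drop,
#' so every nonterminal counts.
#'
#' @param tree A [parse_tree].
#' @param count_preterminals Count POS-level nodes too (default FALSE).
#' @return Data.frame of countable nodes (subset of [tree_nodes()]).
#' @export
countable_nodes <- function(tree, count_preterminals = FALSE) {
  nodes <- tree_nodes(tree)
  if (!count_preterminals && has_pos_layer(tree)) {
    nodes <- nodes[!nodes$is_preterminal | nodes$is_root, , drop = FALSE]
  }
  rownames(nodes) <- NULL
  nodes
}

metric_vector <- function(pos, n, strategy, count_preterminals) {
  v <- tabulate(pos + 1L, nbins = n)
  structure(v, strategy = strategy, count_preterminals = count_preterminals)
}

#' Top-down node counts
#'
#' Counts, at each word, the nodes built when the parser works from the top
#' of the tree toward the terminal: a node is counted when its phrase is
#' opened, i.e. attributed to the leftmost terminal of its span. This is the
#' maximally predictive strategy — a node dominating later material is
#' counted as soon as its first word arrives.
#'
#' @param tree A [parse_tree].
#' @param count_preterminals Count POS-level nodes (default FALSE).
#' @return Integer vector, one entry per word; entries sum to the number of
#'   countable nodes.
#' @examples
#' t1 <- parse_bracketed("(S (NP Mary) (VP (VP eats (NP apples)) (ADVP daily)))")
#' top_down_counts(t1)   # 2 2 1 1
#' @export
top_down_counts <- function(tree, count_preterminals = FALSE) {
  nodes <- countable_nodes(tree, count_preterminals)
  metric_vector(nodes$start, tree_length(tree), "top_down", count_preterminals)
}

#' Bottom-up node counts
#'
#' Counts, at each word, the nodes whose daughters have all been met: a node
#' is counted when its phrase is closed, i.e. attributed to the rightmost
#' terminal of its span. Load therefore concentrates at ends of clauses and
#' sentences.
#'
#' @inheritParams top_down_counts
#' @return Integer vector per word.
#' @export
bottom_up_counts <- function(tree, count_preterminals = FALSE) {
  nodes <- countable_nodes(tree, count_preterminals)
  metric_vector(nodes$end - 1L, tree_length(tree), "bottom_up",
                count_preterminals)
}

#' Left-corner node counts
#'
#' A node is announced when its leftmost daughter is complete — attributed
#' to the terminal at which the first daughter's span ends (for a terminal
#' or preterminal first daughter, that word itself). Intermediate between
#' top-down (needs no evidence beyond the first word) and bottom-up (needs
#' all daughters).
#'
#' @inheritParams top_down_counts
#' @return Integer vector per word.
#' @export
left_corner_counts <- function(tree, count_preterminals = FALSE) {
  nodes <- countable_nodes(tree, count_preterminals)
  metric_vector(nodes$first_child_end - 1L, tree_length(tree), "left_corner",
                count_preterminals)
}

#' Open-nodes working-memory load
#'
#' Number of nodes opened up to (and including) each word that have not yet
#' been closed — the running difference between cumulative top-down and
#' cumulative bottom-up counts. With `timing = "after"` (default) closures
#' at the word are subtracted first, so the final word of a complete
#' sentence carries 0; `timing = "before"` measures load as the word is
#' presented, before its closures apply.
#'
#' @inheritParams top_down_counts
#' @param timing `"after"` (default) or `"before"` closures at the word.
#' @return Integer vector per word, all entries >= 0.
#' @export
open_node_counts <- function(tree, count_preterminals = FALSE,
                             timing = c("after", "before")) {
  timing <- match.arg(timing)
  td <- cumsum(top_down_counts(tree, count_preterminals))
  bu <- cumsum(bottom_up_counts(tree, count_preterminals))
  v <- if (timing == "after") td - bu else td - c(0L, bu[-length(bu)])
  structure(as.integer(v), strategy = "open_nodes",
            count_preterminals = count_preterminals, timing = timing)
}

#' Early top-down node counts (production-specific)
#'
#' Attributes each word's top-down nodes to the preceding word, reflecting
#' grammatical encoding that precedes articulation: at the first word the
#' nodes for the first and second word are counted (rather than positing
#' unobserved pre-sentence events); at word w the nodes for word w+1; the
#' final word carries 0. A single-word sentence equals its top-down vector.
#'
#' @inheritParams top_down_counts
#' @return Integer vector per word; same total as top-down.
#' @export
early_top_down_counts <- function(tree, count_preterminals = FALSE) {
  td <- top_down_counts(tree, count_preterminals)
  structure(shift_early(as.integer(td)), strategy = "early_top_down",
            count_preterminals = count_preterminals)
}

shift_early <- function(td) {
  n <- length(td)
  if (n == 1L) return(td)
  v <- integer(n)
  v[1L] <- td[1L] + td[2L]
  if (n > 2L) v[2:(n - 1L)] <- td[3:n]
  v
}

#' Heads of a dependency parse
#'
#' A head is any token with at least one dependent (e.g. the verb heading
#' its subject and object). Returned as 0-based token positions.
#'
#' @param dep Dependency parse (`head` field: 1-based head per token, 0 =
#'   root), as returned by [read_dependency()].
#' @return Sorted integer vector of 0-based head positions.
#' @export
dependency_heads <- function(dep) {
  h <- dep$head
  sort(unique(h[h > 0L])) - 1L
}

#' Chunked (head-driven) node counts (production-specific)
#'
#' A less incremental generation strategy: all nodes of the constituent
#' structure from the first word up to and including the first dependency
#' head are attributed to the first word; the nodes of each following
#' head-delimited chunk (after head k, up to and including head k+1) to head
#' k; nodes after the last head are attributed to the last head, preserving
#' the total. Non-initial non-head words — sentence-final words in
#' particular — carry 0.
#'
#' @param tree A [parse_tree].
#' @param dep Dependency parse for the same sentence (token counts must
#'   match).
#' @param count_preterminals Count POS-level nodes (default FALSE).
#' @return Integer vector per word; same total as top-down.
#' @export
chunked_counts <- function(tree, dep, count_preterminals = FALSE) {
  n <- tree_length(tree)
  if (length(dep$head) != n) {
    stop(sprintf("token count mismatch: tree has %d terminals, dependency parse %d",
                 n, length(dep$head)))
  }
  td <- top_down_counts(tree, count_preterminals)
  structure(chunk_attribute(as.integer(td), dependency_heads(dep), n),
            strategy = "chunked", count_preterminals = count_preterminals)
}

## Fold the per-word top-down counts into head-delimited chunks: word 0
## receives [0, h1]; head k receives (hk, h(k+1)]; trailing words beyond the
## last head fold into the last head's chunk, preserving the total.
chunk_attribute <- function(td, heads, n) {
  v <- integer(n)
  if (length(heads) == 0L) {
    v[1L] <- sum(td)
    return(v)
  }
  anchors <- c(0L, heads)
  ends <- c(heads, n - 1L)
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    lo <- if (k == 1L) 0L else a + 1L
    hi <- ends[k]
    if (hi >= lo) v[a + 1L] <- v[a + 1L] + sum(td[(lo:hi) + 1L])
  }
  v
}

#' Brute-force span-attribution oracle
#'
#' Independent reference for the three comprehension strategies: enumerates
#' every countable node and attributes it to its leftmost terminal
#' (top-down), rightmost terminal (bottom-up), or the last terminal of its
#' first daughter (left-corner) by direct span inspection, one node at a
#' time, with no vectorised tabulation.
#'
#' @param tree A [parse_tree].
#' @param strategy One of `"top_down"`, `"bottom_up"`, `"left_corner"`.
#' @param count_preterminals Count POS-level nodes (default FALSE).
#' @return Integer vector per word.
#' @export
span_oracle <- function(tree, strategy = c("top_down", "bottom_up", "left_corner"),
                        count_preterminals = FALSE) {
  strategy <- match.arg(strategy)
  nodes <- countable_nodes(tree, count_preterminals)
  n <- tree_length(tree)
  v <- integer(n)
  for (i in seq_len(nrow(nodes))) {
    w <- switch(strategy,
                top_down = nodes$start[i],
                bottom_up = nodes$end[i] - 1L,
                left_corner = nodes$first_child_end[i] - 1L)
    v[w + 1L] <- v[w + 1L] + 1L
  }
  v
}

#' All node-count metrics for a corpus
#'
#' Runs every requested strategy over paired constituent (and, for the
#' chunked strategy, dependency) parses and returns one row per word.
#'
#' @param trees List of [parse_tree] objects.
#' @param deps Optional list of dependency parses aligned with `trees`
#'   (required for the `chunked` strategy).
#' @param strategies Character vector from `top_down`, `bottom_up`,
#'   `left_corner`, `open_nodes`, `early_top_down`, `chunked`.
#' @param count_preterminals Count POS-level nodes (default FALSE).
#' @return Data.frame with `sentence_id` (0-based), `word_index` (0-based
#'   within sentence), `word`, and one column per strategy.
#' @export
node_count_table <- function(trees, deps = NULL,
                             strategies = c("top_down", "bottom_up",
                                            "left_corner", "open_nodes",
                                            "early_top_down", "chunked"),
                             count_preterminals = FALSE) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if ("chunked" %in% strategies) {
    if (is.null(deps)) stop("chunked strategy requires dependency parses")
    if (length(deps) != length(trees)) {
      stop("trees and deps must have equal length")
    }
  }
  rows <- lapply(seq_along(trees), function(s) {
    tree <- trees[[s]]
    n <- tree_length(tree)
    df <- data.frame(sentence_id = s - 1L, word_index = seq_len(n) - 1L,
                     word = tree_terminals(tree), stringsAsFactors = FALSE)
    # one node enumeration per tree; all strategies derived from it
    nodes <- countable_nodes(tree, count_preterminals)
    td <- tabulate(nodes$start + 1L, nbins = n)
    bu <- tabulate(nodes$end, nbins = n)
    for (st in strategies) {
      df[[st]] <- as.integer(switch(st,
        top_down = td,
        bottom_up = bu,
        left_corner = tabulate(nodes$first_child_end, nbins = n),
        open_nodes = cumsum(td) - cumsum(bu),
        early_top_down = shift_early(td),
        chunked = chunk_attribute(td, dependency_heads(deps[[s]]), n)))
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
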