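#' Constituent parse trees
#'
#' A `parse_tree` is a rooted, labeled, ordered tree over the tokens of one
#' sentence. Internal nodes carry a nonterminal label (S, NP, VP, ...);
#' leaves are the words themselves. Every node carries a half-open terminal
#' span `[start, end)` in 0-based word indices, so that the spans of a node's
#' children partition the node's span in order. All incremental complexity
#' metrics are defined in terms of these spans.
#'
#' @param label Nonterminal label (character scalar).
#' @param children List whose elements are `parse_tree` objects or character
#'   scalars (terminal tokens). Must be non-empty.
#' @return A `parse_tree` object with spans annotated.
#' @examples
#' t1 <- parse_bracketed("(S (NP Mary) (VP (VP eats (NP apples)) (ADVP daily)))")
#' tree_terminals(t1)
#' @export
parse_tree <- function(label, children) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.list(children) || length(children) == 0L) {
    stop("a parse_tree node must have at least one child")
  }
  node <- structure(list(label = label, children = children, span = NULL),
                    class = "parse_tree")
  annotate_spans(node, 0L)
}

is_parse_tree <- function(x) inherits(x, "parse_tree")

## Recompute [start, end) spans for a (sub)tree rooted at `start`.
annotate_spans <- function(node, start) {
  pos <- start
  node$children <- lapply(node$children, function(ch) {
    if (is_parse_tree(ch)) {
      ch <- annotate_spans(ch, pos)
      pos <<- ch$span[2L]
      ch
    } else {
      if (!is.character(ch) || length(ch) != 1L || !nzchar(ch)) {
        stop("terminal children must be non-empty character scalars")
      }
      pos <<- pos + 1L
      ch
    }
  })
  node$span <- c(start, pos)
  node
}

#' Parse one bracketed (S-expression) constituency record
#'
#' Accepts the Penn-Treebank dialect: `(LABEL child child ...)` where each
#' child is either another bracketed group or a bare token. Terminal order is
#' preserved and spans are computed.
#'
#' @param x Character scalar holding one balanced bracketing.
#' @return A `parse_tree`.
#' @export
parse_bracketed <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- tokenize_sexpr(x)
  if (length(toks) == 0L) stop("empty parse record")
  st <- read_sexpr(toks, 1L)
  if (st$pos <= length(toks)) {
    stop("unbalanced brackets: trailing content after tree")
  }
  if (!is_parse_tree(st$node)) stop("record is a bare token, not a tree")
  annotate_spans(st$node, 0L)
}

tokenize_sexpr <- function(x) {
  x <- gsub("\\(", " ( ", x)
  x <- gsub("\\)", " ) ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

## Recursive-descent reader; returns list(node=, pos=next token index).
read_sexpr <- function(toks, i) {
  if (i > length(toks)) stop("unbalanced brackets: unexpected end of record")
  if (toks[i] == "(") {
    i <- i + 1L
    if (i > length(toks) || toks[i] %in% c("(", ")")) {
      stop("malformed record: '(' must be followed by a label")
    }
    label <- toks[i]
    i <- i + 1L
    children <- list()
    while (TRUE) {
      if (i > length(toks)) stop("unbalanced brackets: unexpected end of record")
      if (toks[i] == ")") {
        if (length(children) == 0L) stop("malformed record: node with no children")
        node <- structure(list(label = label, children = children, span = NULL),
                          class = "parse_tree")
        return(list(node = node, pos = i + 1L))
      }
      st <- read_sexpr(toks, i)
      children[[length(children) + 1L]] <- st$node
      i <- st$pos
    }
  } else if (toks[i] == ")") {
    stop("unbalanced brackets: unexpected ')'")
  } else {
    list(node = toks[i], pos = i + 1L)
  }
}

#' Terminals (words) of a parse tree, in order
#' @param tree A `parse_tree`.
#' @return Character vector of tokens.
#' @export
tree_terminals <- function(tree) {
  stopifnot(is_parse_tree(tree))
  out <- character(0)
  walk <- function(node) {
    for (ch in node$children) {
      if (is_parse_tree(ch)) walk(ch) else out[[length(out) + 1L]] <<- ch
    }
  }
  walk(tree)
  out
}

#' Number of terminals covered by a tree
#' @param tree A `parse_tree`.
#' @return Integer word count.
#' @export
tree_length <- function(tree) {
  stopifnot(is_parse_tree(tree))
  tree$span[2L] - tree$span[1L]
}

#' Tabulate the nonterminal nodes of a tree
#'
#' Flattens a `parse_tree` into one row per nonterminal with its span, the
#' span of its first daughter (terminal daughters span one word), whether it
#' is preterminal-shaped (single child which is a terminal), and whether it
#' is the root. This table is the common substrate of the span-based metric
#' definitions and of the brute-force oracle.
#'
#' @param tree A `parse_tree`.
#' @return A data.frame with columns `label`, `start`, `end`,
#'   `first_child_end`, `is_preterminal`, `is_root` (spans half-open,
#'   0-based; `first_child_end` is the exclusive end of the first daughter's
#'   span).
#' @export
tree_nodes <- function(tree) {
  stopifnot(is_parse_tree(tree))
  label <- character(0); start <- integer(0); end <- integer(0)
  fce <- integer(0); pret <- logical(0); root <- logical(0)
  walk <- function(node, is_root) {
    first <- node$children[[1L]]
    i <- length(label) + 1L
    label[i] <<- node$label
    start[i] <<- node$span[1L]
    end[i] <<- node$span[2L]
    fce[i] <<- if (is_parse_tree(first)) first$span[2L] else node$span[1L] + 1L
    pret[i] <<- length(node$children) == 1L && !is_parse_tree(first)
    root[i] <<- is_root
    for (ch in node$children) if (is_parse_tree(ch)) walk(ch, FALSE)
  }
  walk(tree, TRUE)
  data.frame(label = label, start = start, end = end, first_child_end = fce,
             is_preterminal = pret, is_root = root, stringsAsFactors = FALSE)
}

## TRUE when every terminal is wrapped in a unary (POS-level) node, i.e. the
## tree has a complete part-of-speech layer.
has_pos_layer <- function(tree) {
  ok <- TRUE
  walk <- function(node) {
    pret <- length(node$children) == 1L && !is_parse_tree(node$children[[1L]])
    for (ch in node$children) {
      if (is_parse_tree(ch)) walk(ch)
      else if (!pret) ok <<- FALSE
    }
  }
  walk(tree)
  ok
}

#' Serialize a parse tree to bracketed text
#' @param tree A `parse_tree`.
#' @return Character scalar in the same S-expression dialect read by
#'   [parse_bracketed()].
#' @export
deparse_bracketed <- function(tree) {
  stopifnot(is_parse_tree(tree))
  parts <- vapply(tree$children, function(ch) {
    if (is_parse_tree(ch)) deparse_bracketed(ch) else ch
  }, character(1))
  paste0("(", tree$label, " ", paste(parts, collapse = " "), ")")
}

#' @export
print.parse_tree <- function(x, ...) {
  cat(deparse_bracketed(x), "\n")
  invisible(x)
}

#' Strip punctuation terminals from a tree
#'
#' Removes terminals whose token is in `strip`, together with any nodes left
#' childless, and renumbers spans. Spontaneous-speech transcripts are usually
#' unpunctuated, so the default strips nothing.
#'
#' @param tree A `parse_tree`.
#' @param strip Character vector of tokens to remove (default `character(0)`).
#' @return A `parse_tree`, or `NULL` if all terminals were stripped.
#' @export
strip_terminals <- function(tree, strip = character(0)) {
  stopifnot(is_parse_tree(tree))
  if (length(strip) == 0L) return(tree)
  prune <- function(node) {
    kept <- list()
    for (ch in node$children) {
      if (is_parse_tree(ch)) {
        sub <- prune(ch)
        if (!is.null(sub)) kept[[length(kept) + 1L]] <- sub
      } else if (!(ch %in% strip)) {
        kept[[length(kept) + 1L]] <- ch
      }
    }
    if (length(kept) == 0L) return(NULL)
    structure(list(label = node$label, children = kept, span = NULL),
              class = "parse_tree")
  }
  out <- prune(tree)
  if (is.null(out)) return(NULL)
  annotate_spans(out, 0L)
}
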