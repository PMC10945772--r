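# Shared fixtures: the worked four-word sentence, its dependency parse, and
# small generators used across test files.

t1_bracketing <- "(S (NP Mary) (VP (VP eats (NP apples)) (ADVP daily)))"

t1_tree <- function() parse_bracketed(t1_bracketing)

# "eats" is the root; Mary, apples and daily all depend on it.
t1_dep <- function() {
  list(form = c("Mary", "eats", "apples", "daily"),
       head = c(2L, 0L, 2L, 2L),
       relation = c("nsubj", "root", "obj", "advmod"))
}

# POS-wrapped variant of the same sentence (complete preterminal layer).
t1_pos_bracketing <- paste0(
  "(S (NP (NNP Mary)) (VP (VP (VBZ eats) (NP (NNS apples)))",
  " (ADVP (RB daily))))")

# Purely right- and left-branching chains over n terminals, no POS layer.
right_chain <- function(n) {
  s <- paste0("w", n)
  for (i in (n - 1):1) s <- sprintf("(X%d w%d %s)", i, i, s)
  parse_bracketed(s)
}

left_chain <- function(n) {
  s <- "w1"
  for (i in 2:n) s <- sprintf("(X%d %s w%d)", i - 1L, s, i)
  parse_bracketed(s)
}

# Random corpus at a fixed seed; memoised per size to keep tests fast.
random_corpus <- local({
  cache <- list()
  function(n_sentences, seed = 20240917) {
    key <- paste(n_sentences, seed)
    if (is.null(cache[[key]])) {
      set.seed(seed)
      cache[[key]] <<- sample_trees(n_sentences, simulation_config())
    }
    cache[[key]]
  }
})

# Small simulation configuration for fast fitting tests.
fast_config <- function(...) {
  simulation_config(...)
}

# One small study (6 participants x 90 scans x 3 ROIs), memoised: several
# encoding tests share it.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(6, 90, fast_config(), seed = 501)
    }
    cache
  }
})

small_long <- function() {
  study <- small_study()
  stack_bold_design(study$bold, study$designs, modality = "production")
}

baseline_terms <- c("word_rate", "n_syllables", "log_frequency", "surprisal",
                    "top_down", "bottom_up")
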