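#' Heuristic syllable count
#'
#' Counts maximal vowel-letter groups (a, e, i, o, u, y) with a silent-e
#' correction: a final "e" (not "le") that forms its own group is not
#' counted when the word would still keep a syllable. An optional
#' pronunciation lexicon (named integer vector, lowercase keys) overrides
#' the heuristic. Non-alphabetic or empty tokens count 1 with a warning.
#'
#' @param token Character vector of word tokens.
#' @param lexicon Optional named integer vector of known syllable counts.
#' @return Integer vector of syllable counts, all >= 1.
#' @examples
#' syllable_count(c("Mary", "I", "suspicious"))
#' @export
syllable_count <- function(token, lexicon = NULL) {
  vapply(token, function(tok) {
    w <- tolower(gsub("[^[:alpha:]]", "", tok))
    if (!nzchar(w)) {
      warning(sprintf("non-alphabetic token '%s'; counting 1 syllable", tok))
      return(1L)
    }
    if (!is.null(lexicon) && w %in% names(lexicon)) {
      return(as.integer(lexicon[[w]]))
    }
    groups <- gregexpr("[aeiouy]+", w)[[1]]
    k <- if (groups[1] == -1L) 0L else length(groups)
    # silent final e: "date" -> 1, but "able" keeps its -le syllable
    if (k > 1L && grepl("e$", w) && !grepl("le$", w)) {
      last_grp_end <- groups[k] + attr(groups, "match.length")[k] - 1L
      if (last_grp_end == nchar(w) && attr(groups, "match.length")[k] == 1L) {
        k <- k - 1L
      }
    }
    max(k, 1L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Sentence onset/offset boundary regressors
#'
#' Marks the first word of each sentence with 1 in `sentence_onset` and the
#' last word with 1 in `sentence_offset` (single-word sentences get both).
#' These columns absorb sentence planning and wrap-up effects not tied to
#' structure building; they are never mean-centered.
#'
#' @param sentence_id Integer vector of sentence ids, one per word, grouped
#'   contiguously (optionally within `recall_id` groups).
#' @param recall_id Optional recall grouping vector.
#' @return Data.frame with 0/1 columns `sentence_onset`, `sentence_offset`.
#' @export
boundary_regressors <- function(sentence_id, recall_id = NULL) {
  n <- length(sentence_id)
  if (n == 0L) {
    return(data.frame(sentence_onset = integer(0), sentence_offset = integer(0)))
  }
  if (is.null(recall_id)) recall_id <- rep("r", n)
  key <- paste(recall_id, sentence_id, sep = "\r")
  if (anyDuplicated(rle(key)$values)) {
    stop("sentence_id groups must be contiguous")
  }
  onset <- as.integer(!duplicated(key))
  offset <- as.integer(!duplicated(key, fromLast = TRUE))
  data.frame(sentence_onset = onset, sentence_offset = offset)
}

#' Word surprisal from conditional probabilities
#'
#' Surprisal is the negative logarithm of the word's conditional probability
#' given its context.
#'
#' @param p Numeric vector of probabilities in (0, 1].
#' @param base `"e"` (natural log, default) or `"2"`.
#' @return Numeric vector of surprisals, all >= 0.
#' @export
surprisal_column <- function(p, base = c("e", "2")) {
  base <- match.arg(base)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("probabilities must lie in (0, 1]")
  }
  if (base == "e") -log(p) else -log2(p)
}

#' Mean-center predictor columns
#'
#' Centers each selected numeric column to mean zero within each centering
#' group (by default per recall, matching per-run convolution). The word
#' rate and the sentence onset/offset columns are excluded by default: they
#' must keep their unit impulses.
#'
#' @param table Data.frame of word-level predictors.
#' @param exclude Columns never centered (default
#'   `c("word_rate", "sentence_onset", "sentence_offset")`).
#' @param group Optional grouping vector (e.g. `table$recall_id`); NULL
#'   centers over all rows.
#' @return The data.frame with centered columns; attribute `"centered"`
#'   lists them.
#' @export
mean_center <- function(table,
                        exclude = c("word_rate", "sentence_onset", "sentence_offset"),
                        group = NULL) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, c(exclude, "onset", "offset", "sentence_id",
                        "word_index", "tr_index"))
  if (is.null(group)) group <- rep(1L, nrow(table))
  for (cn in num) {
    v <- ave(as.numeric(table[[cn]]), group, FUN = mean)
    if (all(table[[cn]] == table[[cn]][1L])) {
      warning(sprintf("zero-variance column '%s' centered to zeros", cn))
    }
    table[[cn]] <- as.numeric(table[[cn]]) - v
  }
  attr(table, "centered") <- num
  table
}

#' Assemble the word-level predictor table
#'
#' Joins word timings, node-count metrics and lexical covariates into one
#' row per word: the substrate for both the HRF design matrix and the
#' behavioral models. Node-count columns are aligned by (sentence, word)
#' position; words missing from the trees are dropped with a message.
#'
#' @param timings Timing data.frame (`word`, `onset`, `offset`,
#'   `sentence_id`, `recall_id`).
#' @param metrics Node-count table from [node_count_table()] (per-sentence
#'   `sentence_id`/`word_index` aligned with the timing rows' order).
#' @param covariates Optional data.frame with per-word `log_frequency`
#'   and/or `surprisal` (row order aligned with `timings`).
#' @param syllable_lexicon Optional lexicon for [syllable_count()].
#' @return Data.frame: one row per word with timings, `word_rate` (all 1),
#'   `n_syllables`, covariates, node-count columns and boundary columns.
#' @export
build_predictor_table <- function(timings, metrics, covariates = NULL,
                                  syllable_lexicon = NULL) {
  timings <- validate_timings(timings)
  n <- nrow(timings)
  ord <- stats::ave(seq_len(n), timings$recall_id, timings$sentence_id,
                    FUN = seq_along) - 1L
  timings$word_index <- ord
  if (nrow(metrics) != n) {
    # align by position within sentence; unmatched words dropped
    key_t <- paste(timings$sentence_id, timings$word_index)
    key_m <- paste(metrics$sentence_id, metrics$word_index)
    keep <- key_t %in% key_m
    if (any(!keep)) {
      message(sprintf("%d word(s) absent from parses dropped", sum(!keep)))
      timings <- timings[keep, , drop = FALSE]
      if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
    }
  }
  if (nrow(metrics) != nrow(timings)) {
    stop("metrics table does not align with timing table")
  }
  out <- timings
  out$word_rate <- 1
  out$n_syllables <- syllable_count(out$word, syllable_lexicon)
  strat_cols <- intersect(c("top_down", "bottom_up", "left_corner",
                            "open_nodes", "early_top_down", "chunked"),
                          names(metrics))
  for (cn in strat_cols) out[[cn]] <- metrics[[cn]]
  if (!is.null(covariates)) {
    if (nrow(covariates) != nrow(out)) {
      stop("covariate table does not align with timing table")
    }
    for (cn in setdiff(names(covariates),
                       c("word", "recall_id", "sentence_id", "word_index"))) {
      out[[cn]] <- covariates[[cn]]
    }
  }
  bnd <- boundary_regressors(out$sentence_id, out$recall_id)
  out$sentence_onset <- bnd$sentence_onset
  out$sentence_offset <- bnd$sentence_offset
  rownames(out) <- NULL
  out
}
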