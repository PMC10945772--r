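#' Default PCFG for synthetic spontaneous-speech corpora
#'
#' A small probabilistic context-free grammar over S/NP/VP/PP with lexical
#' categories expanding directly to words (no part-of-speech layer, like
#' unpunctuated speech bracketings). Rule probabilities are chosen so the
#' expected sentence length is about 9.1 words, matching the scale of
#' disfluency-segmented spontaneous recalls (mean around 9.4 words). Each
#' rule names its head child, from which dependency structure is percolated
#' (verb-headed clauses: the verb heads subject and object).
#'
#' @return A grammar object: list with `rules` (per nonterminal: `rhs`,
#'   `p`, `head`), `lexicon` (per lexical category: word vector) and
#'   `start`.
#' @export
default_grammar <- function() {
  rules <- list(
    S = list(list(rhs = c("NP", "VP"), p = 1.0, head = 2L)),
    NP = list(list(rhs = c("Det", "N"), p = 0.35, head = 2L),
              list(rhs = "N", p = 0.20, head = 1L),
              list(rhs = c("Det", "Adj", "N"), p = 0.20, head = 3L),
              list(rhs = c("NP", "PP"), p = 0.25, head = 1L)),
    VP = list(list(rhs = "V", p = 0.15, head = 1L),
              list(rhs = c("V", "NP"), p = 0.35, head = 1L),
              list(rhs = c("V", "NP", "PP"), p = 0.25, head = 1L),
              list(rhs = c("VP", "Adv"), p = 0.25, head = 1L)),
    PP = list(list(rhs = c("P", "NP"), p = 1.0, head = 1L)))
  lexicon <- list(
    N = c("dog", "cat", "story", "apple", "teacher", "house", "river",
          "idea", "movie", "garden", "letter", "window"),
    V = c("sees", "eats", "likes", "follows", "describes", "remembers",
          "finds", "watches"),
    Det = c("the", "a"),
    Adj = c("big", "small", "strange", "quiet", "red"),
    Adv = c("daily", "quickly", "quietly", "often"),
    P = c("in", "on", "near", "with"))
  for (nt in names(rules)) {
    ps <- vapply(rules[[nt]], `[[`, numeric(1), "p")
    stopifnot(abs(sum(ps) - 1) < 1e-12)
  }
  list(rules = rules, lexicon = lexicon, start = "S")
}

#' Simulation configuration
#'
#' Bundles the generator's study conditions: grammar, speech-timing
#' parameters, and BOLD forward-model parameters. Defaults emulate
#' disfluency-segmented spontaneous recall: sentences of ~9 words,
#' articulation around 0.22 s per syllable, short within-sentence pauses
#' with a log-linear top-down complexity effect, inter-sentence pauses
#' above the segmentation threshold, and BOLD as a known linear combination
#' of HRF-convolved predictors plus by-participant random slopes and AR(1)
#' noise.
#'
#' @param grammar PCFG from [default_grammar()].
#' @param max_words Resampling cap on sentence length (default 40).
#' @param syllable_rate Seconds per syllable of articulation (default 0.22).
#' @param duration_sdlog Lognormal sd of duration noise (default 0.25).
#' @param pause_base Baseline within-sentence pause, seconds (default 0.08).
#' @param pause_td_coef Log-pause slope on the top-down count (default 0.1).
#' @param pause_sdlog Lognormal sd of pause noise (default 0.35).
#' @param segmentation_threshold Pause threshold separating sentences,
#'   seconds (default 1.0). Within-sentence pauses are capped at 0.8x this
#'   value and inter-sentence pauses floored above it, so pause-based
#'   segmentation recovers the generated boundaries exactly.
#' @param tr Repetition time, seconds (default 1.5).
#' @param betas Named vector of generative fixed effects per design column
#'   (default: word rate 0.5, syllable rate 0.2, frequency 0.2, surprisal
#'   0.3, top-down 0.9, bottom-up -0.35, on the scale of ROI encoding
#'   estimates).
#' @param slope_sd Named vector of by-participant random-slope sds (default
#'   0.3 for the syntactic predictors).
#' @param noise_sd Residual sd (default 1).
#' @param ar1_rho Residual lag-1 autocorrelation (default 0.3).
#' @param timing_model Which production timing generates the syntactic BOLD
#'   signal: `"standard_td"`, `"early_td"` or `"chunked"`.
#' @param rois ROI labels (default BA44, BA45, LpMTG).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(grammar = default_grammar(), max_words = 40L,
                              syllable_rate = 0.22, duration_sdlog = 0.25,
                              pause_base = 0.08, pause_td_coef = 0.1,
                              pause_sdlog = 0.35,
                              segmentation_threshold = 1.0, tr = 1.5,
                              betas = c(word_rate = 0.5, n_syllables = 0.2,
                                        log_frequency = 0.2, surprisal = 0.3,
                                        top_down = 0.9, bottom_up = -0.35),
                              slope_sd = c(top_down = 0.3, bottom_up = 0.3),
                              noise_sd = 1, ar1_rho = 0.3,
                              timing_model = c("standard_td", "early_td",
                                               "chunked"),
                              rois = c("BA44", "BA45", "LpMTG")) {
  timing_model <- match.arg(timing_model)
  stopifnot(tr > 0, noise_sd >= 0, abs(ar1_rho) < 1,
            segmentation_threshold > 0)
  structure(list(grammar = grammar, max_words = max_words,
                 syllable_rate = syllable_rate,
                 duration_sdlog = duration_sdlog, pause_base = pause_base,
                 pause_td_coef = pause_td_coef, pause_sdlog = pause_sdlog,
                 segmentation_threshold = segmentation_threshold, tr = tr,
                 betas = betas, slope_sd = slope_sd, noise_sd = noise_sd,
                 ar1_rho = ar1_rho, timing_model = timing_model,
                 rois = rois),
            class = "sim_config")
}

timing_model_column <- function(timing_model) {
  switch(timing_model, standard_td = "top_down", early_td = "early_top_down",
         chunked = "chunked")
}

## One PCFG derivation as a generation node (label, children, head child).
gen_symbol <- function(sym, grammar, depth, max_depth = 60L) {
  if (depth > max_depth) stop("derivation exceeded depth cap; grammar may not terminate")
  if (sym %in% names(grammar$lexicon)) {
    return(sample(grammar$lexicon[[sym]], 1L))
  }
  opts <- grammar$rules[[sym]]
  if (is.null(opts)) stop("symbol with no rules or lexicon: ", sym)
  ps <- vapply(opts, `[[`, numeric(1), "p")
  rule <- opts[[sample.int(length(opts), 1L, prob = ps)]]
  children <- lapply(rule$rhs, gen_symbol, grammar = grammar,
                     depth = depth + 1L)
  structure(list(label = sym, children = children, head_child = rule$head),
            class = "gen_node")
}

gen_terminal_count <- function(node) {
  if (is.character(node)) return(1L)
  sum(vapply(node$children, gen_terminal_count, integer(1)))
}

gen_to_parse_tree <- function(node) {
  build <- function(nd) {
    if (is.character(nd)) return(nd)
    structure(list(label = nd$label,
                   children = lapply(nd$children, build), span = NULL),
              class = "parse_tree")
  }
  annotate_spans(build(node), 0L)
}

## Dependency heads by head percolation: each non-head child's head word
## depends on the node's head word; the root's head word has head 0.
gen_to_dependency <- function(node) {
  n <- gen_terminal_count(node)
  form <- character(n)
  head <- integer(n)
  rel <- character(n)
  pos <- 0L
  head_word <- function(nd) {
    if (is.character(nd)) {
      pos <<- pos + 1L
      form[pos] <<- nd
      return(pos)
    }
    hws <- integer(length(nd$children))
    for (k in seq_along(nd$children)) hws[k] <- head_word(nd$children[[k]])
    h <- hws[nd$head_child]
    for (k in seq_along(hws)) {
      if (k != nd$head_child) {
        head[hws[k]] <<- h
        rel[hws[k]] <<- tolower(nd$label)
      }
    }
    h
  }
  root <- head_word(node)
  head[root] <- 0L
  rel[root] <- "root"
  list(form = form, head = head, relation = rel)
}

#' Sample parsed sentences from the PCFG
#'
#' Draws i.i.d. derivations from the grammar (resampling any derivation
#' longer than `max_words`) and returns paired constituent and dependency
#' parses. Uses the current RNG state; set a seed for reproducibility.
#'
#' @param n_sentences Number of sentences.
#' @param config A [simulation_config()].
#' @return List with `trees` (list of [parse_tree]) and `deps` (aligned
#'   dependency parses).
#' @export
sample_trees <- function(n_sentences, config = simulation_config()) {
  trees <- vector("list", n_sentences)
  deps <- vector("list", n_sentences)
  for (i in seq_len(n_sentences)) {
    repeat {
      g <- gen_symbol(config$grammar$start, config$grammar, 0L)
      if (gen_terminal_count(g) <= config$max_words) break
    }
    trees[[i]] <- gen_to_parse_tree(g)
    deps[[i]] <- gen_to_dependency(g)
  }
  list(trees = trees, deps = deps)
}

#' Simulate word timings for parsed sentences
#'
#' Word durations scale with syllable count (lognormal noise); the pause
#' before each word is log-linear in its top-down node count with slope
#' `pause_td_coef`. Within-sentence pauses are capped below the
#' segmentation threshold and inter-sentence pauses floored above it (same
#' log-linear top-down slope, different baseline, half-normal excess
#' noise), so [segment_sentences()] recovers the generated sentence
#' boundaries exactly.
#'
#' @param corpus Output of [sample_trees()].
#' @param config A [simulation_config()].
#' @param recall_id Recall label (default "recall1").
#' @param start_s Clock time of the first word onset (default 2).
#' @return Timing data.frame (`word`, `onset`, `offset`, `sentence_id`,
#'   `recall_id`) with attribute `"top_down"` holding the generating counts.
#' @export
simulate_timings <- function(corpus, config = simulation_config(),
                             recall_id = "recall1", start_s = 2) {
  thr <- config$segmentation_threshold
  gam <- config$pause_td_coef
  lens <- vapply(corpus$trees, tree_length, numeric(1))
  words <- unlist(lapply(corpus$trees, tree_terminals))
  td <- unlist(lapply(corpus$trees, top_down_counts))
  sent <- rep(seq_along(lens) - 1L, lens)
  n <- length(words)
  nsyl <- syllable_count(words)
  dur <- config$syllable_rate * nsyl * exp(stats::rnorm(n, 0, config$duration_sdlog))
  z <- stats::rnorm(n, 0, config$pause_sdlog)
  is_start <- c(TRUE, diff(sent) != 0)
  pause <- pmin(config$pause_base * exp(gam * td) * exp(z), 0.8 * thr)
  pause[is_start] <- pmax(thr * 1.05 * exp(gam * td[is_start]) *
                            exp(abs(z[is_start])), thr * 1.01)
  pause[1L] <- 0
  onset <- start_s + cumsum(pause) + c(0, cumsum(dur)[-n])
  out <- data.frame(word = words, onset = onset, offset = onset + dur,
                    sentence_id = sent, recall_id = recall_id,
                    stringsAsFactors = FALSE)
  attr(out, "top_down") <- td
  out
}

#' Toy covariates for a synthetic corpus
#'
#' Word frequencies per million drawn once per word type (lognormal) and a
#' toy unigram surprisal (-log corpus-estimated probability, add-one
#' smoothing). Stands in for external frequency norms and transformer
#' surprisal, which real analyses ingest as columns.
#'
#' @param words Character vector of corpus tokens, in order.
#' @return Data.frame with `log_frequency` and `surprisal`.
#' @export
simulate_covariates <- function(words) {
  types <- sort(unique(words))
  fpm <- stats::setNames(exp(stats::rnorm(length(types), mean = 4, sd = 1.5)),
                         types)
  counts <- table(words)
  p <- (as.numeric(counts[words]) + 1) / (length(words) + length(types))
  data.frame(log_frequency = log(fpm[words]),
             surprisal = surprisal_column(p), row.names = NULL)
}

## AR(1) noise with stationary sd `sd` and lag-1 autocorrelation `rho`.
ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  innov[1L] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Simulate one participant's recall: corpus, timings, predictors, design
#'
#' Samples sentences until the recall fills `n_scans` volumes, computes all
#' node-count metrics and covariates, and builds the scan-resolution design
#' matrix with [build_design_matrix()] (the forward model reuses the
#' analysis convolution, it does not re-implement it).
#'
#' @param n_scans Number of volumes.
#' @param config A [simulation_config()].
#' @param recall_id Recall/participant label.
#' @return List with `trees`, `deps`, `timings`, `predictors`, `design`.
#' @export
simulate_recall <- function(n_scans, config = simulation_config(),
                            recall_id = "p1") {
  run_end <- n_scans * config$tr
  # ~2.2 words/s of speech, ~9 words/sentence; oversample, then truncate
  guess <- ceiling(run_end * 2.2 / 8) + 5L
  corpus <- sample_trees(guess, config)
  trees <- corpus$trees; deps <- corpus$deps
  timings <- simulate_timings(corpus, config, recall_id = recall_id)
  while (max(timings$offset) < run_end) {
    batch <- sample_trees(20L, config)
    trees <- c(trees, batch$trees)
    deps <- c(deps, batch$deps)
    timings <- simulate_timings(list(trees = trees, deps = deps), config,
                                recall_id = recall_id)
  }
  keep_sent <- timings$sentence_id[which(timings$offset >= run_end)[1L]]
  sel <- timings$sentence_id < keep_sent
  if (!any(sel)) sel <- timings$sentence_id == 0L  # degenerate short run
  timings <- timings[sel, , drop = FALSE]
  n_sent <- max(timings$sentence_id) + 1L
  trees <- trees[seq_len(n_sent)]
  deps <- deps[seq_len(n_sent)]
  metrics <- node_count_table(trees, deps)
  covs <- simulate_covariates(timings$word)
  pred <- build_predictor_table(timings, metrics, covs)
  cols <- unique(c("word_rate", "n_syllables", "log_frequency", "surprisal",
                   "open_nodes", "top_down", "bottom_up", "left_corner",
                   "early_top_down", "chunked",
                   "sentence_onset", "sentence_offset"))
  design <- build_design_matrix(pred, columns = intersect(cols, names(pred)),
                                spec = hrf_spec(), tr = config$tr,
                                n_scans = n_scans)
  list(trees = trees, deps = deps, timings = timings, predictors = pred,
       design = design)
}

#' Simulate ROI BOLD from a design matrix with known ground truth
#'
#' y = sum_j (beta_j + b_pj) x_j + epsilon per (participant, ROI):
#' by-participant random slopes b_pj ~ N(0, slope_sd^2), independent across
#' predictors and shared across that participant's ROIs; epsilon is AR(1)
#' with the configured rho and sd, independent across ROIs.
#'
#' @param designs Named list participant -> design matrix.
#' @param config A [simulation_config()]; `betas` names must be design
#'   columns. The syntactic column named by `timing_model` is used when
#'   `betas` contains `top_down` and the timing model is not
#'   `standard_td` (the weight transfers to the production-timing column).
#' @return List with `bold` (long data.frame: participant, roi, tr_index,
#'   value) and `truth` (betas actually applied, slopes drawn, config).
#' @export
simulate_bold <- function(designs, config = simulation_config()) {
  betas <- config$betas
  syn_col <- timing_model_column(config$timing_model)
  if (config$timing_model != "standard_td" && "top_down" %in% names(betas)) {
    names(betas)[names(betas) == "top_down"] <- syn_col
  }
  slope_sd <- config$slope_sd
  if (config$timing_model != "standard_td" && "top_down" %in% names(slope_sd)) {
    names(slope_sd)[names(slope_sd) == "top_down"] <- syn_col
  }
  rows <- list()
  slopes <- list()
  for (p in names(designs)) {
    dm <- designs[[p]]
    miss <- setdiff(names(betas), names(dm))
    if (length(miss)) stop("design for ", p, " lacks column(s): ",
                           paste(miss, collapse = ", "))
    n <- nrow(dm)
    b_p <- stats::rnorm(length(betas), 0,
                        ifelse(names(betas) %in% names(slope_sd),
                               slope_sd[names(betas)], 0))
    names(b_p) <- names(betas)
    slopes[[p]] <- b_p
    X <- as.matrix(dm[, names(betas), drop = FALSE])
    mu <- as.numeric(X %*% (betas + b_p))
    for (roi in config$rois) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, roi = roi, tr_index = seq_len(n) - 1L,
        value = mu + ar1_noise(n, config$noise_sd, config$ar1_rho),
        stringsAsFactors = FALSE)
    }
  }
  bold <- do.call(rbind, rows)
  rownames(bold) <- NULL
  list(bold = bold,
       truth = list(betas = as.list(betas), slope_sd = as.list(slope_sd),
                    noise_sd = config$noise_sd, ar1_rho = config$ar1_rho,
                    timing_model = config$timing_model,
                    slopes = slopes))
}

#' Simulate a full multi-participant study
#'
#' One recall, design matrix and BOLD set per participant under a common
#' configuration.
#'
#' @param n_participants Number of participants.
#' @param n_scans Volumes per participant.
#' @param config A [simulation_config()].
#' @param seed Optional RNG seed set before any sampling.
#' @return List with `recalls` (per participant), `designs`, `bold`,
#'   `truth`.
#' @export
simulate_study <- function(n_participants, n_scans,
                           config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n_participants))
  recalls <- lapply(ids, function(p) simulate_recall(n_scans, config, p))
  names(recalls) <- ids
  designs <- lapply(recalls, `[[`, "design")
  sim <- simulate_bold(designs, config)
  list(recalls = recalls, designs = designs, bold = sim$bold,
       truth = sim$truth)
}

#' Write a small deterministic fixture bundle to disk
#'
#' Emits the synthetic corpus in the pipeline's external formats —
#' trees.txt (bracketed), deps.conllu, timings.tsv, covariates.tsv,
#' bold.tsv, truth.json — so every reader and the end-to-end pipeline can
#' be exercised without any download. All files are plain text and
#' synthetic.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed (default 42).
#' @param n_participants Participants (default 3).
#' @param n_scans Volumes per participant (default 80).
#' @param config A [simulation_config()].
#' @return Invisibly, the `simulate_study()` bundle.
#' @export
make_fixture_corpus <- function(dir, seed = 42, n_participants = 3,
                                n_scans = 80, config = simulation_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(n_participants, n_scans, config, seed = seed)
  all_trees <- unlist(lapply(study$recalls, `[[`, "trees"), recursive = FALSE)
  all_deps <- unlist(lapply(study$recalls, `[[`, "deps"), recursive = FALSE)
  write_bracketed_trees(all_trees, file.path(dir, "trees.txt"))
  write_dependency(all_deps, file.path(dir, "deps.conllu"))
  timings <- do.call(rbind, lapply(study$recalls, function(r) {
    t <- r$timings; rownames(t) <- NULL; t
  }))
  rownames(timings) <- NULL
  write_word_timings(timings, file.path(dir, "timings.tsv"))
  covs <- do.call(rbind, lapply(study$recalls, function(r) {
    r$predictors[, c("recall_id", "word", "log_frequency", "surprisal")]
  }))
  utils::write.table(covs, file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_roi_timeseries(study$bold, file.path(dir, "bold.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(study$truth[c("betas", "slope_sd", "noise_sd",
                                       "ar1_rho", "timing_model")],
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(study)
}
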