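#!/usr/bin/env Rscript

# Step 2: read the raw corpus, compute word-level complexity metrics, and
# build scan-resolution design matrices.
#
# Reads data/simulated/ (written by 01_simulate.R), computes all node-count
# strategies per word, joins the lexical covariates, convolves everything
# with the canonical HRF, and writes:
#   data/derived/design_long.tsv  - stacked per-participant design matrices
#   results/metrics_summary.tsv   - per-strategy word-level summaries
#   results/collinearity.tsv      - post-convolution regressor correlations
#
# Usage: Rscript analysis/02_design.R

suppressPackageStartupMessages(library(synbold))

in_dir <- "data/simulated"
trees <- read_bracketed_trees(file.path(in_dir, "trees.txt"))
deps <- read_dependency(file.path(in_dir, "deps.conllu"))
timings <- read_word_timings(file.path(in_dir, "timings.tsv"))
covs <- utils::read.delim(file.path(in_dir, "covariates.tsv"))
bold <- read_roi_timeseries(file.path(in_dir, "bold.tsv"))

tr_s <- 1.5
participants <- unique(timings$recall_id)
n_scans <- max(bold$tr_index) + 1L

# trees.txt concatenates recalls in participant order; sentence_id restarts
# at 0 within each recall, so participant p's sentences are a contiguous
# block of the tree list
sent_per_part <- vapply(participants, function(p) {
  max(timings$sentence_id[timings$recall_id == p]) + 1L
}, integer(1))
offsets <- c(0L, cumsum(sent_per_part))

design_rows <- list()
metric_rows <- list()
for (i in seq_along(participants)) {
  p <- participants[i]
  idx <- (offsets[i] + 1L):offsets[i + 1L]
  tm <- timings[timings$recall_id == p, , drop = FALSE]
  metrics <- node_count_table(trees[idx], deps[idx])
  cv <- covs[covs$recall_id == p, c("log_frequency", "surprisal"),
             drop = FALSE]
  pred <- build_predictor_table(tm, metrics, cv)
  dm <- build_design_matrix(
    pred,
    columns = c("word_rate", "n_syllables", "log_frequency", "surprisal",
                "open_nodes", "top_down", "bottom_up", "left_corner",
                "early_top_down", "chunked", "sentence_onset",
                "sentence_offset"),
    tr = tr_s, n_scans = n_scans)
  dm$participant <- p
  dm$tr_index <- seq_len(nrow(dm)) - 1L
  design_rows[[p]] <- dm
  agg <- pred[, c("top_down", "bottom_up", "left_corner", "open_nodes",
                  "early_top_down", "chunked")]
  metric_rows[[p]] <- data.frame(participant = p, n_words = nrow(pred),
                                 t(colMeans(agg)))
}
design_long <- do.call(rbind, design_rows)

dir.create("data/derived", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)
utils::write.table(design_long, "data/derived/design_long.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(do.call(rbind, metric_rows), "results/metrics_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# collinearity of the convolved regressors, pooled over participants
num_cols <- setdiff(names(design_long), c("participant", "tr_index"))
rep_ <- collinearity_report(design_long[, num_cols])
utils::write.table(rep_, "results/collinearity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("wrote design_long.tsv (%d rows), metrics_summary.tsv, collinearity.tsv\n",
            nrow(design_long)))
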