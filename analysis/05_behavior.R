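#!/usr/bin/env Rscript

# Step 5: behavioral timing models.
#
# Rebuilds the word-level predictor tables from the raw corpus, derives
# pause-before and duration per word, and fits the mixed pause and duration
# models. Writes:
#   results/behavior_pause.tsv    - fixed effects of the log-pause model
#   results/behavior_duration.tsv - fixed effects of the log-duration model
#
# Usage: Rscript analysis/05_behavior.R

suppressPackageStartupMessages(library(synbold))

in_dir <- "data/simulated"
trees <- read_bracketed_trees(file.path(in_dir, "trees.txt"))
deps <- read_dependency(file.path(in_dir, "deps.conllu"))
timings <- read_word_timings(file.path(in_dir, "timings.tsv"))
covs <- utils::read.delim(file.path(in_dir, "covariates.tsv"))

participants <- unique(timings$recall_id)
sent_per_part <- vapply(participants, function(p) {
  max(timings$sentence_id[timings$recall_id == p]) + 1L
}, integer(1))
offsets <- c(0L, cumsum(sent_per_part))

bt <- do.call(rbind, lapply(seq_along(participants), function(i) {
  p <- participants[i]
  idx <- (offsets[i] + 1L):offsets[i + 1L]
  tm <- timings[timings$recall_id == p, , drop = FALSE]
  metrics <- node_count_table(trees[idx], deps[idx])
  cv <- covs[covs$recall_id == p, c("log_frequency", "surprisal"),
             drop = FALSE]
  x <- build_behavioral_table(build_predictor_table(tm, metrics, cv))
  x$participant <- p
  x
}))

fit_p <- fit_pause_model(bt)
fit_d <- fit_duration_model(bt)
print(fit_p)
print(fit_d)

dir.create("results", showWarnings = FALSE)
utils::write.table(fit_p$fixed, "results/behavior_pause.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(fit_d$fixed, "results/behavior_duration.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote behavior_pause.tsv, behavior_duration.tsv\n")
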