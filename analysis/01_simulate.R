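#!/usr/bin/env Rscript

# Step 1: simulate the study and write the raw text corpus.
#
# Generates a multi-participant spontaneous-speech study under the default
# study conditions (PCFG corpus, disfluency-segmented timings, known BOLD
# forward model) and writes it in the pipeline's external formats under
# data/simulated/. Later steps read only those files, exactly as a real
# analysis would start from treebank, CoNLL-U, timing and BOLD files.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

suppressPackageStartupMessages(library(synbold))

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) {
  as.integer(args[match("--seed", args) + 1L])
} else 20240917L

out_dir <- "data/simulated"
study <- make_fixture_corpus(out_dir, seed = seed, n_participants = 8,
                             n_scans = 200)
n_words <- sum(vapply(study$recalls, function(r) nrow(r$timings), integer(1)))
cat(sprintf("wrote %s: %d participants, %d words, %d BOLD rows\n",
            out_dir, length(study$recalls), n_words, nrow(study$bold)))
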