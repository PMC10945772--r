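#!/usr/bin/env Rscript

# Step 3: fit the ROI encoding model.
#
# Merges the stacked design matrices with the BOLD series and fits the
# mixed encoding model (by-participant uncorrelated random slopes on the
# syntactic predictors), then writes:
#   results/encoding_fixed_effects.tsv - estimates, SEs, Wald z per term
#   results/encoding_wald.tsv          - per-term Wald chi-square tests
#   results/encoding_by_roi.tsv        - per-ROI syntactic slopes via
#                                        Helmert-coded interactions
#
# Usage: Rscript analysis/03_encoding.R

suppressPackageStartupMessages(library(synbold))

design_long <- utils::read.delim("data/derived/design_long.tsv")
bold <- read_roi_timeseries("data/simulated/bold.tsv")

designs <- split(design_long, design_long$participant)
designs <- lapply(designs, function(d) {
  d[order(d$tr_index), setdiff(names(d), c("participant", "tr_index"))]
})
long <- stack_bold_design(bold, designs, modality = "production")

terms <- c("word_rate", "n_syllables", "log_frequency", "surprisal",
           "top_down", "bottom_up")
fit <- fit_mixed_model(long, "value", terms,
                       random_slopes = c("top_down", "bottom_up"),
                       focal = c("top_down", "bottom_up"),
                       estimation = "REML")
print(fit)

dir.create("results", showWarnings = FALSE)
utils::write.table(fit$fixed, "results/encoding_fixed_effects.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(wald_tests(fit), "results/encoding_wald.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# per-ROI syntactic slopes: Helmert-coded ROI x top-down interaction
codes <- code_factors(roi = as.character(long$roi))
long$roi_lifg_vs_pmtg <- codes$roi_lifg_vs_pmtg
long$roi_ba44_vs_ba45 <- codes$roi_ba44_vs_ba45
fit_roi <- fit_mixed_model(
  long, "value",
  c(terms, "roi_lifg_vs_pmtg", "roi_ba44_vs_ba45",
    "top_down:roi_lifg_vs_pmtg", "top_down:roi_ba44_vs_ba45"),
  random_slopes = c("top_down", "bottom_up"),
  focal = "top_down", estimation = "REML")
pc <- pairwise_contrasts(
  fit_roi, "top_down",
  by = list(roi_lifg_vs_pmtg = c(BA44 = 0.5, BA45 = 0.5, LpMTG = -1),
            roi_ba44_vs_ba45 = c(BA44 = 1, BA45 = -1, LpMTG = 0)))
cells <- pc$cells[pc$cells$roi_lifg_vs_pmtg == pc$cells$roi_ba44_vs_ba45, ]
names(cells)[names(cells) == "roi_lifg_vs_pmtg"] <- "roi"
cells$roi_ba44_vs_ba45 <- NULL
utils::write.table(cells, "results/encoding_by_roi.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote encoding_fixed_effects.tsv, encoding_wald.tsv, encoding_by_roi.tsv\n")
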