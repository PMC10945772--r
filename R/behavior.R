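#' Build the behavioral (pause / duration) table
#'
#' Derives, for every word, the silent pause before it (onset minus the
#' previous word's offset, within recall; NA for the first word of a
#' recall) and its articulated duration (offset minus onset), joined with
#' the complexity metrics and lexical covariates. Overlapping words
#' (negative gaps) are clamped to a 0 pause and counted in a message.
#'
#' @param predictors Word predictor table from [build_predictor_table()]
#'   (needs `onset`, `offset`, `recall_id`, `sentence_onset` and metric /
#'   covariate columns). A `participant` column is taken from `recall_id`
#'   when absent.
#' @return Data.frame with `pause_before`, `duration` and the predictor
#'   columns.
#' @export
build_behavioral_table <- function(predictors) {
  x <- predictors
  stopifnot(all(c("onset", "offset") %in% names(x)))
  if (!"recall_id" %in% names(x)) x$recall_id <- "recall1"
  if (!"participant" %in% names(x)) x$participant <- x$recall_id
  ord <- order(x$recall_id, x$onset)
  x <- x[ord, , drop = FALSE]
  prev_off <- stats::ave(x$offset, x$recall_id,
                         FUN = function(v) c(NA_real_, v[-length(v)]))
  pause <- x$onset - prev_off
  n_overlap <- sum(pause < 0, na.rm = TRUE)
  if (n_overlap > 0) {
    message(sprintf("%d overlapping word pair(s); pauses clamped to 0",
                    n_overlap))
    pause[!is.na(pause) & pause < 0] <- 0
  }
  x$pause_before <- pause
  x$duration <- x$offset - x$onset
  if (any(x$duration <= 0)) stop("non-positive word duration in table")
  rownames(x) <- NULL
  x
}

behavioral_predictors <- function(table) {
  want <- c("n_syllables", "log_frequency", "surprisal",
            "top_down", "bottom_up", "open_nodes")
  present <- intersect(want, names(table))
  if (length(present) == 0L) stop("no behavioral predictor columns present")
  present
}

fit_timing_model <- function(table, response_raw, log_transform, offset_s,
                             random_slopes, focal, estimation,
                             include_onset_indicator, drop_na) {
  tab <- table
  if (drop_na) tab <- tab[!is.na(tab[[response_raw]]), , drop = FALSE]
  resp <- paste0(response_raw, "_mod")
  tab[[resp]] <- if (log_transform) {
    log(tab[[response_raw]] + offset_s)
  } else tab[[response_raw]]
  fixed <- behavioral_predictors(tab)
  if (include_onset_indicator && "sentence_onset" %in% names(tab)) {
    fixed <- c("sentence_onset", fixed)
  }
  tab$participant <- factor(tab$participant)
  fit_mixed_model(tab, resp, fixed,
                  random_slopes = random_slopes, focal = focal,
                  estimation = estimation)
}

#' Mixed model for pause length before each word
#'
#' Pause length (attributed to the following word) as a function of number
#' of syllables, word frequency, word surprisal, and the top-down,
#' bottom-up and open-nodes counts, with uncorrelated by-participant random
#' slopes. A positive top-down effect indicates structure building before
#' articulation. The response is log(seconds + 1 ms) by default to tame the
#' heavy right skew of pause durations; a sentence-onset indicator is
#' included because boundary pauses — the pauses that define the sentence
#' segmentation — live on a different scale from within-sentence planning
#' pauses.
#'
#' @param table Behavioral table from [build_behavioral_table()].
#' @param random_slopes Columns with by-participant random slopes (default
#'   `"top_down"`).
#' @param focal Slopes protected from the convergence fallback (default =
#'   `random_slopes`).
#' @param log_transform Model log(pause + offset_s) (default TRUE).
#' @param offset_s Additive offset before the log, seconds (default 0.001).
#' @param estimation `"ML"` or `"REML"` (default ML).
#' @param include_onset_indicator Include the sentence-onset nuisance
#'   indicator (default TRUE).
#' @return A `synbold_fit`.
#' @export
fit_pause_model <- function(table, random_slopes = "top_down",
                            focal = random_slopes, log_transform = TRUE,
                            offset_s = 0.001, estimation = c("ML", "REML"),
                            include_onset_indicator = TRUE) {
  estimation <- match.arg(estimation)
  fit_timing_model(table, "pause_before", log_transform, offset_s,
                   random_slopes, focal, estimation,
                   include_onset_indicator, drop_na = TRUE)
}

#' Mixed model for word duration
#'
#' Word duration under the same six predictors and random-effects structure
#' as [fit_pause_model()] — the design columns are identical, only the
#' response differs.
#'
#' @inheritParams fit_pause_model
#' @param random_slopes Columns with by-participant random slopes (default
#'   `"n_syllables"`).
#' @return A `synbold_fit`.
#' @export
fit_duration_model <- function(table, random_slopes = "n_syllables",
                               focal = random_slopes, log_transform = TRUE,
                               offset_s = 0.001, estimation = c("ML", "REML"),
                               include_onset_indicator = TRUE) {
  estimation <- match.arg(estimation)
  fit_timing_model(table, "duration", log_transform, offset_s,
                   random_slopes, focal, estimation,
                   include_onset_indicator, drop_na = FALSE)
}
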