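#' Canonical double-gamma HRF specification
#'
#' Parameters of the canonical hemodynamic response function (SPM-style
#' difference of two gamma densities): a positive response peaking around
#' 5-6 s and a later undershoot, with the undershoot scaled down by
#' `peak_undershoot_ratio`.
#'
#' @param peak_delay Peak delay in seconds (default 6).
#' @param undershoot_delay Undershoot delay in seconds (default 16).
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions (default 1).
#' @param peak_undershoot_ratio Peak:undershoot amplitude ratio (default 6;
#'   `Inf` removes the undershoot).
#' @param kernel_length Kernel support in seconds (default 32).
#' @param oversampling_dt Oversampled grid step in seconds (default 0.05,
#'   fine enough to resolve word-scale onsets; TR/dt is integer for the
#'   default TR of 1.5 s, so exact-TR shifts move the sampled regressor by
#'   whole scans).
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     peak_undershoot_ratio = 6, kernel_length = 32,
                     oversampling_dt = 0.05) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_dispersion > 0,
            undershoot_dispersion > 0, peak_undershoot_ratio > 0,
            kernel_length >= undershoot_delay, oversampling_dt > 0)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 kernel_length = kernel_length,
                 oversampling_dt = oversampling_dt),
            class = "hrf_spec")
}

#' Sample the double-gamma HRF kernel
#'
#' h(t) = g(t; peak) - g(t; undershoot) / ratio, with gamma-density
#' components parameterised by delay (shape * dispersion) and dispersion
#' (scale). The kernel is sampled on the oversampled grid t = 0, dt, ...,
#' kernel_length and normalised to unit peak so regression weights stay on
#' the scale of the word-level predictors.
#'
#' @param spec An [hrf_spec()].
#' @return Numeric vector `h`; attribute `"times"` holds the grid.
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$kernel_length, by = spec$oversampling_dt)
  peak <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_dispersion,
                        scale = spec$peak_dispersion)
  under <- stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                         scale = spec$undershoot_dispersion)
  h <- peak - if (is.finite(spec$peak_undershoot_ratio)) {
    under / spec$peak_undershoot_ratio
  } else 0
  h <- h / max(h)
  structure(h, times = t)
}

## Oversampled impulse train for events, shared by convolve_events and its
## derivative counterpart. Returns list(x = train, n_over = grid length).
impulse_train <- function(onsets, amplitudes, spec, tr, n_scans) {
  stopifnot(length(onsets) == length(amplitudes), tr > 0, n_scans >= 1)
  run_end <- n_scans * tr
  drop <- onsets < 0 | onsets >= run_end + spec$kernel_length
  if (any(drop)) {
    warning(sprintf("%d event(s) outside the run dropped", sum(drop)))
    onsets <- onsets[!drop]
    amplitudes <- amplitudes[!drop]
  }
  dt <- spec$oversampling_dt
  n_over <- ceiling(run_end / dt) + 1L
  x <- numeric(n_over)
  if (length(onsets)) {
    idx <- round(onsets / dt) + 1L
    keep <- idx <= n_over
    for (k in which(keep)) x[idx[k]] <- x[idx[k]] + amplitudes[k]
  }
  list(x = x, n_over = n_over, dt = dt)
}

convolve_sampled <- function(train, kernel, tr, n_scans, dt) {
  # full linear convolution; the causal part is the first length(train) lags
  y <- stats::convolve(train, rev(kernel), type = "open")[seq_along(train)]
  scan_idx <- round((0:(n_scans - 1L)) * tr / dt) + 1L
  y[scan_idx]
}

#' Convolve word events with the HRF
#'
#' Places instantaneous impulses of the given amplitudes at the event onsets
#' on the oversampled grid, convolves with the double-gamma kernel, and
#' samples the result at scan times t_k = k * TR (volume onset). Linear in
#' the amplitudes. Events beyond the run are dropped with a warning.
#'
#' @param onsets Event onsets in seconds.
#' @param amplitudes Event weights (same length as `onsets`).
#' @param spec An [hrf_spec()].
#' @param tr Repetition time in seconds.
#' @param n_scans Number of volumes.
#' @param durations Optional event durations in seconds for boxcar events
#'   (default NULL: impulses at onset, matching regressors time-locked to
#'   word onset).
#' @return Numeric regressor of length `n_scans`.
#' @export
convolve_events <- function(onsets, amplitudes, spec = hrf_spec(), tr = 1.5,
                            n_scans, durations = NULL) {
  kernel <- as.numeric(hrf_kernel(spec))
  if (!is.null(durations)) {
    stopifnot(length(durations) == length(onsets))
    dt <- spec$oversampling_dt
    steps <- pmax(1L, round(durations / dt))
    onsets <- rep(onsets, steps) +
      unlist(lapply(steps, function(s) (seq_len(s) - 1L) * dt))
    amplitudes <- rep(amplitudes / steps, steps)
  }
  tr_evts <- impulse_train(onsets, amplitudes, spec, tr, n_scans)
  convolve_sampled(tr_evts$x, kernel, tr, n_scans, tr_evts$dt)
}

#' Temporal-derivative regressor
#'
#' Convolves the same events with the time-derivative of the HRF kernel
#' (finite differences on the oversampled grid) and orthogonalizes the
#' result against the parent regressor so the parent's coefficient keeps
#' its interpretation; the derivative column then captures latency shifts
#' of the response.
#'
#' @inheritParams convolve_events
#' @param parent The parent regressor returned by [convolve_events()] for
#'   the same events (used for orthogonalization).
#' @return Numeric regressor of length `n_scans`, orthogonal to `parent`.
#' @export
temporal_derivative <- function(onsets, amplitudes, spec = hrf_spec(),
                                tr = 1.5, n_scans, parent = NULL) {
  kernel <- as.numeric(hrf_kernel(spec))
  dkernel <- c(diff(kernel), 0) / spec$oversampling_dt
  tr_evts <- impulse_train(onsets, amplitudes, spec, tr, n_scans)
  d <- convolve_sampled(tr_evts$x, dkernel, tr, n_scans, tr_evts$dt)
  if (is.null(parent)) {
    parent <- convolve_sampled(tr_evts$x, kernel, tr, n_scans, tr_evts$dt)
  }
  if (sum(parent^2) > 0) {
    d <- d - parent * sum(d * parent) / sum(parent^2)
  }
  d
}

#' Build the scan-resolution design matrix
#'
#' Converts a word-level predictor table into TR-resolution regressors:
#' each selected column is used as the amplitude of an impulse at the
#' word's onset and convolved with the canonical HRF. Predictors are
#' mean-centered first (word rate and boundary regressors excepted), per
#' centering group = recall.
#'
#' @param table Word predictor table from [build_predictor_table()].
#' @param columns Regressor columns to build. Default: the baseline rates
#'   and covariates, the comprehension-parser metrics and the boundary
#'   regressors, when present in `table`.
#' @param spec An [hrf_spec()].
#' @param tr Repetition time in seconds (default 1.5).
#' @param n_scans Number of volumes.
#' @param derivatives Also add orthogonalized temporal-derivative columns
#'   (named `<col>_deriv`) for these columns (character vector; default
#'   none).
#' @param center Mean-center amplitude columns first (default TRUE).
#' @return Data.frame of regressors with `n_scans` rows; attributes `tr`,
#'   `hrf_spec`, `centered`.
#' @export
build_design_matrix <- function(table, columns = NULL, spec = hrf_spec(),
                                tr = 1.5, n_scans, derivatives = character(0),
                                center = TRUE) {
  default_cols <- c("word_rate", "n_syllables", "log_frequency", "surprisal",
                    "open_nodes", "top_down", "bottom_up",
                    "sentence_onset", "sentence_offset")
  if (is.null(columns)) columns <- intersect(default_cols, names(table))
  miss <- setdiff(columns, names(table))
  if (length(miss)) stop("design columns absent from table: ",
                         paste(miss, collapse = ", "))
  if (center) {
    grp <- if ("recall_id" %in% names(table)) table$recall_id else NULL
    table <- mean_center(table, group = grp)
  }
  out <- data.frame(row.names = seq_len(n_scans))
  for (cn in columns) {
    out[[cn]] <- convolve_events(table$onset, as.numeric(table[[cn]]),
                                 spec, tr, n_scans)
  }
  for (cn in derivatives) {
    if (!cn %in% columns) stop("derivative requested for absent column: ", cn)
    out[[paste0(cn, "_deriv")]] <- temporal_derivative(
      table$onset, as.numeric(table[[cn]]), spec, tr, n_scans,
      parent = out[[cn]])
  }
  attr(out, "tr") <- tr
  attr(out, "hrf_spec") <- spec
  attr(out, "centered") <- center
  out
}

#' Pairwise collinearity report for a design matrix
#'
#' Pearson correlations between all regressor pairs, flagging pairs above a
#' threshold. HRF convolution smooths word-level predictors over many
#' seconds, so distinct counting strategies can become highly correlated at
#' scan resolution — this report is the diagnostic for deciding which
#' parsers can share a model.
#'
#' @param dm Design matrix (data.frame of regressors).
#' @param threshold Absolute correlation flagged as high (default 0.7).
#' @return Data.frame with `col_a`, `col_b`, `r`, `high` (NA r for
#'   zero-variance columns).
#' @export
collinearity_report <- function(dm, threshold = 0.7) {
  cols <- names(dm)
  if (length(cols) < 2L) stop("need at least two columns")
  pairs <- utils::combn(cols, 2)
  r <- apply(pairs, 2, function(p) {
    a <- dm[[p[1]]]; b <- dm[[p[2]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  })
  data.frame(col_a = pairs[1, ], col_b = pairs[2, ], r = r,
             high = !is.na(r) & abs(r) >= threshold)
}
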