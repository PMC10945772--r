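#' Deviation and Helmert coding for modality and ROI
#'
#' Modality (production vs. comprehension) is deviation-coded as +1/2 vs
#' -1/2, so a slope-by-modality interaction coefficient equals the
#' production-minus-comprehension slope difference. ROI is Helmert-coded
#' with two orthogonal zero-sum columns: LIFG (BA44 + BA45) vs. LpMTG, and
#' BA44 vs. BA45.
#'
#' @param modality Character/factor vector with levels `production`,
#'   `comprehension` (or NULL to skip).
#' @param roi Character/factor vector with levels in `roi_levels` (or NULL
#'   to skip).
#' @param roi_levels ROI label set: first two are the LIFG partes, third
#'   the temporal ROI (default `c("BA44", "BA45", "LpMTG")`).
#' @return Data.frame with any of `modality_dev`, `roi_lifg_vs_pmtg`,
#'   `roi_ba44_vs_ba45`.
#' @export
code_factors <- function(modality = NULL, roi = NULL,
                         roi_levels = c("BA44", "BA45", "LpMTG")) {
  out <- list()
  if (!is.null(modality)) {
    m <- as.character(modality)
    bad <- setdiff(unique(m), c("production", "comprehension"))
    if (length(bad)) stop("unknown modality level(s): ",
                          paste(bad, collapse = ", "))
    out$modality_dev <- ifelse(m == "production", 0.5, -0.5)
  }
  if (!is.null(roi)) {
    r <- as.character(roi)
    bad <- setdiff(unique(r), roi_levels)
    if (length(bad)) stop("unknown ROI level(s): ", paste(bad, collapse = ", "))
    stopifnot(length(roi_levels) == 3L)
    c1 <- c(0.5, 0.5, -1)[match(r, roi_levels)]   # LIFG vs LpMTG
    c2 <- c(1, -1, 0)[match(r, roi_levels)]       # BA44 vs BA45
    out$roi_lifg_vs_pmtg <- c1
    out$roi_ba44_vs_ba45 <- c2
  }
  as.data.frame(out)
}

#' Fit a mixed-effects encoding model
#'
#' Linear mixed model relating a response (ROI BOLD at scan resolution, or
#' log pause/duration at word resolution) to fixed-effect regressors with
#' uncorrelated by-participant random slopes, fit with lme4. If the fit is
#' singular or fails to converge, the weakest non-focal random slope
#' (smallest estimated variance) is dropped and the model refit; the focal
#' slope is never dropped. The normal approximation is used for t and Wald
#' statistics (observations per participant are large).
#'
#' @param data Long data.frame; must contain `participant` and all model
#'   columns.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (column names or
#'   interaction terms like `"top_down:modality_dev"`).
#' @param random_slopes Character vector of columns receiving independent
#'   by-participant random slopes (no correlations, no random intercept
#'   unless `random_intercept = TRUE`).
#' @param focal Random-slope terms protected from the convergence fallback
#'   (default none).
#' @param estimation `"ML"` (required for AIC/LRT comparison across fixed
#'   structures) or `"REML"`.
#' @param random_intercept Add a by-participant random intercept (default
#'   FALSE).
#' @param max_fallbacks Maximum slopes dropped before giving up (default 2).
#' @return A `synbold_fit`: list with `model` (merMod), `fixed` (estimate,
#'   SE, t, p per coefficient), `varcomp`, `logLik`, `AIC`, `n_obs`,
#'   `converged`, `singular`, `dropped_slopes`, `estimation`, `formula`.
#' @export
fit_mixed_model <- function(data, response, fixed, random_slopes = character(0),
                            focal = character(0),
                            estimation = c("ML", "REML"),
                            random_intercept = FALSE, max_fallbacks = 2L) {
  estimation <- match.arg(estimation)
  stopifnot("participant" %in% names(data), response %in% names(data))
  if (anyNA(data[[response]])) stop("response contains missing values")
  check_rank(data, fixed)
  if (length(random_slopes) == 0L && !random_intercept) {
    return(fit_fixed_only(data, response, fixed, estimation))
  }
  slopes <- random_slopes
  dropped <- character(0)
  fit <- NULL
  for (attempt in seq_len(max_fallbacks + 1L)) {
    fml <- build_lmer_formula(response, fixed, slopes, random_intercept)
    fit <- suppressMessages(try(lme4::lmer(
      fml, data = data, REML = (estimation == "REML"),
      control = lme4::lmerControl(calc.derivs = FALSE)), silent = TRUE))
    if (inherits(fit, "try-error")) {
      ok <- FALSE
    } else {
      ok <- !lme4::isSingular(fit, tol = 1e-5)
    }
    droppable <- setdiff(slopes, focal)
    if (ok || length(droppable) == 0L || attempt > max_fallbacks) break
    weakest <- if (inherits(fit, "try-error")) {
      droppable[1L]
    } else {
      vc <- slope_variances(fit)
      cand <- vc[names(vc) %in% droppable]
      names(cand)[which.min(cand)]
    }
    dropped <- c(dropped, weakest)
    slopes <- setdiff(slopes, weakest)
  }
  if (inherits(fit, "try-error")) {
    stop("mixed model failed to fit: ", attr(fit, "condition")$message)
  }
  summarize_fit(fit, estimation, dropped, converged = ok)
}

## Degenerate case: no random terms requested -> ordinary least squares,
## wrapped in the same FitResult shape (ML logLik so AIC/LRT remain valid).
fit_fixed_only <- function(data, response, fixed, estimation) {
  fml <- stats::reformulate(fixed, response = response)
  m <- stats::lm(fml, data = data)
  b <- stats::coef(m)
  V <- stats::vcov(m)
  se <- sqrt(diag(V))
  t <- b / se
  ll <- as.numeric(stats::logLik(m))
  k <- attr(stats::logLik(m), "df")
  structure(list(model = m,
                 fixed = data.frame(term = names(b), estimate = as.numeric(b),
                                    se = se, t = t,
                                    p = 2 * stats::pnorm(-abs(t)),
                                    stringsAsFactors = FALSE, row.names = NULL),
                 vcov = as.matrix(V), varcomp = numeric(0),
                 sigma = stats::sigma(m), logLik = ll, n_params = k,
                 AIC = 2 * k - 2 * ll, n_obs = stats::nobs(m),
                 converged = TRUE, singular = FALSE,
                 dropped_slopes = character(0), estimation = estimation,
                 formula = fml),
            class = "synbold_fit")
}

check_rank <- function(data, fixed) {
  mm <- stats::model.matrix(stats::reformulate(fixed), data)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

build_lmer_formula <- function(response, fixed, slopes, random_intercept) {
  re <- character(0)
  if (random_intercept) re <- "(1 | participant)"
  re <- c(re, sprintf("(0 + %s | participant)", slopes))
  rhs <- paste(c(fixed, re), collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

slope_variances <- function(model) {
  vc <- lme4::VarCorr(model)
  out <- numeric(0)
  for (g in vc) {
    v <- diag(g)
    names(v) <- colnames(g)
    out <- c(out, v)
  }
  out
}

summarize_fit <- function(model, estimation, dropped, converged) {
  b <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(V))
  t <- b / se
  fixed <- data.frame(term = names(b), estimate = as.numeric(b), se = se,
                      t = t, p = 2 * stats::pnorm(-abs(t)),
                      stringsAsFactors = FALSE, row.names = NULL)
  ll <- as.numeric(stats::logLik(model))
  k <- attr(stats::logLik(model), "df")
  vc <- slope_variances(model)
  structure(list(model = model, fixed = fixed, vcov = V,
                 varcomp = vc, sigma = stats::sigma(model),
                 logLik = ll, n_params = k, AIC = 2 * k - 2 * ll,
                 n_obs = stats::nobs(model),
                 converged = converged,
                 singular = lme4::isSingular(model, tol = 1e-5),
                 dropped_slopes = dropped, estimation = estimation,
                 formula = stats::formula(model)),
            class = "synbold_fit")
}

#' @export
print.synbold_fit <- function(x, ...) {
  cat("Mixed-effects encoding model (", x$estimation, ")\n", sep = "")
  cat("  n_obs =", x$n_obs, " logLik =", round(x$logLik, 1),
      " AIC =", round(x$AIC, 1), "\n")
  if (length(x$dropped_slopes)) {
    cat("  dropped random slopes:", paste(x$dropped_slopes, collapse = ", "), "\n")
  }
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Wald chi-square tests per fixed-effect term
#'
#' For each fixed term (interaction bundles included), tests the joint null
#' that the term's coefficient block is zero with a Wald chi-square on the
#' estimated coefficient covariance; df = number of coefficients in the
#' block. For single-coefficient terms the statistic equals t squared.
#'
#' @param fit A `synbold_fit`.
#' @return Data.frame with `term`, `chisq`, `df`, `p`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "synbold_fit"))
  mm <- stats::model.matrix(fit$model)
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(fit$model), "term.labels")
  b <- fit$fixed$estimate
  V <- fit$vcov
  rows <- lapply(seq_along(labels), function(i) {
    idx <- which(asgn == i)
    Vi <- V[idx, idx, drop = FALSE]
    chisq <- tryCatch(
      as.numeric(t(b[idx]) %*% solve(Vi, b[idx])),
      error = function(e) NA_real_)
    if (is.na(chisq)) warning("singular covariance block for term ", labels[i])
    data.frame(term = labels[i], chisq = chisq, df = length(idx),
               p = stats::pchisq(chisq, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell slopes and pairwise contrasts for a continuous predictor
#'
#' Computes the slope of a continuous focal predictor within each cell of
#' coded factor columns (e.g. per modality, per ROI), as linear
#' combinations of the fixed effects, and all pairwise cell differences.
#' SEs come from the coefficient covariance; pairwise p-values are
#' Tukey-adjusted within the family (studentized-range distribution, normal
#' degrees of freedom).
#'
#' @param fit A `synbold_fit`.
#' @param term Name of the continuous focal predictor.
#' @param by Named list of coded factor columns and their cell values, e.g.
#'   `list(modality_dev = c(production = 0.5, comprehension = -0.5))`.
#' @return List with `cells` (cell, slope, se, z, p) and `contrasts`
#'   (pairwise differences, Tukey-adjusted p).
#' @export
pairwise_contrasts <- function(fit, term, by) {
  stopifnot(inherits(fit, "synbold_fit"), length(by) >= 1L)
  coefs <- fit$fixed$term
  if (!term %in% coefs) stop("focal term not in fit: ", term)
  grid <- expand.grid(lapply(by, names), stringsAsFactors = FALSE)
  names(grid) <- names(by)
  b <- fit$fixed$estimate
  V <- fit$vcov
  L <- matrix(0, nrow(grid), length(b), dimnames = list(NULL, coefs))
  for (g in seq_len(nrow(grid))) {
    for (j in seq_along(coefs)) {
      parts <- strsplit(coefs[j], ":", fixed = TRUE)[[1]]
      if (!term %in% parts) next
      others <- setdiff(parts, term)
      if (!all(others %in% names(by))) next
      val <- 1
      for (o in others) val <- val * by[[o]][[grid[g, o]]]
      L[g, j] <- val
    }
  }
  slope <- as.numeric(L %*% b)
  se <- sqrt(diag(L %*% V %*% t(L)))
  cells <- data.frame(grid, slope = slope, se = se, z = slope / se,
                      p = 2 * stats::pnorm(-abs(slope / se)))
  m <- nrow(grid)
  if (m >= 2L) {
    cmb <- utils::combn(m, 2)
    Ld <- L[cmb[1, ], , drop = FALSE] - L[cmb[2, ], , drop = FALSE]
    d <- as.numeric(Ld %*% b)
    sed <- sqrt(diag(Ld %*% V %*% t(Ld)))
    z <- d / sed
    p_adj <- stats::ptukey(abs(z) * sqrt(2), nmeans = m, df = Inf,
                           lower.tail = FALSE)
    lab <- function(i) apply(grid[i, , drop = FALSE], 1, paste, collapse = ".")
    contrasts <- data.frame(contrast = paste(lab(cmb[1, ]), "-", lab(cmb[2, ])),
                            estimate = d, se = sed, z = z, p_tukey = p_adj,
                            stringsAsFactors = FALSE)
  } else {
    contrasts <- data.frame()
  }
  list(cells = cells, contrasts = contrasts)
}

#' Compare encoding models by AIC and likelihood-ratio tests
#'
#' Ranks fits by AIC and, for ML fits on the identical observation set
#' whose parameter counts nest, adds likelihood-ratio chi-squares against
#' the next-smaller model. REML fits with different fixed-effect structures
#' are refused.
#'
#' @param fits Named list of `synbold_fit` objects on the same response.
#' @return Data.frame sorted by AIC: `model`, `n_params`, `logLik`, `AIC`,
#'   `dAIC`, and `lrt_chisq`, `lrt_df`, `lrt_p` versus the preceding
#'   smaller ML model where applicable.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1L) {
    stop("models fit on different observation counts cannot be compared")
  }
  est <- vapply(fits, `[[`, character(1), "estimation")
  if (any(est == "REML")) {
    fmls <- vapply(fits, function(f) {
      paste(deparse(lme4::nobars(f$formula)), collapse = "")
    }, character(1))
    if (length(unique(fmls)) > 1L) {
      stop("REML fits with different fixed effects cannot be compared")
    }
  }
  tab <- data.frame(
    model = names(fits),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$lrt_chisq <- NA_real_; tab$lrt_df <- NA_real_; tab$lrt_p <- NA_real_
  if (all(est == "ML")) {
    ord <- order(tab$n_params)
    for (i in seq_along(ord)[-1]) {
      big <- tab[ord[i], ]; small <- tab[ord[i - 1L], ]
      ddf <- big$n_params - small$n_params
      if (ddf > 0) {
        chisq <- max(0, 2 * (big$logLik - small$logLik))
        tab$lrt_chisq[ord[i]] <- chisq
        tab$lrt_df[ord[i]] <- ddf
        tab$lrt_p[ord[i]] <- stats::pchisq(chisq, ddf, lower.tail = FALSE)
      }
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Stack BOLD series with per-participant design matrices
#'
#' Builds the long table consumed by [fit_mixed_model()]: one row per
#' (participant, roi, scan) with the response `value` and the participant's
#' design-matrix columns, plus coded factor columns.
#'
#' @param bold BOLD data.frame (`participant`, `roi`, `tr_index`, `value`),
#'   as from [read_roi_timeseries()].
#' @param designs Named list: participant id -> design matrix (data.frame
#'   of regressors, rows = scans in order).
#' @param modality Optional single modality label or named vector per
#'   participant; adds deviation-coded `modality_dev`.
#' @param roi_levels Passed to [code_factors()].
#' @return Long data.frame ready for fitting.
#' @export
stack_bold_design <- function(bold, designs, modality = NULL,
                              roi_levels = c("BA44", "BA45", "LpMTG")) {
  parts <- unique(bold$participant)
  miss <- setdiff(as.character(parts), names(designs))
  if (length(miss)) stop("no design matrix for participant(s): ",
                         paste(miss, collapse = ", "))
  rows <- lapply(as.character(parts), function(p) {
    bp <- bold[bold$participant == p, , drop = FALSE]
    dm <- designs[[p]]
    idx <- bp$tr_index + 1L
    if (max(idx) > nrow(dm)) stop("tr_index exceeds design rows for ", p)
    cbind(bp, dm[idx, , drop = FALSE], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(unique(out$roi)) == 3L) {
    out <- cbind(out, code_factors(roi = out$roi, roi_levels = roi_levels))
  }
  if (!is.null(modality)) {
    m <- if (length(modality) == 1L) rep(modality, nrow(out)) else {
      unname(modality[as.character(out$participant)])
    }
    out$modality_dev <- code_factors(modality = m)$modality_dev
  }
  out$participant <- factor(out$participant)
  out
}
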