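#' Read bracketed constituency parses
#'
#' Reads a file of Penn-Treebank-style bracketed parse strings, one sentence
#' per line or per balanced block (a record may span lines; records are
#' delimited by bracket balance). Empty records are skipped with a warning.
#'
#' @param path Path to a text file of bracketed parses.
#' @param strip Tokens (e.g. punctuation) to remove from every tree before
#'   metric computation; default none.
#' @return List of [parse_tree] objects.
#' @export
read_bracketed_trees <- function(path, strip = character(0)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  records <- split_balanced_records(lines)
  trees <- vector("list", 0L)
  rec_no <- 0L
  for (rec in records) {
    rec_no <- rec_no + 1L
    if (!nzchar(trimws(rec))) {
      warning(sprintf("empty record %d skipped", rec_no))
      next
    }
    depth <- bracket_depth(rec)
    if (depth != 0L) stop(sprintf("unbalanced brackets at record %d", rec_no))
    tree <- tryCatch(parse_bracketed(rec), error = function(e) {
      stop(sprintf("unbalanced brackets at record %d: %s", rec_no,
                   conditionMessage(e)), call. = FALSE)
    })
    if (length(strip)) {
      tree <- strip_terminals(tree, strip)
      if (is.null(tree)) {
        warning(sprintf("record %d empty after stripping; skipped", rec_no))
        next
      }
    }
    trees[[length(trees) + 1L]] <- tree
  }
  trees
}

## Split lines into records: a record ends when bracket depth returns to 0.
## Blank lines at depth 0 delimit (and may produce empty records, which the
## caller warns about only if the file had content-bearing separators).
split_balanced_records <- function(lines) {
  records <- character(0)
  buf <- character(0)
  depth <- 0L
  for (ln in lines) {
    has <- nzchar(trimws(ln))
    if (depth == 0L && !has) next
    buf <- c(buf, ln)
    depth <- depth + bracket_depth(ln)
    if (depth < 0L) {
      records <- c(records, paste(buf, collapse = " "))
      buf <- character(0)
      depth <- 0L
    } else if (depth == 0L && has) {
      records <- c(records, paste(buf, collapse = " "))
      buf <- character(0)
    }
  }
  if (length(buf)) records <- c(records, paste(buf, collapse = " "))
  records
}

bracket_depth <- function(x) {
  chars <- strsplit(x, "")[[1]]
  sum(chars == "(") - sum(chars == ")")
}

#' Write trees as bracketed text
#' @param trees List of [parse_tree] objects.
#' @param path Output path; one record per line.
#' @return Invisibly, `path`.
#' @export
write_bracketed_trees <- function(trees, path) {
  writeLines(vapply(trees, deparse_bracketed, character(1)), path)
  invisible(path)
}

#' Read dependency parses from a CoNLL-U file
#'
#' Keeps columns 1 (index), 2 (form), 7 (head) and 8 (relation). Comment
#' lines and multiword-token / empty-node lines (ids containing `-` or `.`)
#' are ignored. Each sentence must have exactly one root (head 0).
#'
#' @param path Path to a CoNLL-U file.
#' @return List of dependency parses; each is a list with `form` (tokens),
#'   `head` (integer vector, 1-based token indices, 0 = root) and `relation`.
#' @export
read_dependency <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  cur <- list()
  sent_no <- 0L
  flush <- function() {
    if (length(cur) == 0L) return(invisible())
    sent_no <<- sent_no + 1L
    form <- vapply(cur, `[[`, character(1), "form")
    head <- vapply(cur, `[[`, integer(1), "head")
    rel <- vapply(cur, `[[`, character(1), "relation")
    n <- length(head)
    if (any(head > n)) {
      stop(sprintf("sentence %d: head index out of range", sent_no))
    }
    if (any(head == seq_len(n))) {
      stop(sprintf("sentence %d: token is its own head", sent_no))
    }
    if (sum(head == 0L) != 1L) {
      stop(sprintf("sentence %d: expected exactly one root, found %d",
                   sent_no, sum(head == 0L)))
    }
    out[[length(out) + 1L]] <<- list(form = form, head = head, relation = rel)
    cur <<- list()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) stop("CoNLL-U line with fewer than 8 columns")
    if (grepl("[-.]", f[1])) next  # multiword token / empty node
    hd <- suppressWarnings(as.integer(f[7]))
    if (is.na(hd)) stop("non-integer HEAD field in CoNLL-U")
    cur[[length(cur) + 1L]] <- list(form = f[2], head = hd, relation = f[8])
  }
  flush()
  out
}

#' Write dependency parses to CoNLL-U
#' @param deps List of dependency parses (`form`, `head`, `relation`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dependency <- function(deps, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(deps)) {
    d <- deps[[i]]
    writeLines(sprintf("# sent_id = %d", i), con)
    for (j in seq_along(d$form)) {
      writeLines(paste(j, d$form[j], "_", "_", "_", "_", d$head[j],
                       d$relation[j], "_", "_", sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a word-timing table
#'
#' Expects a TSV with header and at least columns `word`, `onset`, `offset`
#' (seconds); optional `sentence_id` and `recall_id`. Rows are ordered by
#' onset (with a warning if reordering was needed) and validated:
#' `offset >= onset`, onsets non-negative.
#'
#' @param path TSV path.
#' @return A data.frame with columns `word`, `onset`, `offset`,
#'   `sentence_id`, `recall_id`.
#' @export
read_word_timings <- function(path) {
  stopifnot(file.exists(path))
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("word", "onset", "offset")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("timing table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(x$onset) || !is.numeric(x$offset)) {
    stop("onset/offset must be numeric")
  }
  if (!"recall_id" %in% names(x)) x$recall_id <- "recall1"
  if (!"sentence_id" %in% names(x)) x$sentence_id <- 0L
  validate_timings(x)
}

validate_timings <- function(x) {
  ord <- order(x$recall_id, x$onset)
  if (!identical(ord, seq_len(nrow(x)))) {
    warning("timing rows reordered by onset")
    x <- x[ord, , drop = FALSE]
    rownames(x) <- NULL
  }
  bad <- which(x$offset < x$onset)
  if (length(bad)) {
    stop("offset < onset at row(s): ", paste(utils::head(bad, 10), collapse = ", "))
  }
  if (any(x$onset < 0)) stop("negative onset in timing table")
  x
}

#' Write a timing table to TSV
#' @param timings Data.frame as returned by [read_word_timings()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_word_timings <- function(timings, path) {
  utils::write.table(timings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Disfluency-informed sentence segmentation
#'
#' Re-assigns sentence ids from pausing patterns: a new sentence starts at
#' any word whose gap from the previous word's offset (within the same
#' recall) is at least `pause_threshold` seconds. Existing sentence
#' boundaries are preserved; resulting ids are consecutive from 0 within each
#' recall. Spontaneous monologue transcripts have no objective sentence
#' boundaries; long pauses are taken to mark the speaker's planning chunks,
#' so a long pause splits a sentence even mid-clause.
#'
#' @param timings Timing data.frame (`word`, `onset`, `offset`, optionally
#'   `sentence_id`, `recall_id`).
#' @param pause_threshold Minimum silent gap, in seconds, that starts a new
#'   sentence (default 1.0).
#' @param respect_existing Keep boundaries already present in `sentence_id`
#'   (default TRUE).
#' @return The timing data.frame with `sentence_id` reassigned.
#' @export
segment_sentences <- function(timings, pause_threshold = 1.0,
                              respect_existing = TRUE) {
  stopifnot(pause_threshold > 0)
  if (nrow(timings) == 0L) return(timings)
  timings <- validate_timings(timings)
  if (!"recall_id" %in% names(timings)) timings$recall_id <- "recall1"
  had_ids <- "sentence_id" %in% names(timings) && respect_existing
  out <- timings
  for (rid in unique(timings$recall_id)) {
    idx <- which(timings$recall_id == rid)
    on <- timings$onset[idx]
    off <- timings$offset[idx]
    gap <- c(Inf, on[-1L] - off[-length(idx)])
    new_sent <- gap >= pause_threshold
    if (had_ids) {
      old <- timings$sentence_id[idx]
      new_sent <- new_sent | c(TRUE, diff(old) != 0)
    }
    new_sent[1L] <- TRUE
    out$sentence_id[idx] <- cumsum(new_sent) - 1L
  }
  out
}

#' Read ROI-averaged BOLD timeseries
#'
#' Expects a TSV with header and columns `participant`, `roi`, `tr_index`,
#' `value`. Each (participant, roi) series must have contiguous `tr_index`
#' from its minimum and no duplicates.
#'
#' @param path TSV path.
#' @param tr Repetition time in seconds (default 1.5); attached as an
#'   attribute.
#' @return Data.frame grouped by (participant, roi), ordered by tr_index.
#' @export
read_roi_timeseries <- function(path, tr = 1.5) {
  stopifnot(file.exists(path), tr > 0)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant", "roi", "tr_index", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("BOLD table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(x$value)) stop("value column must be numeric")
  if (!is.numeric(x$tr_index)) stop("tr_index column must be numeric")
  x <- x[order(x$participant, x$roi, x$tr_index), , drop = FALSE]
  rownames(x) <- NULL
  sp <- split(x$tr_index, interaction(x$participant, x$roi, drop = TRUE))
  for (k in names(sp)) {
    ti <- sp[[k]]
    if (anyDuplicated(ti)) {
      stop(sprintf("duplicated (participant, roi, tr_index) in series %s", k))
    }
    if (!identical(as.integer(ti), as.integer(seq(min(ti), by = 1, length.out = length(ti))))) {
      stop(sprintf("gap in tr_index for series %s", k))
    }
  }
  attr(x, "tr") <- tr
  x
}

#' Write a BOLD table to TSV
#' @param bold Data.frame with `participant`, `roi`, `tr_index`, `value`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_roi_timeseries <- function(bold, path) {
  utils::write.table(bold, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
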