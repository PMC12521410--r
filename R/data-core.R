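#' Construct a word pool
#'
#' A word pool is the fixed vocabulary of an experiment: `N` unique item
#' tokens, optionally carrying one embedding row per item, plus dedicated
#' start-of-sequence and end-of-sequence markers that live outside the `N`
#' item slots.
#'
#' @param items Character vector of unique item tokens.
#' @param embeddings Optional numeric matrix with `length(items)` rows, one
#'   embedding per item.
#' @param sos,eos Start/end-of-sequence marker strings; they must not collide
#'   with item tokens.
#' @return An object of class `ms_wordpool` with fields `items`, `N`,
#'   `embeddings`, `sos`, `eos`.
#' @examples
#' pool <- wordpool(c("dog", "cat", "tree"))
#' pool$N
#' @export
wordpool <- function(items, embeddings = NULL, sos = "<s>", eos = "</s>") {
  items <- as.character(items)
  if (length(items) < 2L) stop("a word pool needs at least 2 items")
  if (anyDuplicated(items)) {
    stop("duplicate tokens in word pool: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  }
  if (any(c(sos, eos) %in% items)) stop("sos/eos markers collide with items")
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    if (nrow(embeddings) != length(items)) {
      stop("embeddings must have one row per pool item (",
           length(items), "), got ", nrow(embeddings))
    }
    storage.mode(embeddings) <- "double"
    rownames(embeddings) <- items
  }
  structure(list(items = items, N = length(items), embeddings = embeddings,
                 sos = sos, eos = eos),
            class = "ms_wordpool")
}

#' @export
print.ms_wordpool <- function(x, ...) {
  cat("<ms_wordpool> N =", x$N,
      if (is.null(x$embeddings)) "(no embeddings)" else
        paste0("(embeddings ", x$N, "x", ncol(x$embeddings), ")"), "\n")
  invisible(x)
}

#' Construct a study list
#'
#' A study list is an ordered sequence of distinct pool item indices, the
#' list a participant (or model) studies on one trial.
#'
#' @param positions Integer vector of item indices (1-based, into the pool).
#' @param N Pool size used for range validation.
#' @return Integer vector of class `ms_study_list`.
#' @export
study_list <- function(positions, N) {
  positions <- as.integer(positions)
  if (length(positions) > N) stop("list length exceeds pool size")
  if (length(positions) && (min(positions) < 1L || max(positions) > N)) {
    stop("item index out of range [1, ", N, "]")
  }
  if (anyDuplicated(positions)) {
    stop("repeated item within a study list (positions ",
         paste(which(duplicated(positions)), collapse = ", "), ")")
  }
  structure(positions, class = "ms_study_list")
}

#' Construct a free-recall trial
#'
#' @param study Study list (integer item indices, no repeats).
#' @param recall Integer vector of recalled item indices; may be empty, may
#'   contain repeats and intrusions (items not on the study list).
#' @param participant,session Identifier strings.
#' @param N Pool size for validation.
#' @return An object of class `ms_trial`.
#' @export
trial <- function(study, recall = integer(0), participant = "p1",
                  session = "s1", N = max(c(study, recall, 2L))) {
  study <- study_list(study, N)
  recall <- as.integer(recall)
  if (length(recall) && (min(recall) < 1L || max(recall) > N)) {
    stop("recalled item index out of range [1, ", N, "]")
  }
  structure(list(study = study, recall = recall,
                 participant = as.character(participant),
                 session = as.character(session)),
            class = "ms_trial")
}

#' Bundle trials and a word pool into a dataset
#'
#' All trials must share the pool and (for the fixed-list-length experiments
#' modelled here) the same list length `L`.
#'
#' @param trials List of [trial()] objects.
#' @param pool An [wordpool()] object.
#' @return An object of class `ms_dataset` with fields `trials`, `wordpool`,
#'   `L` (common list length, `NA` for an empty dataset).
#' @export
dataset <- function(trials, pool) {
  stopifnot(inherits(pool, "ms_wordpool"))
  trials <- unname(trials)
  ds <- structure(list(trials = trials, wordpool = pool,
                       L = if (length(trials)) length(trials[[1L]]$study) else NA_integer_),
                  class = "ms_dataset")
  rep <- validate_dataset(ds)
  if (nrow(rep)) {
    stop("invalid dataset:\n", paste(utils::head(rep$message, 5L), collapse = "\n"))
  }
  ds
}

#' @export
print.ms_dataset <- function(x, ...) {
  cat("<ms_dataset>", length(x$trials), "trials, L =", x$L,
      ", pool N =", x$wordpool$N, "\n")
  invisible(x)
}

#' @export
length.ms_dataset <- function(x) length(x$trials)

#' Validate a dataset against its invariants
#'
#' Checks that every study list is within the pool, repeat-free, and that all
#' lists share one length. A reporting operation: it never throws.
#'
#' @param ds An `ms_dataset` (fields `trials`, `wordpool`).
#' @return A data frame with columns `trial`, `type`, `message`; zero rows iff
#'   the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  out <- list()
  N <- ds$wordpool$N
  Ls <- vapply(ds$trials, function(t) length(t$study), integer(1))
  if (length(Ls) && length(unique(Ls)) > 1L) {
    modal <- as.integer(names(sort(table(Ls), decreasing = TRUE))[1L])
    for (i in which(Ls != modal)) {
      out[[length(out) + 1L]] <- data.frame(
        trial = i, type = "mixed_L",
        message = sprintf("trial %d has L = %d, expected %d", i, Ls[i], modal))
    }
  }
  for (i in seq_along(ds$trials)) {
    t <- ds$trials[[i]]
    idx <- c(unclass(t$study), t$recall)
    if (length(idx) && (min(idx) < 1L || max(idx) > N)) {
      out[[length(out) + 1L]] <- data.frame(
        trial = i, type = "index_range",
        message = sprintf("trial %d refers to items outside [1, %d]", i, N))
    }
    if (anyDuplicated(t$study)) {
      out[[length(out) + 1L]] <- data.frame(
        trial = i, type = "intra_list_repeat",
        message = sprintf("trial %d repeats an item within its study list", i))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(trial = integer(0), type = character(0), message = character(0))
}

# --- trial file format -------------------------------------------------------

MS_TRIALS_HEADER <- "#memsearch-trials v1"

#' Read trials from a tab-separated trial file
#'
#' The format is one trial per line:
#' `participant <TAB> session <TAB> study tokens (comma-separated) <TAB>
#' recall tokens (comma-separated, possibly empty)`, preceded by the header
#' line `#memsearch-trials v1`. Recall fields may contain repeats and
#' intrusions; study fields may not.
#'
#' @param path Path to the trial file.
#' @param pool Word pool used to resolve tokens to indices.
#' @return An `ms_dataset`.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, pool) {
  stopifnot(inherits(pool, "ms_wordpool"))
  if (!file.exists(path)) stop("trial file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || lines[1L] != MS_TRIALS_HEADER) {
    stop("missing header line '", MS_TRIALS_HEADER, "' in ", path)
  }
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  lookup <- stats::setNames(seq_len(pool$N), pool$items)
  resolve <- function(tokens, lineno, field) {
    if (!length(tokens)) return(integer(0))
    idx <- lookup[tokens]
    if (anyNA(idx)) {
      bad <- tokens[is.na(idx)][1L]
      stop(sprintf("line %d: unknown token '%s' in %s field", lineno, bad, field))
    }
    as.integer(idx)
  }
  trials <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 3L) f <- c(f, "")
    if (length(f) != 4L) stop(sprintf("line %d: expected 4 tab-separated fields, got %d",
                                      i + 1L, length(f)))
    split_tok <- function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1L]] else character(0)
    study <- resolve(split_tok(f[3L]), i + 1L, "study")
    if (anyDuplicated(study)) stop(sprintf("line %d: duplicate item within study list", i + 1L))
    recall <- resolve(split_tok(f[4L]), i + 1L, "recall")
    trials[[i]] <- trial(study, recall, participant = f[1L], session = f[2L],
                         N = pool$N)
  }
  dataset(trials, pool)
}

#' Write trials to the tab-separated trial format
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(d), pool)` is the
#' identity on valid datasets.
#'
#' @param ds An `ms_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ds, path) {
  stopifnot(inherits(ds, "ms_dataset"))
  toks <- ds$wordpool$items
  lines <- vapply(ds$trials, function(t) {
    paste(t$participant, t$session,
          paste(toks[unclass(t$study)], collapse = ","),
          paste(toks[t$recall], collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(c(MS_TRIALS_HEADER, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Attach word vectors from a text file to a pool
#'
#' Reads the common word-vector text dialect (one record per line: token then
#' whitespace-separated floats, no header) and attaches an embedding row for
#' every pool item. The vector dimension is inferred from the first line and
#' enforced on every subsequent line.
#'
#' @param path Path to the vector file.
#' @param pool Word pool whose items must all be covered by the file.
#' @return The pool with `embeddings` attached.
#' @export
load_word_vectors <- function(path, pool) {
  stopifnot(inherits(pool, "ms_wordpool"))
  if (!file.exists(path)) stop("vector file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty vector file: ", path)
  vecs <- new.env(parent = emptyenv())
  d <- NA_integer_
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric vector entry", i))
    if (is.na(d)) d <- length(v)
    if (length(v) != d) {
      stop(sprintf("line %d: vector length %d, expected %d", i, length(v), d))
    }
    assign(f[1L], v, envir = vecs)
  }
  missing <- pool$items[!vapply(pool$items, exists, logical(1), envir = vecs)]
  if (length(missing)) {
    stop("pool items missing from vector file: ", paste(missing, collapse = ", "))
  }
  emb <- t(vapply(pool$items, get, numeric(d), envir = vecs))
  wordpool(pool$items, embeddings = emb, sos = pool$sos, eos = pool$eos)
}
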