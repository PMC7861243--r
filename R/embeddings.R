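#' Embedding table
#'
#' A dense token -> vector lookup.  Stored as a numeric matrix with one row
#' per token (row names are the tokens, in preprocessed form) plus training
#' metadata (`"pretrained"` for loaded vectors).
#'
#' @param vectors numeric matrix, rows named by token.
#' @param meta list of training metadata, or the string `"pretrained"`.
#' @return Object of class `embedding_table` with fields `dim`, `vectors`,
#'   `training_meta`.
#' @export
embedding_table <- function(vectors, meta = "pretrained") {
  if (!is.matrix(vectors) || !is.numeric(vectors) ||
      is.null(rownames(vectors))) {
    stop_onto("bad_vectors", "vectors must be a numeric matrix with row names")
  }
  if (anyDuplicated(rownames(vectors))) {
    stop_onto("duplicate_token", "duplicate token in embedding table")
  }
  structure(
    list(dim = ncol(vectors), vectors = vectors, training_meta = meta),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  src <- if (identical(x$training_meta, "pretrained")) "pretrained"
         else "trained"
  cat(sprintf("<embedding_table> %d tokens x %d dims (%s)\n",
              nrow(x$vectors), x$dim, src))
  invisible(x)
}

#' Train skip-gram word embeddings
#'
#' Trains a skip-gram model with negative sampling on a tokenized corpus.
#' Training is single-threaded with a self-contained PRNG, so the result is
#' bit-identical for a fixed corpus, hyperparameters and `rng_seed`.
#' Context windows never cross document boundaries.  Defaults mirror the
#' reference protocol: 100 epochs, window 5, minimum count 1.
#'
#' @param corpus_tokens list of character vectors, one per document.
#' @param dim embedding dimension (>= 2; 50/100/200/300 are typical).
#' @param epochs,window,min_count skip-gram hyperparameters.
#' @param negative number of negative samples per positive pair.
#' @param learning_rate initial learning rate (linear decay to
#'   `learning_rate/10000`).
#' @param rng_seed integer seed for initialization, window shrinking and
#'   negative sampling.
#' @return An [embedding_table()] whose `training_meta` records every
#'   effective hyperparameter and a corpus fingerprint.
#' @export
train_embeddings <- function(corpus_tokens, dim = 100L, epochs = 100L,
                             window = 5L, min_count = 1L, negative = 5L,
                             learning_rate = 0.025, rng_seed = 1L) {
  if (!length(corpus_tokens) ||
      all(lengths(corpus_tokens) == 0L)) {
    stop_onto("empty_corpus", "corpus must contain at least one token")
  }
  if (dim < 2L) stop_onto("bad_dim", "embedding dimension must be >= 2")
  flat <- unlist(corpus_tokens, use.names = FALSE)
  freq <- table(flat)
  # vocabulary order: frequency-descending, ties alphabetical (deterministic)
  freq <- freq[order(-as.integer(freq), names(freq), method = "radix")]
  keep <- as.integer(freq) >= min_count
  vocab <- names(freq)[keep]
  counts <- as.numeric(freq)[keep]
  if (!length(vocab)) {
    stop_onto("empty_corpus",
              "no token reaches min_count; vocabulary is empty")
  }
  docs <- lapply(corpus_tokens, function(d) {
    idx <- match(d, vocab)
    as.integer(idx[!is.na(idx)]) - 1L
  })
  docs <- docs[lengths(docs) > 0L]
  mat <- sgns_train_cpp(docs, length(vocab), counts, as.integer(dim),
                        as.integer(epochs), as.integer(window),
                        as.integer(negative), learning_rate,
                        learning_rate / 1e4, as.double(rng_seed))
  rownames(mat) <- vocab
  embedding_table(mat, meta = list(
    algorithm = "skip-gram negative sampling",
    dim = as.integer(dim), epochs = as.integer(epochs),
    window = as.integer(window), min_count = as.integer(min_count),
    negative = as.integer(negative), learning_rate = learning_rate,
    subsampling = 0, workers = 1L, rng_seed = as.integer(rng_seed),
    corpus_fingerprint = corpus_fingerprint(corpus_tokens)
  ))
}

# cheap deterministic corpus fingerprint (polynomial hash over a prefix)
corpus_fingerprint <- function(corpus_tokens) {
  flat <- unlist(corpus_tokens, use.names = FALSE)
  codes <- utf8ToInt(paste(head(flat, 2000L), collapse = " "))
  h <- 7
  for (ch in codes) h <- (h * 31 + ch) %% 2147483647
  sprintf("%d docs/%d tokens/hash:%d", length(corpus_tokens), length(flat),
          as.integer(h))
}

#' Load pre-trained vectors in word2vec or GloVe text format
#'
#' word2vec text format has an optional first line `vocab_size dim`; GloVe
#' files are the same space-separated rows without the header.  With
#' `format = "auto"` the header is detected from the first line.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"word2vec_text"`, `"glove_text"`.
#' @return An [embedding_table()] with `training_meta = "pretrained"`.
#'   Ragged rows and non-numeric fields raise errors; duplicate tokens keep
#'   the first occurrence with a warning.
#' @export
load_vectors <- function(path, format = c("auto", "word2vec_text",
                                          "glove_text")) {
  format <- match.arg(format)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_onto("bad_format", "empty vector file")
  first <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.integer(first)))
  if (format == "word2vec_text" && !has_header) {
    stop_onto("bad_format", "word2vec text format requires a 'vocab dim' header")
  }
  use_header <- has_header && format != "glove_text"
  if (use_header) lines <- lines[-1L]
  rows <- strsplit(lines, " ", fixed = TRUE)
  rows <- lapply(rows, function(r) r[nzchar(r)])
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop_onto("ragged_row", "rows have differing numbers of fields")
  }
  d <- widths[1L] - 1L
  if (d < 1L) stop_onto("bad_format", "rows must have a token and >= 1 value")
  tokens <- vapply(rows, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(d)))
  if (anyNA(vals)) stop_onto("non_numeric", "non-numeric field in vector row")
  mat <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (use_header) {
    hd <- as.integer(first)
    if (hd[2L] != d) stop_onto("bad_format", "header dim disagrees with rows")
    if (hd[1L] != length(tokens)) {
      warning("header vocab size disagrees with row count", call. = FALSE)
    }
  }
  if (anyDuplicated(tokens)) {
    warning("duplicate token(s) in vector file; keeping first occurrence",
            call. = FALSE)
    keep <- !duplicated(tokens)
    tokens <- tokens[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  rownames(mat) <- tokens
  embedding_table(mat, meta = "pretrained")
}

#' Write an embedding table in word2vec or GloVe text format
#'
#' @param table an [embedding_table()].
#' @param path output path.
#' @param format `"word2vec_text"` (with `vocab dim` header) or
#'   `"glove_text"`.
#' @param digits significant digits written (a read round trip reproduces
#'   vectors to this precision).
#' @return Invisibly, `table`.
#' @export
write_vectors <- function(table, path,
                          format = c("word2vec_text", "glove_text"),
                          digits = 17L) {
  format <- match.arg(format)
  mat <- table$vectors
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "g", digits = digits)),
          collapse = " ")
  }, character(1))
  if (format == "word2vec_text") {
    body <- c(paste(nrow(mat), ncol(mat)), body)
  }
  writeLines(body, path, useBytes = TRUE)
  invisible(table)
}

#' Averaged label vector
#'
#' The vector of a label is the arithmetic mean of the embedding vectors of
#' its constituent tokens (a token repeated k times contributes k times).
#' Tokens absent from the table are skipped; `coverage` reports the
#' in-vocabulary fraction, and the vector is `NULL` when coverage is 0.
#'
#' @param tokens a `tokenized_label` or a plain character vector of tokens.
#' @param table an [embedding_table()].
#' @return Object of class `label_vector`: `source_id`, `vector` (length
#'   `table$dim`, or `NULL`), `coverage` in `[0, 1]`.
#' @export
label_vector <- function(tokens, table) {
  source_id <- NA_character_
  if (inherits(tokens, "tokenized_label")) {
    source_id <- tokens$source_id
    tokens <- tokens$tokens
  }
  idx <- match(tokens, rownames(table$vectors))
  hit <- !is.na(idx)
  coverage <- if (length(tokens)) mean(hit) else 0
  vec <- NULL
  if (coverage > 0) {
    vec <- colMeans(table$vectors[idx[hit], , drop = FALSE])
  }
  structure(list(source_id = source_id, vector = vec, coverage = coverage),
            class = "label_vector")
}

#' Label vectors for a whole tokenized-label set
#'
#' @param tokenized named list from [tokenize_labels()].
#' @param table an [embedding_table()].
#' @return Object of class `label_vector_set`: `mat` (one row per id;
#'   `NA` rows for zero-coverage labels) and `coverage` (named numeric).
#' @export
label_vector_set <- function(tokenized, table) {
  ids <- names(tokenized)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = table$dim,
                dimnames = list(ids, NULL))
  coverage <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    lv <- label_vector(tokenized[[id]], table)
    coverage[id] <- lv$coverage
    if (!is.null(lv$vector)) mat[id, ] <- lv$vector
  }
  structure(list(mat = mat, coverage = coverage), class = "label_vector_set")
}
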