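#' Text-preprocessing configuration
#'
#' Bundles the parameters of the deterministic eight-step label/corpus
#' pipeline: lower-case conversion, synonym mapping, punctuation stripping,
#' white-space stripping, numeric stripping, stop-word removal, short-word
#' stripping, and lemmatization, applied in that order.
#'
#' @param synonym_map named character vector mapping a (lower-case) token to
#'   its canonical form.  Must be idempotent: a replacement token may not
#'   itself map to something else (no chains).  Default: empty.
#' @param stopwords character vector of stop-word tokens.  Defaults to the
#'   English list shipped with the package ([default_stopwords()]).
#' @param min_token_len minimum token length kept (default 3: "short words
#'   stripping" without a published threshold).
#' @param lemmatize logical; apply the dictionary+rule noun lemmatizer.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synonym_map = character(),
                            stopwords = default_stopwords(),
                            min_token_len = 3L,
                            lemmatize = TRUE) {
  synonym_map <- stats::setNames(as.character(synonym_map), names(synonym_map))
  if (length(synonym_map)) {
    if (is.null(names(synonym_map)) || any(!nzchar(names(synonym_map)))) {
      stop_onto("bad_config", "synonym_map must be a named character vector")
    }
    # idempotence: a replacement token, if itself a key, must map to itself
    vals <- unname(synonym_map)
    chained <- vals[vals %in% names(synonym_map) & synonym_map[vals] != vals]
    if (length(chained)) {
      stop_onto("bad_config",
                paste0("synonym_map is not idempotent (chained mapping via: ",
                       paste(head(chained, 5L), collapse = ", "), ")"))
    }
  }
  if (!is.numeric(min_token_len) || min_token_len < 1) {
    stop_onto("bad_config", "min_token_len must be >= 1")
  }
  structure(
    list(synonym_map = synonym_map, stopwords = unique(as.character(stopwords)),
         min_token_len = as.integer(min_token_len),
         lemmatize = isTRUE(lemmatize)),
    class = "pipeline_config"
  )
}

#' Default English stop-word list
#'
#' Shipped as a versioned plain-text data file so runs are reproducible.
#' @return Character vector of stop-word tokens.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "ontopop")
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words[nzchar(words) & !startsWith(words, "#")]
}

#' Preprocess text into tokens
#'
#' Applies the eight pipeline steps in order and returns a (possibly empty)
#' lower-case token vector containing no punctuation, digits, stop-words, or
#' tokens shorter than `min_token_len`.  The stop-word and length filters
#' are re-applied after lemmatization so the output invariants hold
#' regardless of what the lemmatizer produces; the operation is idempotent.
#'
#' @param text character scalar (UTF-8).
#' @param config a [pipeline_config()].
#' @return Character vector of tokens.
#' @export
preprocess <- function(text, config = pipeline_config()) {
  if (length(text) != 1L || is.na(text)) {
    stop_onto("bad_input", "text must be a single non-NA string")
  }
  toks <- tolower(enc2utf8(text))                        # 1 lower-case
  toks <- strsplit(trimws(toks), "[[:space:]]+")[[1L]]
  toks <- apply_synonyms(toks, config$synonym_map)       # 2 synonym mapping
  toks <- gsub("[[:punct:]]", "", toks)                  # 3 punctuation
  toks <- toks[nzchar(trimws(toks))]                     # 4 white-space
  toks <- gsub("[0-9]", "", toks)                        # 5 numeric
  toks <- toks[nzchar(toks)]
  toks <- drop_stop_short(toks, config)                  # 6 + 7
  if (config$lemmatize) toks <- lemmatize_tokens(toks)   # 8 lemmatization
  drop_stop_short(toks, config)                          # keep invariants
}

apply_synonyms <- function(toks, map) {
  if (!length(map) || !length(toks)) return(toks)
  hit <- toks %in% names(map)
  toks[hit] <- unname(map[toks[hit]])
  toks
}

drop_stop_short <- function(toks, config) {
  toks <- toks[!toks %in% config$stopwords]
  toks[nchar(toks) >= config$min_token_len]
}

# Small irregular-plural dictionary + suffix rules; noun-preference,
# deliberately conservative, and idempotent (a lemma maps to itself).
.irregular_nouns <- c(
  feet = "foot", geese = "goose", mice = "mouse", lice = "louse",
  teeth = "tooth", children = "child", men = "man", women = "woman",
  people = "person", oxen = "ox", leaves = "leaf", loaves = "loaf",
  knives = "knife", wives = "wife", lives = "life", halves = "half",
  calves = "calf", wolves = "wolf", shelves = "shelf", thieves = "thief"
)

#' Lemmatize tokens (dictionary + noun suffix rules)
#'
#' @param tokens character vector of lower-case tokens.
#' @return Character vector of lemmas, same length.
#' @export
lemmatize_tokens <- function(tokens) {
  if (!length(tokens)) return(tokens)
  irr <- tokens %in% names(.irregular_nouns)
  tokens[irr] <- unname(.irregular_nouns[tokens[irr]])
  t <- tokens[!irr]
  t <- ifelse(grepl("ies$", t) & nchar(t) > 4L, sub("ies$", "y", t), t)
  t <- ifelse(grepl("sses$", t), sub("es$", "", t), t)
  t <- ifelse(grepl("(ches|shes|xes|zes)$", t), sub("es$", "", t), t)
  t <- ifelse(grepl("s$", t) & !grepl("(ss|us|is)$", t), sub("s$", "", t), t)
  tokens[!irr] <- t
  tokens
}

#' Tokenized label
#'
#' @param source_id id of the class or instance the label belongs to.
#' @param raw original label text.
#' @param config a [pipeline_config()].
#' @return Object of class `tokenized_label` with fields `source_id`, `raw`,
#'   `tokens`.
#' @export
tokenized_label <- function(source_id, raw, config = pipeline_config()) {
  structure(
    list(source_id = source_id, raw = raw,
         tokens = preprocess(raw, config)),
    class = "tokenized_label"
  )
}

#' Tokenize every class and instance label of an ontology
#'
#' @param ontology an [ontology()].
#' @param config a [pipeline_config()].
#' @return Named list (id -> `tokenized_label`) covering every class and
#'   instance.  Labels that preprocess to an empty token list trigger a
#'   single consolidated warning (they cannot be embedded and will be
#'   handled by the random fallback at mapping time).
#' @export
tokenize_labels <- function(ontology, config = pipeline_config()) {
  ids <- c(ontology$classes$id, ontology$instances$id)
  raws <- c(ontology$classes$label, ontology$instances$label)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (k in seq_along(ids)) {
    out[[k]] <- tokenized_label(ids[k], raws[k], config)
  }
  empty <- ids[vapply(out, function(tl) length(tl$tokens) == 0L, logical(1))]
  if (length(empty)) {
    warning(sprintf("%d label(s) preprocess to an empty token list: %s",
                    length(empty),
                    paste(head(empty, 5L), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Vocabulary of a tokenized-label set
#'
#' @param tokenized named list of `tokenized_label` (from
#'   [tokenize_labels()]).
#' @return Sorted character vector of unique tokens.
#' @export
vocabulary <- function(tokenized) {
  sort(unique(unlist(lapply(tokenized, `[[`, "tokens"), use.names = FALSE)))
}

#' Preprocess a corpus directory
#'
#' Reads every regular file in `dir` (one document per file, plain text),
#' preprocesses each as a single token stream (no sentence splitting:
#' skip-gram windows later stay within a document but may cross line
#' breaks), and returns one token vector per document in sorted file order.
#'
#' @param dir directory of plain-text documents.
#' @param config a [pipeline_config()].
#' @return Named list (file name -> token character vector).
#' @export
preprocess_corpus <- function(dir, config = pipeline_config()) {
  if (!dir.exists(dir)) stop_onto("bad_input", paste0("no such directory: ", dir))
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[file.exists(files) & !dir.exists(files)]
  if (!length(files)) stop_onto("bad_input", paste0("empty corpus dir: ", dir))
  docs <- lapply(files, function(f) {
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                 collapse = " ")
    preprocess(txt, config)
  })
  names(docs) <- basename(files)
  docs
}

#' Read/write a tokenized corpus (one document per line, space-separated)
#'
#' @param docs list of token character vectors.
#' @param path file path.
#' @return `write_token_lines` returns `docs` invisibly; `read_token_lines`
#'   returns a list of token vectors.
#' @export
write_token_lines <- function(docs, path) {
  writeLines(vapply(docs, paste, character(1), collapse = " "), path,
             useBytes = TRUE)
  invisible(docs)
}

#' @rdname write_token_lines
#' @export
read_token_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(strsplit(lines, " ", fixed = TRUE), function(x) x[nzchar(x)])
}

#' Read a one-entry-per-line word list (stop-words)
#' @param path file path; blank lines and `#` comments ignored.
#' @return Character vector.
#' @export
read_word_list <- function(path) {
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  trimws(words[nzchar(words) & !startsWith(words, "#")])
}

#' Read a synonym map TSV (`from<TAB>to`, one pair per line)
#' @param path file path.
#' @return Named character vector usable as `synonym_map`.
#' @export
read_synonym_map <- function(path) {
  tab <- read_tsv_cols(path, 2L, "synonym map", allow_empty = TRUE)
  stats::setNames(tab[[2L]], tab[[1L]])
}
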