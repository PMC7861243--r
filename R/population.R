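#' Mapper configuration
#'
#' The mapper scores a candidate instance against each target class as
#' `score = alpha * score_siblings + (1 - alpha) * score_parent`, where the
#' sibling score compares the candidate with the centroid of the class's
#' seed instances and the parent score compares it with the class's own
#' label, and assigns the candidate to the argmax class.  `alpha = 0.8` is
#' the empirically chosen default; the grid 0, 0.1, ..., 1 is the
#' conventional sweep.
#'
#' @param method `"embedding"` (similarity of averaged label vectors),
#'   `"jaccard"` (token-set similarity), `"hamming"` (positional string
#'   similarity), or `"random"` (uniform baseline).
#' @param alpha weight of the sibling term, in `[0, 1]`.
#' @param similarity `"cosine"` (default; scores in `[-1, 1]`) or
#'   `"euclidean"` (negative distance: comparable within a run, which is all
#'   argmax needs).  Embedding method only.
#' @param rng_seed seed for the random method and the zero-coverage
#'   fallback.
#' @param combine_scores if `FALSE`, the jaccard/hamming baselines use the
#'   single pairwise candidate-vs-class-label similarity instead of the
#'   alpha combination.
#' @return Object of class `mapper_config`.
#' @export
mapper_config <- function(method = c("embedding", "jaccard", "hamming",
                                     "random"),
                          alpha = 0.8,
                          similarity = c("cosine", "euclidean"),
                          rng_seed = 1L,
                          combine_scores = TRUE) {
  method <- match.arg(method)
  similarity <- match.arg(similarity)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop_onto("bad_alpha", "alpha must be a single number in [0, 1]")
  }
  structure(
    list(method = method, alpha = alpha, similarity = similarity,
         rng_seed = as.integer(rng_seed),
         combine_scores = isTRUE(combine_scores)),
    class = "mapper_config"
  )
}

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length, both nonzero.
#' @return Cosine of the angle between `u` and `v`, in `[-1, 1]`.
#' @export
cosine_sim <- function(u, v) {
  if (length(u) != length(v)) {
    stop_onto("bad_vectors", "vectors must have equal length")
  }
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    stop_onto("zero_vector", "cosine similarity is undefined for zero vectors")
  }
  sum(u * v) / (nu * nv)
}

#' Euclidean similarity (negative distance)
#' @inheritParams cosine_sim
#' @return `-||u - v||`; larger is more similar.
#' @export
euclidean_sim <- function(u, v) {
  if (length(u) != length(v)) {
    stop_onto("bad_vectors", "vectors must have equal length")
  }
  -sqrt(sum((u - v)^2))
}

sim_fun <- function(config) {
  switch(config$similarity, cosine = cosine_sim, euclidean = euclidean_sim)
}

#' Sibling score: similarity of a candidate with a class's seed centroid
#'
#' @param instance_vec a `label_vector` (or plain numeric vector) for the
#'   candidate.
#' @param seed_vecs list of `label_vector`s (or a numeric matrix, one row
#'   per seed) for the class's seed instances; all must be defined.
#' @param config a [mapper_config()].
#' @return Similarity of the candidate vector with the arithmetic-mean
#'   centroid of the seed vectors.
#' @export
score_siblings <- function(instance_vec, seed_vecs,
                           config = mapper_config()) {
  u <- as_defined_vector(instance_vec)
  if (is.matrix(seed_vecs)) {
    if (nrow(seed_vecs) == 0L) stop_onto("empty_seeds", "no seed vectors")
    centroid <- colMeans(seed_vecs)
  } else {
    if (!length(seed_vecs)) stop_onto("empty_seeds", "no seed vectors")
    centroid <- colMeans(do.call(rbind, lapply(seed_vecs, as_defined_vector)))
  }
  sim_fun(config)(u, centroid)
}

#' Parent score: similarity of a candidate with the class's own label
#'
#' @param instance_vec,class_vec `label_vector`s (or numeric vectors); both
#'   must be defined.
#' @param config a [mapper_config()].
#' @return `sim(instance, class label)`.
#' @export
score_parent <- function(instance_vec, class_vec, config = mapper_config()) {
  sim_fun(config)(as_defined_vector(instance_vec),
                  as_defined_vector(class_vec))
}

as_defined_vector <- function(x) {
  if (inherits(x, "label_vector")) {
    if (is.null(x$vector)) {
      stop_onto("undefined_vector",
                "label vector is undefined (zero embedding coverage)")
    }
    return(x$vector)
  }
  if (!is.numeric(x) || anyNA(x)) {
    stop_onto("undefined_vector", "vector is undefined")
  }
  x
}

#' Jaccard similarity of two token sets
#'
#' @param tokens_a,tokens_b character vectors (treated as sets).
#' @return `|A intersect B| / |A union B|`; 0 when both sets are empty.
#' @export
jaccard_sim <- function(tokens_a, tokens_b) {
  a <- unique(tokens_a); b <- unique(tokens_b)
  un <- length(union(a, b))
  if (un == 0L) return(0)
  length(intersect(a, b)) / un
}

#' Hamming similarity of two strings
#'
#' Positional mismatches are counted over the shorter string; the length
#' difference counts fully as mismatches.  Returns
#' `1 - (mismatches + |len(a) - len(b)|) / max(len(a), len(b))`, and 1 when
#' both strings are empty.
#'
#' @param a,b character scalars.
#' @return Similarity in `[0, 1]`.
#' @export
hamming_sim <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  mx <- max(la, lb)
  if (mx == 0L) return(1)
  mn <- min(la, lb)
  mism <- 0L
  if (mn > 0L) {
    ca <- strsplit(substr(a, 1L, mn), "", fixed = TRUE)[[1L]]
    cb <- strsplit(substr(b, 1L, mn), "", fixed = TRUE)[[1L]]
    mism <- sum(ca != cb)
  }
  1 - (mism + (mx - mn)) / mx
}

# Precompute per-target-class scoring state for a skeleton.
# For the embedding method: seed-centroid matrix and class-label matrix
# (NA rows where undefined).  For string methods: seed token sets / raw
# strings per class.
prepare_mapper <- function(skeleton, vectors = NULL, tokenized_labels = NULL,
                           config = mapper_config()) {
  targets <- sort(skeleton$target_class_ids)
  st <- list(targets = targets, config = config, skeleton = skeleton)
  if (config$method == "embedding") {
    if (is.null(vectors) || !inherits(vectors, "label_vector_set")) {
      stop_onto("bad_input", "embedding method needs a label_vector_set")
    }
    d <- ncol(vectors$mat)
    cent <- matrix(NA_real_, length(targets), d,
                   dimnames = list(targets, NULL))
    for (tc in targets) {
      sv <- vectors$mat[skeleton$seeds[[tc]], , drop = FALSE]
      sv <- sv[stats::complete.cases(sv), , drop = FALSE]
      if (nrow(sv)) cent[tc, ] <- colMeans(sv)
    }
    st$centroids <- cent
    st$class_mat <- vectors$mat[targets, , drop = FALSE]
    st$vectors <- vectors
  } else if (config$method %in% c("jaccard", "hamming")) {
    if (is.null(tokenized_labels)) {
      stop_onto("bad_input",
                paste0(config$method, " method needs tokenized_labels"))
    }
    st$tokens <- lapply(tokenized_labels, `[[`, "tokens")
    st$raw <- vapply(tokenized_labels, function(tl) tolower(tl$raw),
                     character(1))
    st$seed_ids <- skeleton$seeds[targets]
  }
  st
}

score_against_targets <- function(st, instance_id) {
  config <- st$config
  targets <- st$targets
  if (config$method == "embedding") {
    u <- st$vectors$mat[instance_id, ]
    if (anyNA(u)) return(NULL) # zero coverage: caller falls back
    sib <- score_row(u, st$centroids, config)
    par <- score_row(u, st$class_mat, config)
  } else if (config$method == "jaccard") {
    ut <- st$tokens[[instance_id]]
    sib <- vapply(targets, function(tc) {
      mean(vapply(st$seed_ids[[tc]],
                  function(s) jaccard_sim(ut, st$tokens[[s]]), numeric(1)))
    }, numeric(1))
    par <- vapply(targets, function(tc) jaccard_sim(ut, st$tokens[[tc]]),
                  numeric(1))
  } else { # hamming
    ur <- st$raw[[instance_id]]
    sib <- vapply(targets, function(tc) {
      mean(vapply(st$seed_ids[[tc]],
                  function(s) hamming_sim(ur, st$raw[[s]]), numeric(1)))
    }, numeric(1))
    par <- vapply(targets, function(tc) hamming_sim(ur, st$raw[[tc]]),
                  numeric(1))
  }
  combine_scores(sib, par, config)
}

# alpha-combination with per-component fallback: when exactly one component
# is undefined for a class (e.g. an out-of-vocabulary class label), the
# defined one is used alone; a class with neither is unscorable (-Inf).
combine_scores <- function(sib, par, config) {
  if (config$method %in% c("jaccard", "hamming") && !config$combine_scores) {
    return(list(score = par, sib = rep(NA_real_, length(par)), par = par))
  }
  a <- config$alpha
  score <- a * sib + (1 - a) * par
  only_sib <- is.na(par) & !is.na(sib)
  only_par <- is.na(sib) & !is.na(par)
  score[only_sib] <- sib[only_sib]
  score[only_par] <- par[only_par]
  score[is.na(score)] <- -Inf
  list(score = score, sib = sib, par = par)
}

# similarity of vector u against each row of mat (NA rows give NA)
score_row <- function(u, mat, config) {
  ok <- stats::complete.cases(mat)
  out <- rep(NA_real_, nrow(mat))
  names(out) <- rownames(mat)
  if (!any(ok)) return(out)
  m <- mat[ok, , drop = FALSE]
  if (config$similarity == "cosine") {
    nu <- sqrt(sum(u * u))
    nm <- sqrt(rowSums(m * m))
    if (nu == 0 || any(nm == 0)) {
      stop_onto("zero_vector", "cosine similarity is undefined for zero vectors")
    }
    out[ok] <- as.numeric(m %*% u) / (nm * nu)
  } else {
    out[ok] <- -sqrt(rowSums(sweep(m, 2L, u)^2))
  }
  out
}

#' Map a single candidate instance to a target class
#'
#' Scores the candidate against every target class and returns the argmax;
#' ties are broken by the lexicographically smallest class id.  A candidate
#' whose label has zero embedding coverage cannot be scored and is assigned
#' a uniformly random target class with `fallback = TRUE` (so precision
#' denominators stay comparable across methods).
#'
#' @param instance_id a candidate instance id of the skeleton.
#' @param skeleton a [make_skeleton()] result.
#' @param vectors a [label_vector_set()] over all class and instance ids
#'   (embedding method).
#' @param config a [mapper_config()].
#' @param tokenized_labels named list from [tokenize_labels()]
#'   (jaccard/hamming methods).
#' @return A one-row data frame with columns `instance_id`,
#'   `predicted_class_id`, `score`, `score_siblings`, `score_parent`,
#'   `fallback`.
#' @export
map_instance <- function(instance_id, skeleton, vectors = NULL,
                         config = mapper_config(),
                         tokenized_labels = NULL) {
  if (!instance_id %in% skeleton$candidates) {
    stop_onto("unknown_id",
              sprintf("'%s' is not a candidate of this skeleton", instance_id))
  }
  st <- prepare_mapper(skeleton, vectors, tokenized_labels, config)
  map_one(st, instance_id, fallback_rng_seed = config$rng_seed)
}

map_one <- function(st, instance_id, fallback_rng_seed) {
  targets <- st$targets
  if (st$config$method == "random") {
    sc <- NULL
  } else {
    sc <- score_against_targets(st, instance_id)
  }
  if (is.null(sc) || all(!is.finite(sc$score))) {
    pick <- with_seed(fallback_rng_seed, sample_ids(targets, 1L))
    return(data.frame(instance_id = instance_id, predicted_class_id = pick,
                      score = NA_real_, score_siblings = NA_real_,
                      score_parent = NA_real_,
                      fallback = st$config$method != "random",
                      stringsAsFactors = FALSE))
  }
  # targets are sorted, so the first maximum is the lexicographic tie-break
  best <- which(sc$score == max(sc$score))[1L]
  data.frame(instance_id = instance_id,
             predicted_class_id = targets[best],
             score = unname(sc$score[best]),
             score_siblings = unname(sc$sib[best]),
             score_parent = unname(sc$par[best]),
             fallback = FALSE, stringsAsFactors = FALSE)
}

#' Map every candidate of a skeleton
#'
#' Runs the configured method over all candidates (in sorted id order, so
#' randomized choices are reproducible given `config$rng_seed`).
#'
#' @inheritParams map_instance
#' @param skeleton a [make_skeleton()] result.
#' @return Data frame with one row per candidate (columns as in
#'   [map_instance()]), of class `mapping_result`.
#' @export
map_all <- function(skeleton, vectors = NULL, config = mapper_config(),
                    tokenized_labels = NULL) {
  cands <- sort(skeleton$candidates)
  targets <- sort(skeleton$target_class_ids)
  empty <- data.frame(instance_id = character(),
                      predicted_class_id = character(), score = numeric(),
                      score_siblings = numeric(), score_parent = numeric(),
                      fallback = logical(), stringsAsFactors = FALSE)
  if (!length(cands)) return(structure(empty, class = c("mapping_result",
                                                        "data.frame")))
  if (config$method == "random") {
    picks <- with_seed(config$rng_seed,
                       targets[sample.int(length(targets), length(cands),
                                          replace = TRUE)])
    out <- data.frame(instance_id = cands, predicted_class_id = picks,
                      score = NA_real_, score_siblings = NA_real_,
                      score_parent = NA_real_, fallback = FALSE,
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("mapping_result", "data.frame")))
  }
  st <- prepare_mapper(skeleton, vectors, tokenized_labels, config)
  rows <- vector("list", length(cands))
  for (k in seq_along(cands)) {
    # per-candidate fallback seed: deterministic and independent per instance
    rows[[k]] <- map_one(st, cands[k],
                         fallback_rng_seed = config$rng_seed + k)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mapping_result", "data.frame"))
}

#' Read/write mapping results as TSV
#'
#' Columns: `instance_id`, `predicted_class_id`, `score`, `score_siblings`,
#' `score_parent`, `fallback` (header included).
#'
#' @param results a `mapping_result` data frame.
#' @param path file path.
#' @return `write_mapping` returns `results` invisibly; `read_mapping`
#'   returns the data frame.
#' @export
write_mapping <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(results)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric", "logical"),
                    fileEncoding = "UTF-8")
  structure(out, class = c("mapping_result", "data.frame"))
}
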