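#' Specification for a synthetic ontology + embedding benchmark
#'
#' The generator emulates the structural features that matter for ontology
#' population at desk scale: a single-root multi-parent class DAG,
#' heterogeneous instance counts per class (many classes with few instances,
#' some with none), and embeddings with per-class cluster structure — each
#' class has a latent centroid and every label token is that centroid plus
#' isotropic Gaussian noise.
#'
#' Defaults state a world resembling the curated food-ontology setting at
#' 1/25 scale: 100 classes with a mean of 3 instances per class (the
#' curated ontology averages ~3 instances/class over 2,764 classes, with a
#' sizable minority of classes empty), moderate multi-parent structure, and
#' cluster noise (`noise_sigma = 0.3` against unit centroid separation)
#' that leaves the mapping hard but learnable.
#'
#' @param n_classes number of classes including the root.
#' @param max_depth maximum class depth.
#' @param branching mean number of children spawned per class (Poisson).
#' @param multi_parent_prob probability a non-root class receives a second
#'   parent (drawn among non-descendants, preserving acyclicity).
#' @param instances_mean mean instances per class.
#' @param instances_dispersion negative-binomial size parameter; `Inf`
#'   (default) gives Poisson counts.
#' @param dim embedding dimension.
#' @param centroid_separation minimum pairwise Euclidean distance between
#'   class centroids (0 collapses all centroids: the no-signal limit).
#' @param noise_sigma standard deviation of the isotropic token noise.
#' @param vocab_tokens_per_label synthetic tokens per label.
#' @param rng_seed integer seed; generation is reproducible byte-for-byte.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 100L, max_depth = 5L, branching = 3,
                           multi_parent_prob = 0.1, instances_mean = 3,
                           instances_dispersion = Inf, dim = 32L,
                           centroid_separation = 1, noise_sigma = 0.3,
                           vocab_tokens_per_label = 2L, rng_seed = 1L) {
  if (n_classes < 1L) stop_onto("bad_spec", "n_classes must be >= 1")
  if (multi_parent_prob < 0 || multi_parent_prob > 1) {
    stop_onto("bad_spec", "multi_parent_prob must be in [0, 1]")
  }
  if (noise_sigma < 0 || centroid_separation < 0) {
    stop_onto("bad_spec", "noise_sigma and centroid_separation must be >= 0")
  }
  if (dim < 2L) stop_onto("bad_spec", "dim must be >= 2")
  if (branching <= 0 && n_classes > 1L) {
    stop_onto("bad_spec", "branching must be > 0 when n_classes > 1")
  }
  structure(
    list(n_classes = as.integer(n_classes), max_depth = as.integer(max_depth),
         branching = branching, multi_parent_prob = multi_parent_prob,
         instances_mean = instances_mean,
         instances_dispersion = instances_dispersion,
         dim = as.integer(dim), centroid_separation = centroid_separation,
         noise_sigma = noise_sigma,
         vocab_tokens_per_label = as.integer(vocab_tokens_per_label),
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_spec"
  )
}

# unique pronounceable-ish alphabetic tokens; letters only so the text
# pipeline (digit stripping, min length 3) passes them through unchanged
make_tokens <- function(n, prefix) {
  stopwords <- default_stopwords()
  out <- character(n)
  taken <- character(0)
  k <- 1L
  while (k <= n) {
    tok <- paste0(prefix,
                  paste(letters[sample.int(26L, 6L, replace = TRUE)],
                        collapse = ""))
    if (!tok %in% taken && !tok %in% stopwords) {
      out[k] <- tok
      taken <- c(taken, tok)
      k <- k + 1L
    }
  }
  out
}

#' Generate a synthetic ontology
#'
#' Classes are grown breadth-first from the root: each class spawns a
#' Poisson(`branching`) number of children while depth allows; leftover
#' classes attach to uniformly chosen non-maximal-depth classes.  Each
#' non-root class then gains a second parent with probability
#' `multi_parent_prob`, drawn uniformly among classes that are not its
#' descendants (acyclicity is preserved by construction and re-checked by
#' the [ontology()] validator).  Instance counts per class are Poisson or
#' negative-binomial draws, so some classes stay empty, as in real curated
#' ontologies.  Every label is built from fresh unique alphabetic tokens so
#' the text pipeline is exercised end to end.
#'
#' @param spec a [synthetic_spec()].
#' @return A validated [ontology()].  Each instance has a single (primary)
#'   parent; multi-parent structure lives on the class DAG.
#' @export
generate_ontology <- function(spec) {
  with_seed(spec$rng_seed, generate_ontology_impl(spec))
}

generate_ontology_impl <- function(spec) {
  n <- spec$n_classes
  ids <- sprintf("c%04d", seq_len(n))
  depth <- integer(n)
  parent1 <- integer(n) # 0 for root
  nxt <- 2L
  queue <- 1L
  while (nxt <= n && length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    if (depth[cur] >= spec$max_depth) next
    kids <- rpois(1L, spec$branching)
    kids <- min(kids, n - nxt + 1L)
    if (kids > 0L) {
      for (j in seq_len(kids)) {
        parent1[nxt] <- cur
        depth[nxt] <- depth[cur] + 1L
        queue <- c(queue, nxt)
        nxt <- nxt + 1L
      }
    }
  }
  while (nxt <= n) { # attach leftovers anywhere depth allows
    ok <- which(depth[seq_len(nxt - 1L)] < spec$max_depth)
    cur <- ok[sample.int(length(ok), 1L)]
    parent1[nxt] <- cur
    depth[nxt] <- depth[cur] + 1L
    nxt <- nxt + 1L
  }
  class_parents <- lapply(seq_len(n), function(k) {
    if (k == 1L) character() else ids[parent1[k]]
  })
  names(class_parents) <- ids
  # Second parents are drawn among lower-index classes only.  BFS growth
  # gives every primary parent a smaller index than its child, so keeping
  # all parent edges index-decreasing guarantees acyclicity (every class's
  # second parent is never one of its descendants).
  if (spec$multi_parent_prob > 0 && n > 2L) {
    for (k in 3:n) {
      if (runif(1L) < spec$multi_parent_prob) {
        pool <- setdiff(seq_len(k - 1L), parent1[k])
        if (length(pool)) {
          class_parents[[k]] <- sort(c(class_parents[[k]],
                                       ids[pool[sample.int(length(pool), 1L)]]))
        }
      }
    }
  }
  class_tokens <- make_tokens(n * spec$vocab_tokens_per_label, "cls")
  class_labels <- vapply(seq_len(n), function(k) {
    paste(class_tokens[((k - 1L) * spec$vocab_tokens_per_label + 1L):
                         (k * spec$vocab_tokens_per_label)], collapse = " ")
  }, character(1))
  names(class_labels) <- ids

  counts <- if (is.finite(spec$instances_dispersion)) {
    rnbinom(n, size = spec$instances_dispersion, mu = spec$instances_mean)
  } else {
    rpois(n, spec$instances_mean)
  }
  counts[1L] <- 0L # the root is structural, never a target class
  total <- sum(counts)
  iids <- if (total) sprintf("i%05d", seq_len(total)) else character()
  inst_parent <- rep(ids, counts)
  inst_tokens <- make_tokens(total * spec$vocab_tokens_per_label, "ins")
  instance_labels <- vapply(seq_len(total), function(k) {
    paste(inst_tokens[((k - 1L) * spec$vocab_tokens_per_label + 1L):
                        (k * spec$vocab_tokens_per_label)], collapse = " ")
  }, character(1))
  names(instance_labels) <- iids
  instance_parents <- as.list(inst_parent)
  names(instance_parents) <- iids
  ontology(class_labels = class_labels, class_parents = class_parents,
           instance_labels = instance_labels,
           instance_parents = instance_parents)
}

#' Generate clustered synthetic embeddings for an ontology
#'
#' Each class receives a latent centroid: random unit vectors, rescaled so
#' the minimum pairwise distance equals `centroid_separation` (the best of
#' up to 50 rejection-sampling rounds is kept before rescaling; with
#' `centroid_separation = 0` all centroids coincide — the no-signal limit).
#' Every token of a class label is its centroid plus isotropic
#' `N(0, noise_sigma^2)` noise; every token of an instance label is its
#' primary parent's centroid plus the same noise.  With `noise_sigma = 0`
#' all label vectors sit exactly on their class centroid.
#'
#' @param ontology an [ontology()] from [generate_ontology()].
#' @param spec the [synthetic_spec()] used to generate it.
#' @return An [embedding_table()] covering every token of every label
#'   (tokenize the labels with [tokenize_labels()] to recover the per-label
#'   token assignment).
#' @export
generate_embeddings <- function(ontology, spec) {
  with_seed(spec$rng_seed + 1L, generate_embeddings_impl(ontology, spec))
}

generate_embeddings_impl <- function(ontology, spec) {
  n <- nrow(ontology$classes)
  d <- spec$dim
  if (spec$centroid_separation == 0) {
    base <- rnorm(d)
    base <- base / sqrt(sum(base^2))
    centroids <- matrix(rep(base, each = n), nrow = n)
  } else {
    best <- NULL
    best_min <- -Inf
    for (try in seq_len(50L)) {
      m <- matrix(rnorm(n * d), n, d)
      m <- m / sqrt(rowSums(m^2))
      mind <- if (n > 1L) min(stats::dist(m)) else 1
      if (mind > best_min) {
        best <- m
        best_min <- mind
      }
      if (best_min > 0) break
    }
    if (best_min <= 0) {
      stop_onto("bad_spec", "could not separate class centroids")
    }
    centroids <- best * (spec$centroid_separation / best_min)
  }
  rownames(centroids) <- ontology$classes$id

  config <- pipeline_config()
  tok <- tokenize_labels(ontology, config)
  rows <- list()
  emit <- function(tokens, centroid) {
    for (t in tokens) {
      rows[[t]] <<- centroid + rnorm(d, sd = spec$noise_sigma)
    }
  }
  for (k in seq_len(n)) {
    id <- ontology$classes$id[k]
    emit(tok[[id]]$tokens, centroids[id, ])
  }
  for (iid in ontology$instances$id) {
    primary <- ontology$instance_parents[[iid]][1L]
    emit(tok[[iid]]$tokens, centroids[primary, ])
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  embedding_table(mat, meta = list(
    algorithm = "synthetic clustered",
    dim = d, noise_sigma = spec$noise_sigma,
    centroid_separation = spec$centroid_separation,
    rng_seed = spec$rng_seed
  ))
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: ontology, tokenized labels, embedding table, and
#' label vectors, all from one spec.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `ontology`, `tokenized`, `table`, `vectors` (a
#'   [label_vector_set()]), and the `spec`.
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  onto <- generate_ontology(spec)
  table <- generate_embeddings(onto, spec)
  tokenized <- tokenize_labels(onto, pipeline_config())
  vectors <- label_vector_set(tokenized, table)
  list(ontology = onto, tokenized = tokenized, table = table,
       vectors = vectors, spec = spec)
}
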