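# Shared fixtures and independent oracles.  Oracles are deliberately naive
# re-implementations (exhaustive enumeration, double loops) kept free of the
# package's internal code paths they check.

# diamond: A (root) <- B, C; D has both B and C as parents; i1 under D
diamond_ontology <- function() {
  ontology(
    class_labels = c(A = "food product", B = "dairy product",
                     C = "fermented product", D = "cow milk cheese"),
    class_parents = list(A = character(), B = "A", C = "A",
                         D = c("B", "C")),
    instance_labels = c(i1 = "brie cheese"),
    instance_parents = list(i1 = "D")
  )
}

# a root with k child classes, n_i instances under child i
star_ontology <- function(n_instances_per_class) {
  k <- length(n_instances_per_class)
  cids <- c("root", sprintf("c%03d", seq_len(k)))
  class_labels <- stats::setNames(paste("class", cids), cids)
  class_parents <- c(list(root = character()),
                     stats::setNames(rep(list("root"), k), cids[-1L]))
  total <- sum(n_instances_per_class)
  iids <- sprintf("i%04d", seq_len(total))
  parents <- rep(cids[-1L], n_instances_per_class)
  ontology(class_labels, class_parents,
           stats::setNames(paste("instance", iids), iids),
           stats::setNames(as.list(parents), iids))
}

# exhaustive directed-path enumeration child -> parent (oracle for
# paths_to_root and a bound for depth_of)
oracle_all_root_paths <- function(ont, class_id) {
  paths <- list()
  walk <- function(node, acc) {
    if (node == ont$root_id) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (p in ont$class_parents[[node]]) walk(p, c(acc, p))
  }
  walk(class_id, character())
  paths
}

# independent scorer: naive double loop with locally written cosine
oracle_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

oracle_map_embedding <- function(skeleton, vectors, alpha,
                                 similarity = "cosine") {
  targets <- sort(skeleton$target_class_ids)
  simf <- if (similarity == "cosine") oracle_cosine else
    function(u, v) -sqrt(sum((u - v)^2))
  out <- character(0)
  scores <- numeric(0)
  for (iid in sort(skeleton$candidates)) {
    u <- vectors$mat[iid, ]
    best_c <- NA_character_
    best_s <- -Inf
    for (tc in targets) {
      seed_mat <- vectors$mat[skeleton$seeds[[tc]], , drop = FALSE]
      centroid <- colMeans(seed_mat)
      s <- alpha * simf(u, centroid) + (1 - alpha) * simf(u, vectors$mat[tc, ])
      if (s > best_s) { # strict: ties keep the earlier (lexicographic) class
        best_s <- s
        best_c <- tc
      }
    }
    out[iid] <- best_c
    scores[iid] <- best_s
  }
  list(predicted = out, score = scores)
}

# independent nearest-seed-centroid rule (the alpha = 1 limit)
oracle_nearest_centroid <- function(skeleton, vectors) {
  targets <- sort(skeleton$target_class_ids)
  vapply(sort(skeleton$candidates), function(iid) {
    u <- vectors$mat[iid, ]
    sims <- vapply(targets, function(tc) {
      oracle_cosine(u, colMeans(vectors$mat[skeleton$seeds[[tc]], ,
                                            drop = FALSE]))
    }, numeric(1))
    targets[which.max(sims)]
  }, character(1))
}

# independent nearest-class-label rule (the alpha = 0 limit)
oracle_nearest_label <- function(skeleton, vectors) {
  targets <- sort(skeleton$target_class_ids)
  vapply(sort(skeleton$candidates), function(iid) {
    u <- vectors$mat[iid, ]
    sims <- vapply(targets,
                   function(tc) oracle_cosine(u, vectors$mat[tc, ]),
                   numeric(1))
    targets[which.max(sims)]
  }, character(1))
}

# small randomized benchmark for property tests
random_benchmark <- function(seed, n_classes = 8L, instances_mean = 4,
                             noise_sigma = 0.4, dim = 8L,
                             multi_parent_prob = 0.15) {
  generate_benchmark(synthetic_spec(
    n_classes = n_classes, max_depth = 3L, branching = 3,
    multi_parent_prob = multi_parent_prob, instances_mean = instances_mean,
    dim = dim, centroid_separation = 1, noise_sigma = noise_sigma,
    vocab_tokens_per_label = 2L, rng_seed = seed))
}

write_ontology_fixture <- function(ont, dir = withr::local_tempdir(
                                     .local_envir = parent.frame())) {
  edges <- file.path(dir, "edges.tsv")
  labels <- file.path(dir, "labels.tsv")
  write_ontology(ont, edges, labels)
  list(edges = edges, labels = labels, dir = dir)
}
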