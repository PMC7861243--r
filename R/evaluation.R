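#' Hop distance between a predicted class and the ground-truth classes
#'
#' Shortest path length, in hops, on the undirected class graph, minimized
#' over the instance's true parent classes.  Undirected is the convention
#' under which a sibling misassignment (shared parent) is 2 hops and a
#' correct assignment is 0.
#'
#' @param ontology an [ontology()].
#' @param predicted a class id.
#' @param truth_parents character vector of ground-truth parent class ids.
#' @return Non-negative integer; 0 iff `predicted` is one of the true
#'   parents.
#' @export
path_distance <- function(ontology, predicted, truth_parents) {
  check_class_id(ontology, predicted)
  for (id in truth_parents) check_class_id(ontology, id)
  if (predicted %in% truth_parents) return(0L)
  d <- igraph::distances(ontology$graph, v = predicted, to = truth_parents,
                         mode = "all")
  as.integer(min(d))
}

#' Evaluate a mapping against ground truth
#'
#' A candidate counts as a true positive (TP) iff its predicted class is one
#' of its ground-truth parent classes (set membership, so multi-parent
#' instances are correct under any of their parents); otherwise it is a
#' false positive (FP).  Precision is `TP / (TP + FP)`; since every
#' candidate receives exactly one class, `TP + FP` equals the number of
#' candidates.  Per-candidate hop distances use [path_distance()], so the
#' distance is 0 exactly for TPs — the 0-hop mass of the distance histogram
#' always equals the TP count, which is asserted.
#'
#' @param results a `mapping_result` data frame from [map_all()].
#' @param ontology the [ontology()] carrying the ground truth.
#' @param strict_single if `TRUE`, score a multi-parent instance against its
#'   primary (first listed) parent only, instead of set membership.
#' @return Object of class `eval_report`: `n_candidates`, `tp`, `fp`,
#'   `precision`, `distances` (named integer vector), `mean_distance`,
#'   `distance_histogram` (named count vector), `per_class_precision`
#'   (classes with at least one candidate only), `n_fallback`.
#' @export
evaluate_mapping <- function(results, ontology, strict_single = FALSE) {
  unknown <- setdiff(results$instance_id, ontology$instances$id)
  if (length(unknown)) {
    stop_onto("unknown_id",
              paste0("unknown instance id(s): ",
                     paste(head(unknown, 5L), collapse = ", ")))
  }
  n <- nrow(results)
  truth <- ontology$instance_parents[results$instance_id]
  if (strict_single) truth <- lapply(truth, `[`, 1L)
  correct <- mapply(function(p, tr) p %in% tr, results$predicted_class_id,
                    truth)
  correct <- as.logical(correct)
  tp <- sum(correct)
  dists <- integer(n)
  if (n) {
    dmat <- igraph::distances(ontology$graph, mode = "all")
    for (k in seq_len(n)) {
      dists[k] <- if (correct[k]) 0L else
        as.integer(min(dmat[results$predicted_class_id[k], truth[[k]]]))
    }
  }
  names(dists) <- results$instance_id
  hist <- table(dists)
  hist <- stats::setNames(as.integer(hist), names(hist))
  zero_mass <- if ("0" %in% names(hist)) hist[["0"]] else 0L
  stopifnot("0-hop mass must equal the TP count" = zero_mass == tp)
  # per-class precision over ground-truth classes with >= 1 candidate
  flat_truth <- unlist(truth, use.names = FALSE)
  correct_flat <- rep(correct, lengths(truth))
  per_class <- if (length(flat_truth)) {
    vapply(split(correct_flat, flat_truth), mean, numeric(1))
  } else numeric(0)
  structure(
    list(n_candidates = n, tp = tp, fp = n - tp,
         precision = if (n) tp / n else NA_real_,
         distances = dists,
         mean_distance = if (n) mean(dists) else NA_real_,
         distance_histogram = hist,
         per_class_precision = per_class,
         n_fallback = sum(results$fallback)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d candidates: precision %.4f (TP %d / FP %d), mean distance %.3f hops\n",
    x$n_candidates, x$precision, x$tp, x$fp, x$mean_distance))
  invisible(x)
}

#' Granularity of a superclass
#'
#' `granularity(c) = |I^C| / |C|` where `C` is the set of classes in the
#' subtree rooted at `c` (descendants plus `c` itself) and `I^C` the set of
#' distinct instances attached to any class in that subtree.  High
#' granularity means fewer, fuller classes under the superclass.
#'
#' @param ontology an [ontology()].
#' @param superclass_id a class id.
#' @return Non-negative real (0 when the subtree holds no instances).
#' @export
granularity <- function(ontology, superclass_id) {
  check_class_id(ontology, superclass_id)
  sub <- subtree_classes(ontology, superclass_id)
  ip <- ontology$instance_parents
  inside <- vapply(ip, function(p) any(p %in% sub), logical(1))
  sum(inside) / length(sub)
}

# classes whose ancestor set (via child->parent edges) includes superclass_id,
# plus the superclass itself
subtree_classes <- function(ontology, superclass_id) {
  names(igraph::subcomponent(ontology$graph, superclass_id, mode = "in"))
}

#' Cohesiveness annotation
#'
#' Holds expert judgments of whether each direct subclass of a superclass is
#' semantically consistent with the superclass's organizing principle.
#'
#' @param superclass_id class id being judged.
#' @param judgments named logical vector, subclass id -> TRUE (correct) /
#'   FALSE (incorrect).
#' @param ontology optional [ontology()]; when given, judged subclasses are
#'   checked to be direct subclasses of `superclass_id`.
#' @return Object of class `cohesiveness_annotation`.
#' @export
cohesiveness_annotation <- function(superclass_id, judgments,
                                    ontology = NULL) {
  if (!is.logical(judgments) || is.null(names(judgments)) ||
      anyNA(judgments)) {
    stop_onto("bad_input", "judgments must be a named logical vector")
  }
  if (!is.null(ontology)) {
    check_class_id(ontology, superclass_id)
    kids <- names(ontology$class_parents)[
      vapply(ontology$class_parents, function(p) superclass_id %in% p,
             logical(1))]
    bad <- setdiff(names(judgments), kids)
    if (length(bad)) {
      stop_onto("bad_input",
                paste0("judged ids are not direct subclasses of '",
                       superclass_id, "': ", paste(bad, collapse = ", ")))
    }
  }
  structure(list(superclass_id = superclass_id, judgments = judgments),
            class = "cohesiveness_annotation")
}

#' Cohesiveness of a superclass
#'
#' The fraction of judged direct subclasses marked correct: e.g. a cheese
#' superclass organized by source organism, with four organism-origin
#' subclasses judged correct and one process-based subclass (blue cheese)
#' judged incorrect, has cohesiveness 4/5 = 0.8.
#'
#' @param annotation a [cohesiveness_annotation()].
#' @return Real in `[0, 1]`.
#' @export
cohesiveness <- function(annotation) {
  j <- annotation$judgments
  if (!length(j)) stop_onto("bad_input", "no judgments to aggregate")
  mean(j)
}

#' Read/write cohesiveness annotations
#' (`superclass_id<TAB>subclass_id<TAB>correct{0,1}`, no header)
#'
#' @param path file path.
#' @param annotations list of [cohesiveness_annotation()].
#' @return `read_cohesiveness` returns a named list of annotations (one per
#'   superclass); `write_cohesiveness` returns `annotations` invisibly.
#' @export
read_cohesiveness <- function(path) {
  tab <- read_tsv_cols(path, 3L, "cohesiveness")
  if (!all(tab[[3L]] %in% c("0", "1"))) {
    stop_onto("bad_format", "correctness column must be 0 or 1")
  }
  out <- lapply(split(tab, tab[[1L]]), function(g) {
    cohesiveness_annotation(g[[1L]][1L],
                            stats::setNames(g[[3L]] == "1", g[[2L]]))
  })
  out
}

#' @rdname read_cohesiveness
#' @export
write_cohesiveness <- function(annotations, path) {
  rows <- unlist(lapply(annotations, function(a) {
    paste(a$superclass_id, names(a$judgments),
          as.integer(a$judgments), sep = "\t")
  }), use.names = FALSE)
  writeLines(rows, path, useBytes = TRUE)
  invisible(annotations)
}

#' Repeated seeded-skeleton experiment
#'
#' Repeat `r = 1, ..., n_repeats`: build a skeleton with
#' `rng_seed = base_seed + r`, map every candidate with the configured
#' method, and evaluate.  Reports both the unweighted mean over repeats and
#' the candidate-pooled aggregate (the two differ when candidate counts vary
#' across repeats).
#'
#' @param ontology an [ontology()].
#' @param vectors a [label_vector_set()] (embedding method) or `NULL`.
#' @param tokenized_labels from [tokenize_labels()] (string methods) or
#'   `NULL`.
#' @param config a [mapper_config()].
#' @param n_seed seeds revealed per target class.
#' @param n_repeats number of independently seeded skeletons.
#' @param base_seed base RNG seed; repeat `r` uses `base_seed + r`.
#' @return Object of class `experiment_summary`: `n_repeats`,
#'   `per_repeat_precision`, `per_repeat_mean_distance`, `mean_precision`,
#'   `mean_distance`, `pooled_precision`, `pooled_mean_distance`,
#'   `rng_base_seed`, `n_seed`, `method`.
#' @export
run_experiment <- function(ontology, vectors = NULL,
                           tokenized_labels = NULL,
                           config = mapper_config(), n_seed = 2L,
                           n_repeats = 10L, base_seed = 0L) {
  if (n_repeats < 1L) stop_onto("bad_input", "n_repeats must be >= 1")
  prec <- numeric(n_repeats)
  mdist <- numeric(n_repeats)
  ncand <- integer(n_repeats)
  for (r in seq_len(n_repeats)) {
    sk <- make_skeleton(ontology, n_seed, rng_seed = base_seed + r)
    cfg <- config
    cfg$rng_seed <- as.integer(base_seed + r) # random draws vary per repeat
    res <- map_all(sk, vectors = vectors, config = cfg,
                   tokenized_labels = tokenized_labels)
    ev <- evaluate_mapping(res, ontology)
    prec[r] <- ev$precision
    mdist[r] <- ev$mean_distance
    ncand[r] <- ev$n_candidates
  }
  structure(
    list(n_repeats = n_repeats,
         per_repeat_precision = prec,
         per_repeat_mean_distance = mdist,
         mean_precision = mean(prec),
         mean_distance = mean(mdist),
         pooled_precision = sum(prec * ncand) / sum(ncand),
         pooled_mean_distance = sum(mdist * ncand) / sum(ncand),
         rng_base_seed = as.integer(base_seed),
         n_seed = as.integer(n_seed),
         method = config$method),
    class = "experiment_summary"
  )
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf(
    "<experiment_summary> method=%s, %d repeats (n_seed=%d): mean precision %.4f, mean distance %.3f hops\n",
    x$method, x$n_repeats, x$n_seed, x$mean_precision, x$mean_distance))
  invisible(x)
}

#' Compare mapping methods on one ontology
#'
#' Runs [run_experiment()] for each method with shared skeleton seeds (so
#' repeats are paired across methods) and reports a method comparison table
#' plus two-sided Wilcoxon signed-rank p-values of each method against the
#' first, paired over repeats.
#'
#' @param ontology an [ontology()].
#' @param vectors,tokenized_labels inputs for the methods that need them.
#' @param methods character vector of method names.
#' @param alpha,similarity passed to [mapper_config()].
#' @param n_seed,n_repeats,base_seed experiment parameters.
#' @return List with `table` (data frame: method, avg_precision,
#'   avg_distance, p_vs_first) and `summaries` (named list of
#'   `experiment_summary`).
#' @export
compare_methods <- function(ontology, vectors = NULL,
                            tokenized_labels = NULL,
                            methods = c("embedding", "jaccard", "hamming",
                                        "random"),
                            alpha = 0.8, similarity = "cosine",
                            n_seed = 2L, n_repeats = 10L, base_seed = 0L) {
  summaries <- lapply(methods, function(m) {
    run_experiment(ontology, vectors = vectors,
                   tokenized_labels = tokenized_labels,
                   config = mapper_config(method = m, alpha = alpha,
                                          similarity = similarity),
                   n_seed = n_seed, n_repeats = n_repeats,
                   base_seed = base_seed)
  })
  names(summaries) <- methods
  ref <- summaries[[1L]]$per_repeat_precision
  pvals <- vapply(summaries, function(s) {
    if (identical(s$per_repeat_precision, ref) || length(ref) < 2L) {
      return(NA_real_)
    }
    suppressWarnings(
      wilcox.test(s$per_repeat_precision, ref, paired = TRUE)$p.value)
  }, numeric(1))
  tab <- data.frame(
    method = methods,
    avg_precision = vapply(summaries, `[[`, numeric(1), "mean_precision"),
    avg_distance = vapply(summaries, `[[`, numeric(1), "mean_distance"),
    p_vs_first = pvals,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(table = tab, summaries = summaries,
       significance_test = "two-sided Wilcoxon signed-rank, paired by repeat")
}

#' Relative reduction between two reported means
#'
#' `(reference - improved) / reference`, the standard "x% shorter/lower"
#' arithmetic used when comparing two methods' mean metrics.
#'
#' @param reference the baseline value.
#' @param improved the improved value.
#' @return Fraction of the baseline that was removed.
#' @export
relative_reduction <- function(reference, improved) {
  if (reference == 0) stop_onto("bad_input", "reference must be nonzero")
  (reference - improved) / reference
}

#' Per-superclass precision of a mapping
#'
#' For each requested superclass, the precision over candidates whose
#' ground-truth classes lie inside the superclass's subtree.  Superclasses
#' with no such candidates are dropped.
#'
#' @param results a `mapping_result`.
#' @param ontology an [ontology()].
#' @param superclass_ids class ids to aggregate under.
#' @return Named numeric vector of precisions.
#' @export
per_superclass_precision <- function(results, ontology, superclass_ids) {
  truth <- ontology$instance_parents[results$instance_id]
  correct <- mapply(function(p, tr) p %in% tr, results$predicted_class_id,
                    truth)
  out <- numeric(0)
  for (sc in superclass_ids) {
    sub <- subtree_classes(ontology, sc)
    sel <- vapply(truth, function(tr) any(tr %in% sub), logical(1))
    if (any(sel)) out[sc] <- mean(correct[sel])
  }
  out
}

#' Pearson correlation between a structural metric and precision
#'
#' Pairs the two named maps on their shared keys and returns the Pearson
#' correlation coefficient with a two-sided p-value.
#'
#' @param per_superclass_precision named numeric vector.
#' @param per_superclass_metric named numeric vector (e.g. granularity or
#'   cohesiveness per superclass).
#' @return List with `r`, `p_value`, `n`.
#' @export
correlate_structure <- function(per_superclass_precision,
                                per_superclass_metric) {
  keys <- intersect(names(per_superclass_precision),
                    names(per_superclass_metric))
  if (length(keys) < 3L) {
    stop_onto("bad_input", "need >= 3 paired superclass observations")
  }
  x <- as.numeric(per_superclass_precision[keys])
  y <- as.numeric(per_superclass_metric[keys])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_onto("zero_variance", "a correlate has zero variance")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(keys))
}

#' Serialize an evaluation report or experiment summary to JSON
#'
#' @param x an `eval_report` or `experiment_summary`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(x, path) {
  y <- unclass(x)
  if (!is.null(y$distances)) y$distances <- unname(y$distances)
  if (!is.null(y$distance_histogram)) {
    y$distance_histogram <- as.list(y$distance_histogram)
  }
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
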