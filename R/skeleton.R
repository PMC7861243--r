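#' Build a seeded skeleton from an ontology
#'
#' A seeded skeleton keeps the class DAG intact, reveals `n_seed` randomly
#' chosen ground-truth instances per target class as seeds, and holds out
#' every other instance as a candidate to be mapped.  Target classes are
#' exactly the classes with at least one ground-truth instance; classes
#' without instances are structural only and never receive candidates.
#'
#' A class with fewer than `n_seed` instances contributes all of them as
#' seeds (so `|seeds[c]| = min(n_seed, |I_c|)`).  An instance attached to
#' several classes may be drawn as a seed for any of them; once drawn
#' anywhere it is removed from the candidate set globally, so no instance is
#' both revealed to the mapper and scored against it.
#'
#' @param ontology an [ontology()].
#' @param n_seed number of seed instances per target class (>= 1).
#' @param rng_seed integer seed; the draw is deterministic given it.
#' @return An object of class `seeded_skeleton`: fields `ontology`,
#'   `n_seed`, `seeds` (named list class id -> instance ids), `candidates`
#'   (character vector), `target_class_ids`, `rng_seed`.
#' @export
make_skeleton <- function(ontology, n_seed, rng_seed = 1L) {
  if (!is.numeric(n_seed) || length(n_seed) != 1L || n_seed < 1) {
    stop_onto("bad_n_seed", "n_seed must be a single integer >= 1")
  }
  n_seed <- as.integer(n_seed)
  ipc <- instances_per_class(ontology)
  targets <- sort(names(ipc)[ipc > 0L])
  members <- instances_of_classes(ontology, targets)
  seeds <- with_seed(rng_seed, {
    lapply(members, function(ic) sort(sample_ids(ic, min(n_seed, length(ic)))))
  })
  seed_union <- unique(unlist(seeds, use.names = FALSE))
  candidates <- setdiff(ontology$instances$id, seed_union)
  structure(
    list(ontology = ontology, n_seed = n_seed, seeds = seeds,
         candidates = candidates, target_class_ids = targets,
         rng_seed = as.integer(rng_seed)),
    class = "seeded_skeleton"
  )
}

# instance ids per class (sorted), for the given class ids
instances_of_classes <- function(ontology, class_ids) {
  ip <- ontology$instance_parents
  flat_parent <- unlist(ip, use.names = FALSE)
  flat_inst <- rep(names(ip), lengths(ip))
  sp <- split(flat_inst, flat_parent)
  out <- lapply(class_ids, function(c) sort(unique(sp[[c]] %||% character())))
  names(out) <- class_ids
  out
}

#' @export
print.seeded_skeleton <- function(x, ...) {
  cat(sprintf(
    "<seeded_skeleton> %d target classes, n_seed=%d, %d seeds, %d candidates (rng_seed=%d)\n",
    length(x$target_class_ids), x$n_seed,
    length(unique(unlist(x$seeds, use.names = FALSE))),
    length(x$candidates), x$rng_seed))
  invisible(x)
}
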