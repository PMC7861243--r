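#' Construct an ontology
#'
#' An ontology is a rooted, multi-parent directed acyclic graph (DAG) of
#' classes together with a set of instances, each attached to one or more
#' classes by an "is a" link.  Edges are stored child -> parent; the root is
#' the unique class with no parents, and every class reaches the root by
#' following parent edges.
#'
#' @param class_labels named character vector, class id -> human-readable
#'   label.
#' @param class_parents named list, class id -> character vector of parent
#'   class ids (`character(0)` for the root only).  Ids absent from the list
#'   are treated as having no parents.
#' @param instance_labels named character vector, instance id -> label.  May
#'   be empty.
#' @param instance_parents named list, instance id -> non-empty character
#'   vector of parent class ids.  The first element is the primary parent
#'   (the one synthetic generators anchor the instance's embedding to).
#'
#' @return An object of class `ontology` with fields `classes` and
#'   `instances` (data frames with columns `id`, `label`), `class_parents`,
#'   `instance_parents`, `root_id`, and a cached child->parent
#'   [igraph::graph] of the class hierarchy.
#'
#' @details Validation raises distinct conditions:
#'   `ontopop_error_duplicate_id`, `ontopop_error_dangling_parent`,
#'   `ontopop_error_cycle`, `ontopop_error_root`,
#'   `ontopop_error_missing_label`.
#' @seealso [read_ontology()], [depth_of()], [paths_to_root()],
#'   [instances_per_class()]
#' @export
ontology <- function(class_labels, class_parents = list(),
                     instance_labels = character(),
                     instance_parents = list()) {
  cids <- names(class_labels)
  iids <- names(instance_labels)
  if (length(cids) == 0L) stop_onto("root", "ontology needs at least one class")
  if (anyDuplicated(cids) || anyDuplicated(iids) || any(cids %in% iids)) {
    stop_onto("duplicate_id", "class/instance ids must be globally unique")
  }
  if (any(!nzchar(class_labels)) || any(!nzchar(instance_labels))) {
    stop_onto("missing_label", "labels must be non-empty")
  }
  cp <- lapply(cids, function(id) {
    as.character(class_parents[[id]] %||% character())
  })
  names(cp) <- cids
  all_cp <- unique(unlist(cp, use.names = FALSE))
  if (length(all_cp) && !all(all_cp %in% cids)) {
    bad <- setdiff(all_cp, cids)
    stop_onto("dangling_parent",
              paste0("unknown parent class id(s): ",
                     paste(head(bad, 5L), collapse = ", ")))
  }
  if (length(instance_parents) != length(iids) ||
      !setequal(names(instance_parents), iids)) {
    stop_onto("dangling_parent",
              "instance_parents must be named by exactly the instance ids")
  }
  ip <- lapply(iids, function(id) as.character(instance_parents[[id]]))
  names(ip) <- iids
  if (length(ip)) {
    if (any(lengths(ip) == 0L)) {
      stop_onto("dangling_parent", "every instance needs >= 1 parent class")
    }
    all_ip <- unique(unlist(ip, use.names = FALSE))
    if (!all(all_ip %in% cids)) {
      bad <- setdiff(all_ip, cids)
      stop_onto("dangling_parent",
                paste0("instance parent(s) are not classes: ",
                       paste(head(bad, 5L), collapse = ", ")))
    }
  }
  g <- class_graph_from_parents(cids, cp)
  if (!igraph::is_dag(g)) {
    stop_onto("cycle", "class hierarchy contains a cycle")
  }
  roots <- cids[lengths(cp) == 0L]
  if (length(roots) != 1L) {
    stop_onto("root", sprintf(
      "ontology must have exactly one root (class with no parents); found %d",
      length(roots)))
  }
  structure(
    list(
      classes = data.frame(id = cids, label = unname(class_labels),
                           stringsAsFactors = FALSE),
      instances = data.frame(id = iids, label = unname(instance_labels),
                             stringsAsFactors = FALSE),
      class_parents = cp,
      instance_parents = ip,
      root_id = roots,
      graph = g
    ),
    class = "ontology"
  )
}

class_graph_from_parents <- function(cids, cp) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(cids), name = cids)
  child <- rep(names(cp), lengths(cp))
  parent <- unlist(cp, use.names = FALSE)
  if (length(child)) {
    g <- igraph::add_edges(g, rbind(match(child, cids), match(parent, cids)))
  }
  g
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> %d classes, %d instances, root '%s'\n",
    nrow(x$classes), nrow(x$instances), x$root_id))
  invisible(x)
}

check_class_id <- function(ontology, class_id) {
  if (!is.character(class_id) || length(class_id) != 1L ||
      !class_id %in% ontology$classes$id) {
    stop_onto("unknown_id", sprintf("unknown class id '%s'", class_id))
  }
}

#' Read an ontology from its TSV serialization
#'
#' The edge file is header-less TSV with columns
#' `child_id<TAB>parent_id<TAB>kind`, `kind` being `class` when the child is
#' a class and `instance` when it is an instance; a child with several
#' parents appears on several lines.  The labels file is
#' `id<TAB>label` (UTF-8).  Ids that appear only in the labels file are
#' parentless classes (this is how a one-class, zero-instance ontology is
#' expressed).
#'
#' @param edges_path,labels_path paths to the two TSV files.
#' @return A validated [ontology()].
#' @export
read_ontology <- function(edges_path, labels_path) {
  lab <- read_tsv_cols(labels_path, 2L, "labels")
  labels <- lab[[2L]]
  names(labels) <- lab[[1L]]
  if (anyDuplicated(names(labels))) {
    stop_onto("duplicate_id", "duplicate id in labels file")
  }
  ed <- read_tsv_cols(edges_path, 3L, "edges", allow_empty = TRUE)
  if (nrow(ed)) {
    if (!all(ed[[3L]] %in% c("class", "instance"))) {
      stop_onto("bad_format", "edge kind must be 'class' or 'instance'")
    }
    inst_ids <- unique(ed[[1L]][ed[[3L]] == "instance"])
    class_children <- unique(ed[[1L]][ed[[3L]] == "class"])
    parents <- unique(ed[[2L]])
  } else {
    inst_ids <- character(); class_children <- character()
    parents <- character()
  }
  if (any(parents %in% inst_ids)) {
    stop_onto("dangling_parent", "an instance id is used as a parent")
  }
  class_ids <- unique(c(class_children, parents,
                        setdiff(names(labels), c(inst_ids, class_children,
                                                 parents))))
  missing_lab <- setdiff(c(class_ids, inst_ids), names(labels))
  if (length(missing_lab)) {
    stop_onto("missing_label",
              paste0("no label for id(s): ",
                     paste(head(missing_lab, 5L), collapse = ", ")))
  }
  cp <- split_edges(ed, "class", class_ids)
  ip <- split_edges(ed, "instance", inst_ids)
  ontology(class_labels = labels[class_ids], class_parents = cp,
           instance_labels = labels[inst_ids], instance_parents = ip)
}

read_tsv_cols <- function(path, ncol, what, allow_empty = FALSE) {
  if (!file.exists(path)) {
    stop_onto("bad_format", sprintf("%s file not found: %s", what, path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    if (allow_empty) {
      out <- as.data.frame(matrix(character(), ncol = ncol),
                           stringsAsFactors = FALSE)
      return(out)
    }
    stop_onto("bad_format", sprintf("%s file is empty: %s", what, path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != ncol)) {
    stop_onto("bad_format",
              sprintf("%s file must have %d tab-separated fields per line",
                      what, ncol))
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  out
}

split_edges <- function(ed, kind, ids) {
  out <- rep(list(character()), length(ids))
  names(out) <- ids
  if (nrow(ed)) {
    sel <- ed[[3L]] == kind
    if (any(sel)) {
      sp <- split(ed[[2L]][sel], ed[[1L]][sel])
      out[names(sp)] <- lapply(sp, unique)
    }
  }
  out
}

#' Write an ontology in the TSV dialect read by [read_ontology()]
#'
#' Output is deterministic (rows sorted by child then parent id, labels
#' sorted by id) so a read/write round trip is byte-identical.
#'
#' @param ontology an [ontology()].
#' @param edges_path,labels_path output file paths.
#' @return Invisibly, the ontology.
#' @export
write_ontology <- function(ontology, edges_path, labels_path) {
  rows <- character()
  for (kind in c("class", "instance")) {
    par <- if (kind == "class") ontology$class_parents else
      ontology$instance_parents
    child <- rep(names(par), lengths(par))
    parent <- unlist(par, use.names = FALSE)
    if (length(child)) {
      o <- order(child, parent, method = "radix")
      rows <- c(rows, paste(child[o], parent[o], kind, sep = "\t"))
    }
  }
  writeLines(rows, edges_path, useBytes = TRUE)
  ids <- c(ontology$classes$id, ontology$instances$id)
  labs <- c(ontology$classes$label, ontology$instances$label)
  o <- order(ids, method = "radix")
  writeLines(paste(ids[o], labs[o], sep = "\t"), labels_path, useBytes = TRUE)
  invisible(ontology)
}

#' Depth of a class
#'
#' Depth is the minimum number of child->parent edges separating the class
#' from the root (the root has depth 0).  With multiple parents a class has
#' several paths to the root; the shortest defines its depth.
#'
#' @param ontology an [ontology()].
#' @param class_id a class id (scalar or vector).
#' @return Integer vector of depths.
#' @export
depth_of <- function(ontology, class_id) {
  for (id in class_id) check_class_id(ontology, id)
  d <- igraph::distances(ontology$graph, v = class_id, to = ontology$root_id,
                         mode = "out")
  as.integer(d[, 1L])
}

#' Number of distinct paths from a class to the root
#'
#' Counts directed child->parent paths; multi-parent classes contribute one
#' path per parent branch, so the count reflects the multi-parent
#' architecture of the DAG (the root itself has one, empty, path).
#'
#' @inheritParams depth_of
#' @return Numeric vector of path counts (double: counts can be large).
#' @export
paths_to_root <- function(ontology, class_id) {
  for (id in class_id) check_class_id(ontology, id)
  counts <- path_counts_all(ontology)
  unname(counts[class_id])
}

path_counts_all <- function(ontology) {
  g <- ontology$graph
  # children before parents along child->parent edges; reverse so every
  # parent's count is ready when its children are processed
  ord <- rev(names(igraph::topo_sort(g, mode = "out")))
  counts <- numeric(length(ord))
  names(counts) <- ord
  counts[ontology$root_id] <- 1
  for (v in ord) {
    if (v == ontology$root_id) next
    counts[v] <- sum(counts[ontology$class_parents[[v]]])
  }
  counts
}

#' Instances per class
#'
#' For every class, the number of instances whose parent set contains it
#' (an instance with k parents is counted in each of the k classes).
#' Classes without instances are reported with count 0.
#'
#' @param ontology an [ontology()].
#' @return Named integer vector, class id -> count, in class order.
#' @export
instances_per_class <- function(ontology) {
  counts <- integer(nrow(ontology$classes))
  names(counts) <- ontology$classes$id
  flat <- unlist(ontology$instance_parents, use.names = FALSE)
  if (length(flat)) {
    tab <- table(flat)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Structural summary of an ontology
#'
#' Convenience wrapper producing the per-class depth, paths-to-root and
#' instance-count tables used for structural analytics of the DAG.
#'
#' @param ontology an [ontology()].
#' @return A data frame with columns `id`, `depth`, `paths_to_root`,
#'   `n_instances`.
#' @export
ontology_structure <- function(ontology) {
  ids <- ontology$classes$id
  data.frame(
    id = ids,
    depth = depth_of(ontology, ids),
    paths_to_root = unname(path_counts_all(ontology)[ids]),
    n_instances = unname(instances_per_class(ontology)[ids]),
    stringsAsFactors = FALSE
  )
}
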