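# The GO directed acyclic graph and all ancestry computations: annotation
# propagation, term depth, and the shared-ancestor grouping used for
# redundancy reduction. Edges point child -> parent, so "upward" traversal is
# igraph mode = "out".

#' Construct a GO DAG
#'
#' Builds the directed acyclic graph of GO terms used for annotation
#' propagation, depth, and ancestry queries. Edges point from child to
#' parent and carry a relation (`is_a` or `part_of`). Construction verifies
#' acyclicity, drops edges to unknown parents (with a warning), and records
#' the root term(s) of each namespace.
#'
#' @param terms A data frame with columns `term_id`, `name`, `namespace`
#'   (one of `biological_process`, `molecular_function`,
#'   `cellular_component`).
#' @param edges A data frame with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`); may have zero rows.
#' @param alias Optional named character vector mapping alternate ids to
#'   primary term ids.
#' @return An object of class `go_dag`.
#' @export
go_dag <- function(terms, edges, alias = character()) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(
    all(c("term_id", "name", "namespace") %in% names(terms)),
    all(c("child", "parent", "relation") %in% names(edges))
  )
  if (anyDuplicated(terms$term_id)) {
    stop("duplicate term ids in GO DAG construction", call. = FALSE)
  }
  bad_ns <- setdiff(unique(terms$namespace), GO_NAMESPACES)
  if (length(bad_ns) > 0L) {
    stop("unknown namespace(s): ", paste(bad_ns, collapse = ", "), call. = FALSE)
  }
  unknown_parent <- !edges$parent %in% terms$term_id
  unknown_child <- !edges$child %in% terms$term_id
  if (any(unknown_parent | unknown_child)) {
    warning(
      sum(unknown_parent | unknown_child),
      " edge(s) referencing terms absent from the ontology dropped",
      call. = FALSE
    )
    edges <- edges[!unknown_parent & !unknown_child, , drop = FALSE]
  }
  edges <- dplyr::distinct(edges)
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE,
    vertices = terms$term_id
  )
  igraph::E(g)$relation <- edges$relation
  if (!igraph::is_dag(g)) {
    cyc <- igraph::girth(g)$circle
    stop(
      "ontology graph contains a cycle",
      if (length(cyc) > 0L) {
        paste0(": ", paste(igraph::V(g)$name[cyc], collapse = " -> "))
      },
      call. = FALSE
    )
  }
  ns <- stats::setNames(terms$namespace, terms$term_id)
  nm <- stats::setNames(terms$name, terms$term_id)
  deg_out <- igraph::degree(g, mode = "out")
  roots <- split(names(deg_out)[deg_out == 0L], ns[names(deg_out)[deg_out == 0L]])
  structure(
    list(
      graph = g,
      terms = terms$term_id,
      name = nm,
      namespace = ns,
      alias = alias,
      roots = roots
    ),
    class = "go_dag"
  )
}

#' @export
print.go_dag <- function(x, ...) {
  ns_counts <- table(x$namespace)
  cat(
    "GO DAG:", length(x$terms), "terms,",
    igraph::ecount(x$graph), "edges\n"
  )
  for (ns in names(ns_counts)) {
    cat("  ", ns, ": ", ns_counts[[ns]], " terms, root(s): ",
      paste(x$roots[[ns]], collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

# Resolve ids through the alias table; unknown ids stay as-is for the caller
# to handle.
resolve_terms <- function(dag, ids) {
  hit <- ids %in% names(dag$alias)
  ids[hit] <- unname(dag$alias[ids[hit]])
  ids
}

assert_known_term <- function(dag, term) {
  if (!term %in% dag$terms) {
    stop("unknown GO term: ", term, call. = FALSE)
  }
}

# The working graph restricted to the enabled edge relations.
relation_graph <- function(dag, relations) {
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  if (setequal(relations, c("is_a", "part_of"))) {
    return(dag$graph)
  }
  keep <- which(igraph::E(dag$graph)$relation %in% relations)
  igraph::subgraph_from_edges(dag$graph, keep, delete.vertices = FALSE)
}

#' Ancestors of a GO term
#'
#' Returns the reflexive transitive closure of the upward (child-to-parent)
#' relation: the term itself plus every term reachable over the enabled edge
#' relations. Alternate ids are resolved before lookup.
#'
#' @param dag A [go_dag()].
#' @param term A term id (or alias).
#' @param relations Edge relations to traverse; default both `is_a` and
#'   `part_of`.
#' @return Character vector of term ids, including `term` itself.
#' @export
go_ancestors <- function(dag, term, relations = c("is_a", "part_of")) {
  term <- resolve_terms(dag, term)
  assert_known_term(dag, term)
  g <- relation_graph(dag, relations)
  out <- igraph::subcomponent(g, term, mode = "out")$name
  ns <- dag$namespace[[term]]
  out[dag$namespace[out] == ns]
}

#' Depth of a GO term
#'
#' Length of the shortest upward path from the term to a root of its
#' namespace (a term with no parents). Roots have depth 0.
#'
#' @inheritParams go_ancestors
#' @return A non-negative integer.
#' @export
go_term_depth <- function(dag, term, relations = c("is_a", "part_of")) {
  term <- resolve_terms(dag, term)
  assert_known_term(dag, term)
  g <- relation_graph(dag, relations)
  roots <- dag$roots[[dag$namespace[[term]]]]
  # under restricted relations a term may gain extra parentless ancestors;
  # keep the namespace roots of the full graph as the reference
  d <- igraph::distances(g, v = term, to = roots, mode = "out")
  d <- d[is.finite(d)]
  if (length(d) == 0L) {
    # unreachable root under the restricted relation set: fall back to the
    # farthest parentless ancestor reachable
    anc <- igraph::subcomponent(g, term, mode = "out")$name
    leaf_roots <- anc[igraph::degree(g, anc, mode = "out") == 0L]
    d <- igraph::distances(g, v = term, to = leaf_roots, mode = "out")
    d <- d[is.finite(d)]
  }
  as.integer(min(d))
}

#' Propagate GO annotations up the ontology
#'
#' Applies the true-path rule: a protein annotated to a term is annotated to
#' every ancestor of that term, so general terms inherit the annotations of
#' their more specific descendants. Duplicates are collapsed; records whose
#' term cannot be resolved in the DAG are dropped, counted in the `dropped`
#' attribute, and reported with a warning.
#'
#' @param dag A [go_dag()].
#' @param records Annotation records (as from [parse_go_annotation()]) whose
#'   `category_id` values are GO accessions.
#' @param relations Edge relations to traverse during propagation.
#' @return Annotation records closed under ancestry, with term names and
#'   namespaces refreshed from the DAG and attribute `dropped` (count of
#'   input records whose term was absent).
#' @export
propagate_annotations <- function(dag, records, relations = c("is_a", "part_of")) {
  records <- tibble::as_tibble(records)
  ids <- resolve_terms(dag, records$category_id)
  known <- ids %in% dag$terms
  n_dropped <- sum(!known)
  if (n_dropped > 0L) {
    warning(
      n_dropped, " annotation record(s) reference GO terms absent from the ",
      "ontology and were dropped",
      call. = FALSE
    )
  }
  records <- records[known, , drop = FALSE]
  records$category_id <- ids[known]
  uniq_terms <- unique(records$category_id)
  anc <- lapply(uniq_terms, function(t) go_ancestors(dag, t, relations))
  names(anc) <- uniq_terms
  expanded <- tibble::tibble(
    protein_id = rep(records$protein_id, lengths(anc[records$category_id])),
    category_id = unlist(anc[records$category_id], use.names = FALSE)
  )
  expanded <- dplyr::distinct(expanded)
  out <- new_annotation_records(
    protein_id = expanded$protein_id,
    category_id = expanded$category_id,
    category_label = unname(dag$name[expanded$category_id]),
    category_group = unname(dag$namespace[expanded$category_id]),
    source = if (nrow(records) > 0L) records$source[[1L]] else character()
  )
  attr(out, "dropped") <- n_dropped
  out
}

#' Group GO terms by a shared nearby ancestor
#'
#' Partitions a set of terms (all from one namespace) into the connected
#' components of the relation "shares a common ancestor within
#' `depth_limit` upward hops of each term" (a term is its own ancestor at
#' distance 0). With `depth_limit = 0` only identical terms group. Namespace
#' roots present in the input are excluded from grouping and returned as
#' singletons.
#'
#' @param dag A [go_dag()].
#' @param terms Character vector of term ids (one namespace).
#' @param depth_limit Non-negative integer: maximum upward distance from each
#'   term to the shared ancestor.
#' @param relations Edge relations to traverse.
#' @return A list of character vectors forming a partition of `terms`.
#' @export
group_terms_by_ancestor <- function(dag, terms, depth_limit,
                                    relations = c("is_a", "part_of")) {
  stopifnot(length(depth_limit) == 1L, depth_limit >= 0)
  terms <- unique(resolve_terms(dag, terms))
  for (t in terms) assert_known_term(dag, t)
  if (length(terms) == 0L) {
    return(list())
  }
  ns <- unique(dag$namespace[terms])
  if (length(ns) > 1L) {
    stop(
      "terms span multiple namespaces: ", paste(ns, collapse = ", "),
      call. = FALSE
    )
  }
  roots <- dag$roots[[ns]]
  is_root <- terms %in% roots
  root_singletons <- lapply(terms[is_root], function(t) t)
  terms <- terms[!is_root]
  if (length(terms) == 0L) {
    return(root_singletons)
  }
  g <- relation_graph(dag, relations)
  hoods <- igraph::ego(g, order = depth_limit, nodes = terms, mode = "out")
  hoods <- lapply(hoods, function(v) v$name)
  # connected components of the term ~ shared-ancestor relation, via a
  # bipartite helper graph term -> ancestor
  anc_edges <- data.frame(
    from = rep(paste0("t|", terms), lengths(hoods)),
    to = paste0("a|", unlist(hoods, use.names = FALSE))
  )
  helper <- igraph::graph_from_data_frame(anc_edges, directed = FALSE)
  comp <- igraph::components(helper)$membership
  term_comp <- comp[paste0("t|", terms)]
  blocks <- split(terms, term_comp)
  names(blocks) <- NULL
  c(blocks, root_singletons)
}
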