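# Independent oracles and small fixture builders used across the suite.
# These stay deliberately naive: exhaustive enumeration, literal textbook
# formulas, breadth-first search — never the package's own code paths.

# Exact upper-tail hypergeometric probability by enumerating every one of
# the C(N, n) equally likely draws. Successes are elements 1..K.
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0L) {
    return(as.numeric(k <= 0))
  }
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

holm_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(cummax((m - seq_len(m) + 1L) * p[o]), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

bonferroni_reference <- function(p) pmin(length(p) * p, 1)

# Build a go_dag from an edge list (child, parent, relation); every id
# mentioned becomes a term of the given namespace.
make_dag <- function(edges, ns = "biological_process", extra_terms = character()) {
  edges <- tibble::as_tibble(edges)
  if (!"relation" %in% names(edges)) {
    edges$relation <- "is_a"
  }
  ids <- unique(c(edges$child, edges$parent, extra_terms))
  go_dag(
    tibble::tibble(term_id = ids, name = paste("term", ids), namespace = ns),
    edges
  )
}

# C is_a B is_a A
chain_dag <- function() {
  make_dag(tibble::tibble(child = c("C", "B"), parent = c("B", "A")))
}

# D is_a B, D is_a C, B is_a A, C is_a A
diamond_dag <- function() {
  make_dag(tibble::tibble(
    child = c("D", "D", "B", "C"),
    parent = c("B", "C", "A", "A")
  ))
}

# A random connected single-root DAG over n nodes (node 1 is the root);
# relies only on the caller's RNG state.
random_test_dag <- function(n_nodes, ns = "biological_process") {
  ids <- sprintf("N%03d", seq_len(n_nodes))
  child <- parent <- character(0)
  if (n_nodes > 1L) {
    for (i in 2:n_nodes) {
      parents <- unique(sample.int(i - 1L, min(i - 1L, sample(1:2, 1L))))
      child <- c(child, rep(ids[[i]], length(parents)))
      parent <- c(parent, ids[parents])
    }
  }
  make_dag(
    tibble::tibble(
      child = child, parent = parent,
      relation = sample(c("is_a", "part_of"), length(child),
        replace = TRUE, prob = c(0.8, 0.2)
      )
    ),
    ns = ns, extra_terms = ids
  )
}

# Reflexive transitive closure by breadth-first search over a raw edge list.
bfs_ancestors <- function(edges, term) {
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(edges$parent[edges$child %in% frontier], seen)
  }
  seen
}

# Upward neighbourhoods within `depth` hops, then connected components of
# the shares-an-ancestor relation, computed by naive set union / fixpoint.
components_by_shared_ancestor <- function(edges, terms, depth) {
  hood <- lapply(terms, function(t) {
    frontier <- t
    seen <- t
    d <- 0L
    while (d < depth && length(frontier) > 0L) {
      frontier <- setdiff(edges$parent[edges$child %in% frontier], seen)
      seen <- union(seen, frontier)
      d <- d + 1L
    }
    seen
  })
  names(hood) <- terms
  blocks <- lapply(terms, function(t) t)
  repeat {
    merged <- FALSE
    for (i in seq_along(blocks)) {
      if (is.null(blocks[[i]])) next
      for (j in seq_along(blocks)) {
        if (j <= i || is.null(blocks[[j]])) next
        share <- any(vapply(blocks[[i]], function(a) {
          any(vapply(blocks[[j]], function(b) {
            length(intersect(hood[[a]], hood[[b]])) > 0L
          }, logical(1)))
        }, logical(1)))
        if (share) {
          blocks[[i]] <- union(blocks[[i]], blocks[[j]])
          blocks[j] <- list(NULL) # keep the slot so indices stay valid
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  Filter(Negate(is.null), blocks)
}

# Annotation records helper for hand-built GO tests.
go_recs <- function(protein, term) {
  tibble::tibble(
    protein_id = protein, category_id = term,
    category_label = term, category_group = "", source = "go"
  )
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
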