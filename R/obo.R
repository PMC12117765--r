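# A minimal parser for the OBO 1.2/1.4 flat-file format: [Term] stanzas with
# id/name/namespace/is_a/relationship/alt_id/is_obsolete tags. Only what the
# GO DAG needs is retained; no installed R package provides this format.

#' Parse an OBO ontology file into a GO DAG
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 flat file, keeping
#' non-obsolete terms, `is_a` and `part_of` edges, names, namespaces, and an
#' alias table built from `alt_id` tags. Obsolete terms are excluded
#' entirely (including their edges). A cyclic parent relation is a hard
#' error, reported with one offending cycle.
#'
#' @param path Path to an OBO file (plain or gzip-compressed).
#' @return A [go_dag()].
#' @export
parse_obo <- function(path) {
  lines <- read_input_lines(path)
  lines <- trimws2(lines)
  # stanza boundaries: [Term] opens a term, any other [Typedef]/[Instance]
  # stanza closes it
  stanza_starts <- grep("^\\[", lines)
  is_term <- lines[stanza_starts] == "[Term]"
  if (!any(is_term)) {
    stop("no [Term] stanzas found in OBO file: ", path, call. = FALSE)
  }
  ends <- c(stanza_starts[-1L] - 1L, length(lines))
  terms <- list()
  edges <- list()
  alias <- character()
  for (i in which(is_term)) {
    block <- lines[(stanza_starts[[i]] + 1L):ends[[i]]]
    block <- block[nzchar(block) & !startsWith(block, "!")]
    tag_val <- function(tag) {
      hits <- block[startsWith(block, paste0(tag, ":"))]
      sub("!.*$", "", sub(paste0("^", tag, ":\\s*"), "", hits))
    }
    id <- trimws2(tag_val("id"))
    if (length(id) != 1L || !nzchar(id)) next
    obsolete <- any(grepl("^true", trimws2(tag_val("is_obsolete"))))
    if (obsolete) next
    name <- trimws2(tag_val("name"))
    ns <- normalize_namespace(tag_val("namespace"))
    if (length(ns) == 0L || is.na(ns[[1L]])) next
    terms[[length(terms) + 1L]] <- tibble::tibble(
      term_id = id,
      name = if (length(name) >= 1L) name[[1L]] else id,
      namespace = ns[[1L]]
    )
    for (parent in trimws2(tag_val("is_a"))) {
      if (nzchar(parent)) {
        edges[[length(edges) + 1L]] <-
          tibble::tibble(child = id, parent = parent, relation = "is_a")
      }
    }
    for (rel in trimws2(tag_val("relationship"))) {
      parts <- strsplit(rel, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] == "part_of") {
        edges[[length(edges) + 1L]] <-
          tibble::tibble(child = id, parent = parts[[2L]], relation = "part_of")
      }
    }
    for (alt in trimws2(tag_val("alt_id"))) {
      if (nzchar(alt)) alias[[alt]] <- id
    }
  }
  terms <- dplyr::bind_rows(terms)
  if (nrow(terms) == 0L) {
    stop("no usable (non-obsolete) terms in OBO file: ", path, call. = FALSE)
  }
  edges <- if (length(edges) > 0L) {
    dplyr::bind_rows(edges)
  } else {
    tibble::tibble(child = character(), parent = character(), relation = character())
  }
  go_dag(terms, edges, alias = alias)
}

#' Write a GO DAG to an OBO file
#'
#' Serializes a [go_dag()] back to the OBO flat format (one `[Term]` stanza
#' per term, `is_a`/`relationship: part_of` tags for edges). Used by the
#' fixture generator; round-trips through [parse_obo()].
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  el <- igraph::as_data_frame(dag$graph, what = "edges")
  out <- c("format-version: 1.2", "")
  for (t in sort_c(dag$terms)) {
    stanza <- c(
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", dag$name[[t]]),
      paste0("namespace: ", dag$namespace[[t]])
    )
    mine <- el[el$from == t, , drop = FALSE]
    mine <- mine[order(mine$to, method = "radix"), , drop = FALSE]
    for (j in seq_len(nrow(mine))) {
      stanza <- c(stanza, if (mine$relation[[j]] == "is_a") {
        paste0("is_a: ", mine$to[[j]])
      } else {
        paste0("relationship: part_of ", mine$to[[j]])
      })
    }
    alts <- names(dag$alias)[dag$alias == t]
    for (a in sort_c(alts)) stanza <- c(stanza, paste0("alt_id: ", a))
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}
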