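# The statistical core: one-sided hypergeometric and chi-squared
# overrepresentation tests, multiple-testing adjustment, enrichment ratios,
# and redundancy reduction of enriched GO terms by shared ancestry.

P_ADJUST_METHODS <- c("BH", "bonferroni", "holm", "BY", "hochberg", "hommel", "none")

check_counts <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || any(c(k, K, n, N) != floor(c(k, K, n, N)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(k > K) || any(K > N) || any(k > n) || any(n > N)) {
    stop(
      "invalid contingency counts: need k <= K <= N and k <= n <= N",
      call. = FALSE
    )
  }
}

#' One-sided hypergeometric overrepresentation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X` hypergeometric with `N`
#' background proteins of which `K` are in the category, drawing `n` query
#' proteins. This is the probability of observing at least the seen overlap
#' by chance, i.e. the overrepresentation p-value. Computed with the stable
#' tail of [stats::phyper()] and clamped to `[0, 1]`. All arguments are
#' vectorized.
#'
#' @param k Query proteins in the category.
#' @param K Background proteins in the category.
#' @param n Mapped query size.
#' @param N Background size.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeometric_pvalue(2, 2, 2, 4) # 1/6
hypergeometric_pvalue <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Chi-squared overrepresentation p-value
#'
#' Two-sided chi-squared test of independence (1 df) on the 2x2 table
#' `[[k, n-k], [K-k, (N-K)-(n-k)]]`, with the Yates continuity correction by
#' default. If any expected cell is zero (a degenerate table), the p-value
#' is 1 with a warning. The test is inherently two-sided; the direction of
#' the effect is read from the enrichment ratio.
#'
#' @inheritParams hypergeometric_pvalue
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return Probability in `[0, 1]`.
#' @export
chisquared_pvalue <- function(k, K, n, N, correct = TRUE) {
  check_counts(k, K, n, N)
  mapply(function(k, K, n, N) {
    tab <- matrix(c(k, K - k, n - k, (N - K) - (n - k)), nrow = 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0) || sum(tab) == 0) {
      warning("degenerate 2x2 table (zero expected cell); p = 1", call. = FALSE)
      return(1)
    }
    unname(suppressWarnings(stats::chisq.test(tab, correct = correct))$p.value)
  }, k, K, n, N)
}

#' Adjust p-values for multiple testing
#'
#' Thin validated wrapper over [stats::p.adjust()]. The default
#' Benjamini-Hochberg (`BH`) step-up procedure controls the false discovery
#' rate; `bonferroni`, `holm`, `BY`, `hochberg`, `hommel`, and `none` are
#' also available.
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @param method Correction method (default `"BH"`).
#' @return Adjusted p-values aligned with the input order.
#' @export
adjust_pvalues <- function(ps, method = "BH") {
  method <- match.arg(method, P_ADJUST_METHODS)
  if (any(is.na(ps)) || any(ps < 0 | ps > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(ps, method = method)
}

new_enrichment_report <- function(results, n_input, n_mapped, dropped_ids,
                                  model_kind, test, correction) {
  structure(
    list(
      results = results,
      n_input = n_input,
      n_mapped = n_mapped,
      dropped_ids = dropped_ids,
      model_kind = model_kind,
      test = test,
      correction = correction
    ),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(
    "Enrichment report [", x$model_kind, "]: ", nrow(x$results),
    " categories tested with k >= 1 (", x$test, ", ", x$correction, ")\n",
    "  query: ", x$n_input, " ids, ", x$n_mapped, " mapped, ",
    length(x$dropped_ids), " dropped\n",
    sep = ""
  )
  if (nrow(x$results) > 0L) {
    print(utils::head(
      x$results[, c("category_id", "k", "K", "ratio", "p_value", "p_adjusted")],
      10L
    ))
  }
  invisible(x)
}

empty_results_tibble <- function() {
  tibble::tibble(
    category_id = character(), label = character(), group = character(),
    k = integer(), K = integer(), n = integer(), N = integer(),
    ratio = numeric(), p_value = numeric(), p_adjusted = numeric(),
    query_hits = list()
  )
}

#' Test a query protein list for category overrepresentation
#'
#' For each category of the background model, counts the overlap `k`
#' between the mapped query and the category's protein set and tests it
#' against the background frequency `K/N`. P-values are computed for every
#' model category (untested categories with `k = 0` included, so the
#' correction spans the full hypothesis family defined by the model) and
#' adjusted together; only categories with `k >= 1` appear in the report.
#' The enrichment ratio is `(k/n) / (K/N)`. Query ids absent from the
#' model's background are recorded as dropped.
#'
#' @param model An [enrichment_model()].
#' @param query Character vector of protein ids (duplicates collapsed).
#' @param test `"hypergeometric"` (one-sided, default) or `"chisquared"`
#'   (two-sided with Yates correction).
#' @param correction A method of [adjust_pvalues()]; default `"BH"`.
#' @param chisq_correct Yates correction for the chi-squared test.
#' @return An `enrichment_report`: `results` tibble (sorted by ascending
#'   `p_adjusted`, then `category_id`) plus mapping bookkeeping
#'   (`n_input`, `n_mapped`, `dropped_ids`).
#' @export
enrich <- function(model, query, test = c("hypergeometric", "chisquared"),
                   correction = "BH", chisq_correct = TRUE) {
  stopifnot(inherits(model, "enrichment_model"))
  test <- match.arg(test)
  correction <- match.arg(correction, P_ADJUST_METHODS)
  if (nrow(model$categories) == 0L) {
    stop("cannot run enrichment against an empty model", call. = FALSE)
  }
  query <- unique(trimws2(as.character(query)))
  query <- query[nzchar(query)]
  mapped <- intersect(query, model$background)
  dropped <- setdiff(query, model$background)
  n <- length(mapped)
  N <- model$background_size
  if (n == 0L) {
    warning("no query ids map to the model background; empty report",
      call. = FALSE
    )
    return(new_enrichment_report(
      empty_results_tibble(),
      n_input = length(query), n_mapped = 0L, dropped_ids = dropped,
      model_kind = model$model_kind, test = test, correction = correction
    ))
  }
  cats <- model$categories
  hits <- lapply(cats$proteins, function(p) intersect(mapped, p))
  k <- lengths(hits)
  K <- cats$count
  p <- switch(test,
    hypergeometric = hypergeometric_pvalue(k, K, n, N),
    chisquared = chisquared_pvalue(k, K, n, N, correct = chisq_correct)
  )
  p_adj <- adjust_pvalues(p, method = correction)
  ratio <- (k / n) / (K / N)
  keep <- k >= 1L
  k_keep <- as.integer(k[keep])
  K_keep <- as.integer(K[keep])
  ratio_keep <- ratio[keep]
  results <- tibble::tibble(
    category_id = cats$category_id[keep],
    label = cats$label[keep],
    group = cats$group[keep],
    k = k_keep,
    K = K_keep,
    n = as.integer(n),
    N = as.integer(N),
    ratio = ratio_keep,
    p_value = p[keep],
    p_adjusted = p_adj[keep],
    query_hits = lapply(hits[keep], sort_c)
  )
  results <- results[order(results$p_adjusted, results$category_id,
    method = "radix"
  ), , drop = FALSE]
  new_enrichment_report(
    results,
    n_input = length(query), n_mapped = n, dropped_ids = sort_c(dropped),
    model_kind = model$model_kind, test = test, correction = correction
  )
}

#' Reduce redundancy among enriched GO terms
#'
#' Keeps, from each group of significant GO terms sharing a common ancestor
#' within `depth_limit` upward hops ([group_terms_by_ancestor()]), only the
#' most significant representative: smallest adjusted p, ties broken by
#' smaller raw p, then lexicographic term id. Rows above `alpha` are
#' dropped. Adjusted p-values are not recomputed after reduction — they
#' retain the correction over the full model family.
#'
#' @param report An `enrichment_report` over GO categories of one namespace.
#' @param dag A [go_dag()].
#' @param depth_limit Non-negative integer passed to
#'   [group_terms_by_ancestor()]; 0 keeps every significant term.
#' @param alpha Significance threshold on `p_adjusted` (default 0.05).
#' @param relations Edge relations used for the ancestry queries.
#' @return A reduced `enrichment_report` with the same bookkeeping fields.
#' @export
reduce_go_redundancy <- function(report, dag, depth_limit, alpha = 0.05,
                                 relations = c("is_a", "part_of")) {
  stopifnot(inherits(report, "enrichment_report"))
  res <- report$results
  sig <- res[res$p_adjusted <= alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    report$results <- empty_results_tibble()
    return(report)
  }
  blocks <- group_terms_by_ancestor(dag, sig$category_id, depth_limit,
    relations = relations
  )
  keep_ids <- vapply(blocks, function(terms) {
    rows <- sig[sig$category_id %in% terms, , drop = FALSE]
    rows <- rows[order(rows$p_adjusted, rows$p_value, rows$category_id,
      method = "radix"
    ), , drop = FALSE]
    rows$category_id[[1L]]
  }, character(1))
  out <- sig[sig$category_id %in% keep_ids, , drop = FALSE]
  out <- out[order(out$p_adjusted, out$category_id, method = "radix"), ,
    drop = FALSE
  ]
  report$results <- out
  report
}

#' Write an enrichment report to a tab-separated file
#'
#' Writes one row per category with the test counts, ratio, and p-values
#' (`query_hits` comma-joined, sorted), plus a JSON sidecar
#' (`<path>.json`) with the mapping bookkeeping: `n_input`, `n_mapped`,
#' `n_dropped`, and the dropped ids.
#'
#' @param report An `enrichment_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  stopifnot(inherits(report, "enrichment_report"))
  res <- report$results
  header <- c(
    "category_id", "label", "group", "k", "K", "n", "N",
    "ratio", "p_value", "p_adjusted", "query_hits"
  )
  rows <- vapply(seq_len(nrow(res)), function(i) {
    paste(
      c(
        res$category_id[[i]], res$label[[i]],
        ifelse(is.na(res$group[[i]]), "", res$group[[i]]),
        res$k[[i]], res$K[[i]], res$n[[i]], res$N[[i]],
        formatC(res$ratio[[i]], digits = 6, format = "g"),
        formatC(res$p_value[[i]], digits = 6, format = "g"),
        formatC(res$p_adjusted[[i]], digits = 6, format = "g"),
        paste(res$query_hits[[i]], collapse = ",")
      ),
      collapse = "\t"
    )
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  jsonlite::write_json(
    list(
      model_kind = report$model_kind,
      test = report$test,
      correction = report$correction,
      n_input = report$n_input,
      n_mapped = report$n_mapped,
      n_dropped = length(report$dropped_ids),
      dropped_ids = report$dropped_ids
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read an enrichment report written by [write_enrichment_report()]
#'
#' @param path Path to the TSV written by [write_enrichment_report()]; the
#'   JSON sidecar `<path>.json` is read when present.
#' @return An `enrichment_report`.
#' @export
read_enrichment_report <- function(path) {
  tbl <- utils::read.delim(path,
    sep = "\t", header = TRUE, quote = "",
    comment.char = "", colClasses = "character", na.strings = character()
  )
  results <- tibble::tibble(
    category_id = tbl$category_id,
    label = tbl$label,
    group = ifelse(nzchar(tbl$group), tbl$group, NA_character_),
    k = as.integer(tbl$k),
    K = as.integer(tbl$K),
    n = as.integer(tbl$n),
    N = as.integer(tbl$N),
    ratio = as.numeric(tbl$ratio),
    p_value = as.numeric(tbl$p_value),
    p_adjusted = as.numeric(tbl$p_adjusted),
    query_hits = lapply(strsplit(tbl$query_hits, ",", fixed = TRUE), function(x) {
      x[nzchar(x)]
    })
  )
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  new_enrichment_report(
    results,
    n_input = meta$n_input %||% (if (nrow(results) > 0L) results$n[[1L]] else 0L),
    n_mapped = meta$n_mapped %||% (if (nrow(results) > 0L) results$n[[1L]] else 0L),
    dropped_ids = meta$dropped_ids %||% character(),
    model_kind = meta$model_kind %||% NA_character_,
    test = meta$test %||% "hypergeometric",
    correction = meta$correction %||% "BH"
  )
}
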