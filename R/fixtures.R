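# Seeded synthetic-annotation generator. Emits every dialect the parsers
# read — KOG/GO/KEGG tables, a toy OBO ontology, a KEGG orthology link file,
# an eggNOG-mapper table, a GTF, and a query id list — over one shared
# protein universe, with known ground truth about which categories were
# planted as enriched in the query. All randomness flows from the seed, and
# identical configurations produce byte-identical files, so the whole
# pipeline is testable offline.

#' Configure the synthetic-annotation generator
#'
#' @param seed Integer seed (mandatory); the single source of randomness.
#' @param n_proteins Size of the protein universe (default 1000).
#' @param n_kog_letters Number of KOG letter categories (default 10, drawn
#'   from the canonical table).
#' @param n_go_terms Terms per GO namespace in the toy ontology
#'   (default 30).
#' @param n_kegg_pathways Number of KEGG pathways (default 8).
#' @param annotation_density Probability that a protein carries a KOG
#'   annotation (default 0.8); GO and KEGG coverage scale from it.
#' @param planted Optional data frame (or list of lists) with columns
#'   `category_id`, `fold`, and optionally `query_fraction`: categories to
#'   overrepresent in the query at `fold` times their background rate
#'   (`fold = 1` plants nothing). Ids must exist among the generated
#'   categories; all planted ids must belong to one model.
#' @param query_size Number of query proteins to emit (default 50).
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed,
                           n_proteins = 1000,
                           n_kog_letters = 10,
                           n_go_terms = 30,
                           n_kegg_pathways = 8,
                           annotation_density = 0.8,
                           planted = NULL,
                           query_size = 50) {
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is mandatory", call. = FALSE)
  }
  if (annotation_density < 0 || annotation_density > 1) {
    stop("annotation_density must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(planted)) {
    if (is.data.frame(planted)) {
      planted <- tibble::as_tibble(planted)
    } else {
      planted <- dplyr::bind_rows(lapply(planted, tibble::as_tibble))
    }
    if (!all(c("category_id", "fold") %in% names(planted))) {
      stop("planted needs columns category_id and fold", call. = FALSE)
    }
    if (!"query_fraction" %in% names(planted)) {
      planted$query_fraction <- NA_real_
    }
    if (any(planted$fold < 1)) {
      stop("planted fold must be >= 1", call. = FALSE)
    }
    bad_qf <- !is.na(planted$query_fraction) &
      (planted$query_fraction < 0 | planted$query_fraction > 1)
    if (any(bad_qf)) {
      stop("planted query_fraction must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed),
      n_proteins = as.integer(n_proteins),
      n_kog_letters = as.integer(n_kog_letters),
      n_go_terms = as.integer(n_go_terms),
      n_kegg_pathways = as.integer(n_kegg_pathways),
      annotation_density = annotation_density,
      planted = planted,
      query_size = as.integer(query_size)
    ),
    class = "fixture_config"
  )
}

# Build the toy GO DAG: one namespace root, every later term wired to >= 1
# earlier term, so the graph is connected and acyclic by construction.
simulate_go_dag <- function(n_terms) {
  ns_prefix <- c(
    biological_process = 1L, molecular_function = 2L, cellular_component = 3L
  )
  terms <- list()
  edges <- list()
  for (ns in names(ns_prefix)) {
    ids <- sprintf("GO:%d%06d", ns_prefix[[ns]], seq_len(n_terms))
    terms[[ns]] <- tibble::tibble(
      term_id = ids,
      name = c(
        paste0(ns, " root"),
        sprintf("%s term %03d", sub("_.*", "", ns), seq_len(n_terms - 1L) + 1L)
      ),
      namespace = ns
    )
    child <- parent <- relation <- character(0)
    for (i in seq(2L, n_terms)) {
      parents <- unique(c(
        sample.int(i - 1L, 1L),
        if (i > 2L && stats::runif(1) < 0.25) sample.int(i - 1L, 1L)
      ))
      child <- c(child, rep(ids[[i]], length(parents)))
      parent <- c(parent, ids[parents])
      relation <- c(relation, ifelse(
        stats::runif(length(parents)) < 0.2, "part_of", "is_a"
      ))
    }
    edges[[ns]] <- tibble::tibble(
      child = child, parent = parent, relation = relation
    )
  }
  go_dag(dplyr::bind_rows(terms), dplyr::bind_rows(edges))
}

#' Simulate a consistent annotation universe in memory
#'
#' The engine behind [generate_fixture()]: draws KOG, GO, and KEGG
#' annotations over one protein universe, builds the corresponding
#' background models, and samples a query list with any planted categories
#' overrepresented at their requested fold. Exposed so simulation studies
#' (and tests) can skip file round-trips.
#'
#' @param config A [fixture_config()].
#' @return A list with the annotation record tibbles (`kog_records`,
#'   `go_records`, `kegg_records`, `ko_link`, `eggnog`), the toy `dag`, the
#'   built `models`, the `query` ids, and a `truth` tibble of planted
#'   categories with their realized counts (`k`, `K`, `n`, `N`).
#' @export
simulate_annotations <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  proteins <- sprintf("prot%05d", seq_len(n))
  density <- config$annotation_density

  # --- KOG ---------------------------------------------------------------
  letters_tbl <- utils::head(kog_letter_table(), config$n_kog_letters)
  kog_on <- stats::runif(n) < density
  primary <- sample(letters_tbl$letter, n, replace = TRUE)
  secondary_on <- kog_on & stats::runif(n) < 0.1
  kog_pairs <- tibble::tibble(
    protein_id = c(proteins[kog_on], proteins[secondary_on]),
    letter = c(primary[kog_on], vapply(which(secondary_on), function(i) {
      sample(setdiff(letters_tbl$letter, primary[[i]]), 1L)
    }, character(1)))
  )
  idx <- match(kog_pairs$letter, letters_tbl$letter)
  kog_records <- dedupe_records(new_annotation_records(
    protein_id = kog_pairs$protein_id,
    category_id = kog_pairs$letter,
    category_label = letters_tbl$name[idx],
    category_group = letters_tbl$class[idx],
    source = "kog"
  ))

  # --- GO ----------------------------------------------------------------
  dag <- simulate_go_dag(config$n_go_terms)
  ns_rate <- c(
    biological_process = 0.6, molecular_function = 0.4,
    cellular_component = 0.3
  ) * density
  go_parts <- lapply(names(ns_rate), function(ns) {
    pool <- dag$terms[dag$namespace[dag$terms] == ns]
    pool <- setdiff(pool, dag$roots[[ns]])
    on <- stats::runif(n) < ns_rate[[ns]]
    n_terms_per <- 1L + stats::rbinom(sum(on), 1L, 0.4)
    tibble::tibble(
      protein_id = rep(proteins[on], n_terms_per),
      term = unlist(lapply(n_terms_per, function(m) sample(pool, m)),
        use.names = FALSE
      )
    )
  })
  go_pairs <- dplyr::distinct(dplyr::bind_rows(go_parts))
  go_records <- new_annotation_records(
    protein_id = go_pairs$protein_id,
    category_id = go_pairs$term,
    category_label = unname(dag$name[go_pairs$term]),
    category_group = unname(dag$namespace[go_pairs$term]),
    source = "go"
  )

  # --- KEGG --------------------------------------------------------------
  npw <- config$n_kegg_pathways
  pathway_tbl <- tibble::tibble(
    pathway = sprintf("Pathway %02d", seq_len(npw)),
    class = sprintf(
      "Pathway class %d", 1L + (seq_len(npw) - 1L) %% max(2L, npw %/% 3L)
    ),
    type = ifelse(seq_len(npw) %% 2L == 1L, "Metabolism", "Cellular Processes"),
    ko = sprintf("K%05d", 1000L + seq_len(npw))
  )
  ec_tbl <- tibble::tibble(
    ec = sprintf("%d.%d.%d.%d", 1L + (seq_len(2L * npw) - 1L) %% 6L,
      1L + (seq_len(2L * npw) - 1L) %% 4L, 1L,
      seq_len(2L * npw)
    ),
    definition = sprintf("enzyme definition %02d", seq_len(2L * npw)),
    pathway_idx = rep(seq_len(npw), each = 2L)
  )
  kegg_on <- stats::runif(n) < density * 0.5
  ec_only <- !kegg_on & stats::runif(n) < 0.05
  rows_full <- tibble::tibble(
    protein_id = proteins[kegg_on],
    ec_idx = sample(nrow(ec_tbl), sum(kegg_on), replace = TRUE)
  )
  rows_full$pathway_idx <- ec_tbl$pathway_idx[rows_full$ec_idx]
  kegg_table <- tibble::tibble(
    protein_id = c(rows_full$protein_id, proteins[ec_only]),
    ecNum = c(
      ec_tbl$ec[rows_full$ec_idx],
      ec_tbl$ec[sample(nrow(ec_tbl), sum(ec_only), replace = TRUE)]
    ),
    pathway = c(pathway_tbl$pathway[rows_full$pathway_idx], rep("", sum(ec_only))),
    pathway_class = c(pathway_tbl$class[rows_full$pathway_idx], rep("", sum(ec_only))),
    pathway_type = c(pathway_tbl$type[rows_full$pathway_idx], rep("", sum(ec_only)))
  )
  kegg_table$definition <- ec_tbl$definition[match(kegg_table$ecNum, ec_tbl$ec)]
  kegg_table <- kegg_table[order(kegg_table$protein_id, kegg_table$ecNum,
    method = "radix"
  ), , drop = FALSE]
  kegg_records <- kegg_table_to_records(kegg_table)
  ko_link <- dplyr::distinct(tibble::tibble(
    gene_id = rows_full$protein_id,
    ko_id = pathway_tbl$ko[rows_full$pathway_idx]
  ))
  ko_link <- ko_link[order(ko_link$gene_id, ko_link$ko_id, method = "radix"), ,
    drop = FALSE
  ]

  # --- eggNOG view of the same universe ---------------------------------
  eggnog <- build_eggnog_view(
    proteins, kog_records, go_pairs, rows_full, pathway_tbl, ec_tbl
  )

  # --- models ------------------------------------------------------------
  models <- list(
    kog = create_kog_model(kog_records),
    go = suppressWarnings(create_go_model(go_records, dag)),
    kegg = create_kegg_models(kegg_records)
  )

  # --- query with planted enrichment ------------------------------------
  sampled <- sample_query(config, models)

  c(
    list(
      config = config,
      proteins = proteins,
      kog_records = kog_records,
      go_records = go_records,
      kegg_records = kegg_records,
      kegg_table = kegg_table,
      ko_link = ko_link,
      eggnog = eggnog,
      dag = dag,
      models = models
    ),
    sampled
  )
}

kegg_table_to_records <- function(kegg_table) {
  parts <- list(
    tibble::tibble(
      protein_id = kegg_table$protein_id, category_id = kegg_table$pathway_type,
      category_label = kegg_table$pathway_type, category_group = "pathway_type"
    ),
    tibble::tibble(
      protein_id = kegg_table$protein_id, category_id = kegg_table$pathway_class,
      category_label = kegg_table$pathway_class, category_group = "pathway_class"
    ),
    tibble::tibble(
      protein_id = kegg_table$protein_id, category_id = kegg_table$pathway,
      category_label = kegg_table$pathway, category_group = "pathway_name"
    ),
    tibble::tibble(
      protein_id = kegg_table$protein_id, category_id = kegg_table$ecNum,
      category_label = kegg_table$definition, category_group = "enzyme"
    )
  )
  recs <- dplyr::bind_rows(parts)
  recs <- recs[nzchar(recs$category_id), , drop = FALSE]
  recs$source <- "kegg"
  recs[!duplicated(recs[, c("protein_id", "category_id", "category_group")]), ,
    drop = FALSE
  ]
}

build_eggnog_view <- function(proteins, kog_records, go_pairs, rows_full,
                              pathway_tbl, ec_tbl) {
  cog <- split(kog_records$category_id, kog_records$protein_id)
  gos <- split(go_pairs$term, go_pairs$protein_id)
  kos <- split(pathway_tbl$ko[rows_full$pathway_idx], rows_full$protein_id)
  # eggNOG spells pathways as map/ko-prefixed 5-digit ids
  pw <- split(
    sprintf("map%05d", rows_full$pathway_idx), rows_full$protein_id
  )
  ecs <- split(ec_tbl$ec[rows_full$ec_idx], rows_full$protein_id)
  annotated <- proteins[proteins %in% c(names(cog), names(gos), names(kos))]
  pick <- function(split_list) {
    sets <- split_list[match(annotated, names(split_list))]
    unname(lapply(sets, function(v) sort_c(unique(v))))
  }
  tibble::tibble(
    query = annotated,
    cog_letters = pick(cog),
    go_ids = pick(gos),
    kegg_kos = pick(kos),
    kegg_pathways = pick(pw),
    ec_numbers = pick(ecs)
  )
}

# Locate each planted category in the generated models; all planted ids must
# live in one model. Returns NULL for an unplanted (null) configuration.
locate_target_model <- function(planted, models) {
  flat <- list(
    kog_letter = models$kog$letter,
    kog_class = models$kog$class,
    go_bp = models$go$bp,
    go_mf = models$go$mf,
    go_cc = models$go$cc,
    kegg_type = models$kegg$type,
    kegg_class = models$kegg$class,
    kegg_name = models$kegg$name,
    kegg_enzyme = models$kegg$enzyme
  )
  hits <- vapply(planted$category_id, function(id) {
    where <- names(flat)[vapply(flat, function(m) {
      id %in% m$categories$category_id
    }, logical(1))]
    if (length(where) == 0L) {
      stop("planted category '", id, "' is not among the generated categories",
        call. = FALSE
      )
    }
    where[[1L]]
  }, character(1))
  if (length(unique(hits)) > 1L) {
    stop("planted categories must all belong to one model; found: ",
      paste(unique(hits), collapse = ", "),
      call. = FALSE
    )
  }
  list(kind = hits[[1L]], model = flat[[hits[[1L]]]])
}

sample_query <- function(config, models) {
  planted <- config$planted
  target <- if (!is.null(planted) && nrow(planted) > 0L) {
    locate_target_model(planted, models)
  } else {
    list(kind = "kog_letter", model = models$kog$letter)
  }
  model <- target$model
  universe <- model$background
  N <- model$background_size
  q <- min(config$query_size, N)
  query <- character()
  if (!is.null(planted) && nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      cat_id <- planted$category_id[[i]]
      members <- model$categories$proteins[[
        match(cat_id, model$categories$category_id)
      ]]
      members <- setdiff(members, query)
      p_in <- planted$query_fraction[[i]]
      if (is.na(p_in)) {
        p_in <- min(0.95, planted$fold[[i]] * length(members) / N)
      }
      n_in <- min(stats::rbinom(1L, q - length(query), p_in), length(members))
      query <- c(query, sample(members, n_in))
    }
  }
  rest_pool <- setdiff(universe, unlist(
    if (is.null(planted)) list() else lapply(planted$category_id, function(id) {
      model$categories$proteins[[match(id, model$categories$category_id)]]
    })
  ))
  rest_pool <- setdiff(rest_pool, query)
  n_rest <- min(q - length(query), length(rest_pool))
  query <- sort_c(c(query, sample(rest_pool, n_rest)))
  truth <- if (is.null(planted) || nrow(planted) == 0L) {
    tibble::tibble(
      category_id = character(), fold = numeric(), enriched = logical(),
      k = integer(), K = integer(), n = integer(), N = integer()
    )
  } else {
    tibble::tibble(
      category_id = planted$category_id,
      fold = planted$fold,
      enriched = planted$fold > 1,
      k = vapply(planted$category_id, function(id) {
        length(intersect(
          query,
          model$categories$proteins[[match(id, model$categories$category_id)]]
        ))
      }, integer(1)),
      K = model$categories$count[match(planted$category_id, model$categories$category_id)],
      n = length(query),
      N = N
    )
  }
  list(query = query, truth = truth, target_model_kind = target$kind)
}

#' Generate a synthetic fixture directory
#'
#' Writes the simulated annotation universe of [simulate_annotations()] to
#' disk in every dialect the parsers read: a JGI-style KOG table, GO table
#' with matching toy OBO ontology, KEGG table, KEGG orthology link file,
#' eggNOG-mapper annotations table, GTF gene models, the query id list, and
#' a `truth.json` ground-truth summary. Identical configurations produce
#' byte-identical directory trees.
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [simulate_annotations()] result, extended with a `files`
#'   element naming every written path, invisibly.
#' @export
generate_fixture <- function(config, out_dir) {
  sim <- simulate_annotations(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    kog = file.path(out_dir, "kog_annotation.tsv"),
    go = file.path(out_dir, "go_annotation.tsv"),
    kegg = file.path(out_dir, "kegg_annotation.tsv"),
    ko_link = file.path(out_dir, "ko_link.tsv"),
    eggnog = file.path(out_dir, "proteome.emapper.annotations"),
    obo = file.path(out_dir, "ontology.obo"),
    gtf = file.path(out_dir, "gene_models.gtf"),
    query = file.path(out_dir, "query_ids.txt"),
    truth = file.path(out_dir, "truth.json")
  )

  kr <- sim$kog_records
  kr <- kr[order(kr$protein_id, kr$category_id, method = "radix"), ]
  writeLines(c(
    "#proteinId\tkogId\tkogDefline\tkogClass\tkogLetter",
    sprintf(
      "%s\tKOG%04d\t%s\t%s\t%s",
      kr$protein_id, match(kr$category_id, LETTERS),
      kr$category_label, kr$category_group, kr$category_id
    )
  ), paths$kog)

  gr <- sim$go_records
  gr <- gr[order(gr$protein_id, gr$category_id, method = "radix"), ]
  writeLines(c(
    "#proteinId\tgotermId\tgoName\tgotermType",
    sprintf(
      "%s\t%d\t%s\t%s",
      gr$protein_id, as.integer(sub("^GO:", "", gr$category_id)),
      gr$category_label, gr$category_group
    )
  ), paths$go)

  kt <- sim$kegg_table
  writeLines(c(
    "#proteinId\tecNum\tdefinition\tpathway\tpathway_class\tpathway_type",
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s",
      kt$protein_id, kt$ecNum, kt$definition, kt$pathway,
      kt$pathway_class, kt$pathway_type
    )
  ), paths$kegg)

  writeLines(
    sprintf("org:%s\tko:%s", sim$ko_link$gene_id, sim$ko_link$ko_id),
    paths$ko_link
  )

  eg <- sim$eggnog
  cell <- function(x) {
    vapply(x, function(v) if (length(v) == 0L) "-" else paste(v, collapse = ","),
      character(1)
    )
  }
  writeLines(c(
    "## generated by the fixture module",
    "#query\tCOG_category\tGOs\tEC\tKEGG_ko\tKEGG_Pathway",
    sprintf(
      "%s\t%s\t%s\t%s\t%s\t%s",
      eg$query,
      vapply(eg$cog_letters, function(v) {
        if (length(v) == 0L) "-" else paste(v, collapse = "")
      }, character(1)),
      cell(eg$go_ids),
      cell(eg$ec_numbers),
      cell(lapply(eg$kegg_kos, function(k) {
        if (length(k) == 0L) character() else paste0("ko:", k)
      })),
      cell(eg$kegg_pathways)
    )
  ), paths$eggnog)

  write_obo(sim$dag, paths$obo)

  idx <- seq_along(sim$proteins)
  writeLines(
    as.vector(rbind(
      sprintf(
        "chr1\tfixture\tgene\t%d\t%d\t.\t+\t.\tgene_id \"gene%05d\"; gene_name \"g%05d\";",
        idx * 1000L, idx * 1000L + 900L, idx, idx
      ),
      sprintf(
        paste0(
          "chr1\tfixture\ttranscript\t%d\t%d\t.\t+\t.\tgene_id \"gene%05d\"; ",
          "gene_name \"g%05d\"; transcript_id \"tx%05d\"; protein_id \"%s\";"
        ),
        idx * 1000L, idx * 1000L + 900L, idx, idx, idx, sim$proteins
      )
    )),
    paths$gtf
  )

  writeLines(sim$query, paths$query)

  jsonlite::write_json(
    list(
      seed = config$seed,
      n_proteins = config$n_proteins,
      query_size = config$query_size,
      target_model_kind = sim$target_model_kind,
      planted = sim$truth,
      query = sim$query,
      files = lapply(paths, basename)
    ),
    paths$truth,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  sim$files <- paths
  invisible(sim)
}
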