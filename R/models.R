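# Background frequency models: per-category protein sets plus the size of
# the annotated universe. Multi-category proteins are counted once in the
# background (the universe is a set union, never a sum of per-category
# counts), which keeps enrichment ratios honest when annotations overlap.

MODEL_KINDS <- c(
  "kog_letter", "kog_class", "go_bp", "go_mf", "go_cc",
  "kegg_type", "kegg_class", "kegg_name", "kegg_enzyme"
)

#' Construct an enrichment model
#'
#' Low-level constructor normally reached through [create_kog_model()],
#' [create_go_model()], [create_kegg_models()], or
#' [create_models_from_eggnog()]. Categories with empty protein sets are
#' dropped; `background_size` is the number of distinct proteins annotated
#' to at least one category.
#'
#' @param model_kind One of `kog_letter`, `kog_class`, `go_bp`, `go_mf`,
#'   `go_cc`, `kegg_type`, `kegg_class`, `kegg_name`, `kegg_enzyme`.
#' @param categories A data frame with columns `category_id`, `label`,
#'   `group`, and a list-column `proteins` of character vectors.
#' @return An object of class `enrichment_model` with elements `model_kind`,
#'   `categories` (tibble with a `count` column), `background` (character
#'   vector of annotated proteins), and `background_size`.
#' @export
enrichment_model <- function(model_kind, categories) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  categories <- tibble::as_tibble(categories)
  stopifnot(all(c("category_id", "label", "group", "proteins") %in% names(categories)))
  categories$proteins <- unname(lapply(categories$proteins, function(p) {
    sort_c(unique(as.character(p)))
  }))
  categories <- categories[lengths(categories$proteins) > 0L, , drop = FALSE]
  categories$label <- ifelse(
    is.na(categories$label) | !nzchar(categories$label),
    categories$category_id, categories$label
  )
  categories$count <- lengths(categories$proteins)
  categories <- categories[order(categories$category_id, method = "radix"), ,
    drop = FALSE
  ]
  background <- sort_c(unique(unlist(categories$proteins, use.names = FALSE)))
  structure(
    list(
      model_kind = model_kind,
      categories = categories[, c("category_id", "label", "group", "count", "proteins")],
      background = background,
      background_size = length(background)
    ),
    class = "enrichment_model"
  )
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat(
    "Enrichment model [", x$model_kind, "]: ",
    nrow(x$categories), " categories, background of ",
    x$background_size, " proteins\n",
    sep = ""
  )
  invisible(x)
}

records_to_categories <- function(records, id_col = "category_id",
                                  label_col = "category_label",
                                  group_col = "category_group") {
  split_idx <- split(seq_len(nrow(records)), records[[id_col]])
  tibble::tibble(
    category_id = names(split_idx),
    label = unname(vapply(split_idx, function(i) {
      records[[label_col]][i[[1L]]]
    }, character(1))),
    group = unname(vapply(split_idx, function(i) {
      records[[group_col]][i[[1L]]]
    }, character(1))),
    proteins = unname(lapply(split_idx, function(i) {
      unique(records$protein_id[i])
    }))
  )
}

#' Build KOG background models
#'
#' Builds the two KOG-level models from parsed KOG annotation records: one
#' keyed by single-letter KOG category and one keyed by KOG class, the class
#' protein sets being the union over the letters belonging to each class.
#' Both models share one background universe, and a protein assigned to
#' several letters of one class is counted once in that class.
#'
#' @param records Annotation records with `source = "kog"` (from
#'   [parse_kog_annotation()] or the fixture generator).
#' @return A list with elements `letter` and `class`, each an
#'   [enrichment_model()].
#' @export
create_kog_model <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    stop("cannot build a KOG model from zero annotation records", call. = FALSE)
  }
  if (!all(records$source == "kog")) {
    stop("records must have source = 'kog'", call. = FALSE)
  }
  letter <- enrichment_model("kog_letter", records_to_categories(records))
  class_cats <- records_to_categories(
    records,
    id_col = "category_group", label_col = "category_group"
  )
  class_cats$group <- NA_character_
  class_cats <- class_cats[nzchar(class_cats$category_id), , drop = FALSE]
  class <- enrichment_model("kog_class", class_cats)
  list(letter = letter, class = class)
}

#' Build GO background models
#'
#' Propagates GO annotation records up the ontology (true-path rule) and
#' splits them into one model per namespace: biological process, molecular
#' function, cellular component. Each namespace's background counts the
#' distinct proteins carrying at least one term in that namespace; an empty
#' namespace yields an empty model.
#'
#' @param records GO annotation records (from [parse_go_annotation()] or
#'   eggNOG-derived).
#' @param dag A [go_dag()].
#' @param relations Edge relations used for propagation.
#' @return A list with elements `bp`, `mf`, `cc`, each an
#'   [enrichment_model()].
#' @export
create_go_model <- function(records, dag, relations = c("is_a", "part_of")) {
  records <- propagate_annotations(dag, records, relations = relations)
  kinds <- c(
    biological_process = "go_bp",
    molecular_function = "go_mf",
    cellular_component = "go_cc"
  )
  out <- lapply(names(kinds), function(ns) {
    sub <- records[records$category_group %in% ns, , drop = FALSE]
    enrichment_model(kinds[[ns]], records_to_categories(sub))
  })
  names(out) <- c("bp", "mf", "cc")
  out
}

#' Build KEGG background models
#'
#' Builds one model per KEGG aggregation axis — pathway type, pathway class,
#' pathway name, and enzyme definition — from parsed KEGG annotation
#' records. Each axis has its own background universe (the proteins with a
#' non-empty value on that axis), so the enzyme model can cover proteins the
#' pathway models do not: the EC fallback for genes absent from the KEGG
#' pathway mapping.
#'
#' @param records Annotation records with `source = "kegg"`.
#' @return A list with elements `type`, `class`, `name`, `enzyme`, each an
#'   [enrichment_model()].
#' @export
create_kegg_models <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0L && !all(records$source == "kegg")) {
    stop("records must have source = 'kegg'", call. = FALSE)
  }
  axes <- c(
    pathway_type = "kegg_type", pathway_class = "kegg_class",
    pathway_name = "kegg_name", enzyme = "kegg_enzyme"
  )
  out <- lapply(names(axes), function(axis) {
    sub <- records[records$category_group %in% axis, , drop = FALSE]
    cats <- records_to_categories(sub)
    cats$group <- NA_character_
    enrichment_model(axes[[axis]], cats)
  })
  names(out) <- c("type", "class", "name", "enzyme")
  out
}

# Normalize an eggNOG KEGG_Pathway id: both "ko00010" and "map00010" name the
# same pathway; key on the 5-digit number with a "map" label.
normalize_kegg_pathway_id <- function(x) {
  digits <- sub("^(ko|map)", "", x)
  ifelse(grepl("^\\d{5}$", digits), paste0("map", digits), x)
}

#' Build all background models from eggNOG-mapper annotations
#'
#' Turns parsed eggNOG-mapper records into the full model bundle: KOG
#' letter/class models from `COG_category` letters (classes via the built-in
#' letter table, overridable), GO models from the `GOs` column (propagated
#' through the supplied ontology), and a KEGG pathway-name model from
#' `KEGG_Pathway` ids, optionally expanded from KOs through a KO-to-pathway
#' map. `ko`- and `map`-prefixed pathway ids are unified on the 5-digit
#' pathway number.
#'
#' @param records A tibble from [parse_eggnog_annotation()].
#' @param dag A [go_dag()] for GO propagation.
#' @param ko_pathway_map Optional named list mapping KO ids (`KNNNNN`) to
#'   character vectors of pathway ids, used to supplement `KEGG_Pathway`.
#' @param letter_table Letter-to-class table; defaults to
#'   [kog_letter_table()].
#' @return A list with elements `kog` (list `letter`, `class`), `go` (list
#'   `bp`, `mf`, `cc`), and `kegg` (list with element `name`).
#' @export
create_models_from_eggnog <- function(records, dag, ko_pathway_map = NULL,
                                      letter_table = kog_letter_table()) {
  records <- tibble::as_tibble(records)
  kog_records <- tibble::tibble(
    protein_id = rep(records$query, lengths(records$cog_letters)),
    category_id = unlist(records$cog_letters, use.names = FALSE)
  )
  idx <- match(kog_records$category_id, letter_table$letter)
  kog_records <- new_annotation_records(
    protein_id = kog_records$protein_id,
    category_id = kog_records$category_id,
    category_label = ifelse(is.na(idx), kog_records$category_id, letter_table$name[idx]),
    category_group = ifelse(is.na(idx), "Unassigned", letter_table$class[idx]),
    source = "kog"
  )
  kog_records <- dedupe_records(kog_records)

  go_records <- new_annotation_records(
    protein_id = rep(records$query, lengths(records$go_ids)),
    category_id = unlist(records$go_ids, use.names = FALSE),
    category_label = "",
    category_group = "",
    source = "go"
  )
  go_records <- dedupe_records(go_records)

  pathway_sets <- records$kegg_pathways
  if (!is.null(ko_pathway_map)) {
    extra <- lapply(records$kegg_kos, function(kos) {
      unlist(ko_pathway_map[intersect(kos, names(ko_pathway_map))], use.names = FALSE)
    })
    pathway_sets <- Map(function(a, b) unique(c(a, b)), pathway_sets, extra)
  }
  pathway_sets <- lapply(pathway_sets, function(p) {
    unique(normalize_kegg_pathway_id(p))
  })
  kegg_records <- new_annotation_records(
    protein_id = rep(records$query, lengths(pathway_sets)),
    category_id = unlist(pathway_sets, use.names = FALSE),
    category_label = unlist(pathway_sets, use.names = FALSE),
    category_group = "pathway_name",
    source = "kegg"
  )
  kegg_records <- dedupe_records(kegg_records)

  empty <- c(
    if (nrow(kog_records) == 0L) "KOG",
    if (nrow(go_records) == 0L) "GO",
    if (nrow(kegg_records) == 0L) "KEGG"
  )
  if (length(empty) == 3L) {
    stop(
      "eggNOG records carry no usable annotations; empty models: ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  list(
    kog = if (nrow(kog_records) > 0L) create_kog_model(kog_records) else NULL,
    go = create_go_model(go_records, dag),
    kegg = list(name = create_kegg_models(kegg_records)$name)
  )
}

#' Write an enrichment model to a tab-separated file
#'
#' Serializes a model as one row per category (`category_id`, `label`,
#' `group`, `count`, comma-joined sorted protein ids) under a
#' `#model_kind=` header comment. [read_enrichment_model()] restores it
#' exactly, so precomputed species models can be shipped as plain text.
#'
#' @param model An [enrichment_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_model <- function(model, path) {
  stopifnot(inherits(model, "enrichment_model"))
  cats <- model$categories
  lines <- c(
    paste0("#model_kind=", model$model_kind),
    paste(c("category_id", "label", "group", "count", "proteins"), collapse = "\t"),
    vapply(seq_len(nrow(cats)), function(i) {
      paste(
        c(
          cats$category_id[[i]], cats$label[[i]],
          ifelse(is.na(cats$group[[i]]), "", cats$group[[i]]),
          cats$count[[i]],
          paste(cats$proteins[[i]], collapse = ",")
        ),
        collapse = "\t"
      )
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an enrichment model written by [write_enrichment_model()]
#'
#' @param path Path to a serialized model.
#' @return An [enrichment_model()].
#' @export
read_enrichment_model <- function(path) {
  lines <- read_input_lines(path)
  kind_line <- grep("^#model_kind=", lines, value = TRUE)
  if (length(kind_line) != 1L) {
    stop("not a serialized enrichment model (missing #model_kind= line): ", path,
      call. = FALSE
    )
  }
  kind <- sub("^#model_kind=", "", kind_line)
  body <- lines[!startsWith(lines, "#")]
  tbl <- utils::read.delim(
    text = paste(body, collapse = "\n"),
    sep = "\t", header = TRUE, quote = "", comment.char = "",
    colClasses = "character", na.strings = character()
  )
  enrichment_model(kind, tibble::tibble(
    category_id = tbl$category_id,
    label = tbl$label,
    group = ifelse(nzchar(tbl$group), tbl$group, NA_character_),
    proteins = strsplit(tbl$proteins, ",", fixed = TRUE)
  ))
}
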