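# Parsers for the annotation file dialects the package consumes: JGI-style
# KOG/GO/KEGG exports, KEGG orthology link files, and eggNOG-mapper output.
# Every parser returns neutral annotation records: a tibble with columns
# protein_id, category_id, category_label, category_group, source. Default
# column roles follow the JGI MycoCosm export dialects; a `column_map`
# argument (role -> column name) adapts any parser to unfamiliar headers.

#' Parse a KOG annotation table
#'
#' Reads a tab-separated KOG annotation export (JGI MycoCosm dialect by
#' default) into annotation records keyed by KOG letter. The KOG class read
#' from the file is carried in `category_group`; labels come from the
#' canonical letter table ([kog_letter_table()]), falling back to the class
#' string for non-standard letters.
#'
#' @param path Path to a tab-separated file (plain or gzip); lines starting
#'   with `#` are treated as comments, except a leading `#header` line.
#' @param column_map Optional named list/vector overriding default column
#'   names for the roles `protein_id`, `kog_id`, `definition`, `class`,
#'   `letter`. Defaults: `proteinId`, `kogId`, `kogDefline`, `kogClass`,
#'   `kogLetter`.
#' @return A tibble of annotation records with `source = "kog"`, one row per
#'   distinct (protein, letter) pair.
#' @export
parse_kog_annotation <- function(path, column_map = NULL) {
  tbl <- read_tsv_dialect(path)
  if (is.null(tbl) || nrow(tbl) == 0L) {
    warning("no KOG annotation rows found in ", path, call. = FALSE)
    return(new_annotation_records())
  }
  map <- resolve_columns(
    tbl,
    defaults = c(
      protein_id = "proteinId", kog_id = "kogId", definition = "kogDefline",
      class = "kogClass", letter = "kogLetter"
    ),
    column_map = column_map,
    optional = c("kog_id", "definition")
  )
  protein <- col_or_empty(tbl, map[["protein_id"]])
  letter <- col_or_empty(tbl, map[["letter"]])
  class <- col_or_empty(tbl, map[["class"]])
  keep <- nzchar(protein) & nzchar(letter)
  letters_tbl <- kog_letter_table()
  label <- letters_tbl$name[match(letter, letters_tbl$letter)]
  label <- ifelse(is.na(label), class, label)
  recs <- new_annotation_records(
    protein_id = protein[keep],
    category_id = letter[keep],
    category_label = ifelse(nzchar(label[keep]), label[keep], letter[keep]),
    category_group = class[keep],
    source = "kog"
  )
  dedupe_records(recs)
}

#' Parse a GO annotation table
#'
#' Reads a tab-separated GO annotation export (JGI MycoCosm dialect by
#' default). Numeric GO ids are normalized to zero-padded `GO:NNNNNNN`
#' accessions and the term type is normalized to the three OBO namespace
#' strings, carried in `category_group`. Rows whose accession cannot be
#' parsed are skipped with a warning; the number of skipped rows is attached
#' as the `"skipped"` attribute of the result.
#'
#' @inheritParams parse_kog_annotation
#' @param column_map Optional override for the roles `protein_id`, `term_id`,
#'   `name`, `term_type`. Defaults: `proteinId`, `gotermId`, `goName`,
#'   `gotermType`.
#' @return A tibble of annotation records with `source = "go"` and attribute
#'   `skipped` (count of rows dropped for malformed accessions).
#' @export
parse_go_annotation <- function(path, column_map = NULL) {
  tbl <- read_tsv_dialect(path)
  if (is.null(tbl) || nrow(tbl) == 0L) {
    warning("no GO annotation rows found in ", path, call. = FALSE)
    out <- new_annotation_records()
    attr(out, "skipped") <- 0L
    return(out)
  }
  map <- resolve_columns(
    tbl,
    defaults = c(
      protein_id = "proteinId", term_id = "gotermId",
      name = "goName", term_type = "gotermType"
    ),
    column_map = column_map,
    optional = "name"
  )
  protein <- col_or_empty(tbl, map[["protein_id"]])
  acc <- normalize_go_id(col_or_empty(tbl, map[["term_id"]]))
  ns <- normalize_namespace(col_or_empty(tbl, map[["term_type"]]))
  name <- col_or_empty(tbl, map[["name"]])
  keep <- nzchar(protein) & !is.na(acc)
  n_skipped <- sum(nzchar(protein) & is.na(acc))
  if (n_skipped > 0L) {
    warning(n_skipped, " row(s) with unparseable GO accession skipped in ", path,
      call. = FALSE
    )
  }
  recs <- new_annotation_records(
    protein_id = protein[keep],
    category_id = acc[keep],
    category_label = ifelse(nzchar(name[keep]), name[keep], acc[keep]),
    category_group = ns[keep],
    source = "go"
  )
  recs <- dedupe_records(recs)
  attr(recs, "skipped") <- n_skipped
  recs
}

# The four KEGG aggregation axes and the roles feeding them.
KEGG_AXES <- c("pathway_type", "pathway_class", "pathway_name", "enzyme")

#' Parse a KEGG annotation table
#'
#' Reads a tab-separated KEGG annotation export (JGI MycoCosm dialect by
#' default). Each row yields up to four records for the same protein, one per
#' aggregation axis — pathway type, pathway class, pathway name, and enzyme
#' definition — with `category_group` recording the axis name. Rows carrying
#' an EC number but no pathway still yield the enzyme-definition record, so
#' enzyme-level models can cover proteins the pathway models do not.
#'
#' @inheritParams parse_kog_annotation
#' @param column_map Optional override for the roles `protein_id`, `ec`,
#'   `definition`, `pathway`, `pathway_class`, `pathway_type`. Defaults:
#'   `proteinId`, `ecNum`, `definition`, `pathway`, `pathway_class`,
#'   `pathway_type`.
#' @return A tibble of annotation records with `source = "kegg"`;
#'   `category_group` is one of `"pathway_type"`, `"pathway_class"`,
#'   `"pathway_name"`, `"enzyme"`.
#' @export
parse_kegg_annotation <- function(path, column_map = NULL) {
  tbl <- read_tsv_dialect(path)
  if (is.null(tbl) || nrow(tbl) == 0L) {
    warning("no KEGG annotation rows found in ", path, call. = FALSE)
    return(new_annotation_records())
  }
  map <- resolve_columns(
    tbl,
    defaults = c(
      protein_id = "proteinId", ec = "ecNum", definition = "definition",
      pathway = "pathway", pathway_class = "pathway_class",
      pathway_type = "pathway_type"
    ),
    column_map = column_map,
    optional = character()
  )
  protein <- col_or_empty(tbl, map[["protein_id"]])
  axis_values <- list(
    pathway_type = col_or_empty(tbl, map[["pathway_type"]]),
    pathway_class = col_or_empty(tbl, map[["pathway_class"]]),
    pathway_name = col_or_empty(tbl, map[["pathway"]]),
    enzyme = col_or_empty(tbl, map[["ec"]])
  )
  definition <- col_or_empty(tbl, map[["definition"]])
  parts <- lapply(KEGG_AXES, function(axis) {
    value <- axis_values[[axis]]
    keep <- nzchar(protein) & nzchar(value)
    label <- if (axis == "enzyme") {
      ifelse(nzchar(definition), definition, value)
    } else {
      value
    }
    new_annotation_records(
      protein_id = protein[keep],
      category_id = value[keep],
      category_label = label[keep],
      category_group = axis,
      source = "kegg"
    )
  })
  recs <- dplyr::bind_rows(parts)
  # (protein, category) pairs are unique within an axis; ids may repeat
  # across axes (group disambiguates), so dedupe on the triple.
  recs[!duplicated(recs[, c("protein_id", "category_id", "category_group")]), ,
    drop = FALSE
  ]
}

#' Parse a KEGG orthology link file
#'
#' Reads a two-column tab-separated gene-to-KO mapping as served by the KEGG
#' REST `link` endpoint. Database prefixes up to and including the first
#' `:` (`tre:`, `ko:`) are stripped from both columns; duplicate pairs are
#' collapsed and lines without a tab are skipped with a warning.
#'
#' @inheritParams parse_kog_annotation
#' @return A tibble with columns `gene_id` and `ko_id`, distinct pairs only.
#' @export
parse_ko_link <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws2(lines))]
  lines <- lines[!startsWith(lines, "#")]
  has_tab <- grepl("\t", lines, fixed = TRUE)
  if (any(!has_tab)) {
    warning(sum(!has_tab), " line(s) without a tab skipped in ", path,
      call. = FALSE
    )
  }
  fields <- strsplit(lines[has_tab], "\t", fixed = TRUE)
  strip <- function(x) sub("^[^:]*:", "", trimws2(x))
  out <- tibble::tibble(
    gene_id = vapply(fields, function(f) strip(f[[1L]]), character(1)),
    ko_id = vapply(fields, function(f) strip(f[[2L]]), character(1))
  )
  out <- out[nzchar(out$gene_id) & nzchar(out$ko_id), , drop = FALSE]
  dplyr::distinct(out)
}

#' Parse an eggNOG-mapper annotations file
#'
#' Reads an eggNOG-mapper v2 `.emapper.annotations` table. `##` lines are
#' comments and the header line starts with `#query`. The `-` sentinel for a
#' missing value yields an empty set; `COG_category` cells are exploded into
#' single letters; `ko:` prefixes are stripped from `KEGG_ko` entries; `GOs`,
#' `KEGG_Pathway`, and `EC` cells split on commas.
#'
#' @inheritParams parse_kog_annotation
#' @return A tibble with one row per query and list-columns `cog_letters`,
#'   `go_ids`, `kegg_kos`, `kegg_pathways`, `ec_numbers`.
#' @export
parse_eggnog_annotation <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws2(lines))]
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#query")) {
    stop(
      "not an eggNOG-mapper annotations file (no '#query' header line): ",
      path,
      call. = FALSE
    )
  }
  lines[[1L]] <- sub("^#", "", lines[[1L]])
  tbl <- utils::read.delim(
    text = paste(lines, collapse = "\n"),
    sep = "\t", header = TRUE, quote = "", comment.char = "",
    colClasses = "character", check.names = FALSE, na.strings = character()
  )
  required <- c("query", "COG_category", "GOs", "KEGG_ko", "KEGG_Pathway", "EC")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L) {
    stop("eggNOG-mapper file is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  split_cell <- function(x) {
    x <- trimws2(x)
    if (!nzchar(x) || x == "-") {
      return(character())
    }
    parts <- trimws2(strsplit(x, ",", fixed = TRUE)[[1L]])
    unique(parts[nzchar(parts) & parts != "-"])
  }
  explode_cog <- function(x) {
    x <- trimws2(x)
    if (!nzchar(x) || x == "-") {
      return(character())
    }
    letters_only <- strsplit(gsub("[^A-Z]", "", x), "")[[1L]]
    unique(letters_only)
  }
  tibble::tibble(
    query = trimws2(tbl$query),
    cog_letters = lapply(tbl$COG_category, explode_cog),
    go_ids = lapply(tbl$GOs, split_cell),
    kegg_kos = lapply(tbl$KEGG_ko, function(x) {
      kos <- sub("^ko:", "", split_cell(x))
      unique(kos[grepl("^K\\d{5}$", kos)])
    }),
    kegg_pathways = lapply(tbl$KEGG_Pathway, split_cell),
    ec_numbers = lapply(tbl$EC, split_cell)
  )
}
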