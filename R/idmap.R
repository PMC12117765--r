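# Identifier mapping: build a gene-name / transcript-id / protein-id
# conversion table from GTF or GFF3 gene models and translate id lists
# between the three namespaces. Identifiers are compared as exact strings
# after trimming (no fuzzy matching), matching the convention that query
# ids must match the gene models used to build the annotation.

ID_ROLES <- c("gene_name", "transcript_id", "protein_id")

#' Build an identifier conversion table from gene models
#'
#' Parses a GTF or GFF3 file (via [rtracklayer::readGFF()]) into one row per
#' transcript linking gene name, transcript id, and protein id. For GTF the
#' default attribute keys are `gene_name` (falling back to `gene_id`),
#' `transcript_id`, and `protein_id`; for GFF3 the gene `Name` (falling back
#' to `ID`), the mRNA/transcript `ID` with its `Parent` chain, and the
#' `proteinId` attribute (the JGI convention), looked up on the transcript
#' first and then on its CDS children. `attribute_map` overrides any of the
#' keys `gene_name`, `gene_id`, `transcript_id`, `protein_id`.
#'
#' @param path Path to a GTF or GFF3 file (plain or gzip).
#' @param dialect `"auto"` (default; sniffs `=`-separated attributes),
#'   `"gtf"`, or `"gff3"`.
#' @param attribute_map Optional named list overriding attribute keys.
#' @return An object of class `id_conversion_table`: a tibble with columns
#'   `gene_name`, `transcript_id`, `protein_id` (`NA` where absent).
#' @export
build_conversion_table <- function(path, dialect = c("auto", "gtf", "gff3"),
                                   attribute_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- sniff_gene_model_dialect(path)
  }
  # readGFF sniffs the container format itself; `dialect` only decides which
  # attribute keys we look for
  feats <- as.data.frame(rtracklayer::readGFF(path))
  attr_key <- function(role, default) {
    (attribute_map[[role]] %||% default)
  }
  get_col <- function(key) {
    if (key %in% names(feats)) {
      v <- feats[[key]]
      if (is.list(v)) {
        v <- vapply(v, function(x) {
          if (length(x) == 0L) NA_character_ else as.character(x[[1L]])
        }, character(1))
      }
      as.character(v)
    } else {
      rep(NA_character_, nrow(feats))
    }
  }
  type <- as.character(feats$type)
  is_tx <- type %in% c("transcript", "mRNA")
  if (dialect == "gtf") {
    tx_id <- get_col(attr_key("transcript_id", "transcript_id"))
    gene_name <- get_col(attr_key("gene_name", "gene_name"))
    gene_id <- get_col(attr_key("gene_id", "gene_id"))
    protein <- get_col(attr_key("protein_id", "protein_id"))
    gene <- ifelse(is.na(gene_name) | !nzchar(gene_name), gene_id, gene_name)
    rows <- tibble::tibble(
      gene_name = gene[is_tx],
      transcript_id = tx_id[is_tx],
      protein_id = protein[is_tx]
    )
    # a transcript's protein_id may live on its CDS lines only
    need <- is.na(rows$protein_id)
    if (any(need)) {
      cds <- type == "CDS" & !is.na(protein)
      cds_map <- protein[cds]
      names(cds_map) <- tx_id[cds]
      rows$protein_id[need] <- unname(cds_map[rows$transcript_id[need]])
    }
  } else {
    id <- get_col("ID")
    name <- get_col("Name")
    parent <- get_col("Parent")
    protein <- get_col(attr_key("protein_id", "proteinId"))
    is_gene <- type == "gene"
    gene_label <- ifelse(is.na(name) | !nzchar(name), id, name)
    gene_lookup <- stats::setNames(gene_label[is_gene], id[is_gene])
    rows <- tibble::tibble(
      gene_name = unname(gene_lookup[parent[is_tx]]),
      transcript_id = id[is_tx],
      protein_id = protein[is_tx]
    )
    # missing gene feature: fall back to the Parent id itself
    rows$gene_name[is.na(rows$gene_name)] <- parent[is_tx][is.na(rows$gene_name)]
    need <- is.na(rows$protein_id)
    if (any(need)) {
      cds <- type == "CDS" & !is.na(protein)
      cds_map <- protein[cds]
      names(cds_map) <- parent[cds]
      rows$protein_id[need] <- unname(cds_map[rows$transcript_id[need]])
    }
  }
  rows[rows == ""] <- NA
  rows <- rows[rowSums(!is.na(rows)) > 0L, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(
      "no transcript features with recognizable attributes found in ", path,
      call. = FALSE
    )
  }
  rows <- rows[!duplicated(rows[, c("transcript_id", "protein_id")]), ,
    drop = FALSE
  ]
  rows <- rows[order(rows$transcript_id, rows$protein_id, method = "radix"), ,
    drop = FALSE
  ]
  structure(rows, class = c("id_conversion_table", class(rows)))
}

sniff_gene_model_dialect <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("no feature lines found in ", path, call. = FALSE)
  }
  fields <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(fields) < 9L) {
    stop("not a 9-column GTF/GFF file: ", path, call. = FALSE)
  }
  if (grepl("^[A-Za-z_]+=", fields[[9L]]) || grepl(";[A-Za-z_]+=", fields[[9L]])) {
    "gff3"
  } else {
    "gtf"
  }
}

#' Convert identifiers between gene-model namespaces
#'
#' Translates ids between `gene_name`, `transcript_id`, and `protein_id`
#' through a conversion table. Order-preserving: one-to-many mappings (a
#' gene with several protein isoforms) expand in place; ids with no mapping
#' are returned in `unmapped`.
#'
#' @param ids Character vector to convert.
#' @param table An [build_conversion_table()] result.
#' @param from,to Source and destination roles (distinct), each one of
#'   `"gene_name"`, `"transcript_id"`, `"protein_id"`.
#' @return A list with `converted` (expanded, in input order) and
#'   `unmapped` (input ids with no destination value).
#' @export
convert_ids <- function(ids, table, from, to) {
  from <- match.arg(from, ID_ROLES)
  to <- match.arg(to, ID_ROLES)
  if (from == to) {
    stop("'from' and 'to' roles must differ", call. = FALSE)
  }
  ids <- trimws2(as.character(ids))
  src <- table[[from]]
  dst <- table[[to]]
  converted <- character()
  unmapped <- character()
  for (id in ids) {
    hit <- !is.na(src) & src == id & !is.na(dst)
    vals <- unique(dst[hit])
    if (length(vals) == 0L) {
      unmapped <- c(unmapped, id)
    } else {
      converted <- c(converted, vals)
    }
  }
  list(converted = converted, unmapped = unmapped)
}

#' Rewrite identifiers with a regular expression
#'
#' Convenience for aligning eggNOG-mapper query ids with upstream gene-model
#' ids when FASTA headers differ from annotation ids (e.g. stripping a
#' `jgi|Trire2|` prefix): applies `sub(pattern, replacement, ids)`.
#'
#' @param ids Character vector.
#' @param pattern,replacement Passed to [sub()].
#' @return The rewritten ids.
#' @export
rewrite_ids <- function(ids, pattern, replacement) {
  sub(pattern, replacement, as.character(ids))
}

#' Write a conversion table as three-column TSV
#'
#' @param table An `id_conversion_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conversion_table <- function(table, path) {
  df <- as.data.frame(table)
  df[is.na(df)] <- ""
  lines <- c(
    paste(ID_ROLES, collapse = "\t"),
    vapply(seq_len(nrow(df)), function(i) {
      paste(df[i, ID_ROLES], collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
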