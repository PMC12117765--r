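# Internal helpers shared across parsers and writers.

#' @importFrom rlang %||%
NULL

# Open a text connection; gzip is detected by the ".gz" suffix.
open_input <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else file(path, open = "rt")
}

read_input_lines <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

trimws2 <- function(x) trimws(x, which = "both")

# Read a tab-separated table with a header line. Comment lines starting with
# "#" are skipped, except that a first line of the form "#col1\tcol2..." is
# treated as the header with its "#" stripped (the JGI export convention).
read_tsv_dialect <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws2(lines))]
  if (length(lines) == 0L) {
    return(NULL)
  }
  if (startsWith(lines[[1L]], "#")) {
    lines[[1L]] <- sub("^#+\\s*", "", lines[[1L]])
  }
  keep <- c(TRUE, !startsWith(lines[-1L], "#"))
  lines <- lines[keep]
  utils::read.delim(
    text = paste(lines, collapse = "\n"),
    sep = "\t", header = TRUE, quote = "", comment.char = "",
    colClasses = "character", check.names = FALSE,
    na.strings = character()
  )
}

# Resolve a role -> column-name map against the columns actually present.
# `defaults` is a named character vector role -> default column name;
# `column_map` overrides individual roles. Missing required columns raise a
# configuration error naming the column; optional roles resolve to NA.
resolve_columns <- function(tbl, defaults, column_map = NULL,
                            optional = character()) {
  map <- defaults
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(defaults))
    if (length(bad) > 0L) {
      stop("unknown column role(s) in column_map: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    map[names(column_map)] <- unlist(column_map)
  }
  for (role in names(map)) {
    if (!map[[role]] %in% names(tbl)) {
      if (role %in% optional) {
        map[[role]] <- NA_character_
      } else {
        stop(
          "required column '", map[[role]], "' (role: ", role,
          ") not found; available columns: ", paste(names(tbl), collapse = ", "),
          call. = FALSE
        )
      }
    }
  }
  map
}

col_or_empty <- function(tbl, colname) {
  if (is.na(colname)) rep("", nrow(tbl)) else trimws2(tbl[[colname]])
}

# Locale-independent sort used everywhere a stable byte-level output matters.
sort_c <- function(x) {
  if (is.null(x)) {
    return(character(0))
  }
  sort(x, method = "radix")
}

new_annotation_records <- function(protein_id = character(),
                                   category_id = character(),
                                   category_label = character(),
                                   category_group = character(),
                                   source = character()) {
  tibble::tibble(
    protein_id = as.character(protein_id),
    category_id = as.character(category_id),
    category_label = as.character(category_label),
    category_group = as.character(category_group),
    source = as.character(source)
  )
}

# Collapse duplicate (protein, category) pairs, keeping the first occurrence.
dedupe_records <- function(records) {
  records[!duplicated(records[, c("protein_id", "category_id")]), , drop = FALSE]
}

# Normalize a GO id: accepts "GO:NNNNNNN" or a bare integer; returns NA for
# anything else.
normalize_go_id <- function(x) {
  x <- trimws2(x)
  out <- rep(NA_character_, length(x))
  ok <- grepl("^GO:\\d{7}$", x)
  out[ok] <- x[ok]
  num <- grepl("^\\d{1,7}$", x)
  out[num] <- sprintf("GO:%07d", as.integer(x[num]))
  out
}

GO_NAMESPACES <- c("biological_process", "molecular_function", "cellular_component")

normalize_namespace <- function(x) {
  y <- gsub("[ -]+", "_", tolower(trimws2(x)))
  y[!y %in% GO_NAMESPACES] <- NA_character_
  y
}
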