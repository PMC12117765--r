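#' Canonical KOG/COG functional category table
#'
#' The 25 single-letter euKaryotic Orthologous Group (KOG) functional
#' categories with their descriptions and broad classes. Used to label KOG
#' letter categories and, for eggNOG-mapper sources (which carry only the
#' letters), to assign each letter to its class. The table can be overridden
#' wherever it is consumed, e.g. by [create_models_from_eggnog()].
#'
#' @return A tibble with columns `letter`, `name`, and `class`.
#' @export
#' @examples
#' kog_letter_table()
kog_letter_table <- function() {
  if (!is.null(.kog_cache$tbl)) {
    return(.kog_cache$tbl)
  }
  .kog_cache$tbl <- tibble::tribble(
    ~letter, ~name, ~class,
    "J", "Translation, ribosomal structure and biogenesis", "Information storage and processing",
    "A", "RNA processing and modification", "Information storage and processing",
    "K", "Transcription", "Information storage and processing",
    "L", "Replication, recombination and repair", "Information storage and processing",
    "B", "Chromatin structure and dynamics", "Information storage and processing",
    "D", "Cell cycle control, cell division, chromosome partitioning", "Cellular processes and signaling",
    "Y", "Nuclear structure", "Cellular processes and signaling",
    "V", "Defense mechanisms", "Cellular processes and signaling",
    "T", "Signal transduction mechanisms", "Cellular processes and signaling",
    "M", "Cell wall/membrane/envelope biogenesis", "Cellular processes and signaling",
    "N", "Cell motility", "Cellular processes and signaling",
    "Z", "Cytoskeleton", "Cellular processes and signaling",
    "W", "Extracellular structures", "Cellular processes and signaling",
    "U", "Intracellular trafficking, secretion, and vesicular transport", "Cellular processes and signaling",
    "O", "Posttranslational modification, protein turnover, chaperones", "Cellular processes and signaling",
    "C", "Energy production and conversion", "Metabolism",
    "G", "Carbohydrate transport and metabolism", "Metabolism",
    "E", "Amino acid transport and metabolism", "Metabolism",
    "F", "Nucleotide transport and metabolism", "Metabolism",
    "H", "Coenzyme transport and metabolism", "Metabolism",
    "I", "Lipid transport and metabolism", "Metabolism",
    "P", "Inorganic ion transport and metabolism", "Metabolism",
    "Q", "Secondary metabolites biosynthesis, transport and catabolism", "Metabolism",
    "R", "General function prediction only", "Poorly characterized",
    "S", "Function unknown", "Poorly characterized"
  )
  .kog_cache$tbl
}

.kog_cache <- new.env(parent = emptyenv())
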