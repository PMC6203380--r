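#' Expand fly hits to human genes through an ortholog table
#'
#' Takes the union over the hit list of each hit's human seed orthologs and,
#' by default, its human inparalogs (one-to-many mappings contribute all
#' their targets). The result is deduplicated and sorted. Hits absent from
#' the table are reported via the `"unmapped"` attribute, never silently
#' dropped.
#'
#' @param fly_hits Character vector of fly gene ids (may be empty).
#' @param table Ortholog table as from [gen_ortholog_table()] or
#'   [read_ortholog_table()]: columns `fly_gene`, `human_seed`,
#'   `human_inparalogs` (character or list-columns).
#' @param include_inparalogs Include inparalogs (default TRUE).
#' @return Sorted character vector of human gene ids with attribute
#'   `"unmapped"` (fly hits not in the table).
#' @export
expand_orthologs <- function(fly_hits, table, include_inparalogs = TRUE) {
  table <- as_tibble(table)
  unmapped <- setdiff(fly_hits, table$fly_gene)
  if (length(unmapped)) {
    inform(sprintf("%d fly hit(s) absent from the ortholog table: %s",
                   length(unmapped), toString(head(unmapped, 5))))
  }
  rows <- table[table$fly_gene %in% fly_hits, ]
  flatten_col <- function(col) {
    if (is.list(col)) unlist(col, use.names = FALSE) else col
  }
  out <- flatten_col(rows$human_seed)
  if (include_inparalogs && "human_inparalogs" %in% names(rows)) {
    out <- c(out, flatten_col(rows$human_inparalogs))
  }
  out <- as.character(sort(unique(out[!is.na(out) & nzchar(out)])))
  attr(out, "unmapped") <- unmapped
  out
}

#' Restrict a gene list to genes measurable on the expression platform
#'
#' Partitions the input into genes with at least one probe set on the
#' platform and genes without any, mirroring the step where orthologs
#' missing from the chip are set aside before scoring.
#'
#' @param genes Character vector of gene ids.
#' @param probe_map Data frame with columns `probe_id`, `gene`.
#' @return List with `measurable` and `dropped` (disjoint, exhaustive).
#' @export
restrict_to_platform <- function(genes, probe_map) {
  probed <- unique(as_tibble(probe_map)$gene)
  on <- genes %in% probed
  list(measurable = genes[on], dropped = genes[!on])
}
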