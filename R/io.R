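# Plain-text readers/writers for the pipeline's tabular interchange formats.
# All files are tab-separated with a header line; missing values are "NA".

write_tsv_na <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read/write a screen table
#'
#' Screen tables are TSV with one row per RNAi line and the columns produced
#' by [gen_screen_table()]; the control summary travels in a two-column
#' companion file (`mean_pupariation`, `sd_pupariation`).
#'
#' @param x Screen table tibble.
#' @param path,control_path File paths (TSV).
#' @return `read_screen_table()` returns the tibble with the control stats
#'   attached when `control_path` exists.
#' @export
write_screen_table <- function(x, path, control_path = NULL) {
  write_tsv_na(as_tibble(x), path)
  if (!is.null(control_path)) write_tsv_na(control_stats(x), control_path)
  invisible(path)
}

#' @rdname write_screen_table
#' @export
read_screen_table <- function(path, control_path = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(control_path)) {
    attr(tbl, "control_stats") <- readr::read_tsv(control_path, show_col_types = FALSE)
  }
  tbl
}

#' Read/write an ortholog table
#'
#' TSV with columns `fly_gene`, `HOMSA`, `HOMSA_INP`, `MUSMU`, `MUSMU_INP`;
#' multiple values are semicolon-separated, empty fields are `NA`.
#'
#' @param table Ortholog tibble with list-columns as from
#'   [gen_ortholog_table()].
#' @param path File path.
#' @return `read_ortholog_table()` returns the list-column form.
#' @export
write_ortholog_table <- function(table, path) {
  pack <- function(col) {
    vapply(col, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_character_ else paste(v, collapse = ";")
    }, character(1))
  }
  flat <- tibble(
    fly_gene = table$fly_gene,
    HOMSA = pack(table$human_seed),
    HOMSA_INP = pack(table$human_inparalogs),
    MUSMU = pack(table$mouse_seed),
    MUSMU_INP = pack(table$mouse_inparalogs)
  )
  write_tsv_na(flat, path)
}

#' @rdname write_ortholog_table
#' @export
read_ortholog_table <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  unpack <- function(col) {
    lapply(col, function(s) if (is.na(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]])
  }
  tibble(
    fly_gene = flat$fly_gene,
    human_seed = unpack(flat$HOMSA),
    human_inparalogs = unpack(flat$HOMSA_INP),
    mouse_seed = unpack(flat$MUSMU),
    mouse_inparalogs = unpack(flat$MUSMU_INP)
  )
}

#' Read/write gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then one member gene per
#' field.
#'
#' @param collection Tibble with `term`, `description`, `genes` list-column.
#' @param path File path.
#' @return `read_gmt()` returns a collection tibble.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    list(collection$term, collection$description %||% collection$term,
         collection$genes),
    function(term, desc, genes) paste(c(term, desc, genes), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    term = vapply(parts, `[`, character(1), 1),
    description = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Read/write an edge list
#'
#' Two-column TSV. For annotation DAGs the columns are `child`, `parent`;
#' for PPI networks `from`, `to`.
#'
#' @param edges Two-column tibble.
#' @param path File path.
#' @return `read_edge_list()` returns the tibble.
#' @export
write_edge_list <- function(edges, path) write_tsv_na(as_tibble(edges), path)

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' Read/write a direction matrix
#'
#' Gene-by-pair TSV with a companion `n_probes` column.
#'
#' @param dm A [direction_scores()] tibble.
#' @param path File path.
#' @return `read_direction_matrix()` returns a `direction_matrix` tibble.
#' @export
write_direction_matrix <- function(dm, path) write_tsv_na(as_tibble(dm), path)

#' @rdname write_direction_matrix
#' @export
read_direction_matrix <- function(path) {
  dm <- readr::read_tsv(path, show_col_types = FALSE)
  class(dm) <- c("direction_matrix", class(dm))
  dm
}

#' Read/write a patient cohort
#'
#' One TSV: per-sample clinical columns (`sample`, `time`, `event`,
#' `mutation_category`, `has_survival`, `has_mutation_call`, and
#' `latent_group` when simulated), then one `expr_<gene>` column per gene
#' and, when present, one `beta_<gene>` column per gene.
#'
#' @param cohort A `patient_cohort`.
#' @param path File path.
#' @param signature Signature genes to record on reading (defaults to the
#'   `# signature:` header comment written by `write_cohort()`).
#' @return `read_cohort()` returns a `patient_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  flat <- cohort$samples
  e <- t(cohort$expr)
  colnames(e) <- paste0("expr_", colnames(e))
  flat <- dplyr::bind_cols(flat, as_tibble(e[flat$sample, , drop = FALSE]))
  if (!is.null(cohort$beta)) {
    b <- t(cohort$beta)
    colnames(b) <- paste0("beta_", colnames(b))
    flat <- dplyr::bind_cols(flat, as_tibble(b[cohort$samples$sample, , drop = FALSE]))
  }
  header <- sprintf("# signature: %s", paste(cohort$signature, collapse = ";"))
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  readr::write_tsv(flat, path, na = "NA", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, signature = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(signature) && startsWith(first, "# signature:")) {
    signature <- strsplit(trimws(sub("^# signature:", "", first)), ";", fixed = TRUE)[[1]]
    signature <- signature[nzchar(signature)]
  }
  flat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expr_cols <- grep("^expr_", names(flat), value = TRUE)
  beta_cols <- grep("^beta_", names(flat), value = TRUE)
  expr <- t(as.matrix(flat[, expr_cols]))
  rownames(expr) <- sub("^expr_", "", expr_cols)
  colnames(expr) <- flat$sample
  beta <- NULL
  if (length(beta_cols)) {
    beta <- t(as.matrix(flat[, beta_cols]))
    rownames(beta) <- sub("^beta_", "", beta_cols)
    colnames(beta) <- flat$sample
  }
  new_patient_cohort(flat[, setdiff(names(flat), c(expr_cols, beta_cols))],
                     expr, beta, signature %||% character())
}

#' Write a systems map as node and edge tables
#'
#' Two TSVs consumable by standard graph viewers: nodes (`id`, `type`,
#' `unassigned`) and edges (`source`, `target`, `type`).
#'
#' @param map A [build_systems_map()] object.
#' @param nodes_path,edges_path File paths.
#' @return Invisibly, the two paths.
#' @export
write_systems_map <- function(map, nodes_path, edges_path) {
  write_tsv_na(map$nodes, nodes_path)
  write_tsv_na(map$edges, edges_path)
  invisible(c(nodes_path, edges_path))
}

#' Read/write an expression panel
#'
#' One probe-by-sample TSV per tissue pair (columns prefixed `T_` for tumor
#' and `N_` for normal samples, first column `probe_id`) inside `dir`, plus
#' a probe-to-gene map TSV.
#'
#' @param panel An `expression_panel`.
#' @param dir Directory to hold `map.tsv` and one `<pair>.tsv` per pair.
#' @return `read_expression_panel()` returns an `expression_panel`.
#' @export
write_expression_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_na(panel$probe_to_gene, file.path(dir, "map.tsv"))
  for (pair_id in names(panel$pairs)) {
    pr <- panel$pairs[[pair_id]]
    tum <- pr$tumor; nor <- pr$normal
    colnames(tum) <- paste0("T_", colnames(tum))
    colnames(nor) <- paste0("N_", colnames(nor))
    tbl <- dplyr::bind_cols(tibble(probe_id = rownames(tum)),
                            as_tibble(tum), as_tibble(nor))
    write_tsv_na(tbl, file.path(dir, paste0(pair_id, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_expression_panel
#' @export
read_expression_panel <- function(dir) {
  map <- readr::read_tsv(file.path(dir, "map.tsv"), show_col_types = FALSE)
  pair_files <- setdiff(list.files(dir, pattern = "\\.tsv$"), "map.tsv")
  pairs <- lapply(pair_files, function(f) {
    tbl <- readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
    m <- as.matrix(tbl[, -1])
    rownames(m) <- tbl$probe_id
    tum <- m[, startsWith(colnames(m), "T_"), drop = FALSE]
    nor <- m[, startsWith(colnames(m), "N_"), drop = FALSE]
    colnames(tum) <- sub("^T_", "", colnames(tum))
    colnames(nor) <- sub("^N_", "", colnames(nor))
    list(tumor = tum, normal = nor)
  })
  names(pairs) <- sub("\\.tsv$", "", pair_files)
  structure(list(genes = sort(unique(map$gene)), probe_to_gene = map,
                 pairs = pairs, planted_genes = character()),
            class = "expression_panel")
}
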