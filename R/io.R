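#' Read and validate a regulatory edge list
#'
#' Reads a tab-separated edge table with columns `regulator`, `target` and
#' `edge_class` and validates it against the tripartite edge-class rules:
#' `TTI` (TF to target gene), `TMI` (TF to miRNA) and `MTI` (miRNA to
#' target). Duplicate rows are collapsed and node types are inferred from
#' the edge classes.
#'
#' Node typing follows the edge semantics: every `TMI` target and `MTI`
#' regulator is a miRNA; every `TTI` or `TMI` regulator is a TF; remaining
#' nodes are targets. A node asserted both miRNA and TF (or a miRNA used as
#' a `TTI` endpoint) is a validation error. A node that is both a TF and
#' someone's target keeps type `TF`.
#'
#' @param path path to a TSV file with header `regulator`, `target`,
#'   `edge_class`.
#' @return a list with `edges` (tibble of deduplicated edge records) and
#'   `node_types` (tibble with columns `node`, `node_type`).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("regulator\ttarget\tedge_class",
#'              "TF1\tmiR1\tTMI", "TF1\tgene1\tTTI", "miR1\tgene1\tMTI"), tf)
#' read_edges(tf)$node_types
#' @export
read_edges <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  assert_columns(raw, c("regulator", "target", "edge_class"), sprintf("edge file '%s'", path))
  validate_edges(raw, source = path)
}

#' Validate an in-memory edge table
#'
#' Same checks as [read_edges()] but starting from a data frame, so
#' programmatically built edge lists go through identical validation.
#'
#' @param edges data frame with columns `regulator`, `target`, `edge_class`.
#' @param source label used in error messages (file name or description).
#' @return list with `edges` and `node_types` tibbles.
#' @export
validate_edges <- function(edges, source = "edge table") {
  assert_columns(edges, c("regulator", "target", "edge_class"), source)
  edges <- as_tibble(edges)
  bad_class <- which(!edges$edge_class %in% c("TTI", "TMI", "MTI"))
  if (length(bad_class) > 0) {
    abort(sprintf("%s: invalid edge_class '%s' at line %d (expected TTI, TMI or MTI)",
                  source, edges$edge_class[bad_class[1]], bad_class[1] + 1L))
  }
  loops <- which(edges$regulator == edges$target)
  if (length(loops) > 0) {
    abort(sprintf("%s: self-loop '%s' at line %d", source,
                  edges$regulator[loops[1]], loops[1] + 1L))
  }
  edges <- distinct(edges, .data$regulator, .data$target, .data$edge_class)
  # one regulator-target pair must not carry two classes
  dup_pair <- duplicated(edges[, c("regulator", "target")])
  if (any(dup_pair)) {
    off <- edges[dup_pair, ]
    abort(sprintf("%s: edge %s->%s appears with more than one edge_class",
                  source, off$regulator[1], off$target[1]))
  }
  node_types <- infer_node_types(edges, source = source)
  list(edges = edges, node_types = node_types)
}

infer_node_types <- function(edges, source = "edge table") {
  mirna_set <- union(edges$target[edges$edge_class == "TMI"],
                     edges$regulator[edges$edge_class == "MTI"])
  tf_set <- union(edges$regulator[edges$edge_class == "TTI"],
                  edges$regulator[edges$edge_class == "TMI"])
  conflict <- intersect(mirna_set, tf_set)
  if (length(conflict) > 0) {
    abort(sprintf("%s: node(s) asserted both miRNA and TF: %s",
                  source, paste(conflict, collapse = ", ")))
  }
  tti_mirna <- intersect(mirna_set, edges$target[edges$edge_class == "TTI"])
  if (length(tti_mirna) > 0) {
    abort(sprintf("%s: miRNA node(s) used as TTI endpoint: %s",
                  source, paste(tti_mirna, collapse = ", ")))
  }
  nodes <- unique(c(edges$regulator, edges$target))
  node_type <- ifelse(nodes %in% mirna_set, "miRNA",
                      ifelse(nodes %in% tf_set, "TF", "target"))
  tibble(node = nodes, node_type = node_type)
}

#' Write an edge table to TSV
#'
#' @param edges tibble with columns `regulator`, `target`, `edge_class`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  readr::write_tsv(edges[, c("regulator", "target", "edge_class")], path)
  invisible(path)
}

#' Read a time-series expression matrix with its sample sheet
#'
#' The expression file is entities-by-samples TSV whose first column holds
#' entity IDs; the sample sheet maps every sample column to an arm
#' (`treatment` or `mock`), a time point in hours, and a replicate index.
#'
#' @param path expression TSV (first column `entity`, remaining columns
#'   numeric sample values).
#' @param meta_path sample sheet TSV with columns `sample`, `arm`,
#'   `time_point`, `replicate`.
#' @return list with `expr` (tibble, first column `entity`) and `meta`
#'   (tibble).
#' @export
read_expression <- function(path, meta_path) {
  expr <- readr::read_tsv(path, col_types = readr::cols(
    entity = readr::col_character(), .default = readr::col_double()))
  if (names(expr)[1] != "entity") names(expr)[1] <- "entity"
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    sample = readr::col_character(), arm = readr::col_character(),
    time_point = readr::col_double(), replicate = readr::col_integer()))
  validate_expression(expr, meta, source = path)
  list(expr = expr, meta = meta)
}

validate_expression <- function(expr, meta, source = "expression table") {
  assert_columns(expr, "entity", source)
  assert_columns(meta, c("sample", "arm", "time_point", "replicate"), "sample sheet")
  sample_cols <- setdiff(names(expr), "entity")
  missing <- setdiff(sample_cols, meta$sample)
  if (length(missing) > 0) {
    abort(sprintf("%s: sample(s) absent from sample sheet: %s",
                  source, paste(missing, collapse = ", ")))
  }
  bad_arm <- setdiff(unique(meta$arm), c("treatment", "mock"))
  if (length(bad_arm) > 0) {
    abort(sprintf("sample sheet: unknown arm value(s): %s", paste(bad_arm, collapse = ", ")))
  }
  vals <- as.matrix(expr[, sample_cols])
  if (anyNA(vals)) abort(sprintf("%s: missing values are not allowed", source))
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: negative value %.4g for entity '%s'", source,
                  vals[bad[1], bad[2]], expr$entity[bad[1]]))
  }
  if (anyDuplicated(expr$entity)) abort(sprintf("%s: duplicated entity IDs", source))
  invisible(TRUE)
}

#' Write an expression matrix and its sample sheet
#'
#' @param expr tibble, first column `entity`.
#' @param meta sample sheet tibble.
#' @param path,meta_path output paths.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, meta, path, meta_path) {
  readr::write_tsv(expr, path)
  readr::write_tsv(meta, meta_path)
  invisible(path)
}

#' Read a sparse cell count matrix (MatrixMarket triplet)
#'
#' Reads a `matrix.mtx` / `barcodes.tsv` / `features.tsv` triplet plus a
#' cell metadata sheet, in the layout produced by droplet-based
#' quantification pipelines: features (genes) as rows, cells as columns,
#' 1-based MatrixMarket indices.
#'
#' @param mtx_path MatrixMarket file of integer counts.
#' @param barcodes_path one barcode per line (no header).
#' @param features_path one feature ID per line (no header; extra columns
#'   ignored).
#' @param meta_path TSV with columns `barcode`, `cell_type`, `condition`.
#' @return list with `counts` (a `dgCMatrix`, features x cells, dimnames
#'   set) and `meta` (tibble, one row per cell, matrix column order).
#' @export
read_cell_matrix <- function(mtx_path, barcodes_path, features_path, meta_path) {
  m <- Matrix::readMM(mtx_path)
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE,
                              col_types = readr::cols(.default = readr::col_character()))[[1]]
  features <- readr::read_tsv(features_path, col_names = FALSE,
                              col_types = readr::cols(.default = readr::col_character()))[[1]]
  if (length(features) != nrow(m)) {
    abort(sprintf("features file has %d rows but matrix has %d rows",
                  length(features), nrow(m)))
  }
  if (length(barcodes) != ncol(m)) {
    abort(sprintf("barcodes file has %d rows but matrix has %d columns",
                  length(barcodes), ncol(m)))
  }
  if (any(m@x != round(m@x))) abort("cell matrix contains non-integer entries")
  if (any(m@x < 0)) abort("cell matrix contains negative entries")
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(features, barcodes)
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(.default = readr::col_character()))
  assert_columns(meta, c("barcode", "cell_type", "condition"), "cell metadata")
  missing <- setdiff(barcodes, meta$barcode)
  if (length(missing) > 0) {
    abort(sprintf("cell metadata lacks %d barcode(s), e.g. %s",
                  length(missing), paste(head(missing, 3), collapse = ", ")))
  }
  meta <- meta[match(barcodes, meta$barcode), ]
  list(counts = m, meta = as_tibble(meta))
}

#' Write a sparse cell matrix as a MatrixMarket triplet
#'
#' @param counts features x cells sparse matrix with dimnames.
#' @param meta cell metadata tibble (`barcode`, `cell_type`, `condition`).
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `barcodes.tsv`, `features.tsv` and `cells.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(counts, meta, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  readr::write_tsv(meta, file.path(dir, "cells.tsv"))
  invisible(dir)
}
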