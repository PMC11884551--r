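# Cell-type pri-miRNA profiling: QC filtering, pseudobulk aggregation per
# (cell type, condition), expressed/differential pri-miRNA tallies, and
# cell-type-unique miRNA feed-forward loop detection.

#' Cell quality-control configuration
#'
#' Defaults follow standard droplet scRNA-seq practice for plant tissue:
#' 500-10000 expressed genes, 500-70000 UMIs, and at most 10%
#' mitochondrial and 10% chloroplast content per cell.
#'
#' @param min_genes,max_genes expressed-gene bounds per cell.
#' @param min_umis,max_umis UMI-count bounds per cell.
#' @param max_mito_frac,max_pt_frac maximum mitochondrial / chloroplast
#'   UMI fractions.
#' @param excluded_genes optional gene IDs dropped before analysis (e.g.
#'   protoplasting-sensitive genes).
#' @param mito_prefix,pt_prefix feature-ID prefixes identifying
#'   organellar genes when explicit sets are not supplied.
#' @param mito_genes,pt_genes explicit organellar gene sets (override the
#'   prefixes).
#' @return a list of class `mdn_qc_config`.
#' @export
cell_qc_config <- function(min_genes = 500, max_genes = 10000,
                           min_umis = 500, max_umis = 70000,
                           max_mito_frac = 0.10, max_pt_frac = 0.10,
                           excluded_genes = NULL,
                           mito_prefix = "ATMG", pt_prefix = "ATCG",
                           mito_genes = NULL, pt_genes = NULL) {
  if (min_genes >= max_genes) abort("min_genes must be < max_genes")
  if (min_umis >= max_umis) abort("min_umis must be < max_umis")
  assert_scalar_num(max_mito_frac, "max_mito_frac", lower = 0, upper = 1)
  assert_scalar_num(max_pt_frac, "max_pt_frac", lower = 0, upper = 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_umis = min_umis, max_umis = max_umis,
                 max_mito_frac = max_mito_frac, max_pt_frac = max_pt_frac,
                 excluded_genes = excluded_genes,
                 mito_prefix = mito_prefix, pt_prefix = pt_prefix,
                 mito_genes = mito_genes, pt_genes = pt_genes),
            class = "mdn_qc_config")
}

#' Quality-filter cells in a sparse count matrix
#'
#' Removes cells outside the expressed-gene, UMI, mitochondrial-fraction
#' or chloroplast-fraction bounds, and drops excluded genes. Filtering is
#' idempotent: running it twice removes nothing new.
#'
#' @param counts features x cells sparse matrix (dimnames required).
#' @param meta cell metadata tibble (`barcode`, `cell_type`, `condition`),
#'   matrix column order.
#' @param config a [cell_qc_config()].
#' @return list with filtered `counts` and `meta`, plus `report`: a tibble
#'   of per-criterion removal counts and the retained-cell tally.
#' @export
qc_filter_cells <- function(counts, meta, config = cell_qc_config()) {
  stopifnot(nrow(meta) == ncol(counts))
  mito <- config$mito_genes %||% rownames(counts)[startsWith(rownames(counts), config$mito_prefix)]
  pt <- config$pt_genes %||% rownames(counts)[startsWith(rownames(counts), config$pt_prefix)]
  umis <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito_frac <- if (length(mito) > 0) {
    Matrix::colSums(counts[rownames(counts) %in% mito, , drop = FALSE]) / pmax(umis, 1)
  } else rep(0, ncol(counts))
  pt_frac <- if (length(pt) > 0) {
    Matrix::colSums(counts[rownames(counts) %in% pt, , drop = FALSE]) / pmax(umis, 1)
  } else rep(0, ncol(counts))

  fail_genes <- n_genes < config$min_genes | n_genes > config$max_genes
  fail_umis <- umis < config$min_umis | umis > config$max_umis
  fail_mito <- mito_frac > config$max_mito_frac
  fail_pt <- pt_frac > config$max_pt_frac
  fail <- fail_genes | fail_umis | fail_mito | fail_pt
  if (all(fail)) abort("no cells pass quality control")

  keep_genes <- !(rownames(counts) %in% (config$excluded_genes %||% character(0)))
  report <- tibble(
    criterion = c("gene_count", "umi_count", "mito_fraction", "pt_fraction",
                  "total_removed", "retained"),
    n_cells = c(sum(fail_genes), sum(fail_umis), sum(fail_mito), sum(fail_pt),
                sum(fail), sum(!fail)))
  list(counts = counts[keep_genes, !fail, drop = FALSE],
       meta = meta[!fail, ], report = report)
}

#' Aggregate single cells to pseudobulk groups
#'
#' Sums counts within each (cell type, condition) group and converts to
#' counts per million (CPM rows sum to 1e6 per group). Groups with fewer
#' than `min_cells` cells are flagged low-confidence but still computed.
#'
#' @param counts features x cells sparse matrix.
#' @param meta cell metadata tibble (`barcode`, `cell_type`, `condition`).
#' @param min_cells low-confidence threshold (default 10).
#' @return object of class `mdn_pseudobulk`: list with `counts` and `cpm`
#'   (features x groups matrices, group names `cell_type|condition`) and
#'   `groups` tibble (`cell_type`, `condition`, `n_cells`,
#'   `low_confidence`).
#' @export
pseudobulk <- function(counts, meta, min_cells = 10) {
  stopifnot(nrow(meta) == ncol(counts))
  unlabeled <- is.na(meta$cell_type) | is.na(meta$condition)
  if (any(unlabeled)) {
    abort(sprintf("unlabeled cell(s): %s",
                  paste(head(meta$barcode[unlabeled], 5), collapse = ", ")))
  }
  key <- paste(meta$cell_type, meta$condition, sep = "|")
  groups <- unique(key)
  agg <- vapply(groups, function(g) {
    Matrix::rowSums(counts[, key == g, drop = FALSE])
  }, numeric(nrow(counts)))
  totals <- colSums(agg)
  cpm <- sweep(agg, 2, pmax(totals, 1), "/") * 1e6
  gtab <- tibble(cell_type = sub("\\|.*$", "", groups),
                 condition = sub("^.*\\|", "", groups),
                 n_cells = as.integer(table(key)[groups]))
  gtab$low_confidence <- gtab$n_cells < min_cells
  structure(list(counts = agg, cpm = cpm, groups = gtab),
            class = "mdn_pseudobulk")
}

#' Profile pri-miRNA expression across cell types and conditions
#'
#' Tallies expressed pri-miRNAs (CPM > 0) per (cell type, condition) and
#' calls each pri-miRNA differential in a treatment group when
#' `|log2((cpm + pc) / (cpm_mock + pc))| >= lfc_threshold` against the
#' same cell type's mock group and the larger of the two CPMs reaches
#' `min_expr`. Per-condition differential sets and their intersection
#' pattern (Venn counts) are included.
#'
#' @param pb an `mdn_pseudobulk`.
#' @param annotation tibble with column `gene` listing pri-miRNA feature
#'   IDs.
#' @param mock_condition reference condition label (default `"Mock"`).
#' @param lfc_threshold,pseudocount,min_expr differential rule parameters.
#' @return object of class `mdn_primirna`: list with `expressed` (tibble
#'   `cell_type`, `condition`, `n_expressed`), `table` (per pri-miRNA x
#'   group log2fc and flags) and `venn` (per condition-set differential
#'   counts).
#' @export
primirna_profile <- function(pb, annotation, mock_condition = "Mock",
                             lfc_threshold = 1, pseudocount = 1, min_expr = 1) {
  stopifnot(inherits(pb, "mdn_pseudobulk"))
  pri <- intersect(annotation$gene, rownames(pb$cpm))
  if (length(pri) == 0) abort("no annotated pri-miRNA present in the feature space")
  cpm <- pb$cpm[pri, , drop = FALSE]
  g <- pb$groups
  expressed <- tibble(cell_type = g$cell_type, condition = g$condition,
                      n_expressed = as.integer(colSums(cpm > 0)))

  rows <- list()
  for (ct in unique(g$cell_type)) {
    mock_col <- which(g$cell_type == ct & g$condition == mock_condition)
    if (length(mock_col) == 0) {
      warn(sprintf("cell type '%s' has no %s group; skipped", ct, mock_condition))
      next
    }
    mock_cpm <- cpm[, mock_col]
    for (col in which(g$cell_type == ct & g$condition != mock_condition)) {
      treat_cpm <- cpm[, col]
      lfc <- log2((treat_cpm + pseudocount) / (mock_cpm + pseudocount))
      rows[[length(rows) + 1]] <- tibble(
        gene = pri, cell_type = ct, condition = g$condition[col],
        cpm = treat_cpm, cpm_mock = mock_cpm, log2fc = lfc,
        differential = abs(lfc) >= lfc_threshold &
          pmax(treat_cpm, mock_cpm) >= min_expr)
    }
  }
  tab <- if (length(rows) > 0) list_rbind(rows) else
    tibble(gene = character(0), cell_type = character(0), condition = character(0),
           cpm = numeric(0), cpm_mock = numeric(0), log2fc = numeric(0),
           differential = logical(0))

  venn <- NULL
  if (nrow(tab) > 0) {
    sets <- tab |> filter(.data$differential) |> distinct(.data$gene, .data$condition)
    if (nrow(sets) > 0) {
      venn <- sets |>
        group_by(.data$gene) |>
        summarise(conditions = paste(sort(unique(.data$condition)), collapse = "&"),
                  .groups = "drop") |>
        count(.data$conditions, name = "n_primirnas")
    }
  }
  structure(list(expressed = expressed, table = tab, venn = venn),
            class = "mdn_primirna")
}

#' Detect cell-type-unique miRNA feed-forward loops
#'
#' Calls per-group activity for every network node from pseudobulk CPM
#' (treatment groups: differential versus the same cell type's mock; mock
#' groups: expressed; or plain expression presence for every group with
#' `activity = "expressed"`), marks a YM-FFL (FFL with a miRNA Y node)
#' active in a group when all three members are active, and reports FFLs
#' active in exactly one group as unique to it, the per-group hub miRNA
#' (the miRNA in the most active YM-FFLs, ties lexicographic), and
#' per-cell-type unique miRNA/target tallies.
#'
#' @param net an `mdn_network` whose node IDs match the pseudobulk feature
#'   space (miRNA nodes are the pri-miRNA features).
#' @param pb an `mdn_pseudobulk` over all entities.
#' @param mock_condition reference condition label.
#' @param activity `"de"` (default) or `"expressed"`.
#' @param include_mock include mock groups in the group universe (the
#'   5 treatment x 9 cell type layout counts them); `FALSE` restricts to
#'   treatment groups.
#' @param lfc_threshold,pseudocount,min_expr differential rule parameters.
#' @return object of class `mdn_ymffl`: list with `ffls` (instances with
#'   `n_groups_active`, `unique`, `unique_group`), `per_group` (tibble
#'   `cell_type`, `condition`, `n_active`, `n_unique`, `hub_mirna`) and
#'   `by_celltype` (unique miRNA / target tallies).
#' @export
celltype_unique_ymffls <- function(net, pb, mock_condition = "Mock",
                                   activity = c("de", "expressed"),
                                   include_mock = TRUE,
                                   lfc_threshold = 1, pseudocount = 1, min_expr = 1) {
  activity <- match.arg(activity)
  stopifnot(inherits(pb, "mdn_pseudobulk"))
  cen <- census_triads(net)
  is_mirna <- setNames(net$node_types$node_type == "miRNA", net$node_types$node)
  ffls <- filter(cen, .data$motif_type == "ffl", is_mirna[.data$Y])
  g <- pb$groups
  use <- if (include_mock) seq_len(nrow(g)) else which(g$condition != mock_condition)
  cpm <- pb$cpm

  node_active <- function(col) {
    act <- setNames(rep(FALSE, nrow(net$node_types)), net$node_types$node)
    present <- intersect(names(act), rownames(cpm))
    if (activity == "expressed" || g$condition[col] == mock_condition) {
      act[present] <- cpm[present, col] > 0
    } else {
      mock_col <- which(g$cell_type == g$cell_type[col] &
                          g$condition == mock_condition)
      if (length(mock_col) == 0) return(act)
      lfc <- log2((cpm[present, col] + pseudocount) /
                    (cpm[present, mock_col] + pseudocount))
      act[present] <- abs(lfc) >= lfc_threshold &
        pmax(cpm[present, col], cpm[present, mock_col]) >= min_expr
    }
    act
  }

  n_ffl <- nrow(ffls)
  active_mat <- matrix(FALSE, nrow = n_ffl, ncol = length(use))
  hub <- character(length(use))
  for (j in seq_along(use)) {
    act <- node_active(use[j])
    if (n_ffl > 0) {
      active_mat[, j] <- act[ffls$X] & act[ffls$Y] & act[ffls$Z]
      ys <- ffls$Y[active_mat[, j]]
      hub[j] <- if (length(ys) > 0) {
        tab <- table(ys)
        sort(names(tab)[tab == max(tab)])[1]
      } else NA_character_
    } else hub[j] <- NA_character_
  }
  n_groups_active <- rowSums(active_mat)
  unique_flag <- n_groups_active == 1
  unique_group <- rep(NA_character_, n_ffl)
  gkey <- paste(g$cell_type[use], g$condition[use], sep = "|")
  unique_group[unique_flag] <- gkey[apply(active_mat[unique_flag, , drop = FALSE], 1, which)]
  ffls <- mutate(ffls, n_groups_active = as.integer(n_groups_active),
                 unique = unique_flag, unique_group = unique_group)

  per_group <- tibble(cell_type = g$cell_type[use], condition = g$condition[use],
                      n_active = as.integer(colSums(active_mat)),
                      n_unique = as.integer(vapply(seq_along(use), function(j) {
                        sum(active_mat[, j] & unique_flag)
                      }, numeric(1))),
                      hub_mirna = hub)

  uniq <- ffls[ffls$unique & !is.na(ffls$unique_group), ]
  by_celltype <- tibble(cell_type = unique(g$cell_type[use])) |>
    mutate(n_unique_mirnas = map_int(.data$cell_type, function(ct) {
      length(unique(uniq$Y[startsWith(uniq$unique_group, paste0(ct, "|"))]))
    }),
    n_unique_targets = map_int(.data$cell_type, function(ct) {
      length(unique(uniq$Z[startsWith(uniq$unique_group, paste0(ct, "|"))]))
    }))
  structure(list(ffls = ffls, per_group = per_group, by_celltype = by_celltype),
            class = "mdn_ymffl")
}
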