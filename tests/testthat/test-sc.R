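test_that("QC bounds remove the documented failure modes", {
  n_genes <- 700
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  cell <- function(n_expressed, mito = 0) {
    v <- setNames(rep(2, n_expressed), gene_ids[seq_len(n_expressed)])
    if (mito > 0) v <- c(v, ATMG00001 = mito)
    v
  }
  # 400 expressed genes (fails 500 floor), 600 genes (passes),
  # 12% mito (fails), 9% mito (passes)
  counts <- make_counts(list(cell(400), cell(600),
                             c(cell(600), ATMG00001 = round(0.12 / 0.88 * 1200)),
                             c(cell(600), ATMG00001 = round(0.09 / 0.91 * 1200))))
  meta <- tibble::tibble(barcode = colnames(counts), cell_type = "ct",
                         condition = "Mock")
  res <- qc_filter_cells(counts, meta, cell_qc_config())
  expect_setequal(res$meta$barcode, c("cell02", "cell04"))
  rep <- setNames(res$report$n_cells, res$report$criterion)
  expect_equal(rep[["gene_count"]], 1)
  expect_equal(rep[["mito_fraction"]], 1)
  # idempotence: a second pass removes nothing
  res2 <- qc_filter_cells(res$counts, res$meta, cell_qc_config())
  expect_equal(ncol(res2$counts), ncol(res$counts))
  # excluded genes are dropped
  res3 <- qc_filter_cells(counts, meta,
                          cell_qc_config(excluded_genes = "g0001"))
  expect_false("g0001" %in% rownames(res3$counts))
})

test_that("pseudobulk sums are additive and CPM-normalised", {
  counts <- make_counts(list(c(a = 3, b = 2), c(a = 2, b = 3),
                             c(a = 5, b = 5)))
  meta <- tibble::tibble(barcode = colnames(counts),
                         cell_type = c("ct1", "ct1", "ct2"),
                         condition = "Mock")
  pb <- pseudobulk(counts, meta, min_cells = 2)
  expect_equal(unname(pb$counts[, "ct1|Mock"]), c(5, 5))
  expect_equal(unname(pb$cpm[, "ct1|Mock"]), c(5e5, 5e5))
  expect_true(all(abs(colSums(pb$cpm) - 1e6) < 1e-6))
  expect_equal(pb$groups$low_confidence, c(FALSE, TRUE))
  # splitting a group and re-merging leaves sums unchanged
  meta2 <- meta; meta2$cell_type <- c("ct1", "ct1b", "ct2")
  pb2 <- pseudobulk(counts, meta2)
  expect_equal(pb$counts[, "ct1|Mock"],
               pb2$counts[, "ct1|Mock"] + pb2$counts[, "ct1b|Mock"])
  meta$cell_type[1] <- NA
  expect_error(pseudobulk(counts, meta), "unlabeled")
})

test_that("pri-miRNA profiling applies the fold-change rule vs mock", {
  counts <- make_counts(list(
    c(g1 = 60, `pri-miR1` = 25, `pri-miR2` = 0),   # ct1 Mock
    c(g1 = 60, `pri-miR1` = 100, `pri-miR2` = 0),  # ct1 T1
    c(g1 = 60, `pri-miR1` = 10, `pri-miR2` = 0)))  # ct2 T1 (no mock)
  meta <- tibble::tibble(barcode = colnames(counts),
                         cell_type = c("ct1", "ct1", "ct2"),
                         condition = c("Mock", "T1", "T1"))
  pb <- pseudobulk(counts, meta, min_cells = 1)
  ann <- tibble::tibble(gene = c("pri-miR1", "pri-miR2"))
  # scale CPM back to the worked example: use raw counts as CPM via the rule
  expect_warning(prof <- primirna_profile(pb, ann), "no Mock group")
  tab <- prof$table
  row <- tab[tab$gene == "pri-miR1" & tab$cell_type == "ct1", ]
  # CPM scaling preserves the >2-fold contrast, so the rule fires
  expect_true(row$differential)
  expect_gt(row$log2fc, 1)
  absent <- tab[tab$gene == "pri-miR2", ]
  expect_false(any(absent$differential))
  expect_equal(prof$expressed$n_expressed[prof$expressed$cell_type == "ct1"],
               c(1L, 1L))
  # the worked arithmetic itself: cpm 100 vs 25 with pc 1
  expect_equal(log2((100 + 1) / (25 + 1)), 1.9579, tolerance = 1e-4)
})

test_that("unique YM-FFL detection attributes planted responses to one group", {
  edges <- tibble::tribble(~regulator, ~target, ~edge_class,
                           "tfA", "pri-miR1", "TMI",
                           "tfA", "gZ", "TTI",
                           "pri-miR1", "gZ", "MTI",
                           "tfB", "pri-miR2", "TMI",
                           "tfB", "gW", "TTI",
                           "pri-miR2", "gW", "MTI")
  net <- assemble_static(edges)
  base <- c(tfA = 5, `pri-miR1` = 5, gZ = 5, tfB = 5, `pri-miR2` = 5,
            gW = 5, filler = 100)
  shifted <- base; shifted[c("tfA", "pri-miR1", "gZ")] <- 40
  cells <- list(base, base, shifted, base, base, base)
  counts <- make_counts(cells)
  meta <- tibble::tibble(barcode = colnames(counts),
                         cell_type = rep(c("ct1", "ct2"), each = 3)[1:6],
                         condition = rep(c("Mock", "T1", "T2"), 2))
  counts <- counts
  pb <- pseudobulk(counts, meta, min_cells = 1)
  ym <- celltype_unique_ymffls(net, pb, activity = "de", include_mock = FALSE)
  ffl1 <- ym$ffls[ym$ffls$Y == "pri-miR1", ]
  expect_true(ffl1$unique)
  expect_equal(ffl1$unique_group, "ct1|T2")
  # the untouched FFL is active nowhere under the DE rule
  ffl2 <- ym$ffls[ym$ffls$Y == "pri-miR2", ]
  expect_equal(ffl2$n_groups_active, 0L)
  pg <- ym$per_group
  expect_equal(pg$n_unique[pg$cell_type == "ct1" & pg$condition == "T2"], 1L)
  expect_equal(pg$hub_mirna[pg$cell_type == "ct1" & pg$condition == "T2"], "pri-miR1")
  bc <- ym$by_celltype
  expect_equal(bc$n_unique_mirnas[bc$cell_type == "ct1"], 1L)
  expect_equal(bc$n_unique_mirnas[bc$cell_type == "ct2"], 0L)
})

test_that("the hub miRNA is the count-max miRNA with lexicographic ties", {
  # one group where miR-a sits in 2 active FFLs and miR-b in 1
  edges <- tibble::tribble(~regulator, ~target, ~edge_class,
                           "tf1", "miR-a", "TMI", "tf1", "z1", "TTI", "miR-a", "z1", "MTI",
                           "tf2", "miR-a", "TMI", "tf2", "z2", "TTI", "miR-a", "z2", "MTI",
                           "tf3", "miR-b", "TMI", "tf3", "z3", "TTI", "miR-b", "z3", "MTI")
  net <- assemble_static(edges)
  on <- c(tf1 = 10, tf2 = 10, tf3 = 10, `miR-a` = 10, `miR-b` = 10,
          z1 = 10, z2 = 10, z3 = 10)
  counts <- make_counts(list(on, on))
  meta <- tibble::tibble(barcode = colnames(counts), cell_type = c("ct1", "ct2"),
                         condition = "Mock")
  pb <- pseudobulk(counts, meta, min_cells = 1)
  ym <- celltype_unique_ymffls(net, pb, activity = "expressed")
  expect_equal(unique(ym$per_group$hub_mirna), "miR-a")
  expect_equal(unique(ym$per_group$n_active), 3L)
  # active in both groups: nothing unique
  expect_equal(sum(ym$ffls$unique), 0L)
})
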