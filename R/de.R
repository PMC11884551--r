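#' Differential-expression calling configuration
#'
#' Thresholds follow common practice for hormone time-course experiments:
#' genes are called at fold change >= 2 with BH-adjusted q <= 0.05, miRNAs
#' at fold change >= 1.5 with raw p <= 0.05 (small-RNA assays are typically
#' gated on the unadjusted p value at these depths).
#'
#' @param fc_threshold_gene,fc_threshold_mirna minimum fold change (linear
#'   scale, >= 1) for genes and miRNAs respectively.
#' @param q_threshold_gene BH-adjusted q-value cutoff for genes.
#' @param p_threshold_mirna raw p-value cutoff for miRNAs.
#' @param test two-sample test applied to log2 abundances per time point:
#'   `"welch_t"` (default) or `"wilcoxon"`.
#' @param pseudocount added to abundances before log transform so zero
#'   values give finite fold changes.
#' @return a list of class `mdn_de_config`.
#' @export
de_config <- function(fc_threshold_gene = 2, q_threshold_gene = 0.05,
                      fc_threshold_mirna = 1.5, p_threshold_mirna = 0.05,
                      test = c("welch_t", "wilcoxon"), pseudocount = 1) {
  test <- match.arg(test)
  assert_scalar_num(fc_threshold_gene, "fc_threshold_gene", lower = 1)
  assert_scalar_num(fc_threshold_mirna, "fc_threshold_mirna", lower = 1)
  assert_scalar_num(q_threshold_gene, "q_threshold_gene", lower = 0, upper = 1)
  assert_scalar_num(p_threshold_mirna, "p_threshold_mirna", lower = 0, upper = 1)
  assert_scalar_num(pseudocount, "pseudocount", lower = 1e-12)
  structure(list(fc_threshold_gene = fc_threshold_gene,
                 q_threshold_gene = q_threshold_gene,
                 fc_threshold_mirna = fc_threshold_mirna,
                 p_threshold_mirna = p_threshold_mirna,
                 test = test, pseudocount = pseudocount),
            class = "mdn_de_config")
}

#' Call per-time-point differential expression against the mock arm
#'
#' For every entity and time point, computes
#' `log2fc = log2((mean treatment + pc) / (mean mock + pc))` on the raw
#' abundance scale and a two-sample test (Welch t by default) on
#' `log2(x + pc)` replicate values. q values are BH-adjusted within each
#' time point. The DE flag applies the kind-specific rule: genes require
#' fold change and q below threshold, miRNAs fold change and raw p.
#'
#' @param expr expression tibble, first column `entity`, remaining columns
#'   samples.
#' @param meta sample sheet tibble (`sample`, `arm`, `time_point`,
#'   `replicate`).
#' @param config a [de_config()].
#' @param kind `"gene"` or `"mirna"`; selects the threshold rule.
#' @return a tibble of class `mdn_de` with columns `entity`, `time_point`,
#'   `log2fc`, `p`, `q`, `is_de`, `direction`.
#' @examples
#' sim <- simulate_timeseries(sim_config(seed = 1, n_targets = 20))
#' de <- call_de(sim$expr, sim$meta, kind = "gene")
#' dplyr::count(de, time_point, is_de)
#' @export
call_de <- function(expr, meta, config = de_config(), kind = c("gene", "mirna")) {
  kind <- match.arg(kind)
  validate_expression(expr, meta)
  pc <- config$pseudocount
  tps <- sort(unique(meta$time_point))
  entities <- expr$entity
  vals <- as.matrix(expr[, setdiff(names(expr), "entity")])
  rownames(vals) <- entities

  res <- map(tps, function(tp) {
    treat <- meta$sample[meta$arm == "treatment" & meta$time_point == tp]
    mock <- meta$sample[meta$arm == "mock" & meta$time_point == tp]
    if (length(treat) < 2 || length(mock) < 2) {
      abort(sprintf("time point %s has fewer than 2 replicates in one arm",
                    hour_label(tp)))
    }
    xt <- vals[, treat, drop = FALSE]
    xm <- vals[, mock, drop = FALSE]
    lfc <- log2((rowMeans(xt) + pc) / (rowMeans(xm) + pc))
    tst <- switch(config$test,
                  welch_t = row_welch(log2(xt + pc), log2(xm + pc)),
                  wilcoxon = row_wilcoxon(log2(xt + pc), log2(xm + pc)))
    tibble(entity = entities, time_point = tp, log2fc = unname(lfc),
           p = unname(tst$p), q = p.adjust(tst$p, method = "BH"))
  })
  de <- list_rbind(res)

  fc_thr <- if (kind == "gene") config$fc_threshold_gene else config$fc_threshold_mirna
  de$is_de <- if (kind == "gene") {
    2^abs(de$log2fc) >= fc_thr & de$q <= config$q_threshold_gene
  } else {
    2^abs(de$log2fc) >= fc_thr & de$p <= config$p_threshold_mirna
  }
  de$direction <- ifelse(de$log2fc >= 0, "up", "down")
  structure(de, class = c("mdn_de", class(de)),
            time_points = tps, kind = kind, config = config)
}

#' Assign temporal response classes from DE occurrence patterns
#'
#' Each DE entity's occurrence bit-vector over the seven time points is
#' mapped to one of eleven classes: `only_<t>` for the seven singletons,
#' `robust` when at least `robust_min` time points are set, `early` when
#' two or more bits are set and all fall in the early window, `late`
#' likewise for the late window, and `dynamic` otherwise. Labels are
#' mutually exclusive and cover every DE entity.
#'
#' @param de an `mdn_de` table from [call_de()].
#' @param early_window,late_window time points (hours) defining the early
#'   and late response windows.
#' @param robust_min minimum number of DE time points for the `robust`
#'   class (checked before the window rules).
#' @return tibble of class `mdn_classes` with columns `entity`, `class`,
#'   `occurrence` (string of 0/1 over time points), `n_de`.
#' @export
classify_temporal <- function(de, early_window = c(0.5, 1, 3),
                              late_window = c(9, 12, 24), robust_min = 6) {
  tps <- attr(de, "time_points") %||% sort(unique(de$time_point))
  wide <- pivot_wider(de[, c("entity", "time_point", "is_de")],
                      names_from = "time_point", values_from = "is_de")
  occ <- as.matrix(wide[, as.character(tps)])
  occ[is.na(occ)] <- FALSE
  n_de <- rowSums(occ)
  keep <- n_de > 0
  if (any(!keep)) {
    warn(sprintf("%d entit(ies) with no DE time point excluded from classification",
                 sum(!keep)))
  }
  wide <- wide[keep, ]
  occ <- occ[keep, , drop = FALSE]
  n_de <- n_de[keep]

  early_idx <- tps %in% early_window
  late_idx <- tps %in% late_window
  cls <- character(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    b <- occ[i, ]
    cls[i] <- if (n_de[i] == 1) {
      paste0("only_", hour_label(tps[which(b)]))
    } else if (n_de[i] >= robust_min) {
      "robust"
    } else if (all(which(b) %in% which(early_idx))) {
      "early"
    } else if (all(which(b) %in% which(late_idx))) {
      "late"
    } else {
      "dynamic"
    }
  }
  out <- tibble(entity = wide$entity, class = cls,
                occurrence = apply(occ, 1, function(b) paste(as.integer(b), collapse = "")),
                n_de = as.integer(n_de))
  structure(out, class = c("mdn_classes", class(out)), time_points = tps)
}

#' Group early responders by breadth of response
#'
#' Among entities DE at 0.5 h or 1 h, group 1 responds only in those first
#' two time points, group 3 responds at `k_robust` or more time points
#' overall, and group 2 is everything in between. The three groups are
#' disjoint and cover the early-responder universe.
#'
#' @param classes an `mdn_classes` table from [classify_temporal()].
#' @param k_robust minimum number of DE time points for group 3.
#' @return tibble with columns `entity`, `group` (`group1`/`group2`/`group3`).
#' @export
group_early_responders <- function(classes, k_robust = 5) {
  tps <- attr(classes, "time_points") %||% default_time_points()
  first_two <- which(tps %in% c(0.5, 1))
  bits <- occ_bits(classes$occurrence)
  in_universe <- map_dbl(bits, ~ sum(.x[first_two])) > 0
  sub <- classes[in_universe, ]
  bits <- bits[in_universe]
  grp <- map_chr(bits, function(b) {
    if (sum(b) >= k_robust) "group3"
    else if (all(which(b) %in% first_two)) "group1"
    else "group2"
  })
  tibble(entity = sub$entity, group = grp)
}

#' Pairwise correlation of fold changes between time points
#'
#' For each time-point pair, the Pearson correlation of log2 fold changes
#' over the union of entities DE at either time point. Pairs with fewer
#' than 3 entities in the union are reported as `NA`, not zero.
#'
#' @param de an `mdn_de` table.
#' @return tibble with columns `tp_a`, `tp_b`, `r`, `n_entities`; the
#'   diagonal is 1 whenever any entity is DE at that time point.
#' @export
timepoint_correlation <- function(de) {
  tps <- attr(de, "time_points") %||% sort(unique(de$time_point))
  lfc <- pivot_wider(de[, c("entity", "time_point", "log2fc")],
                     names_from = "time_point", values_from = "log2fc")
  isde <- pivot_wider(de[, c("entity", "time_point", "is_de")],
                      names_from = "time_point", values_from = "is_de")
  grid <- tidyr::expand_grid(tp_a = tps, tp_b = tps)
  grid$r <- NA_real_
  grid$n_entities <- 0L
  for (k in seq_len(nrow(grid))) {
    a <- as.character(grid$tp_a[k]); b <- as.character(grid$tp_b[k])
    sel <- which(isde[[a]] | isde[[b]])
    grid$n_entities[k] <- length(sel)
    if (length(sel) >= 3) {
      if (a == b) {
        grid$r[k] <- 1
      } else {
        sda <- sd(lfc[[a]][sel]); sdb <- sd(lfc[[b]][sel])
        if (sda > 0 && sdb > 0) grid$r[k] <- cor(lfc[[a]][sel], lfc[[b]][sel])
      }
    }
  }
  grid
}
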