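# Weighted co-expression modules at desk scale: unsigned correlation
# adjacency raised to a soft-threshold power, topological-overlap
# dissimilarity, average-linkage clustering with a static cut plus module
# size filter.

#' Co-expression configuration
#'
#' @param beta soft-threshold exponent (>= 1); see [choose_beta()] for
#'   scale-free-fit-based selection.
#' @param min_module_size smallest retained module (default 30, the usual
#'   WGCNA-style floor).
#' @param cut_height fraction of the maximum merge height at which the
#'   average-linkage tree is cut statically (default 0.98, the usual
#'   static-cut convention for topological-overlap dendrograms).
#' @param correlation `"pearson"` or `"spearman"`.
#' @return a list of class `mdn_coexpress_config`.
#' @export
coexpress_config <- function(beta = 6, min_module_size = 30, cut_height = 0.98,
                             correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  if (beta < 1) abort("beta must be >= 1")
  if (min_module_size < 2) abort("min_module_size must be >= 2")
  assert_scalar_num(cut_height, "cut_height", lower = 1e-9, upper = 1)
  structure(list(beta = beta, min_module_size = min_module_size,
                 cut_height = cut_height, correlation = correlation),
            class = "mdn_coexpress_config")
}

# mean log2 profile per (arm, time point) condition; constant rows flagged
condition_profiles <- function(expr, meta = NULL, pseudocount = 1) {
  vals <- as.matrix(expr[, setdiff(names(expr), "entity")])
  rownames(vals) <- expr$entity
  lv <- log2(vals + pseudocount)
  if (is.null(meta)) return(lv)
  key <- paste(meta$arm, meta$time_point, sep = "_")
  cond <- unique(key)
  prof <- vapply(cond, function(k) {
    rowMeans(lv[, meta$sample[key == k], drop = FALSE])
  }, numeric(nrow(lv)))
  prof
}

#' Build weighted co-expression modules
#'
#' Computes unsigned adjacency `a_ij = |cor(i, j)|^beta` over per-condition
#' mean log2 profiles, converts it to topological-overlap dissimilarity,
#' clusters with average linkage, cuts the tree at the configured
#' dissimilarity quantile, and discards clusters smaller than
#' `min_module_size` (their members become unassigned, module 0).
#' Constant-profile entities are excluded before correlation. Module
#' labels are contiguous from 1 in decreasing size order; each module's
#' eigen-profile (first principal component of scaled member profiles) is
#' attached.
#'
#' @param expr expression tibble (first column `entity`).
#' @param meta optional sample sheet; when given, profiles are mean log2
#'   abundance per (arm, time point), otherwise raw columns are used as
#'   conditions.
#' @param config a [coexpress_config()].
#' @return tibble of class `mdn_modules` with columns `entity`, `module`
#'   (0 = unassigned); attributes `module_sizes`, `eigenprofiles`.
#' @export
build_modules <- function(expr, meta = NULL, config = coexpress_config()) {
  prof <- condition_profiles(expr, meta)
  if (ncol(prof) < 4) abort("need profiles over at least 4 conditions")
  keep <- apply(prof, 1, sd) > 0
  if (!any(keep)) abort("all expression profiles are constant")
  excluded <- rownames(prof)[!keep]
  prof <- prof[keep, , drop = FALSE]
  if (nrow(prof) < config$min_module_size) {
    abort("fewer non-constant entities than min_module_size")
  }
  method <- config$correlation
  r <- cor(t(prof), method = method)
  a <- abs(r)^config$beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  h <- config$cut_height * max(hc$height)
  cl <- cutree(hc, h = h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= config$min_module_size]
  module <- integer(length(cl))
  if (length(big) > 0) {
    ord <- big[order(-sizes[big], as.numeric(big))]
    for (m in seq_along(ord)) module[cl == ord[m]] <- m
  }
  out <- bind_rows(tibble(entity = rownames(prof), module = module),
                   tibble(entity = excluded, module = 0L))
  n_mod <- max(module)
  eig <- NULL
  if (n_mod > 0) {
    eig <- t(vapply(seq_len(n_mod), function(m) {
      sub <- prof[module == m, , drop = FALSE]
      sub <- t(scale(t(sub)))
      pc <- prcomp(t(sub), center = FALSE, scale. = FALSE)$x[, 1]
      # orient along the mean member profile for reproducibility
      if (cor(pc, colMeans(sub)) < 0) pc <- -pc
      pc
    }, numeric(ncol(prof))))
    rownames(eig) <- paste0("module", seq_len(n_mod))
    colnames(eig) <- colnames(prof)
  }
  structure(out, class = c("mdn_modules", class(out)),
            module_sizes = as.integer(table(factor(module, 0:max(0, n_mod)))[-1]),
            eigenprofiles = eig, config = config)
}

#' Choose the soft-threshold exponent by scale-free fit
#'
#' For each candidate beta, the connectivity distribution
#' `k_i = sum_j |cor|^beta` is binned and the R-squared of the regression
#' of `log10(density)` on `log10(k)` is computed. Returns the smallest
#' candidate reaching `rsq_target` (default 0.8), or the argmax R-squared
#' if none does.
#'
#' @param expr,meta as in [build_modules()].
#' @param candidates candidate exponents (>= 2 values).
#' @param rsq_target scale-free fit target.
#' @param n_bins connectivity histogram bins.
#' @param correlation correlation method.
#' @return list with `beta` (chosen value) and `fit` (tibble `beta`,
#'   `rsq`, `slope`, `degenerate`).
#' @export
choose_beta <- function(expr, meta = NULL, candidates = c(1, 2, 4, 6, 8, 10, 12),
                        rsq_target = 0.8, n_bins = 10,
                        correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  if (length(candidates) < 1) abort("need at least one candidate beta")
  prof <- condition_profiles(expr, meta)
  prof <- prof[apply(prof, 1, sd) > 0, , drop = FALSE]
  r <- abs(cor(t(prof), method = correlation))
  diag(r) <- 0
  fit <- map(candidates, function(beta) {
    k <- rowSums(r^beta)
    if (diff(range(k)) < 1e-12) {
      return(tibble(beta = beta, rsq = NA_real_, slope = NA_real_, degenerate = TRUE))
    }
    cuts <- cut(k, breaks = n_bins)
    dens <- tapply(k, cuts, length)
    kmid <- tapply(k, cuts, mean)
    ok <- !is.na(dens) & dens > 0 & kmid > 0
    if (sum(ok) < 3) {
      return(tibble(beta = beta, rsq = NA_real_, slope = NA_real_, degenerate = TRUE))
    }
    m <- lm(log10(as.numeric(dens[ok])) ~ log10(as.numeric(kmid[ok])))
    tibble(beta = beta, rsq = summary(m)$r.squared, slope = unname(coef(m)[2]),
           degenerate = FALSE)
  }) |> list_rbind()
  eligible <- fit$beta[!fit$degenerate & fit$rsq >= rsq_target]
  beta <- if (length(eligible) > 0) {
    min(eligible)
  } else if (any(!fit$degenerate)) {
    fit$beta[which.max(fit$rsq)]
  } else {
    candidates[1]
  }
  list(beta = beta, fit = fit)
}

#' XYZ versus XZ co-module ratios across motif classes
#'
#' Classifies each motif instance by co-expression form: `XYZ` when X, Y
#' and Z share one module, `XZ` when X and Z share a module but Y is
#' elsewhere or unassigned, `neither` otherwise (the three forms partition
#' the instances). Ratios are reported per (motif type, time point with
#' the occurrence bit set) and aggregated per motif type; motif classes
#' are compared pairwise by chi-square on the 2x2 XYZ-versus-not table,
#' with Yates correction when any expected cell is below 5.
#'
#' @param instances motif instance tibble; an `occurrence` column drives
#'   the per-time-point rows (instances lacking it only enter the
#'   aggregate).
#' @param modules an `mdn_modules` assignment; instance members absent
#'   from it count as unassigned.
#' @return list of class `mdn_xyz` with `by_time`, `by_type` and `tests`
#'   tibbles.
#' @export
xyz_ratio <- function(instances, modules) {
  mod <- setNames(modules$module, modules$entity)
  lookup <- function(e) {
    v <- mod[e]
    v[is.na(v)] <- 0L
    unname(v)
  }
  mx <- lookup(instances$X); my <- lookup(instances$Y); mz <- lookup(instances$Z)
  form <- ifelse(mx > 0 & mx == my & my == mz, "XYZ",
                 ifelse(mx > 0 & mx == mz & my != mx, "XZ", "neither"))
  inst <- mutate(instances, coexpr_form = form)

  by_type <- inst |>
    group_by(.data$motif_type) |>
    summarise(n_total = n(),
              n_xyz = sum(.data$coexpr_form == "XYZ"),
              n_xz = sum(.data$coexpr_form == "XZ"), .groups = "drop") |>
    mutate(ratio_xyz = .data$n_xyz / .data$n_total,
           ratio_xz = .data$n_xz / .data$n_total)

  by_time <- NULL
  if ("occurrence" %in% names(inst)) {
    L <- nchar(inst$occurrence[1] %||% "")
    bits <- occ_bits(inst$occurrence)
    rows <- list()
    for (l in seq_len(L %||% 0)) {
      sel <- map_dbl(bits, function(b) b[l]) > 0
      if (!any(sel)) next
      sub <- inst[sel, ]
      rows[[length(rows) + 1]] <- sub |>
        group_by(.data$motif_type) |>
        summarise(n_total = n(),
                  n_xyz = sum(.data$coexpr_form == "XYZ"),
                  n_xz = sum(.data$coexpr_form == "XZ"), .groups = "drop") |>
        mutate(layer = l)
    }
    if (length(rows) > 0) {
      by_time <- list_rbind(rows) |>
        mutate(ratio_xyz = .data$n_xyz / .data$n_total,
               ratio_xz = .data$n_xz / .data$n_total) |>
        select("motif_type", "layer", "n_total", "n_xyz", "n_xz",
               "ratio_xyz", "ratio_xz")
    }
  }

  types <- unique(by_type$motif_type)
  tests <- NULL
  if (length(types) >= 2) {
    pairs <- combn(sort(types), 2)
    tests <- map(seq_len(ncol(pairs)), function(j) {
      a <- by_type[by_type$motif_type == pairs[1, j], ]
      b <- by_type[by_type$motif_type == pairs[2, j], ]
      tab <- matrix(c(a$n_xyz, a$n_total - a$n_xyz,
                      b$n_xyz, b$n_total - b$n_xyz), nrow = 2, byrow = TRUE)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_yates <- any(expected < 5)
      ct <- suppressWarnings(chisq.test(tab, correct = use_yates))
      tibble(type_a = pairs[1, j], type_b = pairs[2, j],
             statistic = unname(ct$statistic), p = ct$p.value,
             yates = use_yates)
    }) |> list_rbind()
  }
  structure(list(by_time = by_time, by_type = by_type, tests = tests,
                 instances = inst),
            class = "mdn_xyz")
}

#' Module-trait significance against the treatment indicator
#'
#' Correlates each module eigen-profile with the treatment-arm indicator
#' over conditions and BH-adjusts across modules, flagging modules whose
#' expression tracks the stress treatment.
#'
#' @param modules an `mdn_modules` with eigen-profiles (built with a
#'   sample sheet so conditions are `arm_time` pairs).
#' @param q_threshold BH-adjusted significance cutoff.
#' @return tibble with `module`, `cor_trait`, `p`, `q`, `significant`.
#' @export
module_trait_significance <- function(modules, q_threshold = 0.05) {
  eig <- attr(modules, "eigenprofiles")
  if (is.null(eig)) abort("modules carry no eigen-profiles")
  trait <- as.numeric(startsWith(colnames(eig), "treatment"))
  if (length(unique(trait)) < 2) {
    abort("conditions do not span both arms; cannot score the treatment trait")
  }
  res <- map(seq_len(nrow(eig)), function(m) {
    ct <- cor.test(eig[m, ], trait)
    tibble(module = m, cor_trait = unname(ct$estimate), p = ct$p.value)
  }) |> list_rbind()
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < q_threshold
  res
}
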