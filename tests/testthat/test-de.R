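make_expr <- function(treat_means, mock_means, tps = default_time_points(),
                      reps = 3, noise = 0, seed = 1) {
  # treat_means/mock_means: entities x time points matrices of abundances
  set.seed(seed)
  meta <- tidyr::expand_grid(arm = c("treatment", "mock"), time_point = tps,
                             replicate = seq_len(reps))
  meta$sample <- sprintf("%s_%s_r%d", substr(meta$arm, 1, 5),
                         meta$time_point, meta$replicate)
  meta <- meta[, c("sample", "arm", "time_point", "replicate")]
  n <- nrow(treat_means)
  vals <- sapply(seq_len(nrow(meta)), function(j) {
    src <- if (meta$arm[j] == "treatment") treat_means else mock_means
    pmax(src[, match(meta$time_point[j], tps)] * 2^rnorm(n, sd = noise), 0)
  })
  colnames(vals) <- meta$sample
  expr <- dplyr::bind_cols(tibble::tibble(entity = sprintf("e%02d", seq_len(n))),
                           tibble::as_tibble(as.data.frame(vals)))
  list(expr = expr, meta = meta)
}

test_that("identical arms yield no DE calls and strong effects are called up", {
  tps <- default_time_points()
  base <- matrix(100, nrow = 4, ncol = 7)
  same <- make_expr(base, base, noise = 0.05, seed = 2)
  de <- call_de(same$expr, same$meta, kind = "gene")
  expect_false(any(de$is_de))

  up <- make_expr(base * 8, base, noise = 0.05, seed = 3)
  de_up <- call_de(up$expr, up$meta, kind = "gene")
  expect_true(all(de_up$is_de))
  expect_true(all(de_up$direction == "up"))
})

test_that("fold-change gate blocks significant but small effects", {
  base <- matrix(1000, nrow = 3, ncol = 7)
  d <- make_expr(base * 1.8, base, noise = 0.01, seed = 4)
  de <- call_de(d$expr, d$meta, kind = "gene")
  expect_true(all(de$p < 1e-3))         # highly significant...
  expect_false(any(de$is_de))           # ...but below FC >= 2
  # the miRNA rule (FC >= 1.5, raw p) calls the same data
  de_m <- call_de(d$expr, d$meta, kind = "mirna")
  expect_true(all(de_m$is_de))
})

test_that("the vectorised Welch test matches t.test row by row", {
  set.seed(9)
  x <- matrix(rnorm(60, mean = 5), nrow = 10)
  y <- matrix(rnorm(60, mean = 5.5), nrow = 10)
  mine <- mirdynet:::row_welch(x, y)
  ref <- vapply(1:10, function(i) t.test(x[i, ], y[i, ])$p.value, numeric(1))
  expect_equal(mine$p, ref, tolerance = 1e-12)
})

test_that("q values are BH-monotone in p within each time point", {
  sim <- simulate_timeseries(sim_config(seed = 11, n_mirnas = 0, n_targets = 80,
                                        effect_log2fc = 1, noise_sd = 0.5))
  de <- call_de(sim$expr, sim$meta, kind = "gene")
  for (tp in unique(de$time_point)) {
    sub <- de[de$time_point == tp, ]
    ord <- order(sub$p)
    expect_true(all(diff(sub$q[ord]) >= -1e-12))
    expect_true(all(sub$q >= sub$p - 1e-12))
  }
})

test_that("temporal classification follows the occurrence-bit rules", {
  tps <- default_time_points()
  cases <- tibble::tribble(
    ~occurrence, ~expected,
    "0000001", "only_24h",
    "1000000", "only_0.5h",
    "1111111", "robust",
    "1111110", "robust",      # 6 of 7
    "1010101", "dynamic",
    "1100000", "early",
    "1110000", "early",
    "0000011", "late",
    "0001100", "dynamic")     # spans 6h + 9h windows
  de <- activity_to_de(tibble::tibble(entity = sprintf("x%02d", seq_len(nrow(cases))),
                                      occurrence = cases$occurrence), tps)
  cl <- classify_temporal(de)
  expect_equal(cl$class[match(sprintf("x%02d", seq_len(nrow(cases))), cl$entity)],
               cases$expected)
  # total and permutation-invariant
  expect_equal(sort(cl$entity), sort(sprintf("x%02d", seq_len(nrow(cases)))))
  de_perm <- de[sample(nrow(de)), ]
  attributes(de_perm) <- c(attributes(de_perm),
                           attributes(de)[c("time_points", "kind", "config")])
  class(de_perm) <- class(de)
  cl2 <- classify_temporal(de_perm)
  expect_equal(cl2$class[match(cl$entity, cl2$entity)], cl$class)
})

test_that("never-DE entities are excluded from classification with a warning", {
  de <- activity_to_de(tibble::tibble(entity = c("a", "b"),
                                      occurrence = c("1000000", "0000000")))
  expect_warning(cl <- classify_temporal(de), "no DE time point")
  expect_equal(cl$entity, "a")
})

test_that("early responders split into the three breadth groups", {
  act <- tibble::tibble(entity = c("a", "b", "c", "d"),
                        occurrence = c("1100000",   # group1
                                       "1111101",   # group3 (6 >= 5)
                                       "1010000",   # group2
                                       "0000001"))  # not in universe
  cl <- classify_temporal(activity_to_de(act))
  grp <- group_early_responders(cl)
  expect_equal(setNames(grp$group, grp$entity)[c("a", "b", "c")],
               c(a = "group1", b = "group3", c = "group2"))
  expect_false("d" %in% grp$entity)
})

test_that("time-point correlations behave on constructed fold changes", {
  tps <- c(1, 2)
  de <- tibble::tibble(entity = rep(c("a", "b", "c"), each = 2),
                       time_point = rep(tps, 3),
                       log2fc = c(1, 1, 2, 2, 3, 4),
                       p = 0.001, q = 0.001, is_de = TRUE, direction = "up")
  de <- structure(de, class = c("mdn_de", class(de)), time_points = tps)
  res <- timepoint_correlation(de)
  r12 <- res$r[res$tp_a == 1 & res$tp_b == 2]
  # closed-form Pearson for (1,2,3) vs (1,2,4)
  expect_equal(r12, 3 / sqrt(2 * 4.666667), tolerance = 1e-6)
  expect_equal(res$r[res$tp_a == 1 & res$tp_b == 1], 1)
  # negated profiles give r = -1
  de$log2fc[de$time_point == 2] <- -de$log2fc[de$time_point == 1]
  expect_equal(timepoint_correlation(de)$r[res$tp_a == 1 & res$tp_b == 2], -1)
  # fewer than 3 entities in the union -> NA, not 0
  de2 <- de[de$entity %in% c("a", "b"), ]
  de2 <- structure(de2, class = class(de), time_points = tps)
  expect_true(is.na(timepoint_correlation(de2)$r[2]))
})
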