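# Shared internal helpers: argument checks, occurrence bit-vectors, and a
# vectorised Welch t-test used by the differential-expression caller.

default_time_points <- function() c(0.5, 1, 3, 6, 9, 12, 24)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# occurrence bit-vectors are stored as strings of 0/1, one character per layer
occ_string <- function(bits) {
  vapply(bits, function(b) paste(as.integer(b), collapse = ""), character(1))
}

occ_bits <- function(occ) {
  lapply(strsplit(occ, "", fixed = TRUE), function(x) x == "1")
}

occ_popcount <- function(occ) {
  vapply(strsplit(occ, "", fixed = TRUE),
         function(x) sum(x == "1"), integer(1))
}

#' Vectorised two-sample Welch t-test on matrix rows
#'
#' Computes, for each row, the Welch (unequal-variance) two-sided t-test
#' between the columns of `x` and the columns of `y`. Equivalent to calling
#' `t.test(x[i, ], y[i, ])` row by row but in one vectorised pass.
#'
#' @param x,y numeric matrices with one row per entity and one column per
#'   replicate.
#' @return a list with components `statistic`, `df` and `p` (two-sided).
#' @keywords internal
#' @noRd
row_welch <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  stat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  # zero-variance rows: identical groups give t = 0/0 -> p = 1
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  degenerate <- !is.finite(stat)
  p[degenerate & abs(mx - my) < .Machine$double.eps^0.5] <- 1
  p[degenerate & abs(mx - my) >= .Machine$double.eps^0.5] <- 0
  stat[!is.finite(stat)] <- 0
  list(statistic = stat, df = df, p = p)
}

row_wilcoxon <- function(x, y) {
  p <- vapply(seq_len(nrow(x)), function(i) {
    suppressWarnings(stats::wilcox.test(x[i, ], y[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  list(statistic = rep(NA_real_, nrow(x)), df = rep(NA_real_, nrow(x)), p = p)
}

# Format hour labels the way sample sheets and figure axes do ("0.5h", "24h")
hour_label <- function(h) paste0(format(h, trim = TRUE, drop0trailing = TRUE), "h")
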