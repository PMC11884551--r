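# ggplot2 front-ends for the main result types.

#' @rdname mirdynet-plots
#' @param object a mirdynet result object.
#' @param ... unused.
#' @method autoplot mdn_de
#' @export
autoplot.mdn_de <- function(object, ...) {
  dat <- object |> filter(.data$is_de) |>
    count(.data$time_point, .data$direction)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$time_point), y = .data$n,
                                    fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "time point (h)", y = "DE entities",
                  title = "Differential expression per time point") +
    ggplot2::theme_minimal()
}

#' Plot methods for mirdynet results
#'
#' `autoplot()` methods give quick-look figures for DE tables, rewiring
#' scores, motif enrichment, XYZ ratios and pri-miRNA profiles;
#' [plot_cc_profile()] draws clustering coefficient by persistence class
#' and motif role.
#'
#' @name mirdynet-plots
NULL

#' @rdname mirdynet-plots
#' @method autoplot mdn_dnscore
#' @export
autoplot.mdn_dnscore <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dn_raw, fill = .data$node_type)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::labs(x = "Dn score (raw)", y = "nodes",
                  title = "Node rewiring scores") +
    ggplot2::theme_minimal()
}

#' @rdname mirdynet-plots
#' @method autoplot mdn_enrichment
#' @export
autoplot.mdn_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$motif_type, y = .data$z)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "enrichment z",
                  title = "Motif enrichment vs degree-preserving nulls") +
    ggplot2::theme_minimal()
}

#' @rdname mirdynet-plots
#' @method autoplot mdn_xyz
#' @export
autoplot.mdn_xyz <- function(object, ...) {
  dat <- pivot_longer(object$by_type[, c("motif_type", "ratio_xyz", "ratio_xz")],
                      cols = c("ratio_xyz", "ratio_xz"),
                      names_to = "form", values_to = "ratio")
  dat$form <- sub("^ratio_", "", dat$form)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$motif_type, y = .data$ratio,
                                    fill = .data$form)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "co-expressed fraction",
                  title = "XYZ / XZ co-module ratios by motif class") +
    ggplot2::theme_minimal()
}

#' @rdname mirdynet-plots
#' @method autoplot mdn_primirna
#' @export
autoplot.mdn_primirna <- function(object, ...) {
  ggplot2::ggplot(object$expressed,
                  ggplot2::aes(x = .data$condition, y = .data$cell_type,
                               fill = .data$n_expressed)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "expressed\npri-miRNAs",
                  title = "Expressed pri-miRNAs per cell type and condition") +
    ggplot2::theme_minimal()
}

#' @rdname mirdynet-plots
#' @param cc_table output of [role_cc_profile()].
#' @export
plot_cc_profile <- function(cc_table) {
  ggplot2::ggplot(cc_table, ggplot2::aes(x = .data$persistence, y = .data$mean_cc,
                                         colour = .data$role)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$motif_type)) +
    ggplot2::labs(x = "persistence class (layers present)",
                  y = "mean clustering coefficient",
                  title = "Clustering coefficient by motif role and persistence") +
    ggplot2::theme_minimal()
}
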