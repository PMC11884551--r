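# broom-style tidiers for the package's result objects.

#' @rdname mirdynet-tidiers
#' @param x a mirdynet result object.
#' @param ... unused.
#' @method tidy mdn_enrichment
#' @export
tidy.mdn_enrichment <- function(x, ...) {
  as_tibble(x)[, c("motif_type", "real_count", "null_mean", "null_sd",
                   "z", "empirical_p")]
}

#' Tidy and summarise mirdynet result objects
#'
#' `tidy()` returns the per-item table of a result; `glance()` a one-row
#' summary.
#'
#' @name mirdynet-tidiers
NULL

#' @rdname mirdynet-tidiers
#' @method glance mdn_enrichment
#' @export
glance.mdn_enrichment <- function(x, ...) {
  tibble(n_motif_types = nrow(x),
         n_enriched = sum(x$empirical_p < 0.05, na.rm = TRUE),
         n_random = x$n_random[1])
}

#' @rdname mirdynet-tidiers
#' @method tidy mdn_modules
#' @export
tidy.mdn_modules <- function(x, ...) as_tibble(x)

#' @rdname mirdynet-tidiers
#' @method glance mdn_modules
#' @export
glance.mdn_modules <- function(x, ...) {
  sizes <- attr(x, "module_sizes")
  tibble(n_modules = length(sizes), n_assigned = sum(x$module > 0),
         n_unassigned = sum(x$module == 0),
         median_module_size = if (length(sizes) > 0) stats::median(sizes) else NA_real_)
}

#' @rdname mirdynet-tidiers
#' @method tidy mdn_de
#' @export
tidy.mdn_de <- function(x, ...) as_tibble(x)

#' @rdname mirdynet-tidiers
#' @method glance mdn_de
#' @export
glance.mdn_de <- function(x, ...) {
  tibble(n_entities = length(unique(x$entity)),
         n_de_entities = length(unique(x$entity[x$is_de])),
         n_de_calls = sum(x$is_de),
         kind = attr(x, "kind") %||% NA_character_)
}

#' @rdname mirdynet-tidiers
#' @method tidy mdn_dnscore
#' @export
tidy.mdn_dnscore <- function(x, ...) as_tibble(x)

#' @rdname mirdynet-tidiers
#' @method glance mdn_dnscore
#' @export
glance.mdn_dnscore <- function(x, ...) {
  tibble(n_nodes = nrow(x), mean_dn_raw = mean(x$dn_raw),
         max_dn_raw = max(x$dn_raw),
         top_node = x$entity[which.max(x$dn_raw)])
}

#' @rdname mirdynet-tidiers
#' @method tidy mdn_xyz
#' @export
tidy.mdn_xyz <- function(x, ...) x$by_type

#' @rdname mirdynet-tidiers
#' @method glance mdn_xyz
#' @export
glance.mdn_xyz <- function(x, ...) {
  tibble(n_motif_types = nrow(x$by_type),
         min_pairwise_p = if (!is.null(x$tests)) min(x$tests$p) else NA_real_)
}

#' @rdname mirdynet-tidiers
#' @method tidy mdn_ymffl
#' @export
tidy.mdn_ymffl <- function(x, ...) x$ffls

#' @rdname mirdynet-tidiers
#' @method glance mdn_ymffl
#' @export
glance.mdn_ymffl <- function(x, ...) {
  tibble(n_ffls = nrow(x$ffls), n_unique = sum(x$ffls$unique),
         n_groups = nrow(x$per_group))
}

#' @rdname mirdynet-tidiers
#' @method tidy mdn_primirna
#' @export
tidy.mdn_primirna <- function(x, ...) x$table

#' @rdname mirdynet-tidiers
#' @method glance mdn_primirna
#' @export
glance.mdn_primirna <- function(x, ...) {
  tibble(n_groups = nrow(x$expressed),
         max_expressed = max(x$expressed$n_expressed),
         n_differential = sum(x$table$differential))
}
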