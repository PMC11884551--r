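#' Assemble the static tripartite regulatory network
#'
#' Validates an edge table (deduplicating rows, enforcing edge-class/type
#' consistency), resolves node types, and returns a simple directed network
#' object.
#'
#' @param edges tibble with columns `regulator`, `target`, `edge_class`
#'   (TTI, TMI or MTI).
#' @return an object of class `mdn_network`: list with `edges`,
#'   `node_types` and `summary` (node counts per type, edge counts per
#'   class).
#' @examples
#' edges <- tibble::tribble(~regulator, ~target, ~edge_class,
#'                          "TF1", "miR1", "TMI",
#'                          "TF1", "geneA", "TTI",
#'                          "miR1", "geneA", "MTI")
#' assemble_static(edges)$summary
#' @export
assemble_static <- function(edges) {
  v <- validate_edges(edges)
  summary <- list(
    n_nodes = nrow(v$node_types),
    n_edges = nrow(v$edges),
    n_by_type = table(factor(v$node_types$node_type, c("TF", "miRNA", "target"))),
    n_by_class = table(factor(v$edges$edge_class, c("TTI", "TMI", "MTI"))))
  structure(list(edges = v$edges, node_types = v$node_types, summary = summary),
            class = "mdn_network")
}

#' @export
print.mdn_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf("mdn_network: %d nodes (%d TF, %d miRNA, %d target), %d edges (%d TTI, %d TMI, %d MTI)\n",
              s$n_nodes, s$n_by_type[["TF"]], s$n_by_type[["miRNA"]],
              s$n_by_type[["target"]], s$n_edges,
              s$n_by_class[["TTI"]], s$n_by_class[["TMI"]], s$n_by_class[["MTI"]]))
  invisible(x)
}

#' Derive the multilayer dynamic network from DE status
#'
#' A miRNA or target node is active in layer `t` iff it is DE at time
#' point `t`; TF activity follows `tf_policy`. An edge is active iff both
#' endpoints are active (conjunction rule). Nodes never active in any
#' layer are dropped; the retained node set is the "final dynamic
#' network".
#'
#' @param net an `mdn_network` from [assemble_static()].
#' @param de an `mdn_de` table; entities absent from it are treated as
#'   never DE.
#' @param tf_policy `"always_active"` (curated TFs enter every layer, the
#'   default), `"de_only"` (TFs follow their own DE calls), or
#'   `"expressed"` (TF active when its mean treatment abundance at `t`
#'   exceeds `expressed_threshold`; requires `expr`/`meta`).
#' @param expr,meta expression table and sample sheet, only for
#'   `tf_policy = "expressed"`.
#' @param expressed_threshold abundance cutoff for the `expressed` policy.
#' @return an object of class `mdn_dynamic`: list with `edges`,
#'   `node_types`, `time_points`, `node_activity` and `edge_activity`
#'   logical matrices (rows named).
#' @export
build_dynamic <- function(net, de,
                          tf_policy = c("always_active", "de_only", "expressed"),
                          expr = NULL, meta = NULL, expressed_threshold = 1) {
  tf_policy <- match.arg(tf_policy)
  stopifnot(inherits(net, "mdn_network"))
  tps <- attr(de, "time_points") %||% sort(unique(de$time_point))
  L <- length(tps)
  nodes <- net$node_types$node
  types <- net$node_types$node_type

  de_mat <- matrix(FALSE, nrow = length(nodes), ncol = L,
                   dimnames = list(nodes, as.character(tps)))
  hit <- de[de$entity %in% nodes & de$is_de, ]
  if (nrow(hit) > 0) {
    de_mat[cbind(match(hit$entity, nodes), match(hit$time_point, tps))] <- TRUE
  }

  act <- de_mat
  is_tf <- types == "TF"
  if (tf_policy == "always_active") {
    act[is_tf, ] <- TRUE
  } else if (tf_policy == "expressed") {
    if (is.null(expr) || is.null(meta)) {
      abort("tf_policy = 'expressed' requires expr and meta")
    }
    vals <- as.matrix(expr[, setdiff(names(expr), "entity")])
    rownames(vals) <- expr$entity
    for (j in seq_len(L)) {
      smp <- meta$sample[meta$arm == "treatment" & meta$time_point == tps[j]]
      tf_nodes <- nodes[is_tf]
      present <- tf_nodes[tf_nodes %in% rownames(vals)]
      act[present, j] <- rowMeans(vals[present, smp, drop = FALSE]) > expressed_threshold
    }
  }

  ridx <- match(net$edges$regulator, nodes)
  tidx <- match(net$edges$target, nodes)
  edge_act <- act[ridx, , drop = FALSE] & act[tidx, , drop = FALSE]
  rownames(edge_act) <- paste(net$edges$regulator, net$edges$target, sep = "->")

  keep_nodes <- rowSums(act) > 0
  keep_edges <- net$edges$regulator %in% nodes[keep_nodes] &
    net$edges$target %in% nodes[keep_nodes]
  structure(list(edges = net$edges[keep_edges, ],
                 node_types = net$node_types[keep_nodes, ],
                 time_points = tps,
                 node_activity = act[keep_nodes, , drop = FALSE],
                 edge_activity = edge_act[keep_edges, , drop = FALSE]),
            class = "mdn_dynamic")
}

#' Per-node rewiring (Dn) scores on a multilayer network
#'
#' For node `i` with union neighbourhood `N(i)` (neighbours via edges
#' active in at least one layer, direction ignored), the raw rewiring
#' score is the summed Bernoulli variance of per-edge activity,
#' `dn_raw(i) = sum_j p_ij (1 - p_ij)` with `p_ij` the fraction of layers
#' in which an edge between `i` and `j` is active. The raw score grows
#' with degree (favouring hubs); the degree-corrected variant divides by
#' `|N(i)|`.
#'
#' @param dyn an `mdn_dynamic` from [build_dynamic()].
#' @return tibble of class `mdn_dnscore` with columns `entity`,
#'   `node_type`, `dn_raw`, `dn_degree_corrected`, `union_degree`.
#' @export
dn_score <- function(dyn) {
  stopifnot(inherits(dyn, "mdn_dynamic"))
  L <- length(dyn$time_points)
  if (L < 2) abort("Dn score undefined for a single-layer network")
  edges <- dyn$edges
  ea <- dyn$edge_activity
  # merge both directions between the same unordered pair
  a <- pmin(edges$regulator, edges$target)
  b <- pmax(edges$regulator, edges$target)
  key <- paste(a, b, sep = "\r")
  pair_act <- rowsum(ea + 0, key) > 0
  pair_ids <- do.call(rbind, strsplit(rownames(pair_act), "\r", fixed = TRUE))
  p <- rowMeans(pair_act)
  contrib <- p * (1 - p)
  ever <- rowSums(pair_act) > 0

  nodes <- dyn$node_types$node
  dn <- setNames(numeric(length(nodes)), nodes)
  deg <- setNames(integer(length(nodes)), nodes)
  for (k in which(ever)) {
    u <- pair_ids[k, 1]; v <- pair_ids[k, 2]
    dn[u] <- dn[u] + contrib[k]; dn[v] <- dn[v] + contrib[k]
    deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
  }
  out <- tibble(entity = nodes, node_type = dyn$node_types$node_type,
                dn_raw = unname(dn),
                dn_degree_corrected = unname(dn / pmax(deg, 1)),
                union_degree = unname(deg))
  structure(out, class = c("mdn_dnscore", class(out)))
}

#' Rank nodes by rewiring score
#'
#' Top-`k` nodes by raw Dn score, ties broken lexicographically by node
#' ID. Per-type counts of the selected nodes are attached as attribute
#' `type_counts` for comparing the miRNA versus gene share among the most
#' dynamic nodes.
#'
#' @param scores an `mdn_dnscore` table.
#' @param k how many nodes to keep (default 100).
#' @return the top-`k` rows, ranked; `attr(, "type_counts")` holds the
#'   per-type tally.
#' @export
rank_dynamic_nodes <- function(scores, k = 100) {
  if (k > nrow(scores)) {
    warn(sprintf("k = %d exceeds node count %d; returning all nodes", k, nrow(scores)))
    k <- nrow(scores)
  }
  ranked <- arrange(scores, desc(.data$dn_raw), .data$entity)
  top <- head(ranked, k)
  attr(top, "type_counts") <- table(factor(top$node_type, c("TF", "miRNA", "target")))
  top
}

#' Export a dynamic network to GraphML
#'
#' Writes the retained static graph with per-layer node and edge activity
#' stored as 0/1 string attributes (`activity`, one character per layer).
#'
#' @param dyn an `mdn_dynamic`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(dyn, path) {
  stopifnot(inherits(dyn, "mdn_dynamic"))
  g <- igraph::graph_from_data_frame(
    dyn$edges, directed = TRUE,
    vertices = data.frame(name = dyn$node_types$node,
                          node_type = dyn$node_types$node_type,
                          activity = apply(dyn$node_activity, 1,
                                           function(b) paste(as.integer(b), collapse = "")),
                          stringsAsFactors = FALSE))
  igraph::E(g)$activity <- apply(dyn$edge_activity, 1,
                                 function(b) paste(as.integer(b), collapse = ""))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Extract the active subgraph of one layer
#'
#' @param dyn an `mdn_dynamic`.
#' @param layer layer index (1-based) or time point value.
#' @return list with `edges` and `node_types` restricted to the layer's
#'   active nodes and edges.
#' @export
layer_network <- function(dyn, layer) {
  stopifnot(inherits(dyn, "mdn_dynamic"))
  if (layer %in% dyn$time_points && !(layer %in% seq_along(dyn$time_points))) {
    layer <- match(layer, dyn$time_points)
  }
  active_nodes <- rownames(dyn$node_activity)[dyn$node_activity[, layer]]
  keep <- dyn$edge_activity[, layer]
  list(edges = dyn$edges[keep, ],
       node_types = dyn$node_types[dyn$node_types$node %in% active_nodes, ])
}
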