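# Triad motif engine. The four shapes counted are, under the
# adjacency-bitmask ID convention (ID = sum of 2^(3(r-1)+(c-1)) over edges
# r->c): the feed-forward loop (id 38), fan-out (id 6), cascade (id 12) and
# fan-in (id 36). Counting uses induced-subgraph semantics (mfinder's
# default): a triple with three edges is an FFL only, never also one of the
# two-edge shapes.

MOTIF_TYPES <- c("ffl", "fanout", "cascade", "fanin")

# Precomputed classification of all 64 directed patterns on an ordered node
# triple (a, b, c). Bit order: a->b, b->a, a->c, c->a, b->c, c->b.
# For each code: type (or NA), role indices (X, Y, Z) into (a, b, c), and
# which role pair is symmetric ("none", "YZ" for fan-out targets, "XY" for
# fan-in regulators).
.triad_lookup <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  type <- rep(NA_character_, 64)
  rx <- ry <- rz <- rep(NA_integer_, 64)
  sym <- rep("none", 64)
  for (code in 0:63) {
    bits <- as.logical(bitwAnd(code, 2^(0:5)))
    M <- matrix(FALSE, 3, 3)
    M[1, 2] <- bits[1]; M[2, 1] <- bits[2]; M[1, 3] <- bits[3]
    M[3, 1] <- bits[4]; M[2, 3] <- bits[5]; M[3, 2] <- bits[6]
    m <- sum(M)
    for (p in perms) {
      x <- p[1]; y <- p[2]; z <- p[3]
      if (m == 3 && M[x, y] && M[x, z] && M[y, z]) {
        type[code + 1] <- "ffl"
      } else if (m == 2 && M[x, y] && M[x, z]) {
        type[code + 1] <- "fanout"; sym[code + 1] <- "YZ"
      } else if (m == 2 && M[x, y] && M[y, z]) {
        type[code + 1] <- "cascade"
      } else if (m == 2 && M[x, z] && M[y, z]) {
        type[code + 1] <- "fanin"; sym[code + 1] <- "XY"
      } else next
      rx[code + 1] <- x; ry[code + 1] <- y; rz[code + 1] <- z
      break
    }
  }
  list(type = type, rx = rx, ry = ry, rz = rz, sym = sym)
})

triad_graph_parts <- function(net) {
  if (inherits(net, "mdn_network")) {
    list(edges = net$edges, node_types = net$node_types)
  } else if (is.list(net) && all(c("edges", "node_types") %in% names(net))) {
    list(edges = net$edges, node_types = net$node_types)
  } else {
    abort("expected an mdn_network or a list with edges and node_types")
  }
}

#' Census the four three-node motif shapes in a directed network
#'
#' Enumerates every connected node triple once and classifies its induced
#' subgraph as a feed-forward loop (X->Y, X->Z, Y->Z), fan-out (X->Y,
#' X->Z), cascade (X->Y->Z) or fan-in (X->Z, Y->Z); triples whose induced
#' edge set is any other pattern (including any mutual pair) are not
#' counted. Roles in the symmetric pairs (fan-out targets, fan-in
#' regulators) put a miRNA in the Y slot when exactly one candidate is a
#' miRNA, otherwise order is lexicographic.
#'
#' @param net an `mdn_network` or a list with `edges` and `node_types`.
#' @return tibble with columns `motif_type`, `X`, `Y`, `Z`.
#' @examples
#' edges <- tibble::tribble(~regulator, ~target, ~edge_class,
#'                          "TF1", "miR1", "TMI",
#'                          "TF1", "geneA", "TTI",
#'                          "miR1", "geneA", "MTI")
#' census_triads(assemble_static(edges))
#' @export
census_triads <- function(net) {
  parts <- triad_graph_parts(net)
  edges <- parts$edges
  if (anyDuplicated(paste(edges$regulator, edges$target))) {
    abort("parallel edges present; simplify the network first")
  }
  nodes <- parts$node_types$node
  n <- length(nodes)
  if (n > 2000) abort("exact census is limited to networks of at most 2000 nodes")
  empty <- tibble(motif_type = character(0), X = character(0),
                  Y = character(0), Z = character(0))
  if (n < 3 || nrow(edges) < 2) return(empty)
  ii <- match(edges$regulator, nodes)
  jj <- match(edges$target, nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(ii, jj)] <- TRUE
  U <- A | t(A)

  # every connected triple, once: pairs of neighbours of each node, deduped
  keys <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- which(U[i, ])
    if (length(nb) < 2) next
    pr <- combn(nb, 2)
    a <- pmin(i, pr[1, ], pr[2, ])
    c_ <- pmax(i, pr[1, ], pr[2, ])
    b <- i + pr[1, ] + pr[2, ] - a - c_
    keys[[i]] <- (a - 1) * n * n + (b - 1) * n + (c_ - 1)
  }
  keys <- unique(unlist(keys))
  if (length(keys) == 0) return(empty)
  a <- keys %/% (n * n) + 1
  b <- (keys %/% n) %% n + 1
  c_ <- keys %% n + 1

  code <- A[cbind(a, b)] + 2 * A[cbind(b, a)] + 4 * A[cbind(a, c_)] +
    8 * A[cbind(c_, a)] + 16 * A[cbind(b, c_)] + 32 * A[cbind(c_, b)]
  lk <- .triad_lookup
  type <- lk$type[code + 1]
  hit <- !is.na(type)
  if (!any(hit)) return(empty)
  trip <- cbind(a, b, c_)[hit, , drop = FALSE]
  code <- code[hit]
  type <- type[hit]
  xi <- trip[cbind(seq_len(nrow(trip)), lk$rx[code + 1])]
  yi <- trip[cbind(seq_len(nrow(trip)), lk$ry[code + 1])]
  zi <- trip[cbind(seq_len(nrow(trip)), lk$rz[code + 1])]
  X <- nodes[xi]; Y <- nodes[yi]; Z <- nodes[zi]

  is_mirna <- setNames(parts$node_types$node_type == "miRNA", nodes)
  sym <- lk$sym[code + 1]
  # fan-out: Y/Z symmetric targets; fan-in: X/Y symmetric regulators
  fo <- sym == "YZ"
  if (any(fo)) {
    swap <- (is_mirna[Z[fo]] & !is_mirna[Y[fo]]) |
      (is_mirna[Z[fo]] == is_mirna[Y[fo]] & Z[fo] < Y[fo])
    tmp <- Y[fo][swap]; Y[fo][swap] <- Z[fo][swap]; Z[fo][swap] <- tmp
  }
  fi <- sym == "XY"
  if (any(fi)) {
    # Y gets the miRNA; otherwise keep X < Y lexicographically
    swap <- (is_mirna[X[fi]] & !is_mirna[Y[fi]]) |
      (is_mirna[X[fi]] == is_mirna[Y[fi]] & Y[fi] < X[fi])
    tmp <- X[fi][swap]; X[fi][swap] <- Y[fi][swap]; Y[fi][swap] <- tmp
  }
  tibble(motif_type = type, X = unname(X), Y = unname(Y), Z = unname(Z))
}

#' Census motif instances across the layers of a dynamic network
#'
#' Runs the induced-subgraph triad census on every layer's active subgraph
#' and merges occurrences: an instance's occurrence bit for layer `t` is
#' set iff the full motif edge set is active and induced semantics hold at
#' `t`. Persistence is the number of set bits; the same node triple
#' appearing as different shapes in different layers yields distinct
#' instances.
#'
#' @param dyn an `mdn_dynamic` from [build_dynamic()].
#' @return tibble of class `mdn_motifs` with columns `motif_type`, `X`,
#'   `Y`, `Z`, `occurrence` (0/1 string over layers), `persistence`.
#' @export
census_dynamic <- function(dyn) {
  stopifnot(inherits(dyn, "mdn_dynamic"))
  L <- length(dyn$time_points)
  per_layer <- map(seq_len(L), function(l) {
    cen <- census_triads(layer_network(dyn, l))
    if (nrow(cen) > 0) cen$layer <- l
    cen
  })
  all <- list_rbind(per_layer)
  if (nrow(all) == 0) {
    out <- tibble(motif_type = character(0), X = character(0), Y = character(0),
                  Z = character(0), occurrence = character(0), persistence = integer(0))
    return(structure(out, class = c("mdn_motifs", class(out)),
                     time_points = dyn$time_points))
  }
  key <- paste(all$motif_type, all$X, all$Y, all$Z, sep = "\r")
  occ <- matrix(FALSE, nrow = length(unique(key)), ncol = L,
                dimnames = list(unique(key), NULL))
  occ[cbind(match(key, rownames(occ)), all$layer)] <- TRUE
  parts <- do.call(rbind, strsplit(rownames(occ), "\r", fixed = TRUE))
  out <- tibble(motif_type = parts[, 1], X = parts[, 2], Y = parts[, 3], Z = parts[, 4],
                occurrence = unname(apply(occ, 1, function(b) {
                  paste(as.integer(b), collapse = "")
                })),
                persistence = as.integer(unname(rowSums(occ))))
  structure(out, class = c("mdn_motifs", class(out)), time_points = dyn$time_points)
}

swap_edges_within_class <- function(edges, n_attempts_factor = 10) {
  # degree-preserving double-edge swaps, performed within each edge class;
  # global duplicate-pair and self-loop checks
  nodes <- unique(c(edges$regulator, edges$target))
  reg <- match(edges$regulator, nodes)
  tgt <- match(edges$target, nodes)
  cls_all <- edges$edge_class
  n <- length(nodes)
  M <- matrix(FALSE, n, n)
  M[cbind(reg, tgt)] <- TRUE
  for (cls in unique(cls_all)) {
    idx <- which(cls_all == cls)
    ne <- length(idx)
    if (ne < 2) next
    pick1 <- idx[sample.int(ne, n_attempts_factor * ne, replace = TRUE)]
    pick2 <- idx[sample.int(ne, n_attempts_factor * ne, replace = TRUE)]
    for (attempt in seq_along(pick1)) {
      e1 <- pick1[attempt]; e2 <- pick2[attempt]
      if (e1 == e2) next
      a <- reg[e1]; b <- tgt[e1]; cc <- reg[e2]; d <- tgt[e2]
      if (a == d || cc == b || b == d) next
      if (M[a, d] || M[cc, b]) next
      M[a, b] <- FALSE; M[cc, d] <- FALSE
      M[a, d] <- TRUE; M[cc, b] <- TRUE
      tgt[e1] <- d
      tgt[e2] <- b
    }
  }
  tibble(regulator = nodes[reg], target = nodes[tgt], edge_class = cls_all)
}

# Fast per-type triad counts via the C-level Davis-Leinhardt census
# (positions: 021D = fan-out, 021U = fan-in, 021C = cascade, 030T = ffl).
# Equivalent to table(census_triads(...)$motif_type) on mutual-free graphs
# and used for the null ensemble, where only counts are needed.
count_triads <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(cbind(edges$regulator, edges$target),
                                     directed = TRUE, vertices = nodes)
  tc <- igraph::triad_census(g)
  c(ffl = tc[9], fanout = tc[4], cascade = tc[6], fanin = tc[5])
}

#' Motif enrichment against degree-preserving random networks
#'
#' Compares real motif counts to a null ensemble generated by
#' degree-preserving double-edge swaps performed within each edge class
#' (TTI, TMI, MTI separately), so node types, in/out degrees and the
#' tripartite structure are conserved. Reports `z = (real - mean) / sd`
#' and the empirical p value `(1 + #{null >= real}) / (n_random + 1)`.
#'
#' @param net an `mdn_network` or list with `edges` and `node_types`.
#' @param n_random number of null networks (default 1000).
#' @param seed RNG seed for the null ensemble.
#' @return tibble of class `mdn_enrichment` with columns `motif_type`,
#'   `real_count`, `null_mean`, `null_sd`, `z`, `empirical_p`,
#'   `degenerate`, `n_random`.
#' @export
motif_enrichment <- function(net, n_random = 1000, seed = 1) {
  parts <- triad_graph_parts(net)
  set.seed(seed)
  nodes <- parts$node_types$node
  real <- count_triads(parts$edges, nodes)[MOTIF_TYPES]
  nulls <- matrix(0, nrow = n_random, ncol = length(MOTIF_TYPES))
  for (r in seq_len(n_random)) {
    shuffled <- swap_edges_within_class(parts$edges)
    nulls[r, ] <- count_triads(shuffled, nodes)[MOTIF_TYPES]
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, sd)
  degenerate <- null_sd == 0
  z <- ifelse(degenerate, NaN, (real - null_mean) / null_sd)
  emp_p <- vapply(seq_along(MOTIF_TYPES), function(j) {
    (1 + sum(nulls[, j] >= real[j])) / (n_random + 1)
  }, numeric(1))
  out <- tibble(motif_type = MOTIF_TYPES, real_count = as.integer(real),
                null_mean = null_mean, null_sd = null_sd, z = z,
                empirical_p = emp_p, degenerate = degenerate,
                n_random = as.integer(n_random))
  structure(out, class = c("mdn_enrichment", class(out)))
}

#' Pairwise expression coherence of motif instances
#'
#' For each instance, the Pearson correlation of the per-time-point
#' treatment log2 fold-change profiles is computed for every node pair;
#' pairs joined by an edge are checked against the expected regulatory
#' sign (activation, positive, for TTI/TMI edges; repression, negative,
#' for MTI edges by default), and the non-edge pair is reported alongside.
#' An instance is coherent iff every edge pair matches its expected sign
#' (and clears `r_min` when set); a constant profile leaves the pair
#' undefined and the flag `NA`.
#'
#' @param instances motif instance tibble (`motif_type`, `X`, `Y`, `Z`).
#' @param de an `mdn_de` table supplying log2 fold changes per time point.
#' @param net the `mdn_network` the instances came from (for edge classes).
#' @param expected_sign named numeric (+1/-1) per edge class.
#' @param r_min optional minimum |r| for an edge pair to count as matching.
#' @return the instance tibble with `r_xy`, `r_xz`, `r_yz` and `coherent`
#'   columns appended.
#' @export
pair_coherence <- function(instances, de, net,
                           expected_sign = c(TTI = 1, TMI = 1, MTI = -1),
                           r_min = 0) {
  parts <- triad_graph_parts(net)
  lfc <- pivot_wider(de[, c("entity", "time_point", "log2fc")],
                     names_from = "time_point", values_from = "log2fc")
  prof <- as.matrix(lfc[, -1])
  rownames(prof) <- lfc$entity
  cls <- setNames(parts$edges$edge_class,
                  paste(parts$edges$regulator, parts$edges$target, sep = "\r"))
  pair_info <- function(u, v) {
    k1 <- paste(u, v, sep = "\r"); k2 <- paste(v, u, sep = "\r")
    if (k1 %in% names(cls)) cls[[k1]] else if (k2 %in% names(cls)) cls[[k2]] else NA_character_
  }
  safe_cor <- function(u, v) {
    if (!(u %in% rownames(prof)) || !(v %in% rownames(prof))) return(NA_real_)
    a <- prof[u, ]; b <- prof[v, ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  n <- nrow(instances)
  r_xy <- r_xz <- r_yz <- rep(NA_real_, n)
  coherent <- rep(NA, n)
  for (i in seq_len(n)) {
    X <- instances$X[i]; Y <- instances$Y[i]; Z <- instances$Z[i]
    r_xy[i] <- safe_cor(X, Y); r_xz[i] <- safe_cor(X, Z); r_yz[i] <- safe_cor(Y, Z)
    pairs <- list(c(X, Y, r_xy[i]), c(X, Z, r_xz[i]), c(Y, Z, r_yz[i]))
    ok <- TRUE; undefined <- FALSE
    for (p in pairs) {
      ec <- pair_info(p[1], p[2])
      if (is.na(ec)) next  # the non-edge pair carries no expectation
      r <- as.numeric(p[3])
      if (is.na(r)) { undefined <- TRUE; next }
      if (sign(r) != expected_sign[[ec]] || abs(r) < r_min) ok <- FALSE
    }
    coherent[i] <- if (undefined && ok) NA else ok
  }
  bind_cols(instances, tibble(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz,
                              coherent = coherent))
}

#' Crosstalk degree of feed-forward loop instances
#'
#' The number of other FFL instances sharing at least one node with each
#' instance.
#'
#' @param ffls motif instance tibble restricted to `motif_type == "ffl"`.
#' @return `ffls` with an integer `crosstalk` column appended.
#' @export
crosstalk_degree <- function(ffls) {
  if (nrow(ffls) > 0 && any(ffls$motif_type != "ffl")) {
    abort("crosstalk_degree expects FFL instances only")
  }
  n <- nrow(ffls)
  if (n == 0) return(bind_cols(ffls, tibble(crosstalk = integer(0))))
  members <- cbind(ffls$X, ffls$Y, ffls$Z)
  nodes <- unique(as.vector(members))
  M <- matrix(0L, nrow = n, ncol = length(nodes))
  for (j in 1:3) M[cbind(seq_len(n), match(members[, j], nodes))] <- 1L
  S <- M %*% t(M)
  bind_cols(ffls, tibble(crosstalk = as.integer(rowSums(S > 0) - 1L)))
}

#' Local clustering coefficient on the undirected view of a network
#'
#' The fraction of a node's neighbour pairs that are themselves connected,
#' computed after collapsing edge directions; nodes of degree below 2 get
#' 0 by convention.
#'
#' @param edges edge tibble (`regulator`, `target`).
#' @param nodes node universe (nodes without edges get CC 0).
#' @return named numeric vector of clustering coefficients.
#' @export
local_clustering <- function(edges, nodes = unique(c(edges$regulator, edges$target))) {
  cc <- setNames(rep(0, length(nodes)), nodes)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("regulator", "target")],
                                       directed = FALSE, vertices = nodes)
    g <- igraph::simplify(g)
    vals <- igraph::transitivity(g, type = "local", isolates = "zero")
    cc[igraph::V(g)$name] <- ifelse(is.nan(vals), 0, vals)
  }
  cc
}

layer_cc <- function(dyn, layer) {
  ln <- layer_network(dyn, layer)
  local_clustering(ln$edges, ln$node_types$node)
}

#' Mean clustering coefficient by motif role and persistence class
#'
#' For every instance, each role node's local undirected clustering
#' coefficient is computed on the layers where the instance occurs (or
#' once on the union network) and averaged; instance values are then
#' averaged within each (motif type, role, persistence class) cell. For
#' fan-out and fan-in, the Y-role rows restricted to miRNA Y nodes are
#' reported separately as role `Y_miRNA`.
#'
#' @param dyn the `mdn_dynamic` the instances were counted on.
#' @param instances an `mdn_motifs` table from [census_dynamic()].
#' @param mode `"per_layer"` (default) or `"union"`.
#' @return tibble with columns `motif_type`, `role`, `persistence`,
#'   `mean_cc`, `n_instances`.
#' @export
role_cc_profile <- function(dyn, instances, mode = c("per_layer", "union")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dyn, "mdn_dynamic"))
  L <- length(dyn$time_points)
  if (nrow(instances) == 0) {
    return(tibble(motif_type = character(0), role = character(0),
                  persistence = integer(0), mean_cc = numeric(0),
                  n_instances = integer(0)))
  }
  if (mode == "union") {
    union_dyn <- dyn
    union_dyn$edge_activity <- matrix(TRUE, nrow = nrow(dyn$edges), ncol = L)
    union_dyn$node_activity <- matrix(TRUE, nrow = nrow(dyn$node_types), ncol = L,
                                      dimnames = dimnames(dyn$node_activity))
    ccs <- replicate(L, layer_cc(union_dyn, 1), simplify = FALSE)
  } else {
    ccs <- map(seq_len(L), function(l) layer_cc(dyn, l))
  }
  bits <- occ_bits(instances$occurrence)
  node_cc <- function(node, b) {
    mean(map_dbl(which(b), function(l) {
      v <- ccs[[l]]
      if (node %in% names(v)) v[[node]] else 0
    }))
  }
  inst <- instances
  inst$cc_X <- map2(inst$X, bits, node_cc) |> unlist()
  inst$cc_Y <- map2(inst$Y, bits, node_cc) |> unlist()
  inst$cc_Z <- map2(inst$Z, bits, node_cc) |> unlist()

  is_mirna <- setNames(dyn$node_types$node_type == "miRNA", dyn$node_types$node)
  long <- pivot_longer(inst[, c("motif_type", "X", "Y", "Z", "persistence",
                                "cc_X", "cc_Y", "cc_Z")],
                       cols = c("cc_X", "cc_Y", "cc_Z"),
                       names_to = "role", values_to = "cc")
  long$role <- sub("^cc_", "", long$role)
  base <- long |>
    group_by(.data$motif_type, .data$role, .data$persistence) |>
    summarise(mean_cc = mean(.data$cc), n_instances = n(), .groups = "drop")
  ym <- long |>
    filter(.data$motif_type %in% c("fanout", "fanin"), .data$role == "Y") |>
    filter(is_mirna[.data$Y]) |>
    group_by(.data$motif_type, .data$persistence) |>
    summarise(mean_cc = mean(.data$cc), n_instances = n(), .groups = "drop") |>
    mutate(role = "Y_miRNA")
  bind_rows(base, ym[, names(base)]) |>
    arrange(.data$motif_type, .data$role, .data$persistence)
}
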