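# Independent oracles and fixture builders shared across the suite.

# Exhaustive O(n^3) triad oracle: enumerates every unordered node triple and
# matches its induced directed edge set, via explicit role permutations,
# against the four shape definitions. Deliberately naive and independent of
# the package's lookup-table census.
oracle_census <- function(edges, node_types) {
  nodes <- node_types$node
  has <- function(u, v) any(edges$regulator == u & edges$target == v)
  shapes <- list(
    ffl = function(x, y, z) list(c(x, y), c(x, z), c(y, z)),
    fanout = function(x, y, z) list(c(x, y), c(x, z)),
    cascade = function(x, y, z) list(c(x, y), c(y, z)),
    fanin = function(x, y, z) list(c(x, z), c(y, z)))
  out <- list()
  if (length(nodes) < 3) {
    return(tibble::tibble(motif_type = character(0), members = character(0)))
  }
  triples <- utils::combn(sort(nodes), 3)
  for (t in seq_len(ncol(triples))) {
    tri <- triples[, t]
    induced <- list()
    for (u in tri) for (v in tri) {
      if (u != v && has(u, v)) induced[[length(induced) + 1]] <- c(u, v)
    }
    m <- length(induced)
    if (m < 2 || m > 3) next
    key_ind <- sort(vapply(induced, paste, character(1), collapse = ">"))
    found <- NULL
    for (shape in names(shapes)) {
      for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))) {
        want <- shapes[[shape]](tri[p[1]], tri[p[2]], tri[p[3]])
        key_want <- sort(vapply(want, paste, character(1), collapse = ">"))
        if (length(key_want) == length(key_ind) && all(key_want == key_ind)) {
          found <- shape
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      out[[length(out) + 1]] <- tibble::tibble(
        motif_type = found, members = paste(tri, collapse = "|"))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(motif_type = character(0), members = character(0)))
  }
  dplyr::bind_rows(out)
}

# Brute-force local clustering coefficient by neighbour-pair counting.
oracle_cc <- function(edges, nodes) {
  und <- unique(rbind(cbind(edges$regulator, edges$target),
                      cbind(edges$target, edges$regulator)))
  nb <- lapply(nodes, function(v) setdiff(unique(und[und[, 1] == v, 2]), v))
  names(nb) <- nodes
  linked <- function(u, v) any(und[, 1] == u & und[, 2] == v)
  vapply(nodes, function(v) {
    k <- length(nb[[v]])
    if (k < 2) return(0)
    pairs <- utils::combn(nb[[v]], 2)
    hits <- sum(vapply(seq_len(ncol(pairs)), function(j) {
      linked(pairs[1, j], pairs[2, j])
    }, logical(1)))
    hits / choose(k, 2)
  }, numeric(1))
}

# Random directed graph over typed nodes (no self-loops, no parallel edges);
# edge classes chosen to satisfy the tripartite type rules.
random_typed_digraph <- function(n, p, seed, frac_mirna = 0.3, frac_tf = 0.3) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  type <- sample(c("TF", "miRNA", "target"), n, replace = TRUE,
                 prob = c(frac_tf, frac_mirna, 1 - frac_tf - frac_mirna))
  cand <- expand.grid(i = seq_len(n), j = seq_len(n))
  cand <- cand[cand$i != cand$j, ]
  # admissible class per (regulator type, target type)
  cls <- character(nrow(cand))
  rt <- type[cand$i]; tt <- type[cand$j]
  cls[rt == "TF" & tt == "miRNA"] <- "TMI"
  cls[rt == "TF" & tt != "miRNA"] <- "TTI"
  cls[rt == "miRNA"] <- "MTI"
  keep <- cls != "" & !(cls == "MTI" & tt == "miRNA") & rt != "target"
  cand <- cand[keep, ]; cls <- cls[keep]
  sel <- runif(nrow(cand)) < p
  edges <- tibble::tibble(regulator = nodes[cand$i[sel]],
                          target = nodes[cand$j[sel]], edge_class = cls[sel])
  list(edges = edges,
       node_types = tibble::tibble(node = nodes, node_type = type))
}

# Two-block expression fixture for module recovery.
make_block_expr <- function(seed, n_block = 40, n_blocks = 2, amp = 2,
                            noise = 0.3, n_cond = 14) {
  set.seed(seed)
  shapes <- matrix(stats::rnorm(n_blocks * n_cond, sd = amp), nrow = n_blocks)
  ent <- sprintf("e%03d", seq_len(n_blocks * n_block))
  block <- rep(seq_len(n_blocks), each = n_block)
  vals <- t(vapply(seq_along(ent), function(i) {
    2^(7 + shapes[block[i], ] + stats::rnorm(n_cond, sd = noise))
  }, numeric(n_cond)))
  colnames(vals) <- sprintf("s%02d", seq_len(n_cond))
  expr <- dplyr::bind_cols(tibble::tibble(entity = ent), tibble::as_tibble(vals))
  list(expr = expr, block = block)
}

# Census output normalised for comparison against the triple oracle.
census_members <- function(cen) {
  if (nrow(cen) == 0) {
    return(tibble::tibble(motif_type = character(0), members = character(0)))
  }
  tibble::tibble(motif_type = cen$motif_type,
                 members = vapply(seq_len(nrow(cen)), function(i) {
                   paste(sort(c(cen$X[i], cen$Y[i], cen$Z[i])), collapse = "|")
                 }, character(1)))
}

sort_tbl <- function(x) x[do.call(order, as.list(x)), ]

# Hand-built sparse count matrix from a list of named gene -> count vectors.
make_counts <- function(cells) {
  genes <- sort(unique(unlist(lapply(cells, names))))
  m <- sapply(cells, function(v) {
    out <- stats::setNames(numeric(length(genes)), genes)
    out[names(v)] <- v
    out
  })
  rownames(m) <- genes
  colnames(m) <- sprintf("cell%02d", seq_along(cells))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}
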