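# Synthetic-data generators. Every downstream stage of the package is
# exercised against data produced here, with planted ground truth: temporal
# response classes for the DE classifier, planted motifs and expression
# archetypes for the network/motif/co-expression stages, and planted
# responsive pri-miRNA triples for the single-cell stage.

temporal_class_vocabulary <- function(time_points = default_time_points()) {
  c(paste0("only_", hour_label(time_points)), "early", "late", "dynamic", "robust")
}

#' Simulation configuration
#'
#' Bundles every tunable of the three generators. Defaults describe a
#' hormone time-course design: seven time points (0.5-24 h), treatment and
#' mock arms with 3 replicates, a planted DE effect of 3 log2 units over
#' replicate noise of 0.1 log2 units, and a tripartite network with planted
#' three-node motifs whose members share expression archetypes with a
#' per-motif-type coupling probability.
#'
#' @param seed integer seed; the generators are fully deterministic given
#'   the config.
#' @param time_points strictly increasing hours.
#' @param n_replicates replicates per arm per time point (>= 2).
#' @param n_tfs,n_mirnas,n_targets node pool sizes for the network and the
#'   number of entities simulated in each kind.
#' @param class_proportions named fractions over the temporal class
#'   vocabulary (must sum to 1).
#' @param effect_log2fc planted |log2 fold change| at a DE entity's class
#'   time points.
#' @param noise_sd replicate noise SD on the log2 scale.
#' @param baseline_range log2 abundance baseline range (uniform).
#' @param n_planted_motifs named counts per motif type
#'   (`ffl`, `fanout`, `cascade`, `fanin`).
#' @param coexpr_coupling named probabilities in `[0,1]` per motif type that
#'   a planted motif's X, Y, Z share one expression archetype.
#' @param background_density probability of each admissible background edge.
#' @param n_archetypes number of distinct expression archetypes.
#' @param archetype_amplitude SD (log2) of archetype temporal shapes; sets
#'   the within-archetype correlation against `noise_sd`.
#' @param cell_config list from [cell_sim_config()].
#' @return a list of class `mdn_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       time_points = default_time_points(),
                       n_replicates = 3,
                       n_tfs = 10, n_mirnas = 40, n_targets = 150,
                       class_proportions = NULL,
                       effect_log2fc = 3,
                       noise_sd = 0.1,
                       baseline_range = c(5, 10),
                       n_planted_motifs = c(ffl = 20, fanout = 10, cascade = 10, fanin = 10),
                       coexpr_coupling = c(ffl = 0.8, fanout = 0, cascade = 0.6, fanin = 0),
                       background_density = 0.01,
                       n_archetypes = 6,
                       archetype_amplitude = 2,
                       cell_config = cell_sim_config()) {
  if (is.unsorted(time_points, strictly = TRUE)) {
    abort("time_points must be strictly increasing")
  }
  if (n_replicates < 2) abort("n_replicates must be >= 2 (DE testing needs replication)")
  vocab <- temporal_class_vocabulary(time_points)
  if (is.null(class_proportions)) {
    class_proportions <- c(setNames(rep(0.05, length(time_points)),
                                    paste0("only_", hour_label(time_points))),
                           early = 0.15, late = 0.15, dynamic = 0.15, robust = 0.20)
  }
  bad <- setdiff(names(class_proportions), vocab)
  if (length(bad) > 0) {
    abort(sprintf("invalid temporal class label(s) in class_proportions: %s",
                  paste(bad, collapse = ", ")))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("class_proportions must sum to 1")
  }
  if (any(c(n_tfs, n_mirnas, n_targets) < 0)) abort("node counts must be >= 0")
  assert_scalar_num(effect_log2fc, "effect_log2fc", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 1e-12)
  for (m in names(coexpr_coupling)) {
    assert_scalar_num(coexpr_coupling[[m]], paste0("coexpr_coupling[", m, "]"),
                      lower = 0, upper = 1)
  }
  structure(list(seed = as.integer(seed), time_points = time_points,
                 n_replicates = as.integer(n_replicates),
                 n_tfs = as.integer(n_tfs), n_mirnas = as.integer(n_mirnas),
                 n_targets = as.integer(n_targets),
                 class_proportions = class_proportions,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 n_planted_motifs = n_planted_motifs,
                 coexpr_coupling = coexpr_coupling,
                 background_density = background_density,
                 n_archetypes = as.integer(n_archetypes),
                 archetype_amplitude = archetype_amplitude,
                 cell_config = cell_config),
            class = "mdn_sim_config")
}

#' Single-cell simulation configuration
#'
#' Negative-binomial count model over a (cell type x condition) design with
#' low-abundance pri-miRNA genes, mitochondrial/chloroplast genes for QC
#' covariates, planted multiplicative responses, and a planted fraction of
#' QC-violating cells (inflated mitochondrial content).
#'
#' @param cell_types,conditions group labels; the first condition is the
#'   mock/reference.
#' @param cells_per_group cells per (cell type, condition) group.
#' @param n_genes ordinary genes; @param n_primirna pri-miRNA genes;
#'   @param n_mito,n_pt organellar genes (`ATMG`/`ATCG` prefixes).
#' @param gene_mean_meanlog,gene_mean_sdlog log-normal law of per-gene mean
#'   counts per cell.
#' @param primirna_mean mean counts per cell for pri-miRNA genes (low).
#' @param mito_mean,pt_mean mean counts per cell per organellar gene.
#' @param nb_dispersion NB dispersion (`size = 1/dispersion`); must be > 0.
#' @param planted_shifts tibble(`gene`, `cell_type`, `condition`, `fold`)
#'   of multiplicative mean shifts, or NULL.
#' @param qc_violation_frac fraction of cells given a mitochondrial load
#'   far above any sane QC cutoff.
#' @return a list of class `mdn_cell_config`.
#' @export
cell_sim_config <- function(cell_types = paste0("ct", 1:9),
                            conditions = c("Mock", "ABA0.5h", "ABA1h", "ABA6h", "ABA12h"),
                            cells_per_group = 40,
                            n_genes = 200, n_primirna = 40,
                            n_mito = 5, n_pt = 5,
                            gene_mean_meanlog = 0, gene_mean_sdlog = 1,
                            primirna_mean = 0.1,
                            mito_mean = 0.5, pt_mean = 0.5,
                            nb_dispersion = 0.5,
                            planted_shifts = NULL,
                            qc_violation_frac = 0) {
  if (length(cell_types) < 2 || length(conditions) < 2) {
    abort("need at least 2 cell types and 2 conditions")
  }
  if (nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  assert_scalar_num(qc_violation_frac, "qc_violation_frac", lower = 0, upper = 1)
  structure(list(cell_types = cell_types, conditions = conditions,
                 cells_per_group = as.integer(cells_per_group),
                 n_genes = as.integer(n_genes), n_primirna = as.integer(n_primirna),
                 n_mito = as.integer(n_mito), n_pt = as.integer(n_pt),
                 gene_mean_meanlog = gene_mean_meanlog,
                 gene_mean_sdlog = gene_mean_sdlog,
                 primirna_mean = primirna_mean,
                 mito_mean = mito_mean, pt_mean = pt_mean,
                 nb_dispersion = nb_dispersion,
                 planted_shifts = planted_shifts,
                 qc_violation_frac = qc_violation_frac),
            class = "mdn_cell_config")
}

#' Time points at which a planted temporal class is differentially expressed
#'
#' The planted-class-to-time-point map mirrors the classifier's own rule
#' set so that label recovery is well defined: singletons occupy their one
#' time point, `early` the 0.5/1/3 h window, `late` the 9/12/24 h window,
#' `robust` all seven, and `dynamic` a fixed pattern spanning both windows
#' without qualifying for either (0.5, 6 and 24 h).
#'
#' @param class a temporal class label.
#' @param time_points the configured time points.
#' @return logical vector over `time_points`.
#' @export
temporal_class_bits <- function(class, time_points = default_time_points()) {
  if (startsWith(class, "only_")) {
    tp <- sub("h$", "", sub("^only_", "", class))
    return(time_points == as.numeric(tp))
  }
  switch(class,
         early = time_points %in% c(0.5, 1, 3),
         late = time_points %in% c(9, 12, 24),
         dynamic = time_points %in% c(0.5, 6, 24),
         robust = rep(TRUE, length(time_points)),
         abort(sprintf("unknown temporal class '%s'", class)))
}

sample_classes <- function(n, proportions) {
  sample(names(proportions), n, replace = TRUE, prob = unname(proportions))
}

#' Simulate replicated treatment/mock time-series expression
#'
#' Log-normal abundance model: each entity has a log2 baseline drawn
#' uniformly from `baseline_range`; the mock arm is stationary around it;
#' the treatment arm adds `effect_log2fc` (random sign per entity) at
#' exactly the time points its planted temporal class prescribes. An
#' entity's archetype contributes a shared temporal shape to both arms, so
#' co-expression structure is planted without disturbing fold changes.
#' Replicate noise is additive Gaussian on the log2 scale.
#'
#' @param config a [sim_config()].
#' @param nodes optional tibble (`entity`, `kind`, `class`, `archetype`)
#'   from [simulate_network()]'s ground truth; when NULL, miRNA and target
#'   entities are created and assigned classes by `class_proportions`.
#' @return list with `expr` (tibble), `meta` (sample sheet tibble) and
#'   `truth` (tibble `entity`, `kind`, `class`, `direction`, `archetype`).
#' @examples
#' sim <- simulate_timeseries(sim_config(seed = 1, n_targets = 10, n_mirnas = 5))
#' head(sim$truth)
#' @export
simulate_timeseries <- function(config, nodes = NULL) {
  stopifnot(inherits(config, "mdn_sim_config"))
  set.seed(config$seed)
  tps <- config$time_points
  if (is.null(nodes)) {
    nodes <- tibble(
      entity = c(sprintf("miR%03d", seq_len(config$n_mirnas)),
                 sprintf("g%04d", seq_len(config$n_targets))),
      kind = c(rep("miRNA", config$n_mirnas), rep("target", config$n_targets)))
    nodes$class <- sample_classes(nrow(nodes), config$class_proportions)
    nodes$archetype <- sample.int(config$n_archetypes, nrow(nodes), replace = TRUE)
  } else {
    assert_columns(nodes, c("entity", "kind", "class", "archetype"), "nodes table")
  }
  n <- nrow(nodes)
  reps <- seq_len(config$n_replicates)
  meta <- tidyr::expand_grid(arm = c("treatment", "mock"), time_point = tps,
                             replicate = reps)
  meta$sample <- sprintf("%s_%s_r%d", ifelse(meta$arm == "treatment", "treat", "mock"),
                         hour_label(meta$time_point), meta$replicate)
  meta <- meta[, c("sample", "arm", "time_point", "replicate")]

  baseline <- runif(n, config$baseline_range[1], config$baseline_range[2])
  direction <- sample(c(1, -1), n, replace = TRUE)
  # archetype temporal shapes: mutually orthogonal (when they fit in the
  # time dimension) so distinct archetypes are uncorrelated by construction
  K <- config$n_archetypes
  raw <- matrix(rnorm(length(tps) * K), nrow = length(tps))
  if (K <= length(tps)) raw <- qr.Q(qr(raw))
  shapes <- t(apply(raw, 2, function(s) {
    (s - mean(s)) / sd(s) * config$archetype_amplitude
  }))
  bits <- t(vapply(nodes$class, temporal_class_bits, logical(length(tps)),
                   time_points = tps))

  vals <- matrix(0, nrow = n, ncol = nrow(meta),
                 dimnames = list(nodes$entity, meta$sample))
  for (j in seq_len(nrow(meta))) {
    ti <- match(meta$time_point[j], tps)
    mu <- baseline + shapes[cbind(nodes$archetype, ti)]
    if (meta$arm[j] == "treatment") {
      mu <- mu + direction * config$effect_log2fc * bits[, ti]
    }
    vals[, j] <- 2^(mu + rnorm(n, sd = config$noise_sd))
  }
  expr <- bind_cols(tibble(entity = nodes$entity), as_tibble(vals))
  truth <- mutate(nodes, direction = ifelse(direction > 0, "up", "down"))
  list(expr = expr, meta = meta, truth = truth)
}

motif_edges <- function(type, x, y, z) {
  switch(type,
         ffl = tibble(regulator = c(x, x, y), target = c(y, z, z),
                      edge_class = c("TMI", "TTI", "MTI")),
         fanout = tibble(regulator = c(x, x), target = c(y, z),
                         edge_class = c("TMI", "TTI")),
         cascade = tibble(regulator = c(x, y), target = c(y, z),
                          edge_class = c("TMI", "MTI")),
         fanin = tibble(regulator = c(x, y), target = c(z, z),
                        edge_class = c("TTI", "MTI")),
         abort(sprintf("unknown motif type '%s'", type)))
}

#' Simulate a tripartite regulatory network with planted motifs
#'
#' Plants the requested number of each motif shape (X a TF, Y a miRNA, Z a
#' target gene) on disjoint node triples while pools last, reusing nodes
#' only when counts demand; adds background edges uniformly within each
#' edge class at `background_density`; and assigns every node a temporal
#' class and an expression archetype. With coupling probability `c` for a
#' motif type, a planted motif's three members share one archetype;
#' otherwise each member draws its own.
#'
#' @param config a [sim_config()].
#' @return list with `edges`, `node_types`, and `truth` (list of `nodes`
#'   and `motifs` tibbles; `motifs` has `motif_type`, `X`, `Y`, `Z`,
#'   `coupled`, `archetype`).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "mdn_sim_config"))
  set.seed(config$seed + 1L)
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  mirnas <- sprintf("miR%03d", seq_len(config$n_mirnas))
  targets <- sprintf("g%04d", seq_len(config$n_targets))
  counts <- config$n_planted_motifs
  total <- sum(counts)
  if (total > config$n_tfs * config$n_mirnas * config$n_targets) {
    abort("requested planted motifs exceed available node triples")
  }
  if (total > 0 && (config$n_tfs < 1 || config$n_mirnas < 1 || config$n_targets < 1)) {
    abort("planting motifs requires at least one node of each kind")
  }
  # disjoint triples while pools last; after that, draw distinct triples
  # uniformly from the remaining combinations (nodes may repeat, triples not)
  xs <- ys <- zs <- character(0)
  if (total > 0) {
    k_dis <- min(total, config$n_tfs, config$n_mirnas, config$n_targets)
    xs <- sample(tfs)[seq_len(k_dis)]
    ys <- sample(mirnas)[seq_len(k_dis)]
    zs <- sample(targets)[seq_len(k_dis)]
    used <- new.env(hash = TRUE)
    for (i in seq_len(k_dis)) {
      assign(paste(xs[i], ys[i], zs[i], sep = "\r"), TRUE, envir = used)
    }
    while (length(xs) < total) {
      x <- sample(tfs, 1); y <- sample(mirnas, 1); z <- sample(targets, 1)
      key <- paste(x, y, z, sep = "\r")
      if (exists(key, envir = used, inherits = FALSE)) next
      assign(key, TRUE, envir = used)
      xs <- c(xs, x); ys <- c(ys, y); zs <- c(zs, z)
    }
  }
  types <- rep(names(counts), times = counts)
  motifs <- tibble(motif_type = types, X = xs, Y = ys, Z = zs)
  coupling <- config$coexpr_coupling
  motifs$coupled <- runif(nrow(motifs)) < coupling[match(motifs$motif_type, names(coupling))]
  motifs$coupled[is.na(motifs$coupled)] <- FALSE
  motifs$archetype <- ifelse(motifs$coupled,
                             sample.int(config$n_archetypes, nrow(motifs), replace = TRUE),
                             NA_integer_)

  planted <- list_rbind(pmap(motifs[, c("motif_type", "X", "Y", "Z")],
                             function(motif_type, X, Y, Z) motif_edges(motif_type, X, Y, Z)))
  planted <- distinct(planted)

  # background edges sampled uniformly within each edge class
  bg <- list()
  if (config$background_density > 0) {
    cand <- bind_rows(
      tidyr::expand_grid(regulator = tfs, target = c(tfs, targets), edge_class = "TTI"),
      tidyr::expand_grid(regulator = tfs, target = mirnas, edge_class = "TMI"),
      tidyr::expand_grid(regulator = mirnas, target = targets, edge_class = "MTI"))
    cand <- filter(cand, .data$regulator != .data$target)
    keep <- runif(nrow(cand)) < config$background_density
    bg <- cand[keep, ]
  }
  edges <- distinct(bind_rows(planted, bg))
  edges <- edges[!duplicated(edges[, c("regulator", "target")]), ]

  nodes <- tibble(entity = c(tfs, mirnas, targets),
                  kind = c(rep("TF", length(tfs)), rep("miRNA", length(mirnas)),
                           rep("target", length(targets))))
  nodes$class <- sample_classes(nrow(nodes), config$class_proportions)
  nodes$archetype <- sample.int(config$n_archetypes, nrow(nodes), replace = TRUE)
  for (i in seq_len(nrow(motifs))) {
    if (motifs$coupled[i]) {
      members <- c(motifs$X[i], motifs$Y[i], motifs$Z[i])
      nodes$archetype[nodes$entity %in% members] <- motifs$archetype[i]
    }
  }
  node_types <- infer_node_types(edges, source = "simulated network")
  list(edges = edges, node_types = node_types,
       truth = list(nodes = nodes, motifs = motifs))
}

#' Simulate a sparse single-cell count matrix with planted responses
#'
#' Negative-binomial counts over (cell type x condition) groups. Ordinary
#' genes draw log-normal mean abundances; pri-miRNA genes sit at a low
#' mean; mitochondrial (`ATMG*`) and chloroplast (`ATCG*`) genes provide QC
#' covariates. Each planted (gene, cell type, condition) triple multiplies
#' that group's mean; a planted fraction of cells gets mitochondrial
#' content far above the usual 10% QC bound.
#'
#' @param config a [sim_config()] (uses its `seed` and `cell_config`).
#' @return list with `counts` (dgCMatrix, features x cells), `meta`
#'   (tibble `barcode`, `cell_type`, `condition`), `annotation` (tibble of
#'   pri-miRNA gene IDs) and `truth` (planted shifts and QC violators).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "mdn_sim_config"))
  cc <- config$cell_config
  set.seed(config$seed + 2L)
  genes <- sprintf("gene%05d", seq_len(cc$n_genes))
  pri <- sprintf("pri-miR%03d", seq_len(cc$n_primirna))
  mito <- sprintf("ATMG%05d", seq_len(cc$n_mito))
  pt <- sprintf("ATCG%05d", seq_len(cc$n_pt))
  features <- c(genes, pri, mito, pt)
  base_mean <- c(exp(rnorm(cc$n_genes, cc$gene_mean_meanlog, cc$gene_mean_sdlog)),
                 rep(cc$primirna_mean, cc$n_primirna),
                 rep(cc$mito_mean, cc$n_mito),
                 rep(cc$pt_mean, cc$n_pt))
  groups <- tidyr::expand_grid(cell_type = cc$cell_types, condition = cc$conditions)
  size <- 1 / cc$nb_dispersion

  blocks <- vector("list", nrow(groups))
  metas <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    mu <- base_mean
    if (!is.null(cc$planted_shifts)) {
      hits <- filter(cc$planted_shifts,
                     .data$cell_type == groups$cell_type[g],
                     .data$condition == groups$condition[g])
      if (nrow(hits) > 0) {
        idx <- match(hits$gene, features)
        mu[idx] <- mu[idx] * hits$fold
      }
    }
    m <- matrix(rnbinom(length(features) * cc$cells_per_group,
                        mu = mu, size = size),
                nrow = length(features))
    blocks[[g]] <- m
    metas[[g]] <- tibble(cell_type = groups$cell_type[g],
                         condition = groups$condition[g],
                         n = cc$cells_per_group)
  }
  counts <- do.call(cbind, blocks)
  meta <- list_rbind(map(metas, function(m) {
    tibble(cell_type = rep(m$cell_type, m$n), condition = rep(m$condition, m$n))
  }))
  meta$barcode <- sprintf("cell%05d", seq_len(nrow(meta)))
  meta <- meta[, c("barcode", "cell_type", "condition")]
  colnames(counts) <- meta$barcode
  rownames(counts) <- features

  violators <- character(0)
  if (cc$qc_violation_frac > 0) {
    n_bad <- round(cc$qc_violation_frac * nrow(meta))
    bad <- sample(meta$barcode, n_bad)
    # inflate mitochondrial load well past any sane max_mito_frac bound
    tot <- colSums(counts[, bad, drop = FALSE])
    counts[mito[1], bad] <- counts[mito[1], bad] + pmax(20, ceiling(tot))
    violators <- bad
  }
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  list(counts = counts, meta = meta,
       annotation = tibble(gene = pri),
       truth = list(planted_shifts = cc$planted_shifts, qc_violators = violators,
                    mito_genes = mito, pt_genes = pt))
}

#' Simulate a crosstalk-graded feed-forward-loop design
#'
#' Builds a deterministic dynamic network in which planted FFL persistence
#' increases together with planted Y-node crosstalk, for studying how motif
#' neighbourhood density relates to temporal persistence. Persistence class
#' `p` (1..7) consists of `p` FFLs sharing one miRNA Y: `p` TFs X_i and `p`
#' TF-typed targets Z_j, with all X-X, X-Z and Z-Z pairs co-regulated (so X
#' and Z neighbourhoods are saturated in every class) and `7 - p` dangling
#' miRNA targets diluting Y's neighbourhood in low-persistence classes. All
#' members of class `p` are active in the first `p` layers.
#'
#' @param time_points layer time points (default 7).
#' @return list with `edges`, `node_types` and `activity` (tibble `entity`,
#'   `occurrence` over layers).
#' @export
simulate_crosstalk_design <- function(time_points = default_time_points()) {
  L <- length(time_points)
  edges <- list(); activity <- list()
  for (p in seq_len(L)) {
    y <- sprintf("miR_p%d", p)
    xs <- sprintf("TF_p%d_x%d", p, seq_len(p))
    zs <- sprintf("ZT_p%d_z%d", p, seq_len(p))
    dang <- if (p < L) sprintf("gD_p%d_%d", p, seq_len(L - p)) else character(0)
    e <- bind_rows(
      tibble(regulator = xs, target = y, edge_class = "TMI"),
      tibble(regulator = y, target = zs, edge_class = "MTI"),
      tidyr::expand_grid(regulator = xs, target = zs) |> mutate(edge_class = "TTI"),
      if (p > 1) {
        pairs <- tidyr::expand_grid(regulator = xs, target = xs) |>
          filter(.data$regulator != .data$target) |> mutate(edge_class = "TTI")
        zpairs <- tidyr::expand_grid(regulator = zs, target = zs) |>
          filter(.data$regulator != .data$target) |> mutate(edge_class = "TTI")
        bind_rows(pairs, zpairs)
      },
      if (length(dang) > 0) tibble(regulator = y, target = dang, edge_class = "MTI"))
    edges[[p]] <- e
    mask <- paste(as.integer(seq_len(L) <= p), collapse = "")
    activity[[p]] <- tibble(entity = c(y, xs, zs, dang), occurrence = mask)
  }
  edges <- distinct(list_rbind(edges))
  node_types <- infer_node_types(edges, source = "crosstalk design")
  list(edges = edges, node_types = node_types, activity = list_rbind(activity))
}

#' Convert an activity table to a DE-table stand-in
#'
#' Turns per-entity occurrence masks into the minimal `mdn_de` table that
#' [build_dynamic()] consumes (log2fc set to the effect's sign pattern is
#' not needed; only `is_de` drives layer activity).
#'
#' @param activity tibble with `entity` and `occurrence` (0/1 string per
#'   layer).
#' @param time_points layer time points.
#' @return an `mdn_de`-classed tibble.
#' @export
activity_to_de <- function(activity, time_points = default_time_points()) {
  bits <- occ_bits(activity$occurrence)
  de <- list_rbind(map2(activity$entity, bits, function(e, b) {
    tibble(entity = e, time_point = time_points, log2fc = ifelse(b, 1, 0),
           p = ifelse(b, 1e-9, 1), q = ifelse(b, 1e-9, 1),
           is_de = b, direction = "up")
  }))
  structure(de, class = c("mdn_de", class(de)),
            time_points = time_points, kind = "gene", config = de_config())
}
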