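#' Run the full synthetic-data analysis pipeline
#'
#' One-command orchestration: simulate a tripartite network, time-series
#' expression and single-cell counts from one configuration, then run
#' differential expression and temporal classification, dynamic-network
#' assembly and rewiring scores, the motif census with enrichment,
#' co-expression modules with the XYZ ratio statistic, and the single-cell
#' pri-miRNA stage. Identical config and seed give an identical report.
#'
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param out_dir optional directory; when given, stage outputs are
#'   written as TSV/JSON as they complete.
#' @param n_random null networks for motif enrichment.
#' @return a list of class `mdn_report` with one element per stage
#'   (`simulate`, `de`, `network`, `motifs`, `coexpress`, `sc`), each
#'   carrying its main result objects and a `summary` list of key counts.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, n_random = 200) {
  stopifnot(inherits(config, "mdn_sim_config"))
  save <- function(obj, name) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      readr::write_tsv(obj, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim <- stage("simulate", function() {
    net <- simulate_network(config)
    ts <- simulate_timeseries(config, nodes = net$truth$nodes)
    cells <- simulate_cells(config)
    list(net = net, ts = ts, cells = cells)
  })
  if (!is.null(out_dir)) {
    write_edges(sim$net$edges, file.path(out_dir, "edges.tsv"))
    write_expression(sim$ts$expr, sim$ts$meta,
                     file.path(out_dir, "expression.tsv"),
                     file.path(out_dir, "samples.tsv"))
  }

  de <- stage("de", function() {
    kinds <- sim$ts$truth$kind
    mir <- sim$ts$expr[kinds == "miRNA", ]
    gen <- sim$ts$expr[kinds != "miRNA", ]
    parts <- list()
    if (nrow(gen) > 0) parts$gene <- call_de(gen, sim$ts$meta, kind = "gene")
    if (nrow(mir) > 0) parts$mirna <- call_de(mir, sim$ts$meta, kind = "mirna")
    combined <- list_rbind(parts)
    combined <- structure(combined, class = c("mdn_de", class(combined)),
                          time_points = config$time_points, kind = "mixed",
                          config = de_config())
    classes <- classify_temporal(combined)
    list(table = combined, classes = classes,
         correlation = timepoint_correlation(combined))
  })
  save(de$table, "de")
  save(de$classes, "temporal_classes")

  network <- stage("network", function() {
    net <- assemble_static(sim$net$edges)
    dyn <- build_dynamic(net, de$table, tf_policy = "always_active")
    scores <- dn_score(dyn)
    list(static = net, dynamic = dyn, dn = scores,
         top = rank_dynamic_nodes(scores, k = min(100, nrow(scores))))
  })
  save(network$dn, "dn_scores")

  motifs <- stage("motifs", function() {
    instances <- census_dynamic(network$dynamic)
    enrich <- motif_enrichment(network$static, n_random = n_random,
                               seed = config$seed)
    ffls <- filter(instances, .data$motif_type == "ffl")
    list(instances = instances, enrichment = enrich,
         coherence = pair_coherence(instances, de$table, network$static),
         crosstalk = crosstalk_degree(ffls),
         cc_profile = role_cc_profile(network$dynamic, instances))
  })
  save(motifs$instances, "motif_instances")
  save(motifs$enrichment, "motif_enrichment")

  coexpress <- stage("coexpress", function() {
    modules <- build_modules(sim$ts$expr, sim$ts$meta,
                             coexpress_config(min_module_size = 10))
    ratios <- xyz_ratio(motifs$instances, modules)
    list(modules = modules, ratios = ratios)
  })
  save(coexpress$modules, "modules")

  sc <- stage("sc", function() {
    qc <- qc_filter_cells(sim$cells$counts, sim$cells$meta,
                          cell_qc_config(min_genes = 10, min_umis = 10))
    pb <- pseudobulk(qc$counts, qc$meta)
    prof <- primirna_profile(pb, sim$cells$annotation)
    list(qc_report = qc$report, pseudobulk = pb, profile = prof)
  })
  save(sc$qc_report, "qc_report")

  report <- list(
    simulate = list(summary = list(
      n_nodes = nrow(sim$net$truth$nodes), n_edges = nrow(sim$net$edges),
      n_cells = ncol(sim$cells$counts))),
    de = list(table = de$table, classes = de$classes,
              correlation = de$correlation,
              summary = list(n_de_entities = length(unique(de$table$entity[de$table$is_de])),
                             class_counts = as.list(table(de$classes$class)))),
    network = c(network, list(summary = list(
      n_retained = nrow(network$dynamic$node_types),
      mean_dn = mean(network$dn$dn_raw)))),
    motifs = c(motifs, list(summary = list(
      instance_counts = as.list(table(motifs$instances$motif_type)),
      enrichment_z = setNames(as.list(motifs$enrichment$z),
                              motifs$enrichment$motif_type)))),
    coexpress = c(coexpress, list(summary = list(
      n_modules = sum(attr(coexpress$modules, "module_sizes") > 0),
      ratio_xyz = setNames(as.list(coexpress$ratios$by_type$ratio_xyz),
                           coexpress$ratios$by_type$motif_type)))),
    sc = c(sc, list(summary = list(
      retained_cells = sc$qc_report$n_cells[sc$qc_report$criterion == "retained"],
      n_groups = nrow(sc$pseudobulk$groups)))))
  report$seed <- config$seed
  class(report) <- "mdn_report"
  if (!is.null(out_dir)) {
    summaries <- map(report[setdiff(names(report), "seed")], "summary")
    jsonlite::write_json(summaries, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.mdn_report <- function(x, ...) {
  cat("mdn_report (seed", x$seed, ")\n")
  for (s in setdiff(names(x), "seed")) {
    cat(sprintf("  %-10s %s\n", s,
                paste(names(x[[s]]$summary), collapse = ", ")))
  }
  invisible(x)
}
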