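# Config-driven orchestration: synthetic inputs -> repertoire statistics ->
# overlap/TVI -> expression screen -> network module -> survival.
# Stages communicate only via files in the output directory, so each stage
# can be re-run and audited independently; all randomness flows from the
# single top-level seed through fixed per-stage offsets.

#' Default pipeline configuration
#'
#' A plain list (serializable to JSON) holding every threshold of the
#' analysis plus the synthetic-generation block. Override any entry with
#' `pipeline_config(seed = 7, fdr_threshold = 0.1, ...)`.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    outdir = "tvinet_run",
    top_n = 100,
    fdr_threshold = 0.05,
    textmining_min = 200,
    combined_min = 400,
    rho_min = 0.5,
    top_fraction = 0.05,
    k_min = 3,
    clustering_distance = "euclidean",
    clustering_linkage = "average",
    stages = c("simulate", "repstats", "tvi", "screen", "network", "survive"),
    synthetic = list(
      n_pairs_per_stage = 8,
      n_genes = 1000, n_pos = 50, n_neg = 50,
      effect = 1, noise_sd = 0.5,
      planted_module_size = 11, planted_k = 5,
      background_edge_prob = 0.05,
      n_per_group = 50, hazard_ratio = 3,
      baseline_hazard = 0.1, censoring_rate = 0.02,
      separation = 2))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(cfg), names(cfg$synthetic)))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    for (nm in intersect(names(over), names(cfg$synthetic)))
      cfg$synthetic[[nm]] <- over[[nm]]
    for (nm in intersect(names(over), names(cfg)))
      cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with (a subset of) the [pipeline_config()] entries.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

stage_seed <- function(cfg, offset) as.integer(cfg$seed) + offset * 10000L

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing per-stage TSV/JSON
#' artifacts under `cfg$outdir` plus a JSON run report (parameter echo,
#' per-stage record counts, artifact list). Rerunning with the same config
#' and seed reproduces byte-identical tabular outputs.
#'
#' Stage artifacts: `pairs/` (clonotype tables), `repertoire_stats.tsv`,
#' `cumulative_curves.tsv`, `tvi_table.tsv`, `gene_screen.tsv`,
#' `ppi_edges.tsv`, `network_report.json`, `module_genes.txt`,
#' `survival.tsv`, `km_curves.tsv`, `logrank.json`, `run_report.json`.
#'
#' @param cfg a [pipeline_config()] (or path to a JSON config).
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "pairs"), showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("tvinet")),
                 seed = cfg$seed, config = unclass(cfg), stages = list())
  syn <- cfg$synthetic
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$stages[[name]] <<- res
    invisible(NULL)
  }

  run_stage("simulate", function() {
    stages <- c("LGIN", "HGIN", "EGC")
    pairs <- list()
    i <- 0L
    for (st in stages) for (r in seq_len(syn$n_pairs_per_stage)) {
      i <- i + 1L
      pid <- sprintf("P%s%02d", substr(st, 1L, 1L), r)
      pr <- simulate_paired_repertoires(stage_preset(st), patient_id = pid,
                                        seed = stage_seed(cfg, 1L) + i)
      write_clonotype_table(pr$lesion,
                            file.path(outdir, "pairs", paste0(pid, "_lesion.tsv")))
      write_clonotype_table(pr$adjacent,
                            file.path(outdir, "pairs", paste0(pid, "_adjacent.tsv")))
      pairs[[pid]] <- pr
    }
    state$pairs <- pairs
    list(n_pairs = length(pairs))
  })

  run_stage("repstats", function() {
    if (is.null(state$pairs)) stop("no repertoire pairs available (enable 'simulate')")
    reps <- unlist(lapply(state$pairs, function(p) list(p$lesion, p$adjacent)),
                   recursive = FALSE)
    stats_rows <- lapply(reps, function(r) {
      d <- shannon_diversity(r)
      data.frame(sample_id = attr(r, "sample_id"), stage = attr(r, "stage"),
                 richness = d$richness, shannon = d$shannon,
                 normalized_shannon = d$normalized_shannon,
                 top100_cum_freq = sum(top_clones(r, cfg$top_n)$freq))
    })
    write_tsv(do.call(rbind, stats_rows), file.path(outdir, "repertoire_stats.tsv"))
    curves <- lapply(reps, function(r) {
      cc <- cumulative_frequency_curve(r, cfg$top_n)
      cbind(sample_id = attr(r, "sample_id"), cc)
    })
    write_tsv(do.call(rbind, curves), file.path(outdir, "cumulative_curves.tsv"))
    list(n_samples = length(reps))
  })

  run_stage("tvi", function() {
    if (is.null(state$pairs)) stop("no repertoire pairs available (enable 'simulate')")
    tab <- tvi_table(state$pairs, n = cfg$top_n)
    write_tsv(tab, file.path(outdir, "tvi_table.tsv"))
    state$tvi <- stats::setNames(tab$tvi, tab$patient_id)
    list(n_pairs = nrow(tab), mean_tvi_by_stage =
           as.list(tapply(tab$tvi, tab$stage, mean)))
  })

  run_stage("screen", function() {
    if (is.null(state$tvi)) stop("no TVI values available (enable 'tvi')")
    sim <- simulate_expression(state$tvi, n_genes = syn$n_genes,
                               n_pos = syn$n_pos, n_neg = syn$n_neg,
                               effect = syn$effect, noise_sd = syn$noise_sd,
                               seed = stage_seed(cfg, 2L))
    state$expr <- sim$expr
    state$expr_truth <- sim$truth
    res <- correlate_with_tvi(sim$expr, state$tvi,
                              fdr_threshold = cfg$fdr_threshold)
    write_tsv(res, file.path(outdir, "gene_screen.tsv"))
    sets <- partition_gene_sets(res, cfg$fdr_threshold)
    state$gene_sets <- sets
    list(n_genes = nrow(res), n_positive = length(sets$positive),
         n_negative = length(sets$negative))
  })

  run_stage("network", function() {
    if (is.null(state$gene_sets)) stop("no gene universe available (enable 'screen')")
    universe <- c(state$gene_sets$positive, state$gene_sets$negative)
    if (length(universe) < cfg$synthetic$planted_module_size)
      stop("gene universe too small for network stage")
    # plant the module inside the positively correlated set: co-regulated
    # genes are mutually co-expressed, so the module survives the rho filter
    sim <- simulate_ppi(c(state$gene_sets$positive, state$gene_sets$negative),
                        planted_module_size = syn$planted_module_size,
                        planted_k = syn$planted_k,
                        background_edge_prob = syn$background_edge_prob,
                        seed = stage_seed(cfg, 3L))
    write_tsv(sim$edges, file.path(outdir, "ppi_edges.tsv"))
    g <- filter_string_edges(sim$edges, cfg$textmining_min, cfg$combined_min,
                             gene_universe = universe)
    g <- filter_edges_by_coexpression(g, state$expr, rho_min = cfg$rho_min)
    g <- maximal_connected_subnetwork(g)
    sf <- tryCatch(scale_free_fit(g), error = function(e) NULL)
    hub <- hub_network(g, top_fraction = cfg$top_fraction)
    mod <- select_module(hub, k_min = cfg$k_min)
    state$module <- mod$selected_module
    writeLines(mod$selected_module, file.path(outdir, "module_genes.txt"))
    rep <- list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
                scale_free_r_squared = if (is.null(sf)) NA else sf$r_squared,
                n_hub_nodes = sum(igraph::V(hub)$is_hub),
                k = mod$k,
                communities = mod$communities,
                selected_module = mod$selected_module,
                planted_module = sim$truth$planted_module)
    jsonlite::write_json(rep, file.path(outdir, "network_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    rep[c("n_nodes", "n_edges", "k")]
  })

  run_stage("survive", function() {
    if (is.null(state$module) || length(state$module) == 0L)
      stop("no gene module available (enable 'network')")
    surv <- simulate_survival(n_per_group = syn$n_per_group,
                              hazard_ratio = syn$hazard_ratio,
                              baseline_hazard = syn$baseline_hazard,
                              censoring_rate = syn$censoring_rate,
                              seed = stage_seed(cfg, 4L))
    truth <- stats::setNames(surv$group, surv$sample_id)
    expr <- simulate_signature_expression(truth, genes = state$module,
                                          separation = syn$separation,
                                          seed = stage_seed(cfg, 5L))
    res <- stratify_survival(surv[, c("sample_id", "time", "event")], expr,
                             state$module,
                             distance = cfg$clustering_distance,
                             linkage = cfg$clustering_linkage)
    write_tsv(cbind(surv, cluster_group = res$groups[surv$sample_id]),
              file.path(outdir, "survival.tsv"))
    km_tab <- do.call(rbind, lapply(names(res$km), function(gname)
      if (nrow(res$km[[gname]]))
        cbind(group = gname, as.data.frame(res$km[[gname]]))))
    write_tsv(km_tab, file.path(outdir, "km_curves.tsv"))
    lr <- list(chi_square = res$logrank$chi_square,
               p = res$logrank$p_value,
               group_sizes = as.list(res$logrank$group_sizes))
    jsonlite::write_json(lr, file.path(outdir, "logrank.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    lr
  })

  report$artifacts <- sort(list.files(outdir, recursive = TRUE))
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Command-line entry point
#'
#' Parses `Rscript`-style arguments and dispatches to the pipeline. Usage:
#'
#' ```
#' Rscript -e 'tvinet::pipeline_cli()' <subcommand> [--config FILE]
#'     [--seed INT] [--outdir DIR]
#' ```
#'
#' Subcommands `simulate`, `repstats`, `tvi`, `screen`, `network`,
#' `survive` run the pipeline up to (and including) that stage; `run-all`
#' runs everything.
#'
#' @param args character vector (defaults to [commandArgs()] trailing
#'   arguments).
#' @return the run report, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages_all <- c("simulate", "repstats", "tvi", "screen", "network", "survive")
  if (length(args) == 0L)
    stop("usage: <subcommand> [--config FILE] [--seed INT] [--outdir DIR]; ",
         "subcommands: ", paste(c(stages_all, "run-all"), collapse = ", "))
  cmd <- args[[1L]]
  if (!cmd %in% c(stages_all, "run-all")) stop("unknown subcommand: ", cmd)
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% c("config", "seed", "outdir", "log-level"))
      stop("unknown option: ", args[[i]])
    if (i + 1L > length(args)) stop("option ", args[[i]], " needs a value")
    opts[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
  if (cmd != "run-all")
    cfg$stages <- stages_all[seq_len(match(cmd, stages_all))]
  run_pipeline(cfg)
}
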