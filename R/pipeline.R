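#' Build an analysis configuration
#'
#' Exactly one of `paths` (named list/vector with `trips`, `islands`, `sst`
#' CSV files) or `scenario` (a [synthetic_scenario()]) must be given.
#'
#' @param paths Optional named list of input CSV paths.
#' @param scenario Optional `synthetic_scenario`.
#' @param sigma_t Gaussian SST kernel scale, degrees C (default 2).
#' @param n_sims Small-world null ensemble size (default 1000).
#' @param n_perm Modularity permutation count (default 1000).
#' @param resolution Community-detection resolution (default 1).
#' @param month_rule `"best_median"` (pick the month maximising median SST
#'   similarity, earliest month on ties) or a fixed `"YYYY-MM"` month.
#' @param seed Master seed (mandatory); stage seeds are derived from it.
#' @param window Optional month window for [build_network()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(paths = NULL, scenario = NULL, sigma_t = 2,
                            n_sims = 1000, n_perm = 1000, resolution = 1,
                            month_rule = "best_median", seed, window = NULL) {
  if (missing(seed)) stop("seed is required")
  if (is.null(paths) == is.null(scenario)) {
    stop("give exactly one of `paths` or `scenario`")
  }
  if (!is.null(paths)) {
    stopifnot(all(c("trips", "islands", "sst") %in% names(paths)))
  }
  structure(
    list(paths = paths, scenario = scenario, sigma_t = sigma_t,
         n_sims = n_sims, n_perm = n_perm, resolution = resolution,
         month_rule = month_rule, seed = as.integer(seed), window = window),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys mirror the [analysis_config()] arguments; a `scenario`
#' block holds [synthetic_scenario()] parameters, a `paths` block the three
#' input files.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    y$scenario <- do.call(synthetic_scenario, y$scenario)
  }
  do.call(analysis_config, y)
}

# derive reproducible, independent stage seeds from the master seed
derive_seeds <- function(master, stages) {
  set.seed(master)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)),
                  stages)
}

#' Run the full invasion-risk network analysis
#'
#' Stages, in order: ingest or simulate inputs; build the directed weighted
#' trip network; weighted small-world test; node metrics and the four
#' rankings; community detection with the degree-preserving modularity null
#' test and vulnerability metrics; monthly SST similarity and seasonal
#' Kruskal-Wallis/Dunn comparison; month selection; SST-composite network;
#' composite metrics, rankings (with rank shifts), communities and
#' vulnerability.
#'
#' @param cfg An `analysis_config` (or path to a YAML config).
#' @return An `analysis_report` list with elements `network`, `smallworld`,
#'   `metrics`, `rankings`, `partition`, `modularity_test`, `vulnerability`,
#'   `seasonal`, `composite_month`, `composite` (network, metrics, rankings
#'   with rank-shift, partition, vulnerability), `zone_stats`, and
#'   `provenance`.
#' @export
run_full_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  stopifnot(inherits(cfg, "analysis_config"))
  seeds <- derive_seeds(cfg$seed, c("smallworld", "communities",
                                    "null_test", "composite_communities"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  inputs <- stage("ingest", {
    if (!is.null(cfg$scenario)) {
      simulate_scenario(cfg$scenario)
    } else {
      islands <- read_islands(cfg$paths$islands)
      list(islands = islands,
           trips = read_trip_records(cfg$paths$trips, islands),
           sst = read_sst(cfg$paths$sst))
    }
  })
  net <- stage("network",
               build_network(inputs$trips, inputs$islands, cfg$window))
  sw <- stage("smallworld",
              smallworldness(net, n_sims = cfg$n_sims,
                             seed = seeds[["smallworld"]]))
  metrics <- stage("node_metrics", node_metrics(net))
  indices <- c("out_degree", "out_strength", "betweenness", "out_closeness")
  rankings <- stage("rankings",
                    purrr::map(stats::setNames(indices, indices),
                               ~rank_nodes(metrics, .x)))
  partition <- stage("communities",
                     detect_communities(net, resolution = cfg$resolution,
                                        seed = seeds[["communities"]]))
  mtest <- stage("modularity_null",
                 modularity_null_test(net, n_perm = cfg$n_perm,
                                      seed = seeds[["null_test"]],
                                      resolution = cfg$resolution))
  vuln <- stage("vulnerability", community_vulnerability(net, partition))
  zstats <- stage("zone_stats", zone_connection_stats(net, inputs$islands))
  seasonal <- stage("seasonal", seasonal_comparison(inputs$sst, cfg$sigma_t))
  month <- stage("month_selection", {
    if (identical(cfg$month_rule, "best_median")) {
      best_similarity_month(seasonal)
    } else {
      cfg$month_rule
    }
  })
  comp <- stage("composite", {
    sim <- sst_similarity(inputs$sst, month, cfg$sigma_t)
    composite_network(net, sim, month)
  })
  comp_metrics <- stage("composite_metrics", node_metrics(comp))
  comp_rankings <- stage("composite_rankings", {
    purrr::map(stats::setNames(indices, indices), function(idx) {
      r <- rank_nodes(comp_metrics, idx)
      base <- rankings[[idx]]
      r$rank_shift <- base$rank[match(r$island, base$island)] - r$rank
      r
    })
  })
  comp_partition <- stage("composite_communities",
                          detect_communities(comp, resolution = cfg$resolution,
                                             seed = seeds[["composite_communities"]]))
  comp_vuln <- stage("composite_vulnerability",
                     community_vulnerability(comp, comp_partition))
  structure(
    list(
      network = net, smallworld = sw, metrics = metrics, rankings = rankings,
      partition = partition, modularity_test = mtest, vulnerability = vuln,
      zone_stats = zstats, seasonal = seasonal, composite_month = month,
      composite = list(network = comp, metrics = comp_metrics,
                       rankings = comp_rankings, partition = comp_partition,
                       vulnerability = comp_vuln),
      provenance = list(seed = cfg$seed, stage_seeds = as.list(seeds),
                        sigma_t = cfg$sigma_t, n_sims = cfg$n_sims,
                        n_perm = cfg$n_perm, resolution = cfg$resolution,
                        month_rule = cfg$month_rule,
                        package_version = as.character(utils::packageVersion("vesselnet")))
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Vessel-network invasion-risk analysis ==\n")
  print(x$network)
  print(x$smallworld)
  print(x$partition)
  print(x$modularity_test)
  print(x$seasonal)
  cat("Composite month:", x$composite_month, "\n")
  cat(sprintf("Composite communities: %d, Q = %.4f (frequency-only Q = %.4f)\n",
              x$composite$partition$n_communities, x$composite$partition$Q,
              x$partition$Q))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits TSV tables (metrics, rankings, membership, vulnerability, for the
#' frequency-only and composite networks), GraphML exports of both networks,
#' the similarity-month seasonal statistics, and a `report.json` with the
#' headline blocks and provenance.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_metrics_tsv(report$metrics, file.path(out_dir, "node_metrics.tsv"))
  write_metrics_tsv(report$composite$metrics,
                    file.path(out_dir, "node_metrics_composite.tsv"))
  write_membership_tsv(report$partition, file.path(out_dir, "membership.tsv"))
  write_membership_tsv(report$composite$partition,
                       file.path(out_dir, "membership_composite.tsv"))
  readr::write_tsv(report$vulnerability,
                   file.path(out_dir, "vulnerability.tsv"))
  readr::write_tsv(report$composite$vulnerability,
                   file.path(out_dir, "vulnerability_composite.tsv"))
  write_network_graphml(report$network, file.path(out_dir, "network.graphml"))
  write_network_graphml(report$composite$network,
                        file.path(out_dir, "network_composite.graphml"))
  rank_tbl <- function(rl) {
    purrr::imap_dfr(rl, ~dplyr::mutate(.x, index = .y, .before = 1))
  }
  readr::write_tsv(rank_tbl(report$rankings),
                   file.path(out_dir, "rankings.tsv"))
  readr::write_tsv(rank_tbl(report$composite$rankings),
                   file.path(out_dir, "rankings_composite.tsv"))
  js <- list(
    smallworld = jsonlite::fromJSON(smallworld_json(report$smallworld)),
    modularity_test = jsonlite::fromJSON(modularity_null_json(report$modularity_test)),
    seasonal = list(
      statistic = report$seasonal$kw$statistic,
      df = report$seasonal$kw$df,
      p_value = report$seasonal$kw$p_value,
      medians = report$seasonal$medians
    ),
    composite_month = report$composite_month,
    composite_Q = report$composite$partition$Q,
    frequency_Q = report$partition$Q,
    zone_stats = report$zone_stats$summary,
    provenance = report$provenance
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write scenario fixtures), `build` (network
#' exports from CSVs), `smallworld`, `communities`, `rank`, `sst` (seasonal
#' statistics), `report`/`run` (full analysis). Global flags: `--config`,
#' `--seed`, `--out`. Intended to be wrapped by a thin Rscript.
#'
#' @param argv Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: vesselnet <subcommand> [--config FILE] [--seed INT] [--out DIR]",
    "subcommands: simulate build smallworld communities sst rank report run",
    sep = "\n")
  if (length(argv) == 0) {
    message(usage)
    return(invisible(1L))
  }
  sub <- argv[1]
  flags <- list(config = NULL, seed = NULL, out = ".")
  i <- 2
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(flags) || i == length(argv)) {
      message("unknown or incomplete flag: ", argv[i], "\n", usage)
      return(invisible(1L))
    }
    flags[[key]] <- argv[i + 1]
    i <- i + 2
  }
  if (!is.null(flags$seed)) flags$seed <- as.integer(flags$seed)
  need_cfg <- function() {
    if (is.null(flags$config) || !file.exists(flags$config)) {
      stop("--config FILE is required and must exist")
    }
    cfg <- read_analysis_config(flags$config)
    if (!is.null(flags$seed)) cfg$seed <- flags$seed
    cfg
  }
  status <- tryCatch({
    switch(sub,
      simulate = {
        if (is.null(flags$seed)) stop("--seed is required for simulate")
        scn <- synthetic_scenario(seed = flags$seed)
        write_fixtures(scn, flags$out)
      },
      build = {
        cfg <- need_cfg()
        rep0 <- if (!is.null(cfg$scenario)) simulate_scenario(cfg$scenario) else
          list(islands = read_islands(cfg$paths$islands),
               trips = read_trip_records(cfg$paths$trips))
        net <- build_network(rep0$trips, rep0$islands, cfg$window)
        dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
        write_network_graphml(net, file.path(flags$out, "network.graphml"))
        write_edgelist_tsv(net, file.path(flags$out, "edges.tsv"))
      },
      smallworld = ,
      communities = ,
      sst = ,
      rank = ,
      report = ,
      run = {
        cfg <- need_cfg()
        report <- run_full_analysis(cfg)
        dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
        if (sub %in% c("report", "run")) {
          write_report(report, flags$out)
        } else if (sub == "smallworld") {
          smallworld_json(report$smallworld,
                          file.path(flags$out, "smallworld.json"))
        } else if (sub == "communities") {
          write_membership_tsv(report$partition,
                               file.path(flags$out, "membership.tsv"))
          modularity_null_json(report$modularity_test,
                               file.path(flags$out, "modularity_test.json"))
        } else if (sub == "sst") {
          readr::write_tsv(report$seasonal$pairwise,
                           file.path(flags$out, "dunn_pairwise.tsv"))
          readr::write_tsv(report$seasonal$medians,
                           file.path(flags$out, "monthly_medians.tsv"))
        } else if (sub == "rank") {
          purrr::iwalk(report$rankings, function(r, idx) {
            readr::write_tsv(r, file.path(flags$out,
                                          paste0("ranking_", idx, ".tsv")))
          })
        }
        invisible(NULL)
      },
      {
        message("unknown subcommand: ", sub, "\n", usage)
        return(invisible(1L))
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
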