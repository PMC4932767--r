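#' Default pipeline configuration
#'
#' All stage parameters with their package-wide defaults: window length
#' 10, all 32 parameter combinations, 1e5 Monte-Carlo samples, UPGMA
#' cut at join height 0.05, pattern lengths 2-5 at alpha 0.05, and the
#' default evolution schedule (evolution is off unless requested: it is
#' by far the most expensive stage).
#'
#' @param out_dir output directory.
#' @param seed integer seed used by every stage.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("hydrosep_run"),
                                    seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    cache = TRUE,
    stages = c("simulate", "pools", "cluster_scales", "params",
               "separate", "patterns"),
    scales = list(path = NULL, dialect = "two_column"),
    synthetic = list(n_proteins = 60L, segments_per_protein = 5L,
                     kr_spacer_rate = 0.9),
    window_len = 10L,
    combos = 0:31,
    mc_samples = 1e5,
    cluster_threshold = 0.05,
    separate = list(pools = c("tm-helix", "tm-sheet", "s-helix", "s-sheet",
                              "random"),
                    scales = NULL, combos = c(0L, 31L), min_peptides = 6L),
    patterns = list(k = 4L, alpha = 0.05),
    aggregation_mode = "best-combo-mean",
    evolution = list(enabled = FALSE, n_random = 20L,
                     children_per_round = 50L,
                     eval_pools = c("tm-helix", "tm-sheet", "random")))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validate_pipeline_config <- function(config) {
  known <- c("simulate", "pools", "cluster_scales", "params", "separate",
             "patterns", "evolve")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (lab in c(config$separate$pools, config$evolution$eval_pools))
    if (!lab %in% ALL_POOL_LABELS)
      stop(sprintf("unknown pool label in config: '%s'", lab))
  if (!is.null(config$scales$path) && !file.exists(config$scales$path))
    stop(sprintf("scale file not found: %s", config$scales$path))
  invisible(config)
}

write_records_tsv <- function(records, path) {
  df <- data.frame(id = vapply(records, function(r) r$id, character(1)),
                   sequence = vapply(records, function(r) r$sequence, character(1)),
                   sse = vapply(records, function(r) r$sse, character(1)),
                   topo = vapply(records, function(r) r$topo, character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_records_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    peptide_record(df$id[i], df$sequence[i], df$sse[i], df$topo[i]))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: synthetic protein
#' generation, pool assembly, scale clustering, window-parameter export,
#' the separation sweep (with pairwise best matrix and, when enough
#' scenarios exist, the parameter-influence table), k-mer enrichment and
#' optionally scale evolution.  Every stage writes plain-text artifacts
#' into `out_dir`; a run log records seeds, stage timings and an MD5
#' manifest of the outputs.  With `cache = TRUE`, stages whose outputs
#' already exist are reloaded instead of recomputed, which never changes
#' results because all stages are seeded.
#'
#' @param config nested list as produced by [default_pipeline_config];
#'   partial lists are merged over the defaults.  A path to a YAML file
#'   with the same structure is also accepted.
#' @return invisibly, a list with the main in-memory results (`pools`,
#'   `clustering`, `sweep`, `patterns`, `evolution`) and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- merge_config(default_pipeline_config(), config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_lines <- c(sprintf("hydrosep pipeline run, config hash %s, seed %d",
                         cfg_hash, config$seed))
  tick <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  out <- list(out_dir = config$out_dir)

  scales <- if (is.null(config$scales$path)) bundled_scales() else
    parse_scale_table(config$scales$path, config$scales$dialect)

  proteins <- NULL
  if ("simulate" %in% config$stages) {
    prot_path <- file.path(config$out_dir, "proteins.tsv")
    if (config$cache && file.exists(prot_path)) {
      proteins <- read_records_tsv(prot_path)
      tick("simulate", sprintf("reloaded %d cached proteins", length(proteins)))
    } else {
      t0 <- Sys.time()
      spec <- synthetic_spec(seed = config$seed,
                             n_proteins = config$synthetic$n_proteins,
                             segments_per_protein = config$synthetic$segments_per_protein,
                             kr_spacer_rate = config$synthetic$kr_spacer_rate)
      gen <- generate_proteins(spec)
      proteins <- gen$proteins
      write_records_tsv(proteins, prot_path)
      jsonlite::write_json(gen$ledger,
                           file.path(config$out_dir, "ledger.json"),
                           dataframe = "rows")
      tick("simulate", sprintf("generated %d proteins (%.1fs)",
                               length(proteins),
                               as.numeric(Sys.time() - t0, units = "secs")))
    }
  }

  pools <- NULL
  if ("pools" %in% config$stages) {
    if (is.null(proteins))
      stop("the 'pools' stage needs proteins from the 'simulate' stage or a cached proteins.tsv")
    t0 <- Sys.time()
    pools <- assemble_pools(proteins)
    write_pools(pools, file.path(config$out_dir, "pools"))
    out$pools <- pools
    tick("pools", sprintf("assembled pools (%.1fs)",
                          as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("cluster_scales" %in% config$stages) {
    cl <- upgma_cluster(c(scales, lapply(scales, reverse_scale)),
                        threshold = config$cluster_threshold)
    export_clustering(cl,
                      newick = file.path(config$out_dir, "scales_upgma.nwk"),
                      tsv = file.path(config$out_dir, "scale_clusters.tsv"))
    out$clustering <- cl
    tick("cluster_scales", sprintf("%d scales into %d clusters",
                                   length(cl$scale_ids),
                                   length(unique(cl$clusters))))
  }

  usable_pools <- function(labels, min_n) {
    if (is.null(pools)) stop("stage needs pools; enable the 'pools' stage")
    ps <- pools[labels]
    Filter(function(p) length(p$records) >= min_n, ps)
  }

  if ("params" %in% config$stages) {
    ps <- usable_pools(config$separate$pools, 1L)
    sc <- scales[[1L]]
    for (p in ps)
      write_extrema(pool_extrema(p, sc, window_len = config$window_len),
                    file.path(config$out_dir,
                              sprintf("extrema_%s_%s.tsv", p$label, sc$id)))
    tick("params", sprintf("extrema for %d pools under scale '%s'",
                           length(ps), sc$id))
  }

  if ("separate" %in% config$stages) {
    ps <- usable_pools(config$separate$pools, config$separate$min_peptides)
    if (length(ps) < 2L) {
      tick("separate", "skipped: fewer than two sufficiently large pools")
    } else {
      t0 <- Sys.time()
      use_scales <- if (is.null(config$separate$scales)) scales else
        scales[config$separate$scales]
      sweep <- scenario_sweep(ps, use_scales,
                              combos = config$separate$combos,
                              window_len = config$window_len,
                              mc_samples = config$mc_samples,
                              seed = config$seed)
      write_scenarios(sweep, file.path(config$out_dir, "separation.tsv"))
      best <- pairwise_best_matrix(ps, use_scales, sweep = sweep)
      utils::write.csv(best$S, file.path(config$out_dir, "pairwise_best.csv"))
      if (nrow(sweep) >= 20L)
        write.table(data.frame(choice = EXTREMA_NAMES,
                               influence = parameter_influence(sweep)),
                    file.path(config$out_dir, "parameter_influence.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      out$sweep <- sweep
      tick("separate", sprintf("%d scenarios (%.1fs)", nrow(sweep),
                               as.numeric(Sys.time() - t0, units = "secs")))
    }
  }

  if ("patterns" %in% config$stages) {
    nonempty <- Filter(function(p) length(p$records) > 0,
                       pools[names(pools) %in% ALL_POOL_LABELS])
    if (length(nonempty) < 2L) {
      tick("patterns", "skipped: fewer than two non-empty pools")
    } else {
      st <- enrichment_table(nonempty, k = config$patterns$k,
                             alpha = config$patterns$alpha)
      write_pattern_stats(st, file.path(config$out_dir, "pattern_enrichment.tsv"))
      cov <- coverage_by_length(nonempty)
      write.table(data.frame(k = names(cov), coverage = as.numeric(cov)),
                  file.path(config$out_dir, "pattern_coverage.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out$patterns <- st
      tick("patterns", sprintf("%d enrichment rows at k = %d", nrow(st),
                               config$patterns$k))
    }
  }

  if ("evolve" %in% config$stages && isTRUE(config$evolution$enabled)) {
    ev_pools <- usable_pools(config$evolution$eval_pools, 6L)
    if (length(ev_pools) < 2L) {
      tick("evolve", "skipped: fewer than two usable evaluation pools")
    } else {
      t0 <- Sys.time()
      st <- evolve_scale(scales, ev_pools,
                         schedule = scaled_evolution_schedule(
                           config$evolution$children_per_round),
                         seed = config$seed,
                         n_random = config$evolution$n_random,
                         window_len = config$window_len)
      export_evolution(st,
                       trajectory_tsv = file.path(config$out_dir, "evolution_trajectory.tsv"),
                       scale_file = file.path(config$out_dir, "evolved_scale.txt"))
      out$evolution <- st
      tick("evolve", sprintf("best fitness %.4f (%.1fs)",
                             max(st$best_trajectory$fitness),
                             as.numeric(Sys.time() - t0, units = "secs")))
    }
  }

  arts <- setdiff(list.files(config$out_dir, recursive = TRUE,
                             full.names = TRUE),
                  file.path(config$out_dir, "run_log.txt"))
  manifest <- tools::md5sum(arts)
  log_lines <- c(log_lines, "", "artifact manifest (md5):",
                 sprintf("%s  %s", unname(manifest),
                         substring(arts, nchar(config$out_dir) + 2L)))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(out)
}
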