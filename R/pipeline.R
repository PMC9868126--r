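#' Run configuration for the full analysis pipeline
#'
#' Collects paths, thresholds and options for [run_all()] with the study
#' defaults: BH cutoff 0.1 for activation lists, node threshold 0.01,
#' edge threshold r > 0.75, complete linkage, 101 cut fractions.
#'
#' @param regions path to the region CSV.
#' @param counts path to the count CSV.
#' @param output_dir directory for stage outputs.
#' @param bh_cutoff,node_p_cut,edge_r_cut analysis thresholds, all in (0, 1).
#' @param linkage linkage criterion for [cluster_structures()].
#' @param cut_steps grid size for [modularity_curve()].
#' @param exclude character vector (or file path) of excluded region acronyms.
#' @param families family design for [fos_diff()] (NULL = infer from labels).
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(regions, counts, output_dir,
                       bh_cutoff = 0.1, node_p_cut = 0.01, edge_r_cut = 0.75,
                       linkage = "complete", cut_steps = 101,
                       exclude = character(0), families = NULL, seed = 1L) {
  for (th in c(bh_cutoff, node_p_cut))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  if (edge_r_cut <= 0 || edge_r_cut >= 1) stop("edge_r_cut must lie in (0, 1)")
  structure(list(regions = regions, counts = counts, output_dir = output_dir,
                 bh_cutoff = bh_cutoff, node_p_cut = node_p_cut,
                 edge_r_cut = edge_r_cut, linkage = linkage,
                 cut_steps = cut_steps, exclude = exclude,
                 families = families, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file
#' @return a [run_config]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config a [run_config]
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- unclass(config)
  keep$output_dir <- NULL
  writeLines(yaml::as.yaml(keep[order(names(keep))]), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr, log_con) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  msg <- sprintf("[%s] completed in %.2fs", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  res
}

#' Run the whole pipeline: validate, densities, differential, connectivity,
#' graphs, report
#'
#' Executes every stage in order and writes the stage outputs to
#' `config$output_dir`: `differential.csv`, per-group `corr_<group>.csv`,
#' `linkage_<group>.csv`, `modularity_<group>.csv`, `logrank.csv` (each
#' treatment dendrogram vs its family control), per-treatment
#' `graph_<group>_edges.csv` / `graph_<group>_nodes.csv`, and a deterministic
#' `manifest.json` (package version, seed, config hash, per-stage row counts).
#' Stage timings go to stderr and `run.log` only, so repeated runs with the
#' same config produce byte-identical result files.
#'
#' @param config a [run_config]
#' @return the manifest, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$output_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  cfg_echo <- unclass(config)
  cfg_echo$output_dir <- NULL   # keep the manifest independent of where it ran
  manifest <- list(package = "fosnet",
                   version = as.character(utils::packageVersion("fosnet")),
                   seed = config$seed, config_hash = config_hash(config),
                   config = cfg_echo, stages = list())

  # validate
  loaded <- run_stage("validate", {
    if (!file.exists(config$regions)) stop("regions file not found: ", config$regions)
    if (!file.exists(config$counts)) stop("counts file not found: ", config$counts)
    rs <- read_region_set(config$regions, exclude = config$exclude)
    ct <- read_count_table(config$counts)
    missing <- setdiff(colnames(ct$counts), rs$acronym)
    if (length(missing)) stop("count regions absent from region set: ",
                              paste(missing, collapse = ", "))
    list(regions = rs, counts = drop_excluded(ct, rs))
  }, log_con)
  manifest$stages$validate <- list(n_regions = ncol(loaded$counts$counts),
                                   n_animals = nrow(loaded$counts$counts))

  dens <- run_stage("density", to_density(loaded$counts, loaded$regions), log_con)
  manifest$stages$density <- list(n_values = length(dens$values))

  diff <- run_stage("differential", {
    d <- fos_diff(loaded$counts, loaded$regions, families = config$families,
                  bh_cutoff = config$bh_cutoff)
    utils::write.csv(d$table, file.path(config$output_dir, "differential.csv"),
                     row.names = FALSE)
    d
  }, log_con)
  manifest$stages$differential <- list(n_rows = nrow(diff$table),
                                       n_sig = sum(diff$table$sig_bh))

  conn <- run_stage("connectivity", {
    out <- list()
    for (g in levels(loaded$counts$group)) {
      cm <- correlation_matrix(dens, g)
      utils::write.csv(as.data.frame(unclass(cm)),
                       file.path(config$output_dir, paste0("corr_", g, ".csv")))
      dend <- suppressMessages(cluster_structures(cm, method = config$linkage))
      utils::write.csv(data.frame(merge_a = dend$hclust$merge[, 1],
                                  merge_b = dend$hclust$merge[, 2],
                                  height = dend$merge_heights,
                                  height_norm = dend$heights_norm),
                       file.path(config$output_dir, paste0("linkage_", g, ".csv")),
                       row.names = FALSE)
      mc <- modularity_curve(dend, config$cut_steps)
      utils::write.csv(as.data.frame(mc),
                       file.path(config$output_dir, paste0("modularity_", g, ".csv")),
                       row.names = FALSE)
      out[[g]] <- list(corr = cm, dend = dend, curve = mc)
    }
    out
  }, log_con)
  manifest$stages$connectivity <- list(groups = names(conn))

  fams <- diff$families
  lr <- run_stage("logrank", {
    rows <- list()
    for (fam in names(fams)) {
      ctrl <- fams[[fam]]$control
      for (tg in fams[[fam]]$treatments) {
        cmp <- compare_modularity_logrank(conn[[ctrl]]$dend, conn[[tg]]$dend)
        rows[[length(rows) + 1L]] <- data.frame(
          control = ctrl, treatment = tg,
          chisq = cmp$statistic, p_value = cmp$p_value)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(config$output_dir, "logrank.csv"),
                     row.names = FALSE)
    tab
  }, log_con)
  manifest$stages$logrank <- list(n_comparisons = nrow(lr))

  graphs <- run_stage("graph", {
    out <- list()
    for (fam in names(fams)) for (tg in fams[[fam]]$treatments) {
      g <- suppressWarnings(build_graph(diff, conn[[tg]]$corr,
                                        p_cut = config$node_p_cut,
                                        r_cut = config$edge_r_cut,
                                        family = fam, group = tg))
      utils::write.csv(g$edges,
                       file.path(config$output_dir, paste0("graph_", tg, "_edges.csv")),
                       row.names = FALSE)
      utils::write.csv(data.frame(region = g$nodes, degree = unname(g$degree[g$nodes])),
                       file.path(config$output_dir, paste0("graph_", tg, "_nodes.csv")),
                       row.names = FALSE)
      out[[tg]] <- g
    }
    out
  }, log_con)
  manifest$stages$graph <- lapply(graphs, function(g)
    list(n_nodes = length(g$nodes), n_edges = nrow(g$edges)))

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(manifest)
}

#' Summarise a completed run
#'
#' Reads the stage outputs of [run_all()] back and assembles the headline
#' tables: significant-region counts per contrast, the strongest fold
#' indices, modularity curves, log-rank comparisons and the graph degree
#' (hub) table. Writes `report.json` next to the stage outputs.
#'
#' @param output_dir the run's output directory (must contain `manifest.json`).
#' @param top number of top regions/hubs to keep in the summary tables.
#' @return list of class `fos_report`.
#' @export
fos_report <- function(output_dir, top = 10) {
  mf <- file.path(output_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", output_dir, "; run incomplete?")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("validate", "differential", "connectivity", "logrank", "graph")
  if (!all(need %in% manifest$completed))
    stop("run incomplete: missing stages ",
         paste(setdiff(need, manifest$completed), collapse = ", "))
  diff <- utils::read.csv(file.path(output_dir, "differential.csv"))

  sig <- do.call(rbind, lapply(split(diff, paste(diff$family, diff$group)),
    function(d) data.frame(family = d$family[1], group = d$group[1],
                           n_sig_bh = sum(d$sig_bh), n_sig_network = sum(d$sig_network))))
  rownames(sig) <- NULL

  folds <- diff[!is.na(diff$fold_index), ]
  folds <- folds[order(-folds$fold_index), ]
  folds <- utils::head(folds[, c("region", "family", "group", "fold_index", "q_bh")], top)

  curves <- list()
  for (g in manifest$stages$connectivity$groups) {
    f <- file.path(output_dir, paste0("modularity_", g, ".csv"))
    if (file.exists(f)) curves[[g]] <- utils::read.csv(f)
  }
  logrank <- utils::read.csv(file.path(output_dir, "logrank.csv"))

  degrees <- list()
  for (g in names(manifest$stages$graph)) {
    f <- file.path(output_dir, paste0("graph_", g, "_nodes.csv"))
    if (file.exists(f)) {
      d <- utils::read.csv(f)
      degrees[[g]] <- utils::head(d[order(-d$degree), ], top)
    }
  }

  rep <- structure(list(significant = sig, top_folds = folds,
                        modularity = curves, logrank = logrank,
                        hubs = degrees, manifest = manifest),
                   class = "fos_report")
  jsonlite::write_json(list(significant = sig, top_folds = folds,
                            logrank = logrank, hubs = degrees),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  rep
}

#' @export
print.fos_report <- function(x, ...) {
  cat("Run report (", length(x$manifest$completed), "stages )\n")
  cat("\nSignificant regions per contrast:\n")
  print(x$significant, row.names = FALSE)
  cat("\nModularity comparisons (log-rank):\n")
  print(x$logrank, row.names = FALSE)
  invisible(x)
}
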