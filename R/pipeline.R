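# known run-configuration keys and their defaults; sim_* keys forward to
# simulation_config()
.config_defaults <- function() {
  sim <- formals(simulation_config)
  sim$seed <- NULL
  sim <- lapply(sim, eval)
  names(sim) <- paste0("sim_", names(sim))
  c(list(seed = 1L,
         stages = c("simulate", "predict", "eps", "synergy", "report"),
         tau = 0.1,
         quartile_direction = "sensitive_first",
         cv_model = "rf_classifier", cv_folds = 100L, cv_holdout = 0.15,
         cv_select = 10L, cv_ntree = 500L,
         eps_self_weight = 0,
         bliss_summary = "mean", bliss_threshold = 0.1, top_k = 5L,
         n_permutations = 10000L,
         plate_file = NULL, matrix_file = NULL, gi50_file = NULL,
         genotype_file = NULL, screen_file = NULL,
         network_edge_file = NULL, network_tractable_file = NULL,
         network_map_file = NULL),
    sim)
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list, checks every key against the
#' schema (unknown keys are rejected with a nearest-key suggestion),
#' validates value ranges, and fills defaults. The fully resolved
#' configuration is echoed into the run manifest by [run_pipeline()].
#'
#' @param config YAML path, named list, or `NULL` (all defaults).
#' @return A validated list of class `run_config`.
#' @examples
#' cfg <- validate_config(list(tau = 0.2, seed = 7))
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    key <- unknown[1L]
    d <- utils::adist(key, names(defaults))
    hint <- names(defaults)[which.min(d)]
    stop(sprintf("unknown config key '%s' (did you mean '%s'?)",
                 key, hint))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$tau) || cfg$tau <= 0)
    stop("config key 'tau' must be positive")
  if (cfg$cv_holdout <= 0 || cfg$cv_holdout >= 1)
    stop("config key 'cv_holdout' must lie in (0, 1)")
  bad <- setdiff(cfg$stages,
                 c("simulate", "normalize", "predict", "eps", "synergy",
                   "report"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!cfg$bliss_summary %in% c("mean", "max", "topq"))
    stop("config key 'bliss_summary' must be mean, max or topq")
  structure(cfg, class = "run_config")
}

.pipeline_version <- function() {
  as.character(utils::packageVersion("phosphoresponse"))
}

.require_stage_input <- function(path, stage, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("stage '%s' requires %s but none is available", stage,
                 what))
  path
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate / normalize -> predict, eps, synergy -> report), writing all
#' outputs as plain CSV/TSV/JSON under `out_dir` together with a
#' reproducibility manifest (`manifest.json`: resolved configuration,
#' input/output checksums, per-stage row counts, seeds, timestamp, tool
#' version). Re-running with the same configuration and seed reproduces
#' byte-identical numeric outputs; when a previous manifest is present and
#' its recorded output checksums still match, completed stages are resumed
#' (skipped) unless `force = TRUE`, and a checksum mismatch is an error
#' unless forced.
#'
#' @param config A [validate_config()] result, raw list, or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param force Re-run stages even when resumable, and overwrite outputs
#'   whose checksums disagree with the previous manifest.
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir = "pipeline_out",
                         force = FALSE) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pathto <- function(f) file.path(out_dir, f)
  prev <- if (file.exists(pathto("manifest.json")))
    jsonlite::read_json(pathto("manifest.json")) else NULL
  manifest <- list(config = unclass(cfg), version = .pipeline_version(),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = cfg$seed, stages = list())
  log_line <- function(...) message("[pipeline] ", sprintf(...))

  resumable <- function(stage, files) {
    if (force || is.null(prev) || is.null(prev$stages[[stage]]))
      return(FALSE)
    rec <- prev$stages[[stage]]$checksums
    ok <- all(vapply(files, file.exists, TRUE)) &&
      identical(unname(unlist(rec[basename(files)])),
                unname(tools::md5sum(files)))
    if (!ok && all(vapply(files, file.exists, TRUE)) &&
        length(rec))
      stop("stage '", stage, "' outputs changed since last run; ",
           "use force = TRUE to overwrite")
    ok
  }
  record <- function(stage, files, rows) {
    manifest$stages[[stage]] <<- list(
      checksums = as.list(stats::setNames(tools::md5sum(files),
                                          basename(files))),
      rows = rows, seed = cfg$seed)
    log_line("stage=%s rows=%s done", stage,
             paste(rows, collapse = "/"))
  }

  st <- cfg$stages
  # ---- simulate -------------------------------------------------------
  if ("simulate" %in% st) {
    files <- pathto(c("matrix.csv", "gi50.csv", "genotypes.csv",
                      "screen.csv", "network_edges.tsv",
                      "network_tractable.tsv", "network_map.tsv",
                      "truth.json"))
    if (resumable("simulate", files)) {
      log_line("stage=simulate resumed from existing outputs")
      manifest$stages$simulate <- prev$stages$simulate
    } else {
      sim_args <- cfg[startsWith(names(cfg), "sim_")]
      names(sim_args) <- sub("^sim_", "", names(sim_args))
      sim_args$seed <- cfg$seed
      cohort <- simulate_cohort(do.call(simulation_config, sim_args))
      write_perturbation_matrix(cohort$matrix, pathto("matrix.csv"))
      utils::write.csv(cohort$sens[, c("sample", "drug", "gi50")],
                       pathto("gi50.csv"), row.names = FALSE)
      utils::write.csv(cohort$genotypes, pathto("genotypes.csv"),
                       row.names = FALSE)
      write_combination_screen(cohort$screen, pathto("screen.csv"))
      write_interaction_network(cohort$network,
                                pathto("network_edges.tsv"),
                                pathto("network_tractable.tsv"),
                                pathto("network_map.tsv"))
      write_ground_truth(cohort$truth, pathto("truth.json"))
      jsonlite::write_json(cohort$drugs, pathto("drug_targets.json"),
                           auto_unbox = FALSE)
      record("simulate", files,
             c(conditions = nrow(cohort$matrix$changes),
               gi50 = nrow(cohort$sens),
               grids = length(cohort$screen$grids)))
    }
    cfg$matrix_file <- pathto("matrix.csv")
    cfg$gi50_file <- pathto("gi50.csv")
    cfg$genotype_file <- pathto("genotypes.csv")
    cfg$screen_file <- pathto("screen.csv")
    cfg$network_edge_file <- pathto("network_edges.tsv")
    cfg$network_tractable_file <- pathto("network_tractable.tsv")
    cfg$network_map_file <- pathto("network_map.tsv")
  }
  # ---- normalize ------------------------------------------------------
  if ("normalize" %in% st) {
    plate_path <- .require_stage_input(cfg$plate_file, "normalize",
                                       "a raw plate file (plate_file)")
    plate <- read_raw_plate(plate_path)
    panel <- analyte_panel(c("GAPDH",
                             setdiff(unique(plate$wells$analyte),
                                     "GAPDH")))
    pm <- normalize_plate(plate, panel)
    write_perturbation_matrix(pm, pathto("matrix.csv"))
    cfg$matrix_file <- pathto("matrix.csv")
    record("normalize", pathto("matrix.csv"),
           c(conditions = nrow(pm$changes)))
  }

  load_matrix <- function(stage) {
    path <- .require_stage_input(cfg$matrix_file, stage,
                                 "a perturbation matrix (matrix_file)")
    header <- strsplit(readLines(path, n = 1L), "[,\t]")[[1L]]
    analytes <- setdiff(header, c("sample", "drug", "sample_type"))
    read_perturbation_matrix(path, analyte_panel(c("GAPDH", analytes)))
  }
  load_network <- function(stage) {
    for (f in c("network_edge_file", "network_tractable_file",
                "network_map_file"))
      .require_stage_input(cfg[[f]], stage, paste0("a network file (", f,
                                                   ")"))
    read_interaction_network(cfg$network_edge_file,
                             cfg$network_tractable_file,
                             cfg$network_map_file)
  }
  load_targets <- function(stage) {
    p <- pathto("drug_targets.json")
    .require_stage_input(p, stage, "drug target annotations")
    lapply(jsonlite::read_json(p), unlist)
  }

  # ---- predict --------------------------------------------------------
  if ("predict" %in% st) {
    pm <- load_matrix("predict")
    gi <- utils::read.csv(.require_stage_input(cfg$gi50_file, "predict",
                                               "a GI50 table (gi50_file)"),
                          stringsAsFactors = FALSE)
    sens <- sensitivity_table(gi, direction = cfg$quartile_direction)
    cv <- cohort_cv(pm, sens, model = cfg$cv_model,
                    n_folds = cfg$cv_folds, holdout = cfg$cv_holdout,
                    select = cfg$cv_select, ntree = cfg$cv_ntree,
                    seed = cfg$seed)
    jsonlite::write_json(
      list(pooled_auc = as.list(cv$pooled_auc),
           per_drug_pooled_auc = lapply(cv$per_drug, function(z)
             as.list(z$pooled_auc))),
      pathto("predict.json"), auto_unbox = TRUE, digits = NA)
    fw <- do.call(rbind, lapply(unique(sens$drug), function(d) {
      i <- pm$drug == d & pm$sample %in% sens$sample[sens$drug == d]
      y <- sens$quartile[match(paste(pm$sample[i], d),
                               paste(sens$sample, sens$drug))]
      w <- elastic_net_weights(pm$changes[i, , drop = FALSE], y,
                               seed = cfg$seed)
      cbind(drug = d, w)
    }))
    utils::write.table(fw, pathto("feature_weights.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    record("predict", pathto(c("predict.json", "feature_weights.tsv")),
           c(weights = nrow(fw)))
  }
  # ---- eps ------------------------------------------------------------
  if ("eps" %in% st) {
    pm <- load_matrix("eps")
    net <- load_network("eps")
    ep <- eps_score(pm, net, self_weight = cfg$eps_self_weight)
    utils::write.table(ep, pathto("eps.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    record("eps", pathto("eps.tsv"), c(scores = nrow(ep)))
  }
  # ---- synergy --------------------------------------------------------
  if ("synergy" %in% st) {
    scr <- read_combination_screen(
      .require_stage_input(cfg$screen_file, "synergy",
                           "a combination screen (screen_file)"))
    bl <- screen_bliss(scr, summary = cfg$bliss_summary)
    utils::write.table(bl, pathto("bliss.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    # unordered heatmap view: average the two orientations
    key <- t(apply(bl[, c("drug_a", "drug_b")], 1L, sort))
    un <- stats::aggregate(bliss ~ sample + drug_x + drug_y,
                           data.frame(sample = bl$sample,
                                      drug_x = key[, 1L],
                                      drug_y = key[, 2L],
                                      bliss = bl$bliss), FUN = mean)
    utils::write.table(un, pathto("bliss_unordered.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    record("synergy", pathto(c("bliss.tsv", "bliss_unordered.tsv")),
           c(ordered = nrow(bl), unordered = nrow(un)))
  }
  # ---- report ---------------------------------------------------------
  if ("report" %in% st) {
    ep <- utils::read.table(.require_stage_input(pathto("eps.tsv"),
                                                 "report", "EPS scores"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    bl <- utils::read.table(.require_stage_input(pathto("bliss.tsv"),
                                                 "report",
                                                 "Bliss summaries"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    targets <- load_targets("report")
    rb <- eps_rank_bias(ep, bl, targets)
    pn <- permutation_robustness(ep, bl, targets,
                                 n = cfg$n_permutations,
                                 seed = cfg$seed)
    conc <- topk_concordance(ep, bl, targets,
                             bliss_threshold = cfg$bliss_threshold,
                             k = cfg$top_k)
    jsonlite::write_json(
      list(rank_bias = list(U = rb$U, p_two_sided = rb$p_two_sided,
                            n_top = rb$n_top, n_bottom = rb$n_bottom),
           permutation = list(observed_p = pn$observed_p,
                              empirical_quantile = pn$empirical_quantile,
                              n_permutations = pn$n_permutations),
           concordance = unclass(conc)[c("n_synergistic", "n_hit",
                                         "fraction", "percent", "k")]),
      pathto("report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(p_null = pn$p_null), pathto("null_p_values.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    record("report", pathto(c("report.json", "null_p_values.tsv")),
           c(null = length(pn$p_null)))
  }
  jsonlite::write_json(manifest, pathto("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
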