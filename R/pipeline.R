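#' Run the full RPPA-to-prediction pipeline
#'
#' Orchestrates the whole analysis: load (or take) an RPPA table, select the
#' divergent endpoints and calibration proteins, build the pathway model,
#' run the conditional-robustness calibration, fix the high-MIRI parameters
#' to opposite tail values for the two patients, validate the personalized
#' models, and assemble a report. All randomness derives from `seed`.
#'
#' @param rppa an `rppa_table` or a path to one.
#' @param mapping antibody-to-node map (data.frame or path); defaults to the
#'   map shipped for the patient panel.
#' @param model a `pathway_model`; default [build_default_model()].
#' @param fold divergence threshold.
#' @param k_per_side calibration proteins per direction.
#' @param calibration a [calibration_config()].
#' @param validation a [validation_config()].
#' @param seed integer seed overriding the configs' seeds.
#' @param out_dir optional directory: when given, the report is written as
#'   JSON plus CSV matrices.
#' @return object of class `cra_pipeline`: list with `selection`,
#'   `calibration`, `selected_params`, `patients`, `report`,
#'   `direction_comparison`, `difference_map`, `graph`, `node_ratios`.
#' @export
run_pipeline <- function(rppa = NULL, mapping = NULL,
                         model = build_default_model(),
                         fold = 2, k_per_side = 2,
                         calibration = calibration_config(),
                         validation = validation_config(),
                         seed = NULL, out_dir = NULL) {
  if (is.null(rppa)) {
    rppa <- system.file("extdata", "rppa_table1.csv", package = "pathwayCRA")
  }
  if (is.character(rppa)) rppa <- load_rppa_table(rppa)
  if (is.null(mapping)) {
    mapping <- if (!is.null(rppa$mapping)) rppa$mapping else load_antibody_map()
  } else if (is.character(mapping)) {
    mapping <- load_antibody_map(mapping)
  }
  if (!is.null(seed)) {
    calibration$seed <- as.integer(seed)
    validation$seed <- as.integer(seed) + 1000L
  }

  selection <- select_calibration_proteins(rppa, mapping, model$nodes$name,
                                           k_per_side = k_per_side,
                                           fold = fold)
  node_ratios <- aggregate_phosphosites(rppa, mapping)
  space <- parameter_space(model)

  calib <- run_calibration(model, space, selection, calibration)
  selected <- threshold_parameters(calib$miri[!space$fixed],
                                   rule = calibration$threshold_rule,
                                   value = calibration$threshold_value)
  sOS <- fix_patient_parameters(model, selected, calib$tails, "s-OS")
  lOS <- fix_patient_parameters(model, selected, calib$tails, "l-OS")

  report <- run_validation(sOS, lOS, validation)
  comparison <- compare_directions(report, node_ratios)
  dmap <- miri_difference_map(report$miri_sOS, report$miri_lOS)
  graph <- graph_metrics(model)

  result <- structure(
    list(selection = selection, calibration = calib,
         selected_params = selected,
         patients = list(sOS = sOS, lOS = lOS),
         report = report, direction_comparison = comparison,
         difference_map = dmap, graph = graph, node_ratios = node_ratios,
         seeds = c(calibration = calibration$seed,
                   validation = validation$seed)),
    class = "cra_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_report(result, out_dir)
  result
}

#' @export
print.cra_pipeline <- function(x, ...) {
  print(x$selection)
  cat("Selected parameters (", length(x$selected_params), "): ",
      paste(x$selected_params, collapse = ", "), "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Serializes the pipeline result as `report.json` (selection, selected
#' parameters, fixed values per patient, direction comparison, overall
#' robustness, seeds) plus CSV matrices of the two MIRI maps and their
#' clustered difference, and the dendrogram as Newick text.
#'
#' @param result a `cra_pipeline`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_pipeline_report <- function(result, out_dir) {
  stopifnot(inherits(result, "cra_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    report = file.path(out_dir, "report.json"),
    miri_sOS = file.path(out_dir, "miri_sOS.csv"),
    miri_lOS = file.path(out_dir, "miri_lOS.csv"),
    difference = file.path(out_dir, "miri_difference.csv"),
    dendrogram = file.path(out_dir, "dendrogram.nwk"),
    metrics = file.path(out_dir, "graph_metrics.csv")
  )
  report <- list(
    calibration_proteins = result$selection$calibration_proteins,
    n_divergent = result$selection$n_divergent,
    selected_params = result$selected_params,
    fixed_sOS = as.list(result$patients$sOS$fixed_params),
    fixed_lOS = as.list(result$patients$lOS$fixed_params),
    direction_comparison = result$direction_comparison,
    overall_robustness = as.list(result$report$overall_robustness),
    failure_rate = as.list(result$report$failure_rate),
    seeds = as.list(result$seeds)
  )
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(result$report$miri_sOS, paths["miri_sOS"])
  utils::write.csv(result$report$miri_lOS, paths["miri_lOS"])
  utils::write.csv(result$difference_map$matrix, paths["difference"])
  if (!is.null(result$difference_map$newick)) {
    writeLines(result$difference_map$newick, paths["dendrogram"])
  }
  utils::write.csv(as.data.frame(result$graph), paths["metrics"],
                   row.names = FALSE)
  invisible(paths)
}
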