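#' Validation configuration
#'
#' Study scale is 10000 samples and 100 realizations per patient; the
#' desk-scale defaults (n = 2000, 5 realizations) keep a two-patient
#' validation within minutes on one CPU.
#'
#' @param n_samples hypercube samples per realization.
#' @param realizations independent realizations.
#' @param alpha tail fraction for per-node conditioning.
#' @param seed base RNG seed.
#' @param validation_nodes nodes compared against RPPA directionality
#'   (default ERK, AMPK, mTOR: high closeness-centrality/eccentricity
#'   readouts).
#' @param prediction_nodes nodes reported without RPPA data (default RAS,
#'   the KRAS readout).
#' @return object of class `validation_config`.
#' @export
validation_config <- function(n_samples = 2000, realizations = 5,
                              alpha = 0.1, seed = 1,
                              validation_nodes = c("ERK", "AMPK", "mTOR"),
                              prediction_nodes = "RAS") {
  if (n_samples < 1 || realizations < 1) stop("counts must be >= 1")
  structure(
    list(n_samples = n_samples, realizations = realizations, alpha = alpha,
         seed = seed, validation_nodes = validation_nodes,
         prediction_nodes = prediction_nodes),
    class = "validation_config"
  )
}

# Sample a patient model's free parameters and return pooled AUCs per node
# plus the per-realization node x parameter MIRI matrices.
sample_patient <- function(pm, cfg, with_miri = TRUE, ...) {
  model <- pm$model
  space <- parameter_space(model, fixed = pm$fixed_params)
  nodes <- model$nodes$name
  aucs <- list()
  failed_total <- 0
  mats <- array(NA_real_, dim = c(length(nodes), nrow(space),
                                  cfg$realizations),
                dimnames = list(nodes, space$name, NULL))
  for (r in seq_len(cfg$realizations)) {
    draws <- sample_hypercube(space, cfg$n_samples, seed = cfg$seed + r - 1)
    samples <- run_sampling(model, draws, eval_nodes = nodes, ...)
    failed_total <- failed_total + sum(samples$failed)
    ok <- which(!samples$failed)
    aucs[[r]] <- samples$auc[ok, , drop = FALSE]
    if (with_miri) {
      m <- max(20, floor(cfg$alpha * length(ok)))
      log_draws <- log10(samples$draws)
      free <- which(!space$fixed)
      for (nd in nodes) {
        v <- samples$auc[ok, nd]
        ord <- order(v)
        lower <- ok[ord[seq_len(m)]]
        upper <- ok[rev(ord)[seq_len(m)]]
        for (j in free) {
          mats[nd, j, r] <- compute_miri(log_draws[, j], lower, upper)
        }
      }
    }
  }
  mats[is.na(mats)] <- 0
  list(
    auc = do.call(rbind, aucs),
    miri_mean = apply(mats, c(1, 2), mean),
    miri_sd = apply(mats, c(1, 2), stats::sd),
    failure_rate = failed_total / (cfg$n_samples * cfg$realizations),
    space = space
  )
}

#' Simulate and compare the two personalized models
#'
#' Samples the shared free-parameter space of the s-OS and l-OS patient
#' models, simulates both, summarizes each node's evaluation-function (AUC)
#' distribution, derives the predicted activation direction (which patient
#' is higher), and computes each patient's node-by-parameter MIRI matrix
#' restricted to the free parameters.
#'
#' @param sOS,lOS `patient_model` objects sharing the same free parameters.
#' @param cfg a [validation_config()].
#' @param with_miri compute the node-by-parameter MIRI matrices (default
#'   `TRUE`); set to `FALSE` for a cheap direction-only run.
#' @param ... forwarded to [run_sampling()].
#' @return object of class `prediction_report`: list with `nodes`
#'   (data.frame of per-node mean/median AUC per patient and direction),
#'   `miri_sOS`, `miri_lOS` (node x free-parameter matrices),
#'   `overall_robustness` (per patient), `failure_rate`, `config`.
#' @export
run_validation <- function(sOS, lOS, cfg = validation_config(),
                           with_miri = TRUE, ...) {
  stopifnot(inherits(sOS, "patient_model"), inherits(lOS, "patient_model"))
  if (!setequal(sOS$free_params, lOS$free_params)) {
    stop("patient models must share the same free parameters")
  }
  res_s <- sample_patient(sOS, cfg, with_miri = with_miri, ...)
  res_l <- sample_patient(lOS, cfg, with_miri = with_miri, ...)
  nodes <- colnames(res_s$auc)
  mean_s <- colMeans(res_s$auc)
  mean_l <- colMeans(res_l$auc)
  med_s <- apply(res_s$auc, 2, stats::median)
  med_l <- apply(res_l$auc, 2, stats::median)
  direction <- ifelse(mean_s < mean_l, "lower",
               ifelse(mean_s > mean_l, "higher", "tie"))
  free <- sOS$free_params
  miri_s <- if (with_miri) res_s$miri_mean[, free, drop = FALSE] else NULL
  miri_l <- if (with_miri) res_l$miri_mean[, free, drop = FALSE] else NULL
  structure(
    list(
      nodes = data.frame(
        node = nodes,
        mean_auc_sOS = unname(mean_s), mean_auc_lOS = unname(mean_l),
        median_auc_sOS = unname(med_s), median_auc_lOS = unname(med_l),
        direction = unname(direction),
        stringsAsFactors = FALSE
      ),
      miri_sOS = miri_s,
      miri_lOS = miri_l,
      miri_sd_sOS = if (with_miri) res_s$miri_sd[, free, drop = FALSE],
      miri_sd_lOS = if (with_miri) res_l$miri_sd[, free, drop = FALSE],
      overall_robustness = if (with_miri) c(
        sOS = overall_robustness(miri_s),
        lOS = overall_robustness(miri_l)
      ) else c(sOS = NA_real_, lOS = NA_real_),
      failure_rate = c(sOS = res_s$failure_rate, lOS = res_l$failure_rate),
      config = cfg
    ),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Prediction report over", nrow(x$nodes), "nodes;",
      "overall robustness s-OS =", signif(x$overall_robustness["sOS"], 3),
      "vs l-OS =", signif(x$overall_robustness["lOS"], 3), "\n")
  invisible(x)
}

#' Clustered difference of the two patients' MIRI matrices
#'
#' Element-wise s-OS minus l-OS MIRI, with rows (nodes) ordered by
#' hierarchical clustering (Euclidean distance, average linkage). The
#' dendrogram is returned both as an `hclust` object and as a Newick
#' string.
#'
#' @param sOS_matrix,lOS_matrix node x parameter MIRI matrices of identical
#'   shape and dimnames.
#' @return list with `matrix` (rows in dendrogram order), `hclust`,
#'   `order`, `newick`.
#' @export
miri_difference_map <- function(sOS_matrix, lOS_matrix) {
  if (!identical(dim(sOS_matrix), dim(lOS_matrix))) {
    stop("MIRI matrices must have the same shape")
  }
  d <- sOS_matrix - lOS_matrix
  if (nrow(d) < 3) {
    return(list(matrix = d, hclust = NULL, order = seq_len(nrow(d)),
                newick = NULL))
  }
  hc <- stats::hclust(stats::dist(d, method = "euclidean"),
                      method = "average")
  ord <- hc$order
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(matrix = d[ord, , drop = FALSE], hclust = hc, order = ord,
       newick = newick)
}

#' Compare predicted directions with RPPA directionality
#'
#' A node predicted `"lower"` (s-OS mean AUC below l-OS) agrees with the
#' RPPA data when its aggregated s-OS/l-OS ratio is below 1, and
#' conversely. Nodes without an RPPA ratio are reported as
#' `"prediction-only"`; ties carry no agreement claim.
#'
#' @param report a `prediction_report`.
#' @param rppa_ratios per-node ratio table as from
#'   [aggregate_phosphosites()].
#' @param nodes nodes to assess (default: the report's validation nodes
#'   plus prediction nodes).
#' @return data.frame with `node`, `direction`, `rppa_ratio`,
#'   `rppa_direction`, `status` (`"agree"`, `"disagree"`, `"tie"`,
#'   `"prediction-only"`); the number of agreements is in
#'   `attr(, "n_agree")`.
#' @export
compare_directions <- function(report, rppa_ratios, nodes = NULL) {
  stopifnot(inherits(report, "prediction_report"))
  if (is.null(nodes)) {
    nodes <- c(report$config$validation_nodes, report$config$prediction_nodes)
  }
  missing_nodes <- setdiff(nodes, report$nodes$node)
  if (length(missing_nodes) > 0) {
    stop("nodes absent from report: ", paste(missing_nodes, collapse = ", "))
  }
  idx <- match(nodes, report$nodes$node)
  direction <- report$nodes$direction[idx]
  ratio <- rppa_ratios$ratio[match(nodes, rppa_ratios$node)]
  rppa_dir <- ifelse(is.na(ratio), NA_character_,
              ifelse(ratio < 1, "lower", ifelse(ratio > 1, "higher", "tie")))
  status <- ifelse(is.na(ratio), "prediction-only",
            ifelse(direction == "tie" | rppa_dir == "tie", "tie",
            ifelse(direction == rppa_dir, "agree", "disagree")))
  out <- data.frame(node = nodes, direction = direction,
                    rppa_ratio = ratio, rppa_direction = rppa_dir,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "n_agree") <- sum(status == "agree")
  attr(out, "n_assessable") <- sum(status %in% c("agree", "disagree"))
  out
}

#' Overall robustness of a patient
#'
#' Our operationalization of whole-network robustness: the mean of all
#' entries of the node-by-parameter MIRI matrix. Higher values indicate a
#' network whose outputs are more strongly conditioned by its parameters,
#' read as a more robust signaling state.
#'
#' @param matrix node x parameter MIRI matrix.
#' @return scalar mean MIRI.
#' @export
overall_robustness <- function(matrix) {
  if (length(matrix) == 0) stop("empty MIRI matrix")
  mean(matrix)
}
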