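#' Calibration configuration
#'
#' Study-scale settings are 100000 samples and 10 realizations; the package
#' defaults are desk-scale (n = 5000, 3 realizations) so a calibration
#' completes in minutes on one CPU. The scale only affects Monte-Carlo
#' precision, not the algorithm.
#'
#' @param n_samples hypercube samples per realization.
#' @param realizations independent hypercube realizations.
#' @param alpha tail fraction for the conditioning.
#' @param threshold_rule `"boxplot-fence"` (default) or `"fixed-value"`.
#' @param threshold_value cutoff when `threshold_rule = "fixed-value"`.
#' @param seed base RNG seed.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(n_samples = 5000, realizations = 3,
                               alpha = 0.1,
                               threshold_rule = c("boxplot-fence",
                                                  "fixed-value"),
                               threshold_value = NULL, seed = 1) {
  if (n_samples < 1 || realizations < 1) stop("counts must be >= 1")
  threshold_rule <- match.arg(threshold_rule)
  if (threshold_rule == "fixed-value" && is.null(threshold_value)) {
    stop("fixed-value rule needs threshold_value")
  }
  structure(
    list(n_samples = n_samples, realizations = realizations, alpha = alpha,
         threshold_rule = threshold_rule, threshold_value = threshold_value,
         seed = seed),
    class = "calibration_config"
  )
}

#' Run the conditional-robustness calibration
#'
#' For each hypercube realization: draw parameters, simulate, evaluate the
#' AUC of the four calibration proteins, split the samples into the
#' "s-OS-like" and "l-OS-like" joint directional tails, and score every free
#' parameter with the MIRI between its two conditioned distributions.
#' Results are averaged over realizations; the tail-conditioned draws are
#' pooled across realizations for later parameter fixing.
#'
#' @param model a `pathway_model`.
#' @param space a `parameter_space`.
#' @param selection a `divergence_selection` carrying `calibration_proteins`
#'   (see [select_calibration_proteins()]); `"+"` proteins condition on
#'   their upper AUC tail in the s-OS-like set, `"-"` proteins on their
#'   lower tail.
#' @param cfg a [calibration_config()].
#' @param ... forwarded to [run_sampling()].
#' @return object of class `cra_calibration`: list with `miri` (named mean
#'   over realizations), `miri_sd`, `tails` (pooled conditioned draw
#'   matrices `sOS` and `lOS`), `directions`, `fallback_count`,
#'   `failure_rate`, `config`.
#' @export
run_calibration <- function(model, space, selection, cfg = calibration_config(),
                            ...) {
  stopifnot(inherits(model, "pathway_model"),
            inherits(space, "parameter_space"),
            inherits(cfg, "calibration_config"))
  cp <- selection$calibration_proteins
  if (is.null(cp) || nrow(cp) < 2) {
    stop("selection must carry directed calibration proteins")
  }
  if (!all(cp$node %in% model$nodes$name)) {
    stop("calibration proteins must be model nodes")
  }
  directions <- stats::setNames(
    ifelse(cp$direction == "+", "upper", "lower"), cp$node)
  ts <- tail_spec(cfg$alpha, directions)

  R <- cfg$realizations
  miri_real <- matrix(NA_real_, nrow = R, ncol = nrow(space),
                      dimnames = list(NULL, space$name))
  tails_s <- list()
  tails_l <- list()
  fallback_count <- 0
  n_failed <- 0
  for (r in seq_len(R)) {
    draws <- sample_hypercube(space, cfg$n_samples, seed = cfg$seed + r - 1)
    samples <- run_sampling(model, draws, eval_nodes = cp$node, ...)
    n_failed <- n_failed + sum(samples$failed)
    tails <- select_joint_tail(samples, ts)
    fallback_count <- fallback_count + tails$fallback
    miri_real[r, ] <- miri_per_parameter(samples, space,
                                         tails$lOS_like, tails$sOS_like)
    tails_s[[r]] <- samples$draws[tails$sOS_like, , drop = FALSE]
    tails_l[[r]] <- samples$draws[tails$lOS_like, , drop = FALSE]
  }
  structure(
    list(
      miri = colMeans(miri_real),
      miri_sd = apply(miri_real, 2, stats::sd),
      miri_realizations = miri_real,
      tails = list(sOS = do.call(rbind, tails_s),
                   lOS = do.call(rbind, tails_l)),
      directions = directions,
      fallback_count = fallback_count,
      failure_rate = n_failed / (cfg$n_samples * R),
      config = cfg
    ),
    class = "cra_calibration"
  )
}

#' Threshold the calibration MIRI values
#'
#' The default rule selects parameters above the upper boxplot fence of the
#' MIRI distribution, `Q3 + 1.5 * IQR`; an explicit cutoff is available as
#' the `"fixed-value"` rule. An empty selection is returned with a warning
#' (the caller decides how to proceed).
#'
#' @param miri named numeric vector of per-parameter MIRI values.
#' @param rule `"boxplot-fence"` or `"fixed-value"`.
#' @param value cutoff for the fixed-value rule.
#' @return character vector of selected parameter names (may be empty).
#' @export
threshold_parameters <- function(miri, rule = c("boxplot-fence",
                                                "fixed-value"),
                                 value = NULL) {
  rule <- match.arg(rule)
  if (length(miri) < 4) stop("need at least 4 parameters to threshold")
  if (is.null(names(miri))) stop("miri must be named")
  cutoff <- if (rule == "boxplot-fence") {
    q <- stats::quantile(miri, c(0.25, 0.75), names = FALSE)
    q[2] + 1.5 * (q[2] - q[1])
  } else {
    if (is.null(value)) stop("fixed-value rule needs value")
    value
  }
  selected <- names(miri)[miri > cutoff]
  if (length(selected) == 0) {
    warning("no parameter exceeds the MIRI threshold (cutoff = ",
            signif(cutoff, 3), ")")
  }
  selected
}

#' Fix patient-specific parameter values from the conditioned tails
#'
#' Builds one personalized model per patient by fixing each selected
#' parameter to the median of its conditioned draws in that patient's tail
#' set: the s-OS model uses the "s-OS-like" tail, the l-OS model the
#' opposite tail. The two patient models therefore fix the same parameter
#' names to opposite-tail values and share the remaining free space.
#'
#' @param model a `pathway_model`.
#' @param selected parameter names to fix (from [threshold_parameters()]).
#' @param tails pooled conditioned draws, the `tails` element of a
#'   `cra_calibration`.
#' @param patient `"s-OS"` or `"l-OS"`.
#' @return object of class `patient_model`: list with `patient_label`,
#'   `model`, `fixed_params` (named values), `free_params` (names).
#' @export
fix_patient_parameters <- function(model, selected, tails, patient) {
  stopifnot(inherits(model, "pathway_model"))
  patient <- match.arg(patient, c("s-OS", "l-OS"))
  if (length(selected) == 0) {
    warning("empty selection: patient model keeps all parameters free")
    fixed <- stats::setNames(numeric(0), character(0))
  } else {
    pool <- if (patient == "s-OS") tails$sOS else tails$lOS
    if (is.null(pool) || !all(selected %in% colnames(pool))) {
      stop("missing conditioned samples for selected parameters")
    }
    fixed <- apply(pool[, selected, drop = FALSE], 2, stats::median)
  }
  structure(
    list(
      patient_label = patient,
      model = model,
      fixed_params = fixed,
      free_params = setdiff(model$param_names, names(fixed))
    ),
    class = "patient_model"
  )
}

#' @export
print.patient_model <- function(x, ...) {
  cat("Patient model [", x$patient_label, "]: ",
      length(x$fixed_params), " fixed, ", length(x$free_params),
      " free parameters\n", sep = "")
  invisible(x)
}
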