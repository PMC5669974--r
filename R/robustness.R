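#' Define the parameter space of a model
#'
#' Per-parameter log-scale sampling intervals around the nominal values.
#' Rate and Michaelis constants default to a symmetric `span`-fold range
#' (nominal/span to nominal*span, log-uniform); clamped-activity `level_*`
#' parameters are additionally capped at 1 because they are active
#' fractions. Individual parameters can be fixed to a constant.
#'
#' @param model a `pathway_model`.
#' @param span multiplicative half-range (default 100, i.e. two decades each
#'   way).
#' @param fixed named numeric vector of parameters held constant.
#' @return An object of class `parameter_space`: data.frame with `name`,
#'   `nominal`, `lower`, `upper`, `fixed` (logical), `value` (fixed value or
#'   `NA`).
#' @export
parameter_space <- function(model, span = 100, fixed = numeric(0)) {
  stopifnot(inherits(model, "pathway_model"))
  if (span <= 1) stop("span must be > 1")
  nominal <- model$nominal
  lower <- nominal / span
  upper <- nominal * span
  is_level <- startsWith(names(nominal), "level_")
  upper[is_level] <- pmin(upper[is_level], 1)
  sp <- data.frame(
    name = names(nominal), nominal = unname(nominal),
    lower = unname(lower), upper = unname(upper),
    fixed = FALSE, value = NA_real_, stringsAsFactors = FALSE
  )
  if (length(fixed) > 0) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% sp$name)) {
      stop("fixed must be named after model parameters")
    }
    i <- match(names(fixed), sp$name)
    sp$fixed[i] <- TRUE
    sp$value[i] <- unname(fixed)
    out_of_bounds <- fixed < sp$lower[i] | fixed > sp$upper[i]
    if (any(out_of_bounds)) {
      stop("fixed value outside bounds for: ",
           paste(names(fixed)[out_of_bounds], collapse = ", "))
    }
  }
  structure(sp, class = c("parameter_space", "data.frame"))
}

#' Latin-hypercube sample of a parameter space
#'
#' Stratified draws: each free dimension is divided into `n` equal-
#' probability strata on the log scale, each hit exactly once (Latin
#' hypercube via the `lhs` package), then mapped log-uniformly onto its
#' bounds. Fixed dimensions are constant columns.
#'
#' @param space a `parameter_space`.
#' @param n number of samples (>= 2).
#' @param seed integer RNG seed.
#' @return `n` x `n_parameters` matrix with parameter names as columns.
#' @export
sample_hypercube <- function(space, n, seed = 1) {
  stopifnot(inherits(space, "parameter_space"))
  if (!is.numeric(n) || n < 2) stop("n must be at least 2")
  free <- !space$fixed
  if (!any(free)) stop("degenerate parameter space: all parameters fixed")
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(as.integer(n), sum(free))
  lo <- log(space$lower[free])
  hi <- log(space$upper[free])
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(space),
                  dimnames = list(NULL, space$name))
  draws[, free] <- exp(sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))
  if (any(!free)) {
    draws[, !free] <- matrix(rep(space$value[!free], each = n), nrow = n)
  }
  draws
}

#' Simulate a hypercube sample and record evaluation-function values
#'
#' Runs one model simulation per parameter draw and records the trajectory
#' AUC of every requested node. Integration failures are flagged and
#' retained (their AUCs are `NA`); downstream statistics exclude them. A
#' failure rate above `max_failure_rate` aborts with diagnostics.
#'
#' @param model a `pathway_model`.
#' @param draws matrix from [sample_hypercube()].
#' @param eval_nodes nodes whose AUC to record (default: all).
#' @param horizon,n_times,rtol,atol forwarded to [simulate_pathway()].
#' @param max_failure_rate abort threshold for the failed fraction.
#' @return An object of class `cra_samples`: list with `draws`, `auc`
#'   (n x node matrix), `failed` (logical), `n`.
#' @export
run_sampling <- function(model, draws, eval_nodes = model$nodes$name,
                         horizon = model$horizon, n_times = 51,
                         rtol = 1e-6, atol = 1e-9,
                         max_failure_rate = 0.05) {
  stopifnot(inherits(model, "pathway_model"))
  if (!all(eval_nodes %in% model$nodes$name)) {
    stop("unknown evaluation node(s): ",
         paste(setdiff(eval_nodes, model$nodes$name), collapse = ", "))
  }
  draws <- draws[, model$param_names, drop = FALSE]
  n <- nrow(draws)
  ctx <- if (is.null(model$ctx)) model_context(model) else model$ctx
  times <- seq(0, horizon, length.out = n_times)
  dt <- times[2] - times[1]
  rec <- model$nodes$role == "input-receptor"
  cl <- model$nodes$clamped
  level_names <- paste0("level_", model$nodes$name[cl])
  nodes <- model$nodes$name
  eval_idx <- match(eval_nodes, nodes)
  auc <- matrix(NA_real_, nrow = n, ncol = length(eval_nodes),
                dimnames = list(NULL, eval_nodes))
  failed <- rep(FALSE, n)
  y0 <- stats::setNames(rep(0, length(nodes)), nodes)
  y0[rec] <- model$receptor_seed
  # trapezoid weights on the fixed output grid
  w <- c(dt / 2, rep(dt, n_times - 2), dt / 2)
  for (i in seq_len(n)) {
    theta <- draws[i, ]
    invisible(.Call(set_pathway_ctx, ctx$node_info, ctx$edge_info,
                    as.numeric(theta)))
    y <- y0
    if (any(cl)) y[cl] <- pmin(pmax(theta[level_names], 0), 1)
    out <- tryCatch(
      deSolve::lsoda(y, times, func = "pathway_deriv", parms = NULL,
                     dllname = "pathwayCRA", initfunc = NULL,
                     rtol = rtol, atol = atol),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(out) || nrow(out) < n_times) {
      failed[i] <- TRUE
      next
    }
    st <- out[, 1 + eval_idx, drop = FALSE]
    if (any(!is.finite(st)) || any(st < -1e-6) || any(st > 1 + 1e-6)) {
      failed[i] <- TRUE
      next
    }
    auc[i, ] <- as.numeric(crossprod(w, st))
  }
  rate <- mean(failed)
  if (rate > max_failure_rate) {
    stop(sprintf(
      "integration failure rate %.1f%% exceeds %.1f%% (n = %d failed of %d)",
      100 * rate, 100 * max_failure_rate, sum(failed), n))
  }
  structure(list(draws = draws, auc = auc, failed = failed, n = n),
            class = "cra_samples")
}

#' Tail specification for joint conditioning
#'
#' @param alpha tail fraction, in (0, 0.5).
#' @param directions named character vector, one of `"upper"`/`"lower"` per
#'   calibration protein: the tail of its evaluation function that
#'   corresponds to the short-survival ("s-OS-like") state.
#' @return object of class `tail_spec`.
#' @export
tail_spec <- function(alpha = 0.1, directions) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop("alpha must be in (0, 0.5)")
  }
  if (is.null(names(directions)) ||
      !all(directions %in% c("upper", "lower"))) {
    stop("directions must be a named vector of 'upper'/'lower'")
  }
  structure(list(alpha = alpha, directions = directions),
            class = "tail_spec")
}

#' Joint directional tail conditioning
#'
#' Splits the non-failed samples into a "s-OS-like" set (every calibration
#' protein's evaluation function in its assigned tail: upper for "+"
#' proteins, lower for "-") and the opposite "l-OS-like" set, by
#' intersecting the per-protein alpha-tails. When an intersection holds
#' fewer than `min_size` samples (at small n the product of tail
#' probabilities makes this the norm), the conditioning falls back to
#' ranking samples by the mean of direction-signed standardized evaluation
#' values and taking the alpha-fraction extremes; the fallback is reported.
#'
#' @param samples a `cra_samples`.
#' @param spec a [tail_spec()]; its `directions` names must be columns of
#'   the sample AUC matrix.
#' @param min_size smallest usable intersection (default 20, the minimum
#'   tail size accepted by [compute_miri()]).
#' @return list with `sOS_like`, `lOS_like` (row indices into the draws),
#'   `fallback` (logical), `alpha`, `n_ok`.
#' @export
select_joint_tail <- function(samples, spec, min_size = 20) {
  stopifnot(inherits(samples, "cra_samples"), inherits(spec, "tail_spec"))
  prot <- names(spec$directions)
  if (!all(prot %in% colnames(samples$auc))) {
    stop("tail spec names missing from sampled evaluation functions")
  }
  ok <- which(!samples$failed)
  if (length(ok) == 0) stop("computation error: all samples failed")
  if (length(ok) < ceiling(4 / spec$alpha)) {
    stop("too few non-failed samples for alpha = ", spec$alpha)
  }
  auc <- samples$auc[ok, prot, drop = FALSE]
  alpha <- spec$alpha

  in_tail <- function(v, side) {
    if (side == "upper") v >= stats::quantile(v, 1 - alpha, names = FALSE)
    else v <= stats::quantile(v, alpha, names = FALSE)
  }
  flip <- c(upper = "lower", lower = "upper")
  s_mask <- rep(TRUE, length(ok))
  l_mask <- rep(TRUE, length(ok))
  for (p in prot) {
    s_mask <- s_mask & in_tail(auc[, p], spec$directions[[p]])
    l_mask <- l_mask & in_tail(auc[, p], flip[[spec$directions[[p]]]])
  }
  fallback <- sum(s_mask) < min_size || sum(l_mask) < min_size
  if (!fallback) {
    sOS <- ok[s_mask]
    lOS <- ok[l_mask]
  } else {
    sgn <- ifelse(spec$directions[prot] == "upper", 1, -1)
    z <- scale(auc)
    z[!is.finite(z)] <- 0              # degenerate constant column
    score <- as.numeric(z %*% sgn) / length(prot)
    m <- max(min_size, floor(alpha * length(ok)))
    ord <- order(score)
    sOS <- ok[rev(ord)[seq_len(m)]]
    lOS <- ok[ord[seq_len(m)]]
  }
  list(sOS_like = sOS, lOS_like = lOS, fallback = fallback,
       alpha = alpha, n_ok = length(ok))
}

#' Moment independent robustness indicator (MIRI)
#'
#' The dissimilarity between the two tail-conditioned distributions of a
#' parameter, measured as their total-variation distance
#' `0.5 * integral |f_L - f_U|`, where `f_L` and `f_U` are Gaussian kernel
#' density estimates with a common Silverman bandwidth computed on the
#' pooled data, evaluated on a shared 512-point grid spanning both sets.
#' The result lies in `[0, 1]`: 0 for identical conditioned distributions,
#' 1 for disjoint supports.
#'
#' @param values numeric vector (one parameter's sampled values; the CRA
#'   drivers pass log10 draws since parameters are sampled log-uniformly).
#' @param lower_idx,upper_idx index sets of the two conditioned subsamples
#'   (each at least `min_size`).
#' @param n_grid evaluation grid size (default 512).
#' @param min_size minimum tail size (default 20).
#' @return MIRI value in `[0, 1]`.
#' @export
compute_miri <- function(values, lower_idx, upper_idx, n_grid = 512,
                         min_size = 20) {
  if (length(lower_idx) < min_size || length(upper_idx) < min_size) {
    stop("insufficient data: each tail needs at least ", min_size, " samples")
  }
  x_l <- values[lower_idx]
  x_u <- values[upper_idx]
  if (any(!is.finite(c(x_l, x_u)))) stop("non-finite values in tails")
  pooled <- c(x_l, x_u)
  bw <- tryCatch(stats::bw.nrd0(pooled), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) {
    # pooled sample (numerically) constant: distributions coincide
    return(if (stats::sd(pooled) == 0 || diff(range(pooled)) == 0) 0 else 1)
  }
  lo <- min(pooled) - 3 * bw
  hi <- max(pooled) + 3 * bw
  grid <- seq(lo, hi, length.out = n_grid)
  f_l <- stats::density(x_l, bw = bw, from = lo, to = hi, n = n_grid)$y
  f_u <- stats::density(x_u, bw = bw, from = lo, to = hi, n = n_grid)$y
  miri <- 0.5 * trapz(grid, abs(f_l - f_u))
  min(max(miri, 0), 1)
}

#' Histogram estimator of the MIRI (cross-check)
#'
#' Same total-variation distance as [compute_miri()] but estimated from
#' 64-bin histograms on a common range. Kept as an independent estimator to
#' cross-check the kernel version.
#'
#' @inheritParams compute_miri
#' @param bins number of common-range bins.
#' @return MIRI value in `[0, 1]`.
#' @export
compute_miri_hist <- function(values, lower_idx, upper_idx, bins = 64,
                              min_size = 20) {
  if (length(lower_idx) < min_size || length(upper_idx) < min_size) {
    stop("insufficient data: each tail needs at least ", min_size, " samples")
  }
  x_l <- values[lower_idx]
  x_u <- values[upper_idx]
  rng <- range(c(x_l, x_u))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  p_l <- tabulate(findInterval(x_l, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), bins) / length(x_l)
  p_u <- tabulate(findInterval(x_u, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), bins) / length(x_u)
  0.5 * sum(abs(p_l - p_u))
}

# MIRI of every free parameter between two conditioned index sets,
# computed on the log10 scale of the draws.
miri_per_parameter <- function(samples, space, lower_idx, upper_idx) {
  free <- space$name[!space$fixed]
  miri <- stats::setNames(rep(0, nrow(space)), space$name)
  for (p in free) {
    miri[p] <- compute_miri(log10(samples$draws[, p]), lower_idx, upper_idx)
  }
  miri
}

#' Node-by-parameter MIRI matrix
#'
#' For each node taken alone as evaluation function, conditions the samples
#' on the node's own lower and upper alpha-tails and scores every free
#' parameter with the MIRI; repeated over independent hypercube
#' realizations and averaged. Parameters fixed in the space (or absent from
#' a node's ancestry) report 0 / statistically zero values.
#'
#' @param model a `pathway_model`.
#' @param space a `parameter_space`.
#' @param eval_nodes nodes to use as evaluation functions (default: all).
#' @param n samples per realization.
#' @param realizations number of independent realizations.
#' @param seed base RNG seed (realization r uses `seed + r - 1`).
#' @param alpha tail fraction.
#' @param ... forwarded to [run_sampling()].
#' @return list with `mean` and `sd` (node x parameter matrices over
#'   realizations), `realizations`, `n`, `failure_rate`.
#' @export
miri_matrix <- function(model, space, eval_nodes = model$nodes$name,
                        n = 2000, realizations = 3, seed = 1, alpha = 0.1,
                        ...) {
  stopifnot(inherits(model, "pathway_model"))
  if (!all(eval_nodes %in% model$nodes$name)) {
    stop("eval_nodes must be model nodes")
  }
  per_real <- array(
    NA_real_,
    dim = c(length(eval_nodes), nrow(space), realizations),
    dimnames = list(eval_nodes, space$name, NULL)
  )
  n_failed <- 0
  for (r in seq_len(realizations)) {
    draws <- sample_hypercube(space, n, seed = seed + r - 1)
    samples <- run_sampling(model, draws, eval_nodes = eval_nodes, ...)
    n_failed <- n_failed + sum(samples$failed)
    ok <- which(!samples$failed)
    m <- max(20, floor(alpha * length(ok)))
    log_draws <- log10(samples$draws)
    free <- which(!space$fixed)
    for (nd in eval_nodes) {
      v <- samples$auc[ok, nd]
      ord <- order(v)
      lower <- ok[ord[seq_len(m)]]
      upper <- ok[rev(ord)[seq_len(m)]]
      for (j in free) {
        per_real[nd, j, r] <- compute_miri(log_draws[, j], lower, upper)
      }
    }
  }
  per_real[is.na(per_real)] <- 0      # fixed parameters score 0
  list(
    mean = apply(per_real, c(1, 2), mean),
    sd = apply(per_real, c(1, 2), stats::sd),
    realizations = realizations, n = n,
    failure_rate = n_failed / (n * realizations)
  )
}
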