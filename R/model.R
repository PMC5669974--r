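#' Build a pathway model from a model-definition file
#'
#' Reads a YAML description of the signaling network (nodes with roles,
#' signed enzymatic edges, nominal parameter values) and assembles the
#' parameter table. The default definition shipped with the package encodes
#' the 21-node EGFR/IGF1R-MAPK-PI3K/mTOR network with 30 interactions and 86
#' named parameters.
#'
#' The construction rules are: every edge is an enzymatic conversion
#' following Michaelis-Menten kinetics on its substrate fraction (the
#' inactive fraction for activating edges, the active fraction for
#' inhibiting ones); every node obeys the conservation law
#' `active + inactive = 1` so only the active fraction is a state; receptors
#' are driven by a constant stimulus (mass action on the inactive fraction);
#' basal deactivation is mass action. Nodes marked `clamped` (the
#' constitutive phosphatases) are held at a constant active fraction given by
#' a `level_*` parameter; nodes marked `basal_activation` carry a `kact_*`
#' rate; a node marked `irreversible` (cleaved caspase) has no basal
#' deactivation.
#'
#' @param config path to a YAML model definition; default is the shipped
#'   21-node network.
#' @return An object of class `pathway_model` with elements `nodes`
#'   (data.frame `name`, `role`, `clamped`, ...), `edges` (data.frame with
#'   parameter names), `param_names`, `nominal` (named numeric vector),
#'   `horizon`, `receptor_seed`.
#' @export
build_default_model <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "model_21node.yaml", package = "pathwayCRA")
  }
  if (!file.exists(config)) stop("model definition not found: ", config)
  def <- yaml::read_yaml(config)

  nodes <- do.call(rbind, lapply(def$nodes, function(nd) {
    data.frame(
      name = nd$name,
      role = nd$role,
      clamped = isTRUE(nd$clamped),
      basal_activation = isTRUE(nd$basal_activation),
      irreversible = isTRUE(nd$irreversible),
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(nodes$name)) {
    stop("model config error: duplicate node ",
         nodes$name[duplicated(nodes$name)][1])
  }
  edges <- do.call(rbind, lapply(def$edges, function(e) {
    data.frame(source = e$source, target = e$target, sign = e$sign,
               law = if (is.null(e$law)) "michaelis_menten" else e$law,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        sign = character(0), law = character(0),
                        stringsAsFactors = FALSE)
  }
  bad_sign <- !edges$sign %in% c("activating", "inhibiting")
  if (any(bad_sign)) stop("model config error: invalid edge sign")
  dangling <- setdiff(unique(c(edges$source, edges$target)), nodes$name)
  if (length(dangling) > 0) {
    stop("model config error: edge references undeclared node(s): ",
         paste(dangling, collapse = ", "))
  }
  if (any(edges$target %in% nodes$name[nodes$clamped])) {
    stop("model config error: clamped node cannot be an edge target")
  }

  nominal_kind <- def$nominal
  edges$k_name <- sprintf("k_%s_%s", edges$source, edges$target)
  edges$K_name <- ifelse(edges$law == "michaelis_menten",
                         sprintf("K_%s_%s", edges$source, edges$target),
                         NA_character_)

  receptors <- nodes$name[nodes$role == "input-receptor"]
  decaying <- nodes$name[!nodes$clamped & !nodes$irreversible]
  basal <- nodes$name[nodes$basal_activation]
  clamped <- nodes$name[nodes$clamped]

  param_names <- c(
    edges$k_name,
    edges$K_name[!is.na(edges$K_name)],
    sprintf("kdec_%s", decaying),
    sprintf("stim_%s", receptors),
    sprintf("kact_%s", basal),
    sprintf("level_%s", clamped)
  )
  nominal <- c(
    rep(nominal_kind$k, nrow(edges)),
    rep(nominal_kind$K, sum(!is.na(edges$K_name))),
    rep(nominal_kind$kdec, length(decaying)),
    rep(nominal_kind$stim, length(receptors)),
    rep(nominal_kind$kact, length(basal)),
    rep(nominal_kind$level, length(clamped))
  )
  names(nominal) <- param_names

  model <- structure(
    list(
      name = def$name,
      nodes = nodes,
      edges = edges,
      param_names = param_names,
      nominal = nominal,
      horizon = if (is.null(def$horizon)) 100 else def$horizon,
      receptor_seed = if (is.null(def$receptor_seed)) 1e-3 else def$receptor_seed
    ),
    class = "pathway_model"
  )
  model$ctx <- model_context(model)
  model
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("Pathway model '", x$name, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " interactions, ", length(x$param_names),
      " parameters\n", sep = "")
  invisible(x)
}

# Integer encodings of the model topology consumed by the compiled
# derivative. Parameter indices are 0-based positions in the model's
# parameter vector; -1 marks an absent term.
model_context <- function(model) {
  pidx <- function(nm) {
    i <- match(nm, model$param_names)
    ifelse(is.na(i), 0L, i - 1L)
  }
  has <- function(nm) nm %in% model$param_names
  nd <- model$nodes
  node_info <- vapply(seq_len(nrow(nd)), function(i) {
    nm <- nd$name[i]
    c(
      clamped = as.integer(nd$clamped[i]),
      stim = if (has(paste0("stim_", nm))) pidx(paste0("stim_", nm)) else -1L,
      kact = if (has(paste0("kact_", nm))) pidx(paste0("kact_", nm)) else -1L,
      kdec = if (has(paste0("kdec_", nm))) pidx(paste0("kdec_", nm)) else -1L,
      level = if (has(paste0("level_", nm))) pidx(paste0("level_", nm)) else -1L
    )
  }, integer(5))
  ed <- model$edges
  edge_info <- vapply(seq_len(nrow(ed)), function(i) {
    c(
      src = match(ed$source[i], nd$name) - 1L,
      tgt = match(ed$target[i], nd$name) - 1L,
      sign = if (ed$sign[i] == "activating") 1L else -1L,
      mm = as.integer(ed$law[i] == "michaelis_menten"),
      k = pidx(ed$k_name[i]),
      K = if (is.na(ed$K_name[i])) -1L else pidx(ed$K_name[i])
    )
  }, integer(6))
  list(node_info = node_info, edge_info = edge_info)
}

# Initial condition: all nodes inactive except a small receptor seed;
# clamped nodes start at their level parameter.
initial_state <- function(model, theta) {
  y0 <- stats::setNames(rep(0, nrow(model$nodes)), model$nodes$name)
  rec <- model$nodes$role == "input-receptor"
  y0[rec] <- model$receptor_seed
  cl <- model$nodes$clamped
  if (any(cl)) {
    y0[cl] <- pmin(pmax(theta[paste0("level_", model$nodes$name[cl])], 0), 1)
  }
  y0
}

#' Assemble the ODE derivative function of a pathway model
#'
#' Returns an R closure `f(t, state, theta)` evaluating the right-hand side
#' of the model's ODE system, in the `deSolve` convention (a list whose first
#' element is the derivative vector). [simulate_pathway()] does not use this
#' closure (it integrates through the compiled equivalent); the closure is
#' the reference form of the equations, convenient for inspection and for
#' cross-checking the compiled code.
#'
#' @param model a `pathway_model`.
#' @return function of `(t, state, theta)`.
#' @export
assemble_odes <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  nd <- model$nodes
  ed <- model$edges
  function(t, state, theta) {
    a <- pmin(pmax(as.numeric(state), 0), 1)
    names(a) <- nd$name
    a[nd$clamped] <- pmin(pmax(
      theta[paste0("level_", nd$name[nd$clamped])], 0), 1)
    d <- stats::setNames(rep(0, nrow(nd)), nd$name)
    rec <- nd$role == "input-receptor"
    d[rec] <- d[rec] + theta[paste0("stim_", nd$name[rec])] * (1 - a[rec])
    bas <- nd$basal_activation
    d[bas] <- d[bas] + theta[paste0("kact_", nd$name[bas])] * (1 - a[bas])
    dec <- !nd$clamped & !nd$irreversible
    d[dec] <- d[dec] - theta[paste0("kdec_", nd$name[dec])] * a[dec]
    for (i in seq_len(nrow(ed))) {
      tg <- ed$target[i]
      s <- a[ed$source[i]]
      k <- theta[ed$k_name[i]]
      sub <- if (ed$sign[i] == "activating") 1 - a[tg] else a[tg]
      v <- if (ed$law[i] == "michaelis_menten") {
        k * s * sub / (theta[ed$K_name[i]] + sub)
      } else {
        k * s * sub
      }
      d[tg] <- d[tg] + if (ed$sign[i] == "activating") v else -v
    }
    d[nd$clamped] <- 0
    list(d)
  }
}

#' Simulate a pathway model
#'
#' Integrates the active-fraction ODE system with `deSolve::lsoda` (stiff-
#' capable) through the package's compiled right-hand side. Integration
#' problems are reported in the `failed` field, never silently defaulted:
#' a run is failed if the integrator stops early or any state leaves
#' `[0, 1]` beyond numerical tolerance.
#'
#' @param model a `pathway_model`.
#' @param theta named (or model-ordered) strictly positive parameter vector.
#' @param horizon end time; defaults to the model's horizon.
#' @param n_times number of equally spaced output times (including 0).
#' @param rtol,atol integrator tolerances.
#' @return An object of class `pathway_trajectory`: list with `times`,
#'   `states` (time x node matrix of active fractions) and `failed`.
#' @export
simulate_pathway <- function(model, theta = model$nominal,
                             horizon = model$horizon, n_times = 51,
                             rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "pathway_model"))
  theta <- check_theta(model, theta)
  if (horizon <= 0) stop("horizon must be positive")
  ctx <- if (is.null(model$ctx)) model_context(model) else model$ctx
  invisible(.Call(set_pathway_ctx, ctx$node_info, ctx$edge_info,
                  as.numeric(theta)))
  y0 <- initial_state(model, theta)
  times <- seq(0, horizon, length.out = n_times)
  out <- tryCatch(
    deSolve::lsoda(y0, times, func = "pathway_deriv",
                   parms = NULL, dllname = "pathwayCRA",
                   initfunc = NULL, rtol = rtol, atol = atol),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  failed <- is.null(out) || nrow(out) < length(times)
  states <- NULL
  if (!failed) {
    states <- unname(out[, -1, drop = FALSE])
    colnames(states) <- model$nodes$name
    if (any(!is.finite(states)) ||
        any(states < -1e-6) || any(states > 1 + 1e-6)) {
      failed <- TRUE
    }
  }
  structure(
    list(times = if (failed) times else out[, 1], states = states,
         failed = failed),
    class = "pathway_trajectory"
  )
}

check_theta <- function(model, theta) {
  p <- length(model$param_names)
  if (length(theta) != p) {
    stop("theta must have length ", p)
  }
  if (is.null(names(theta))) {
    names(theta) <- model$param_names
  } else {
    if (!setequal(names(theta), model$param_names)) {
      stop("theta names do not match the model parameters")
    }
    theta <- theta[model$param_names]
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("theta must be strictly positive")
  }
  theta
}

#' Area under the active-fraction curve of one node
#'
#' The evaluation function of the robustness analysis: the trapezoidal
#' integral of a node's active fraction over the simulated horizon.
#'
#' @param traj a `pathway_trajectory`.
#' @param node node name.
#' @return non-negative scalar; `NA` for a failed trajectory.
#' @export
evaluation_auc <- function(traj, node) {
  stopifnot(inherits(traj, "pathway_trajectory"))
  if (traj$failed) return(NA_real_)
  if (!node %in% colnames(traj$states)) stop("unknown node: ", node)
  trapz(traj$times, traj$states[, node])
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

#' Conservation residual of a trajectory
#'
#' The conservation law is enforced structurally (only the active fraction
#' is integrated, the inactive fraction is `1 - active`), so the residual
#' reported here is the largest violation of the `[0, 1]` state bounds,
#' which is the only way conservation can fail numerically.
#'
#' @param traj a `pathway_trajectory`.
#' @return non-negative scalar.
#' @export
conservation_residual <- function(traj) {
  stopifnot(inherits(traj, "pathway_trajectory"))
  if (traj$failed) return(NA_real_)
  max(0, max(traj$states - 1), max(-traj$states))
}
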