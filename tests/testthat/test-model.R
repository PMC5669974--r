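test_that("default model has the published structure", {
  m <- build_default_model()
  expect_equal(nrow(m$nodes), 21)
  expect_equal(length(m$param_names), 86)
  expect_setequal(
    m$nodes$name,
    c("EGFR", "IGF1R", "ERBB4", "cKIT", "SOS", "RAS", "RasGAP", "RAF",
      "RafPP", "MEK", "ERK", "p90RSK", "PP2A", "PI3K", "AKT", "mTOR",
      "p70S6K", "AMPK", "LKB1", "BAD", "CASP")
  )
  expect_length(intersect(c("SMAD2", "COX2", "NQO1", "BAK", "STAT3"),
                          m$nodes$name), 0)
  expect_false(anyDuplicated(m$param_names) > 0)
  # weakly connected after exclusions
  expect_equal(max(graph_metrics(m)$component), 1)
})

test_that("config errors are caught at build time", {
  bad_edge <- write_model_yaml(list(
    name = "bad", nominal = default_nominal,
    nodes = list(list(name = "A", role = "kinase")),
    edges = list(list(source = "A", target = "ZZZ", sign = "activating"))
  ))
  expect_error(build_default_model(bad_edge), "undeclared node")

  dup <- write_model_yaml(list(
    name = "dup", nominal = default_nominal,
    nodes = list(list(name = "A", role = "kinase"),
                 list(name = "A", role = "kinase")),
    edges = list()
  ))
  expect_error(build_default_model(dup), "duplicate node")
})

test_that("one-node stimulus system reaches its closed-form steady state", {
  m <- one_node_model()
  theta <- m$nominal
  theta["stim_R"] <- 0.8
  theta["kdec_R"] <- 0.3
  traj <- simulate_pathway(m, theta, horizon = 100)
  expect_false(traj$failed)
  expect_equal(unname(traj$states[nrow(traj$states), "R"]),
               0.8 / (0.8 + 0.3), tolerance = 1e-5)
})

test_that("two-node MM cascade matches an independent root-finding oracle", {
  m <- two_node_model()
  theta <- m$nominal
  theta[c("stim_R", "kdec_R", "k_R_A", "K_R_A", "kdec_A")] <-
    c(0.6, 0.25, 1.4, 0.3, 0.5)
  traj <- simulate_pathway(m, theta, horizon = 400, n_times = 201)
  ss <- two_node_steady_state(0.6, 0.25, 1.4, 0.3, 0.5)
  expect_false(traj$failed)
  expect_equal(unname(traj$states[nrow(traj$states), c("R", "A")]),
               unname(ss), tolerance = 1e-6)
})

test_that("compiled derivative agrees with the reference R closure", {
  m <- build_default_model()
  f <- assemble_odes(m)
  theta <- m$nominal * exp(stats::runif(86, -1, 1))
  names(theta) <- m$param_names
  y <- stats::setNames(stats::runif(21, 0.05, 0.95), m$nodes$name)
  ref <- f(0, y, theta)[[1]]
  # integrate one tiny step from y with the compiled path and compare slopes
  traj_fwd <- local({
    ctx <- m$ctx
    invisible(.Call(pathwayCRA:::set_pathway_ctx, ctx$node_info,
                    ctx$edge_info, as.numeric(theta[m$param_names])))
    h <- 1e-6
    out <- deSolve::lsoda(y, c(0, h), func = "pathway_deriv", parms = NULL,
                          dllname = "pathwayCRA", initfunc = NULL,
                          rtol = 1e-10, atol = 1e-12)
    (out[2, -1] - out[1, -1]) / h
  })
  clamped <- m$nodes$clamped
  expect_lt(max(abs(traj_fwd[!clamped] - ref[!clamped])), 1e-4)
})

test_that("trajectories conserve totals and stay inside [0, 1]", {
  m <- build_default_model()
  set.seed(21)
  for (i in 1:5) {
    theta <- m$nominal * exp(stats::runif(86, log(0.1), log(10)))
    names(theta) <- m$param_names
    traj <- simulate_pathway(m, theta)
    expect_false(traj$failed)
    expect_lt(conservation_residual(traj), 1e-6)
  }
})

test_that("doubling all rates rescales time by one half", {
  m <- chain_model()
  theta <- m$nominal
  rates <- grepl("^(k_|kdec_|stim_|kact_)", names(theta))
  theta2 <- theta
  theta2[rates] <- 2 * theta[rates]
  t1 <- simulate_pathway(m, theta, horizon = 50, n_times = 101)
  t2 <- simulate_pathway(m, theta2, horizon = 25, n_times = 101)
  expect_equal(t2$states, t1$states, tolerance = 1e-5)
})

test_that("a vanishing rate is the continuous limit of small rates", {
  m <- chain_model()
  th1 <- m$nominal
  th2 <- m$nominal
  th1["k_A_B"] <- 1e-8
  th2["k_A_B"] <- 1e-10
  t1 <- simulate_pathway(m, th1)
  t2 <- simulate_pathway(m, th2)
  expect_equal(t1$states, t2$states, tolerance = 1e-5)
})

test_that("all-zero kinetics leave the state constant", {
  m <- one_node_model()
  theta <- c(stim_R = 1e-14, kdec_R = 1e-14)
  traj <- simulate_pathway(m, theta, horizon = 10)
  expect_equal(unname(traj$states[, "R"]), rep(0, nrow(traj$states)),
               tolerance = 1e-10)
})

test_that("AUC evaluation matches analytic integrals", {
  mktraj <- function(times, vals) {
    structure(list(times = times,
                   states = matrix(vals, ncol = 1,
                                   dimnames = list(NULL, "X")),
                   failed = FALSE),
              class = "pathway_trajectory")
  }
  tt <- seq(0, 10, length.out = 11)
  expect_equal(evaluation_auc(mktraj(tt, rep(0.3, 11)), "X"), 3.0)
  expect_equal(evaluation_auc(mktraj(tt, tt / 10), "X"), 5.0)
  tt <- seq(0, 5, length.out = 2001)
  expect_equal(evaluation_auc(mktraj(tt, exp(-tt)), "X"),
               1 - exp(-5), tolerance = 1e-4)
  expect_error(evaluation_auc(mktraj(tt, exp(-tt)), "nope"), "unknown node")
})

test_that("invalid parameter vectors are rejected", {
  m <- build_default_model()
  expect_error(simulate_pathway(m, m$nominal[-1]), "length")
  bad <- m$nominal
  bad[3] <- -1
  expect_error(simulate_pathway(m, bad), "strictly positive")
  wrongnames <- stats::setNames(m$nominal, rev(names(m$nominal)))
  expect_error(simulate_pathway(m, wrongnames), NA)  # same set, reordered ok
})
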