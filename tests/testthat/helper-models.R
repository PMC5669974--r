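# Small model definitions written to temp files, used across tests.

write_model_yaml <- function(def) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(def, path)
  path
}

default_nominal <- list(k = 1.0, K = 0.5, kdec = 0.2, stim = 0.5,
                        kact = 0.5, level = 0.5)

# single receptor node, no edges: mass-action on/off with closed-form
# steady state stim / (stim + kdec)
one_node_model <- function() {
  build_default_model(write_model_yaml(list(
    name = "one_node", horizon = 100, receptor_seed = 0,
    nominal = default_nominal,
    nodes = list(list(name = "R", role = "input-receptor")),
    edges = list()
  )))
}

# receptor -> A Michaelis-Menten cascade
two_node_model <- function() {
  build_default_model(write_model_yaml(list(
    name = "two_node", horizon = 200, receptor_seed = 0,
    nominal = default_nominal,
    nodes = list(list(name = "R", role = "input-receptor"),
                 list(name = "A", role = "kinase")),
    edges = list(list(source = "R", target = "A", sign = "activating"))
  )))
}

# receptor -> A -> B chain plus a structurally disconnected node D
chain_model <- function(with_disconnected = FALSE) {
  nodes <- list(list(name = "R", role = "input-receptor"),
                list(name = "A", role = "kinase"),
                list(name = "B", role = "kinase"))
  if (with_disconnected) {
    nodes <- c(nodes, list(list(name = "D", role = "effector",
                                basal_activation = TRUE)))
  }
  build_default_model(write_model_yaml(list(
    name = "chain", horizon = 100, receptor_seed = 1e-3,
    nominal = default_nominal,
    nodes = nodes,
    edges = list(list(source = "R", target = "A", sign = "activating"),
                 list(source = "A", target = "B", sign = "activating"))
  )))
}

fixture_table <- function() {
  load_rppa_table(system.file("extdata", "rppa_table1.csv",
                              package = "pathwayCRA"))
}

# hand-made sample container for tail/MIRI tests that need no ODE runs
fake_samples <- function(draws, auc, failed = rep(FALSE, nrow(draws))) {
  structure(list(draws = draws, auc = auc, failed = failed,
                 n = nrow(draws)),
            class = "cra_samples")
}
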