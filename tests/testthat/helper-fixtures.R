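# small in-code fixtures shared across test files

toy_panel <- function(n = 2, prefix = "A") {
  analyte_panel(c("GAPDH", sprintf("%s%02d", prefix, seq_len(n))))
}

# long-format plate rows for one well
well_rows <- function(sample, condition, replicate, mfi) {
  data.frame(sample = sample, condition = condition,
             replicate = replicate, analyte = names(mfi),
             mfi = unname(mfi), stringsAsFactors = FALSE)
}

# star graph: center connected to each leaf; one analyte per node named
# <node>_S1 unless a map is given
star_network <- function(center = "A", leaves = c("B", "C"),
                         tractable = NULL, analyte_map = NULL) {
  nodes <- c(center, leaves)
  edges <- cbind(center, leaves)
  if (is.null(tractable))
    tractable <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  if (is.null(analyte_map))
    analyte_map <- stats::setNames(nodes, paste0(nodes, "_S1"))
  interaction_network(edges, tractable, analyte_map, nodes = nodes)
}

# random simple graph + profile for oracle comparisons
random_network_profile <- function(n_nodes, p_edge = 0.15, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n_nodes, p_edge)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  igraph::V(g)$name <- nodes
  analytes <- paste0(nodes, "_S1")
  # a couple of nodes carry a second phosphosite
  extra <- sample(nodes, min(2L, n_nodes))
  analytes <- c(analytes, paste0(extra, "_S2"))
  map <- stats::setNames(c(nodes, extra), analytes)
  tract <- stats::setNames(sample(c(TRUE, FALSE), n_nodes, TRUE), nodes)
  net <- interaction_network(igraph::as_edgelist(g), tract, map,
                             nodes = nodes)
  changes <- stats::setNames(round(stats::rnorm(length(analytes)), 3),
                             analytes)
  list(network = net, changes = changes)
}

# independent brute-force EPS oracle: triple loop over
# (node, neighbor, analyte)
eps_oracle <- function(changes, network, self_weight = 0) {
  g <- network$graph
  ent <- phosphoresponse:::.eps_entities(network)
  vapply(seq_len(nrow(ent)), function(i) {
    v <- ent$node[i]
    total <- 0
    nb <- igraph::neighbors(g, v)$name
    for (u in nb)
      for (a in names(network$analyte_map))
        if (network$analyte_map[[a]] == u && a %in% names(changes))
          total <- total + abs(changes[[a]])
    if (self_weight != 0) {
      own <- if (!is.na(ent$analyte[i])) abs(changes[[ent$analyte[i]]])
      else sum(abs(changes[names(network$analyte_map)[
        network$analyte_map == v]]))
      total <- total + self_weight * own
    }
    total
  }, 0)
}

# tiny cohort for fast end-to-end tests
small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_cell_lines = 12, n_patients = 4,
                    n_drugs = 3, panel_size = 12, n_nodes = 16,
                    n_combo_samples = 3, ...)
}
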