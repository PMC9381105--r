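#' Construct a protein-protein interaction network with tractability flags
#'
#' Undirected simple graph over protein nodes, with a per-node druggability
#' ("tractable") flag and a mapping from panel analytes to the node carrying
#' them (several phosphosite analytes may map to one protein).
#'
#' @param edges Two-column character matrix or data frame of undirected
#'   edges (node pairs).
#' @param tractable Named logical vector over all nodes.
#' @param analyte_map Named character vector: `names()` are analyte ids,
#'   values are node ids.
#' @param nodes Optional character vector of node ids, to include isolated
#'   nodes; defaults to the union of edge endpoints, mapped nodes and
#'   `names(tractable)`.
#' @return An object of class `interaction_network` with elements `graph`
#'   (an [igraph::igraph]), `nodes`, `tractable` and `analyte_map`.
#' @export
interaction_network <- function(edges, tractable, analyte_map,
                                nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loop edges are not allowed")
  nodes <- unique(c(nodes, as.vector(edges), names(tractable),
                    unname(analyte_map)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  tr <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  tr[names(tractable)] <- as.logical(tractable)
  analyte_map <- stats::setNames(as.character(analyte_map),
                                 names(analyte_map))
  bad <- !analyte_map %in% nodes
  if (any(bad))
    stop("analyte_map points to unknown node(s): ",
         paste(unique(analyte_map[bad]), collapse = ", "))
  structure(list(graph = g, nodes = igraph::V(g)$name, tractable = tr,
                 analyte_map = analyte_map),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$nodes), "nodes,",
      igraph::ecount(x$graph), "edges;",
      sum(x$tractable), "tractable;",
      length(x$analyte_map), "mapped analytes\n")
  invisible(x)
}

#' Read an interaction network from SIF-like text files
#'
#' @param edge_file Two-column TSV (`nodeA<TAB>nodeB`), no header.
#' @param tractable_file TSV with header `node, tractable` (logical or 0/1).
#' @param map_file TSV with header `analyte, node`.
#' @return An [interaction_network].
#' @export
read_interaction_network <- function(edge_file, tractable_file, map_file) {
  e <- utils::read.table(edge_file, sep = "\t", stringsAsFactors = FALSE)
  tr <- utils::read.table(tractable_file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  mp <- utils::read.table(map_file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  interaction_network(e[, 1:2],
                      stats::setNames(as.logical(tr$tractable), tr$node),
                      stats::setNames(mp$node, mp$analyte))
}

#' Write an interaction network to SIF-like text files
#' @param network An [interaction_network].
#' @param edge_file,tractable_file,map_file Output paths.
#' @return `edge_file`, invisibly.
#' @export
write_interaction_network <- function(network, edge_file, tractable_file,
                                      map_file) {
  e <- igraph::as_edgelist(network$graph)
  utils::write.table(e, edge_file, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(node = names(network$tractable),
               tractable = unname(network$tractable)),
    tractable_file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(analyte = names(network$analyte_map),
               node = unname(network$analyte_map)),
    map_file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(edge_file)
}

# Scored entities: a node with >= 2 mapped phosphosite analytes is scored
# at site level (one entity per analyte, e.g. AKT_S308 and AKT_S473 ranked
# separately); any other node is scored once as itself.
.eps_entities <- function(network) {
  map <- network$analyte_map
  cnt <- table(unname(map))
  multi <- names(cnt)[cnt >= 2L]
  ent_node <- network$nodes[!network$nodes %in% multi]
  site_an <- names(map)[map %in% multi]
  data.frame(
    entity = c(ent_node, site_an),
    node = c(ent_node, unname(map[site_an])),
    analyte = c(rep(NA_character_, length(ent_node)), site_an),
    stringsAsFactors = FALSE)
}

#' Environmental perturbation score (EPS)
#'
#' For each network node \eqn{v}, the EPS integrates the absolute
#' phosphoprotein changes measured over the node's direct interaction
#' neighborhood:
#' \deqn{EPS(v) = \sum_{u \in N(v)} \sum_{a \mapsto u} |\Delta_a|}
#' where \eqn{N(v)} are the direct graph neighbors of \eqn{v} (the node
#' itself is excluded, so a protein can score as a perturbed signalling
#' junction even when its own measured change is small). For proteins
#' carrying several measured phosphosites, each site is a separate scored
#' entity inheriting the protein node's neighborhood sum plus
#' `self_weight` times the absolute change of that site itself
#' (`self_weight = 0` by default).
#'
#' Applied across a [perturbation_matrix], returns one long-format row per
#' (sample, drug, entity) with tractable-entity ranks from
#' [rank_tractable()].
#'
#' @param x A [perturbation_matrix] (or a single named change vector over
#'   the panel's analytes).
#' @param network An [interaction_network]; every analyte of the profile
#'   must be mapped to a node.
#' @param self_weight Weight on an entity's own absolute change (site-level
#'   entities) or on the node's own analytes (node entities); default 0
#'   (pure neighborhood score).
#' @return Data frame of class `eps_table` with columns `sample, drug,
#'   entity, node, eps, tractable, rank` (rank is `NA` for non-tractable
#'   entities).
#' @export
eps_score <- function(x, network, self_weight = 0) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- perturbation_matrix(matrix(x, 1L, dimnames = list(NULL, names(x))),
                             "sample", "drug",
                             analyte_panel(c("GAPDH", names(x))))
  }
  stopifnot(inherits(x, "perturbation_matrix"),
            inherits(network, "interaction_network"))
  analytes <- colnames(x$changes)
  unmapped <- setdiff(analytes, names(network$analyte_map))
  if (length(unmapped))
    stop("analyte(s) with no node mapping: ",
         paste(unmapped, collapse = ", "))
  map <- network$analyte_map[analytes]
  nodes <- network$nodes
  # analyte -> node incidence, so node_abs = |changes| %*% t(A)
  A <- matrix(0, length(nodes), length(analytes),
              dimnames = list(nodes, analytes))
  A[cbind(match(map, nodes), seq_along(analytes))] <- 1
  adj <- igraph::as_adjacency_matrix(network$graph, sparse = FALSE)
  adj <- adj[nodes, nodes]
  absch <- abs(x$changes)                       # conditions x analytes
  node_abs <- absch %*% t(A)                    # conditions x nodes
  node_eps <- node_abs %*% adj                  # neighborhood sums

  ent <- .eps_entities(network)
  eps <- node_eps[, ent$node, drop = FALSE]
  if (self_weight != 0) {
    own <- matrix(0, nrow(eps), nrow(ent))
    is_site <- !is.na(ent$analyte)
    own[, is_site] <- absch[, ent$analyte[is_site], drop = FALSE]
    own[, !is_site] <- node_abs[, ent$node[!is_site], drop = FALSE]
    eps <- eps + self_weight * own
  }
  out <- data.frame(
    sample = rep(x$sample, each = nrow(ent)),
    drug = rep(x$drug, each = nrow(ent)),
    entity = rep(ent$entity, nrow(eps)),
    node = rep(ent$node, nrow(eps)),
    eps = as.vector(t(eps)),
    tractable = rep(unname(network$tractable[ent$node]), nrow(eps)),
    stringsAsFactors = FALSE)
  out$rank <- rank_tractable(out)
  class(out) <- c("eps_table", "data.frame")
  out
}

#' Rank tractable entities by EPS within each condition
#'
#' Within each (sample, drug), tractable entities are ranked by descending
#' EPS (rank 1 = highest). Tied scores all receive the minimum rank of the
#' tied block; within a tied block, output order is fixed by entity id.
#' Non-tractable entities are kept in the table but receive `NA` rank.
#'
#' @param eps_table Data frame with columns `sample, drug, entity, eps,
#'   tractable`.
#' @return Integer vector of ranks aligned with the rows of `eps_table`.
#' @export
rank_tractable <- function(eps_table) {
  rk <- rep(NA_integer_, nrow(eps_table))
  key <- paste(eps_table$sample, eps_table$drug, sep = "\r")
  for (k in unique(key)) {
    i <- which(key == k & eps_table$tractable)
    if (!length(i)) next
    rk[i] <- as.integer(rank(-eps_table$eps[i], ties.method = "min"))
  }
  rk
}

# Best (minimum) rank over a partner drug's target entities in one
# (sample, anchor) ranking; NA when no target entity is ranked.
.best_target_rank <- function(eps_table, sample, anchor, target_nodes) {
  i <- eps_table$sample == sample & eps_table$drug == anchor &
    eps_table$node %in% target_nodes & !is.na(eps_table$rank)
  if (!any(i)) return(list(rank = NA_integer_, entity = NA_character_))
  j <- which(i)[which.min(eps_table$rank[i])]
  list(rank = eps_table$rank[j], entity = eps_table$entity[j])
}

#' Nominate combination partner drugs from EPS rankings
#'
#' For each (sample, anchor drug), candidate partner drugs are ordered by
#' the best (minimum) EPS rank achieved by any of their target entities in
#' the anchor's tractable-entity ranking; the top `k` partners are returned
#' together with the achieving target entity and its rank.
#'
#' @param eps_table An `eps_table` from [eps_score()].
#' @param drugs Named list mapping each drug id to its target node ids
#'   (or a list of [drug_info] objects).
#' @param k Number of partners to return per (sample, anchor).
#' @return Data frame `sample, anchor, partner, target_entity, rank,
#'   position`.
#' @export
nominate_combinations <- function(eps_table, drugs, k = 3L) {
  targets <- .drug_targets(drugs)
  out <- list()
  combos <- unique(eps_table[, c("sample", "drug")])
  for (r in seq_len(nrow(combos))) {
    s <- combos$sample[r]; anchor <- combos$drug[r]
    partners <- setdiff(names(targets), anchor)
    br <- lapply(partners, function(p)
      .best_target_rank(eps_table, s, anchor, targets[[p]]))
    rks <- vapply(br, `[[`, 0L, "rank")
    drop <- is.na(rks)
    if (any(drop))
      warning("partner(s) with no ranked target excluded: ",
              paste(partners[drop], collapse = ", "))
    partners <- partners[!drop]; br <- br[!drop]; rks <- rks[!drop]
    ord <- order(rks, partners)[seq_len(min(k, length(partners)))]
    if (!length(ord)) next
    out[[length(out) + 1L]] <- data.frame(
      sample = s, anchor = anchor, partner = partners[ord],
      target_entity = vapply(br[ord], `[[`, "", "entity"),
      rank = rks[ord], position = seq_along(ord),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.drug_targets <- function(drugs) {
  if (inherits(drugs, "drug_info")) drugs <- list(drugs)
  if (is.list(drugs) && all(vapply(drugs, inherits, TRUE, "drug_info"))) {
    stats::setNames(lapply(drugs, `[[`, "target_node_ids"),
                    vapply(drugs, `[[`, "", "drug_id"))
  } else if (is.list(drugs) && !is.null(names(drugs))) {
    lapply(drugs, as.character)
  } else stop("drugs must be a named list of target nodes or drug_info")
}

#' Top-k concordance between EPS rankings and observed synergy
#'
#' Over all screened (sample, anchor, partner) records whose Bliss summary
#' score exceeds `bliss_threshold` (i.e. synergistic combinations), counts
#' those where some target entity of the partner drug ranks within the top
#' `k` of the anchor's EPS ranking for that sample.
#'
#' @param eps_table An `eps_table` from [eps_score()].
#' @param screen Data frame `sample, drug_a, drug_b, bliss` (the summary
#'   per ordered pair), e.g. from [screen_bliss()].
#' @param drugs Drug-to-target mapping as in [nominate_combinations()].
#' @param bliss_threshold Synergy call threshold on the Bliss summary.
#' @param k Rank cutoff.
#' @return List of class `concordance` with `n_synergistic`, `n_hit`,
#'   `fraction` (NA when no record is synergistic) and `k`.
#' @export
topk_concordance <- function(eps_table, screen, drugs,
                             bliss_threshold = 0.1, k = 5L) {
  targets <- .drug_targets(drugs)
  syn <- screen[screen$bliss > bliss_threshold, , drop = FALSE]
  n_hit <- 0L
  for (r in seq_len(nrow(syn))) {
    br <- .best_target_rank(eps_table, syn$sample[r], syn$drug_a[r],
                            targets[[syn$drug_b[r]]])
    if (!is.na(br$rank) && br$rank <= k) n_hit <- n_hit + 1L
  }
  concordance_report(n_hit, nrow(syn), k = k)
}

#' Concordance reporting path
#'
#' Turns hit counts into the reported fraction; shared by
#' [topk_concordance()] and usable directly on externally obtained counts.
#'
#' @param n_hit Number of synergistic records whose partner target ranked
#'   within the cutoff.
#' @param n_synergistic Total number of synergistic records.
#' @param k Rank cutoff (annotation only).
#' @return List of class `concordance` with `n_synergistic`, `n_hit`,
#'   `fraction` and `percent` (both NA when `n_synergistic` is 0).
#' @examples
#' concordance_report(73, 128)$percent  # ~57
#' @export
concordance_report <- function(n_hit, n_synergistic, k = NA_integer_) {
  frac <- if (n_synergistic > 0) n_hit / n_synergistic else NA_real_
  structure(list(n_synergistic = n_synergistic, n_hit = n_hit,
                 fraction = frac, percent = 100 * frac, k = k),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  if (is.na(x$fraction)) {
    cat("Concordance: no synergistic records (fraction undefined)\n")
  } else {
    cat(sprintf("Concordance: %d of %d synergistic combinations (%d%%)%s\n",
                x$n_hit, x$n_synergistic, round(x$percent),
                if (is.na(x$k)) "" else sprintf(" at top-%d", x$k)))
  }
  invisible(x)
}
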