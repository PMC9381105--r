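#' Synthetic cohort simulation settings
#'
#' Collects all tunables of the synthetic cohort generator, which emulates
#' the study design every downstream stage assumes: a 52-analyte
#' phosphoprotein panel measured across 35 cell lines and 16
#' patient-derived samples under 7 drugs, GI50 values driven by planted
#' signature analytes, and a pairwise combination screen in 6
#' representative cell lines with network-localized planted synergy.
#'
#' @param seed Integer seed (mandatory); each stage derives its own
#'   sub-seed from it (`seed + 101, 202, 303, 404, 505` for network,
#'   perturbations, sensitivity, genotypes and screen respectively) so
#'   stages can be regenerated independently.
#' @param n_cell_lines,n_patients,n_drugs,panel_size Cohort dimensions.
#' @param n_nodes,edges_per_node,tractable_fraction Interaction-network
#'   size, density and druggable fraction.
#' @param signature_size Analytes per drug truly linked to sensitivity.
#' @param signature_coef Common coefficient of the signature analytes in
#'   the log10(GI50) linear model; 0 makes GI50 pure noise (the global
#'   null for predictor calibration).
#' @param effect_size Mean |change| (log2 units) at a drug target's own
#'   analytes; propagation decays as `0.5^distance`, zero beyond
#'   distance 2.
#' @param noise_sd Gaussian measurement noise SD on changes.
#' @param patient_noise_inflation Multiplier on `noise_sd` for
#'   patient-derived samples.
#' @param n_feedback Analytes per drug carrying planted feedback
#'   up-regulation (positive mean `effect_size / 2`, placed beyond the
#'   propagation radius).
#' @param gi50_log_mu,gi50_log_sd Baseline log10 molar GI50 and the SD of
#'   its Gaussian noise around the signature-driven linear score.
#' @param hill_slope Hill coefficient of the single-agent dose-response
#'   curves in the combination screen.
#' @param n_combo_samples Cell lines entering the combination screen.
#' @param synergy_excess Maximum planted Bliss excess (attained when the
#'   partner's target is the anchor's top-ranked EPS entity).
#' @param align_scale Planted excess decays linearly with the partner
#'   target's EPS rank in the anchor's ranking, reaching zero at rank
#'   `align_scale + 1`; with the defaults roughly half of all tested
#'   pairs clear the 0.1 synergy threshold, so EPS-synergy concordance is
#'   recoverable by construction at a realistic synergy rate.
#' @param synergy_pairs Optional data frame `drug_a, drug_b, excess`
#'   overriding the EPS-aligned assignment.
#' @param combo_noise_sd Gaussian noise SD on combined-effect grid cells.
#' @param anchor_conc_factor Anchor concentration as a multiple of its
#'   GI50.
#' @param partner_doses Number of partner concentrations per grid.
#' @param mutation_rate Bernoulli rate of the independent mutation flags.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_cell_lines = 35L, n_patients = 16L,
                              n_drugs = 7L, panel_size = 52L,
                              n_nodes = 60L, edges_per_node = 3L,
                              tractable_fraction = 0.5,
                              signature_size = 5L, signature_coef = 1,
                              effect_size = 2,
                              noise_sd = 1,
                              patient_noise_inflation = 1.5,
                              n_feedback = 2L,
                              gi50_log_mu = -7, gi50_log_sd = 0.3,
                              hill_slope = 1,
                              n_combo_samples = 6L,
                              synergy_excess = 0.45, align_scale = 20,
                              synergy_pairs = NULL,
                              combo_noise_sd = 0.02,
                              anchor_conc_factor = 0.5,
                              partner_doses = 5L,
                              mutation_rate = 0.2) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is mandatory")
  cfg <- as.list(environment())
  for (f in c("n_cell_lines", "n_patients", "n_drugs", "panel_size",
              "n_nodes", "edges_per_node", "signature_size",
              "n_combo_samples", "partner_doses"))
    if (cfg[[f]] < 1L) stop(f, " must be positive")
  if (noise_sd < 0 || combo_noise_sd < 0 || gi50_log_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (tractable_fraction < 0 || tractable_fraction > 1)
    stop("tractable_fraction must lie in [0, 1]")
  if (n_nodes < panel_size - 1L)
    stop("n_nodes must cover the panel's proteins")
  if (n_combo_samples > n_cell_lines)
    stop("n_combo_samples exceeds n_cell_lines")
  structure(cfg, class = "simulation_config")
}

.stage_seed <- function(cfg, offset) {
  as.integer((cfg$seed + offset) %% .Machine$integer.max)
}

#' Simulate a protein-protein interaction network
#'
#' Generates a connected undirected scale-free random graph
#' (Barabasi-Albert preferential attachment, `edges_per_node` edges per
#' added node, giving the hub-dominated degree structure of curated
#' interactomes; regenerated with a derived seed and a message in the
#' unexpected disconnected case), maps the panel's analytes onto its nodes
#' (one protein carries two phosphosite analytes, exercising site-level
#' ranking), assigns each drug a distinct measured target node, and flags
#' the configured fraction of nodes as tractable, always including all
#' drug targets.
#'
#' @param cfg A [simulation_config()].
#' @return An [interaction_network] with attributes `drug_targets` (named
#'   list drug -> target node) and `panel` (the [analyte_panel]).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(.stage_seed(cfg, 101L))
  nodes <- sprintf("P%02d", seq_len(cfg$n_nodes))
  g <- NULL
  for (attempt in 1:50) {
    gg <- igraph::sample_pa(cfg$n_nodes, m = cfg$edges_per_node,
                            directed = FALSE)
    if (igraph::is_connected(gg)) { g <- gg; break }
    message("disconnected graph regenerated (attempt ", attempt, ")")
  }
  if (is.null(g)) stop("failed to generate a connected network")
  # shuffle vertex identities so node index carries no degree information
  igraph::V(g)$name <- sample(nodes)
  edges <- igraph::as_edgelist(g)

  # panel: panel_size analytes over panel_size - 1 proteins; the first
  # measured protein carries two phosphosites
  n_prot <- cfg$panel_size - 1L
  measured <- nodes[seq_len(n_prot)]
  analytes <- c(paste0(measured[1L], "_S1"), paste0(measured[1L], "_S2"),
                paste0(measured[-1L], "_S1"))
  analyte_map <- stats::setNames(c(measured[1L], measured[1L],
                                   measured[-1L]), analytes)
  panel <- analyte_panel(c("GAPDH", analytes))

  drug_ids <- sprintf("drug%d", seq_len(cfg$n_drugs))
  # targeted drugs hit central signalling proteins: sample targets with
  # probability proportional to node degree
  deg <- igraph::degree(g)[measured]
  targets <- stats::setNames(
    as.list(sample(measured, cfg$n_drugs, prob = deg)), drug_ids)
  tract <- stats::setNames(rep(FALSE, cfg$n_nodes), nodes)
  tract[sample(nodes, round(cfg$tractable_fraction * cfg$n_nodes))] <- TRUE
  tract[unlist(targets)] <- TRUE

  net <- interaction_network(edges, tract, analyte_map, nodes = nodes)
  attr(net, "drug_targets") <- targets
  attr(net, "panel") <- panel
  net
}

# per-drug mean change vector over analytes: -effect_size * 0.5^d within
# distance 2 of the target, +effect_size/2 at the feedback analytes
.mean_profiles <- function(cfg, network) {
  targets <- attr(network, "drug_targets")
  panel <- attr(network, "panel")
  analytes <- panel$phospho
  anode <- network$analyte_map[analytes]
  d <- igraph::distances(network$graph)
  mu <- matrix(0, length(targets), length(analytes),
               dimnames = list(names(targets), analytes))
  feedback <- list()
  for (dr in names(targets)) {
    dd <- d[targets[[dr]], anode]
    mu[dr, ] <- ifelse(dd <= 2, -cfg$effect_size * 0.5^dd, 0)
    far <- analytes[dd >= 3]
    nf <- min(cfg$n_feedback, length(far))
    fb <- if (nf > 0L) sample(far, nf) else character(0)
    mu[dr, fb] <- cfg$effect_size / 2
    feedback[[dr]] <- fb
  }
  list(mu = mu, feedback = feedback)
}

#' Simulate perturbation profiles for a cohort
#'
#' For each (sample, drug), changes at the drug target's analytes and
#' their network neighbors are drawn around `-effect_size * 0.5^distance`
#' (zero beyond distance 2: inhibition propagates locally and decays),
#' planted feedback analytes get a positive mean, everything else mean 0;
#' Gaussian noise of SD `noise_sd` is added (inflated for patient-derived
#' samples).
#'
#' @param cfg A [simulation_config()].
#' @param network Network from [simulate_network()].
#' @return List with `matrix` (a [perturbation_matrix]) and `truth`
#'   (ground-truth record: mean profiles, feedback sets).
#' @export
simulate_perturbations <- function(cfg, network) {
  set.seed(.stage_seed(cfg, 202L))
  mp <- .mean_profiles(cfg, network)
  panel <- attr(network, "panel")
  drugs <- rownames(mp$mu)
  cl <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  pt <- sprintf("PT%02d", seq_len(cfg$n_patients))
  samples <- c(cl, pt)
  stype <- stats::setNames(rep(c("cell_line", "patient"),
                               c(length(cl), length(pt))), samples)
  grid <- expand.grid(sample = samples, drug = drugs,
                      stringsAsFactors = FALSE)
  sdvec <- ifelse(stype[grid$sample] == "patient",
                  cfg$noise_sd * cfg$patient_noise_inflation, cfg$noise_sd)
  ch <- mp$mu[grid$drug, , drop = FALSE] +
    matrix(stats::rnorm(nrow(grid) * ncol(mp$mu), 0, sdvec),
           nrow(grid), ncol(mp$mu))
  colnames(ch) <- colnames(mp$mu)
  pm <- perturbation_matrix(ch, grid$sample, grid$drug, panel,
                            sample_type = stype)
  list(matrix = pm,
       truth = list(mean_profiles = mp$mu, feedback = mp$feedback))
}

#' Simulate drug-sensitivity GI50 values
#'
#' log10(GI50) for each (cell line, drug) is a linear combination (common
#' coefficient `signature_coef`) of that sample's observed changes at the drug's planted
#' signature analytes - the `signature_size` analytes with the strongest
#' mean perturbation - plus Gaussian noise of SD `gi50_log_sd` around the
#' baseline `gi50_log_mu`. The true quartile is recorded from the
#' noiseless linear score.
#'
#' @param cfg A [simulation_config()].
#' @param matrix Perturbation matrix from [simulate_perturbations()].
#' @param truth Ground-truth record from the same call.
#' @return List with `sens` (a [sensitivity_table()] over cell lines),
#'   `truth` extended by `signature_analytes` (drug -> analyte set) and
#'   `true_quartile`.
#' @export
simulate_sensitivity <- function(cfg, matrix, truth) {
  set.seed(.stage_seed(cfg, 303L))
  mu <- truth$mean_profiles
  sig <- lapply(rownames(mu), function(dr) {
    v <- abs(mu[dr, ])
    names(sort(v, decreasing = TRUE))[seq_len(cfg$signature_size)]
  })
  names(sig) <- rownames(mu)
  cl <- matrix$sample_type[matrix$sample] == "cell_line"
  rows <- which(cl)
  score <- cfg$signature_coef * vapply(rows, function(i)
    sum(matrix$changes[i, sig[[matrix$drug[i]]]]), 0)
  log_gi50 <- cfg$gi50_log_mu + score +
    stats::rnorm(length(rows), 0, cfg$gi50_log_sd)
  df <- data.frame(sample = matrix$sample[rows], drug = matrix$drug[rows],
                   gi50 = 10^log_gi50, stringsAsFactors = FALSE)
  sens <- sensitivity_table(df)
  tq <- df[, c("sample", "drug")]
  tq$true_quartile <- factor(NA_character_, levels = paste0("Q", 1:4))
  for (d in unique(tq$drug)) {
    i <- tq$drug == d
    tq$true_quartile[i] <- assign_quartiles(
      stats::setNames(score[i], tq$sample[i]))
  }
  truth$signature_analytes <- sig
  truth$true_quartile <- tq
  list(sens = sens, truth = truth)
}

#' Simulate independent mutation flags
#'
#' Binary EGFR / KRAS / PIK3CA mutation flags drawn independently per
#' sample at `mutation_rate`; by construction uninformative about drug
#' sensitivity, serving as the genomic decoy baseline.
#'
#' @param cfg A [simulation_config()].
#' @param samples Character vector of sample ids.
#' @return Data frame `sample, EGFR, KRAS, PIK3CA`.
#' @export
simulate_genotypes <- function(cfg, samples) {
  set.seed(.stage_seed(cfg, 404L))
  g <- matrix(stats::rbinom(length(samples) * 3L, 1L, cfg$mutation_rate),
              ncol = 3L, dimnames = list(NULL, c("EGFR", "KRAS", "PIK3CA")))
  cbind(data.frame(sample = samples, stringsAsFactors = FALSE),
        as.data.frame(g))
}

.hill_effect <- function(conc, gi50, h) 1 / (1 + (gi50 / conc)^h)

#' Simulate a pairwise two-drug combination screen
#'
#' For each of `n_combo_samples` cell lines and every ordered drug pair,
#' builds a dose grid with the anchor at a fixed fraction of its GI50 and
#' the partner over a log-spaced concentration range; single-agent effects
#' follow Hill curves through the simulated GI50s, and the combined effect
#' is the Bliss expectation plus the planted excess plus noise. Unless
#' explicit `synergy_pairs` are configured, the planted excess decays
#' linearly with the partner target's EPS rank in the anchor's ranking
#' for that sample (zero beyond rank `align_scale`), so EPS-synergy
#' concordance is recoverable by construction.
#'
#' @param cfg A [simulation_config()].
#' @param matrix Perturbation matrix (for the EPS alignment).
#' @param network The simulated network.
#' @param sens Sensitivity table with simulated GI50s.
#' @param truth Ground-truth record to extend.
#' @return List with `screen` (a `combination_screen`), `truth` extended
#'   by `planted_synergy` (`sample, drug_a, drug_b, excess`).
#' @export
simulate_combination_screen <- function(cfg, matrix, network, sens,
                                        truth) {
  set.seed(.stage_seed(cfg, 505L))
  drugs <- names(attr(network, "drug_targets"))
  targets <- attr(network, "drug_targets")
  combo_samples <- sprintf("CL%02d", seq_len(cfg$n_combo_samples))
  design <- enumerate_screen(drugs, combo_samples, ordered = TRUE)

  keep <- matrix$sample %in% combo_samples
  sub <- perturbation_matrix(matrix$changes[keep, , drop = FALSE],
                             matrix$sample[keep], matrix$drug[keep],
                             matrix$panel,
                             sample_type = matrix$sample_type)
  ep <- eps_score(sub, network)

  gi <- stats::setNames(sens$gi50, paste(sens$sample, sens$drug))
  planted <- numeric(nrow(design))
  if (!is.null(cfg$synergy_pairs)) {
    sp <- cfg$synergy_pairs
    key <- paste(design$drug_a, design$drug_b)
    idx <- match(key, paste(sp$drug_a, sp$drug_b))
    planted[!is.na(idx)] <- sp$excess[idx[!is.na(idx)]]
  } else {
    for (r in seq_len(nrow(design))) {
      br <- .best_target_rank(ep, design$sample[r], design$drug_a[r],
                              targets[[design$drug_b[r]]])
      if (!is.na(br$rank))
        planted[r] <- cfg$synergy_excess *
          max(0, 1 - (br$rank - 1) / cfg$align_scale)
    }
  }
  grids <- lapply(seq_len(nrow(design)), function(r) {
    s <- design$sample[r]; a <- design$drug_a[r]; b <- design$drug_b[r]
    gia <- gi[paste(s, a)]; gib <- gi[paste(s, b)]
    ca <- cfg$anchor_conc_factor * gia
    cb <- gib * 10^seq(-2, 0, length.out = cfg$partner_doses)
    fa <- .hill_effect(ca, gia, cfg$hill_slope)
    fb <- .hill_effect(cb, gib, cfg$hill_slope)
    f_obs <- outer(fa, fb, bliss_expected) + planted[r]
    if (cfg$combo_noise_sd > 0)
      f_obs <- f_obs + stats::rnorm(length(f_obs), 0, cfg$combo_noise_sd)
    suppressWarnings(
      dose_response_grid(s, a, b, ca, cb, fa, fb,
                         pmin(pmax(f_obs, 0), 1)))
  })
  truth$planted_synergy <- cbind(design, excess = planted)
  list(screen = structure(list(grids = grids),
                          class = "combination_screen"),
       truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Runs all generator stages (network, perturbations, sensitivity,
#' genotypes, combination screen) under one seed with documented
#' per-stage sub-seeds.
#'
#' @param cfg A [simulation_config()] (or an integer seed, taken as
#'   `simulation_config(seed = cfg)`).
#' @return List of class `synthetic_cohort`: `network`, `drugs` (named
#'   list drug -> target nodes), `matrix`, `sens`, `genotypes`, `screen`,
#'   `truth`, `cfg`.
#' @export
simulate_cohort <- function(cfg) {
  if (is.numeric(cfg)) cfg <- simulation_config(seed = cfg)
  stopifnot(inherits(cfg, "simulation_config"))
  network <- simulate_network(cfg)
  pert <- simulate_perturbations(cfg, network)
  sn <- simulate_sensitivity(cfg, pert$matrix, pert$truth)
  geno <- simulate_genotypes(cfg, unique(pert$matrix$sample))
  scr <- simulate_combination_screen(cfg, pert$matrix, network, sn$sens,
                                     sn$truth)
  structure(
    list(network = network,
         drugs = attr(network, "drug_targets"),
         matrix = pert$matrix, sens = sn$sens, genotypes = geno,
         screen = scr$screen, truth = scr$truth, cfg = cfg),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$cfg$seed, "):\n", sep = "")
  print(x$matrix)
  cat("  ", length(x$screen$grids), "combination grids;",
      nrow(x$sens), "GI50 records\n")
  invisible(x)
}

#' Serialize ground truth to JSON
#' @param truth Ground-truth record from a [simulate_cohort()] run.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(signature_analytes = truth$signature_analytes,
         feedback = truth$feedback,
         true_quartile = truth$true_quartile,
         planted_synergy = truth$planted_synergy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
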