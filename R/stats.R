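# Mann-Whitney U for x vs y: number of (x, y) pairs with x > y, ties 0.5.
.mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# tie-corrected normal approximation, continuity-corrected two-sided p
.mw_p_norm <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u <- .mw_u(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sig2)
  if (z < 0) z <- 0
  min(1, 2 * stats::pnorm(-z))
}

# exact two-sided p: closed-form null distribution when there are no
# ties; full enumeration of group assignments for small tied samples
.mw_p_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u <- .mw_u(x, y)
  if (!anyDuplicated(c(x, y))) {
    lo <- stats::pwilcox(u, n1, n2)
    hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    return(min(1, 2 * min(lo, hi)))
  }
  if (choose(n1 + n2, n1) > 5e5)  # tied large samples: approximate
    return(.mw_p_norm(x, y))
  r <- rank(c(x, y))
  off <- n1 * (n1 + 1) / 2
  cmb <- utils::combn(n1 + n2, n1)
  us <- colSums(matrix(r[cmb], nrow = n1)) - off
  min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
}

#' Mann-Whitney test of EPS rank bias between synergy groups
#'
#' Two-sided Mann-Whitney U comparison of the EPS ranks attained by
#' partner-drug targets in the most-synergistic versus least-synergistic
#' records. Uses exact enumeration when both groups have at most
#' `exact_max` observations, and the tie-corrected, continuity-corrected
#' normal approximation otherwise. The reported direction is positive when
#' the top group is biased toward higher EPS rankings, i.e. numerically
#' lower rank values.
#'
#' @param ranks_top Integer EPS ranks for top-quartile (most synergistic)
#'   records.
#' @param ranks_bottom Likewise for the bottom quartile.
#' @param exact_max Largest per-group size at which the exact enumeration
#'   is used.
#' @return Object of class `rank_bias_result`: `U` (pairs where the top
#'   rank exceeds the bottom rank, ties counted half), `p_two_sided`,
#'   `direction` (+1 when top ranks are lower), `method`, group sizes.
#' @examples
#' mann_whitney_rank_bias(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
mann_whitney_rank_bias <- function(ranks_top, ranks_bottom,
                                   exact_max = 8L) {
  if (length(ranks_top) == 0L || length(ranks_bottom) == 0L)
    stop("both groups must be non-empty")
  u <- .mw_u(ranks_top, ranks_bottom)
  mu <- length(ranks_top) * length(ranks_bottom) / 2
  exact <- length(ranks_top) <= exact_max &&
    length(ranks_bottom) <= exact_max
  p <- if (exact) .mw_p_exact(ranks_top, ranks_bottom)
       else .mw_p_norm(ranks_top, ranks_bottom)
  structure(
    list(U = u, p_two_sided = p,
         direction = sign(mu - u),  # +1: top group has lower rank numbers
         method = if (exact) "exact" else "normal_approx",
         n_top = length(ranks_top), n_bottom = length(ranks_bottom)),
    class = "rank_bias_result")
}

#' @export
print.rank_bias_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney rank bias (%s): U = %g, n = %d vs %d, p = %.5g\n",
    x$method, x$U, x$n_top, x$n_bottom, x$p_two_sided))
  cat(if (x$direction > 0)
    "  top synergy group biased toward higher EPS rankings\n"
  else if (x$direction < 0)
    "  top synergy group biased toward lower EPS rankings\n"
  else "  no directional bias\n")
  invisible(x)
}

# Assemble EPS ranks of partner targets for the extreme Bliss quartiles.
# mode "best": one rank per record (partner's best target); "all": every
# ranked target entity of the partner contributes a rank.
.quartile_ranks <- function(eps_table, screen, drugs, mode = "best") {
  targets <- .drug_targets(drugs)
  q <- synergy_quartiles(screen)
  pull <- function(recs) {
    out <- integer(0)
    for (r in seq_len(nrow(recs))) {
      trg <- targets[[recs$drug_b[r]]]
      i <- eps_table$sample == recs$sample[r] &
        eps_table$drug == recs$drug_a[r] &
        eps_table$node %in% trg & !is.na(eps_table$rank)
      if (!any(i)) next
      out <- c(out, if (mode == "best") min(eps_table$rank[i])
               else eps_table$rank[i])
    }
    out
  }
  list(top = pull(q$top), bottom = pull(q$bottom))
}

#' EPS rank-bias test over a combination screen
#'
#' Glue from an EPS table and a summarized screen to
#' [mann_whitney_rank_bias()]: records are split into the top and bottom
#' Bliss-synergy quartiles, each record contributes the EPS rank(s) of the
#' partner drug's target entities in the anchor drug's ranking, and the
#' two rank samples are compared.
#'
#' @param eps_table An `eps_table` from [eps_score()].
#' @param screen Data frame `sample, drug_a, drug_b, bliss`.
#' @param drugs Drug-to-target mapping (named list or `drug_info` list).
#' @param mode `"best"`: one rank per record, the partner's best target
#'   rank (default); `"all"`: all ranked target entities contribute.
#' @return A `rank_bias_result` with the rank samples attached as
#'   `ranks_top` / `ranks_bottom`.
#' @export
eps_rank_bias <- function(eps_table, screen, drugs, mode = c("best",
                                                             "all")) {
  mode <- match.arg(mode)
  rk <- .quartile_ranks(eps_table, screen, drugs, mode)
  out <- mann_whitney_rank_bias(rk$top, rk$bottom)
  out$ranks_top <- rk$top; out$ranks_bottom <- rk$bottom
  out
}

#' Permutation robustness of the EPS rank-bias p-value
#'
#' Locates the observed rank-bias p-value within a null distribution
#' obtained by randomly re-assigning EPS rankings: in each permutation the
#' rank values are shuffled across entities within each (sample, anchor
#' drug) ranking universe (preserving each universe's rank support;
#' `scheme = "global"` instead shuffles record-level ranks across all
#' records), the partner target ranks are re-extracted, and the
#' Mann-Whitney p recomputed.
#'
#' @param eps_table An `eps_table` from [eps_score()].
#' @param screen Data frame `sample, drug_a, drug_b, bliss`.
#' @param drugs Drug-to-target mapping.
#' @param n Number of permutations (default 10000; below 100 the
#'   empirical quantile is unstable and a warning is issued).
#' @param seed Integer seed.
#' @param scheme `"within"` (default) or `"global"`.
#' @param mode Passed to the rank extraction, see [eps_rank_bias()].
#' @return Object of class `permutation_null`: `p_null` (length `n`),
#'   `observed_p`, `empirical_quantile` (fraction of null p-values below
#'   the observed, counting ties half, which is unbiased under the
#'   discrete permutation null).
#' @export
permutation_robustness <- function(eps_table, screen, drugs, n = 10000L,
                                   seed = 1L,
                                   scheme = c("within", "global"),
                                   mode = "best") {
  scheme <- match.arg(scheme)
  if (n < 100L) warning("fewer than 100 permutations: ",
                        "empirical quantile is unstable")
  obs <- eps_rank_bias(eps_table, screen, drugs, mode = mode)

  # precompute: per record, its universe and target entity positions
  targets <- .drug_targets(drugs)
  q <- synergy_quartiles(screen)
  ukey <- paste(eps_table$sample, eps_table$drug, sep = "\r")
  ranked <- !is.na(eps_table$rank)
  universes <- lapply(split(which(ranked), ukey[ranked]), function(i)
    list(ranks = eps_table$rank[i], node = eps_table$node[i]))
  prep <- function(recs) {
    lapply(seq_len(nrow(recs)), function(r) {
      uk <- paste(recs$sample[r], recs$drug_a[r], sep = "\r")
      u <- universes[[uk]]
      if (is.null(u)) return(NULL)
      pos <- which(u$node %in% targets[[recs$drug_b[r]]])
      if (!length(pos)) return(NULL)
      list(u = uk, pos = pos)
    })
  }
  rec_top <- Filter(Negate(is.null), prep(q$top))
  rec_bottom <- Filter(Negate(is.null), prep(q$bottom))
  usizes <- vapply(universes, function(u) length(u$ranks), 0L)

  extract <- function(recs, perm_ranks) {
    vapply(recs, function(rc) {
      rk <- perm_ranks[[rc$u]][rc$pos]
      if (mode == "best") min(rk) else min(rk)  # "all" handled below
    }, 0)
  }
  set.seed(seed)
  p_null <- numeric(n)
  all_rec <- c(rec_top, rec_bottom)
  n_top <- length(rec_top)
  for (b in seq_len(n)) {
    if (scheme == "within") {
      perm_ranks <- lapply(universes, function(u)
        u$ranks[sample.int(length(u$ranks))])
      if (mode == "all") {
        gt <- unlist(lapply(rec_top, function(rc)
          perm_ranks[[rc$u]][rc$pos]))
        gb <- unlist(lapply(rec_bottom, function(rc)
          perm_ranks[[rc$u]][rc$pos]))
      } else {
        gt <- extract(rec_top, perm_ranks)
        gb <- extract(rec_bottom, perm_ranks)
      }
    } else {
      pooled <- c(obs$ranks_top, obs$ranks_bottom)
      pooled <- pooled[sample.int(length(pooled))]
      gt <- pooled[seq_len(length(obs$ranks_top))]
      gb <- pooled[-seq_len(length(obs$ranks_top))]
    }
    p_null[b] <- .mw_p_norm(gt, gb)
  }
  # mid-tie empirical quantile: unbiased under the discrete null
  eq <- (sum(p_null < obs$p_two_sided) +
           0.5 * sum(p_null == obs$p_two_sided)) / n
  structure(
    list(p_null = p_null, observed_p = obs$p_two_sided,
         empirical_quantile = eq,
         n_permutations = n, scheme = scheme, observed = obs),
    class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null (%d %s permutations):\n  observed p = %.5g, empirical quantile = %.4f\n",
    x$n_permutations, x$scheme, x$observed_p, x$empirical_quantile))
  invisible(x)
}

#' Compare cell-line and patient cohorts
#'
#' Principal component analysis of the (condition x analyte) change
#' matrix (centered per analyte), per-cohort kernel density curves of the
#' pooled change values, and a Welch two-sample t-test of pooled changes
#' (cell lines vs patient-derived samples).
#'
#' @param x A [perturbation_matrix].
#' @return List of class `cohort_comparison`: `pca` (scores for the first
#'   three components, per-component variance, full `sdev`), `densities`
#'   (per cohort), `welch` (`htest` or `NULL` with a warning when only one
#'   cohort is present), `cohort` (per-condition cohort labels).
#' @export
cohort_compare <- function(x) {
  stopifnot(inherits(x, "perturbation_matrix"))
  cohort <- unname(x$sample_type[x$sample])
  pc <- stats::prcomp(x$changes, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pc$x))
  pooled <- split(as.vector(x$changes),
                  rep(cohort, times = ncol(x$changes)))
  densities <- lapply(pooled, stats::density)
  welch <- NULL
  if (length(pooled) >= 2L) {
    welch <- stats::t.test(pooled$cell_line, pooled$patient)
  } else {
    warning("single cohort: Welch test skipped")
  }
  structure(
    list(pca = list(coords = pc$x[, seq_len(k), drop = FALSE],
                    var = pc$sdev^2, sdev = pc$sdev),
         densities = densities, welch = welch, cohort = cohort),
    class = "cohort_comparison")
}

#' Hierarchical clustering of analytes or conditions
#'
#' Agglomerative clustering (average linkage on Euclidean distances by
#' default) of the change matrix along either axis, with a deterministic
#' leaf order.
#'
#' @param x A [perturbation_matrix].
#' @param axis `"analytes"` (cluster analyte change vectors across
#'   conditions) or `"conditions"`.
#' @param method Linkage method passed to [stats::hclust()].
#' @return List with `tree` (an `hclust`) and `order` (leaf labels).
#' @export
hierarchical_cluster <- function(x, axis = c("analytes", "conditions"),
                                 method = "average") {
  stopifnot(inherits(x, "perturbation_matrix"))
  axis <- match.arg(axis)
  m <- if (axis == "analytes") t(x$changes) else x$changes
  hc <- stats::hclust(stats::dist(m), method = method)
  list(tree = hc, order = rownames(m)[hc$order])
}
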