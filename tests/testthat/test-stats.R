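test_that("Mann-Whitney exact small-sample results", {
  r <- mann_whitney_rank_bias(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.1)   # 2/20 arrangements as extreme
  expect_equal(r$method, "exact")
  expect_equal(r$direction, 1)       # top ranks lower = positive bias

  same <- mann_whitney_rank_bias(c(1, 2, 5), c(1, 2, 5))
  expect_equal(same$p_two_sided, 1)
  expect_error(mann_whitney_rank_bias(numeric(0), 1:3), "non-empty")
})

test_that("exact path agrees with wilcox.test and with the normal
          approximation at moderate sizes", {
  set.seed(31)
  for (i in 1:20) {
    x <- sample(1:30, 7); y <- sample(1:30, 8)
    r <- mann_whitney_rank_bias(x, y)
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                             correct = FALSE))
    expect_equal(r$U, unname(w$statistic))
    if (!any(duplicated(c(x, y))))
      expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-12)
  }
  # |exact - approx| <= 0.02 at group sizes 8-15 on random data
  for (i in 1:30) {
    n1 <- sample(8:15, 1); n2 <- sample(8:15, 1)
    v <- sample(1:80, n1 + n2)  # untied: exact closed form applies
    pe <- phosphoresponse:::.mw_p_exact(v[1:n1], v[-(1:n1)])
    pa <- phosphoresponse:::.mw_p_norm(v[1:n1], v[-(1:n1)])
    expect_lt(abs(pe - pa), 0.02)
  }
  # tied small samples fall back to full enumeration
  pt <- phosphoresponse:::.mw_p_exact(c(1, 1, 2, 3), c(2, 3, 3, 4))
  expect_true(pt > 0 && pt <= 1)
})

test_that("rank-bias glue extracts quartile rank samples and both
          extraction modes run", {
  co <- simulate_cohort(small_config(seed = 6))
  ep <- eps_score(co$matrix, co$network)
  bl <- screen_bliss(co$screen)
  rb <- eps_rank_bias(ep, bl, co$drugs)
  expect_s3_class(rb, "rank_bias_result")
  expect_equal(rb$n_top, nrow(synergy_quartiles(bl)$top))
  rba <- eps_rank_bias(ep, bl, co$drugs, mode = "all")
  expect_gte(rba$n_top, rb$n_top)
  expect_true(rb$p_two_sided > 0 && rb$p_two_sided <= 1)
})

test_that("permutation robustness: planted concordance is extreme in the
          null, few permutations warn, determinism holds", {
  co <- simulate_cohort(small_config(seed = 6))
  ep <- eps_score(co$matrix, co$network)
  bl <- screen_bliss(co$screen)
  pn <- permutation_robustness(ep, bl, co$drugs, n = 500, seed = 3)
  expect_length(pn$p_null, 500L)
  expect_lt(pn$empirical_quantile, 0.05)
  pn2 <- permutation_robustness(ep, bl, co$drugs, n = 500, seed = 3)
  expect_identical(pn$p_null, pn2$p_null)
  expect_warning(permutation_robustness(ep, bl, co$drugs, n = 50,
                                        seed = 1), "unstable")
})

test_that("cohort comparison: duplicated cohorts coincide, planted mean
          shift is detected, rank-2 data has no third component", {
  panel <- toy_panel(6)
  set.seed(41)
  base <- matrix(rnorm(48), 8, 6, dimnames = list(NULL, panel$phospho))
  pm <- perturbation_matrix(rbind(base, base),
                            c(paste0("cl", 1:8), paste0("pt", 1:8)),
                            rep("d1", 16), panel,
                            sample_type = stats::setNames(
                              rep(c("cell_line", "patient"), each = 8),
                              c(paste0("cl", 1:8), paste0("pt", 1:8))))
  cmp <- cohort_compare(pm)
  expect_equal(cmp$welch$p.value, 1)
  expect_equal(unname(cmp$pca$coords[1:8, ]),
               unname(cmp$pca$coords[9:16, ]))

  # delta = 1, sd = 1, ~500 pooled values per cohort: overwhelming power
  panel25 <- toy_panel(25)
  big <- matrix(rnorm(20 * 25), 20, 25,
                dimnames = list(NULL, panel25$phospho))
  ids <- c(paste0("cl", 1:20), paste0("pt", 1:20))
  shifted <- perturbation_matrix(
    rbind(big, big + 1), ids, rep("d1", 40), panel25,
    sample_type = stats::setNames(rep(c("cell_line", "patient"),
                                      each = 20), ids))
  expect_lt(cohort_compare(shifted)$welch$p.value, 1e-10)

  # rank-2 matrix: variance beyond the second component vanishes
  u <- rnorm(10); v <- rnorm(10)
  low <- outer(u, rnorm(6)) + outer(v, rnorm(6))
  colnames(low) <- panel$phospho
  pml <- perturbation_matrix(low, paste0("s", 1:10), rep("d1", 10), panel)
  expect_warning(cl <- cohort_compare(pml), "single cohort")
  expect_lt(cl$pca$var[3] / sum(cl$pca$var), 1e-20)
  # variance conservation across components
  expect_equal(sum(cl$pca$var),
               sum(apply(low, 2, stats::var)), tolerance = 1e-10)
})

test_that("hierarchical clustering merges identical profiles first and is
          invariant to input row order", {
  panel <- toy_panel(3)
  m <- rbind(c(0, 0, 0), c(0, 0, 0.01), c(5, 5, 5), c(0, 1, 10))
  colnames(m) <- panel$phospho
  pm <- perturbation_matrix(m, paste0("s", 1:4), rep("d", 4), panel)
  hc <- hierarchical_cluster(pm, axis = "conditions")
  expect_equal(sort(hc$tree$merge[1, ]), c(-2, -1))  # closest pair first

  # three points on a line at 0, 1, 10: first merge joins 0 and 1
  m2 <- cbind(c(0, 1, 10), 0, 0); colnames(m2) <- panel$phospho
  pm2 <- perturbation_matrix(m2, paste0("s", 1:3), rep("d", 3), panel)
  hc2 <- hierarchical_cluster(pm2, axis = "conditions")
  expect_equal(sort(hc2$tree$merge[1, ]), c(-2, -1))

  perm <- c(3, 1, 4, 2)
  pmp <- perturbation_matrix(m[perm, ], paste0("s", 1:4)[perm],
                             rep("d", 4), panel)
  hcp <- hierarchical_cluster(pmp, axis = "conditions")
  expect_equal(sort(hcp$tree$height), sort(hc$tree$height))
  # analyte axis runs too
  expect_length(hierarchical_cluster(pm, axis = "analytes")$order, 3L)
})
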