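test_that("screen enumeration: ordered and unordered designs", {
  expect_equal(nrow(enumerate_screen(paste0("D", 1:7), paste0("S", 1:6))),
               252L)
  expect_equal(nrow(enumerate_screen(paste0("D", 1:7), "S1",
                                     ordered = FALSE)), 21L)
  expect_equal(nrow(enumerate_screen(c("a", "b"), "S1")), 2L)
  expect_error(enumerate_screen(c("a", "a"), "S1"), "duplicate")
  expect_error(enumerate_screen("a", "S1"), "at least two")
})

test_that("Bliss expectation: arithmetic, symmetry, monotonicity, range", {
  expect_equal(bliss_expected(0, 0.3), 0.3)
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0.2, 0.4), 0.52)
  expect_error(bliss_expected(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(bliss_expected(0.1, 1.5), "\\[0, 1\\]")

  g <- seq(0, 1, length.out = 100)
  tol <- 1e-12  # floating-point slack at the fb = 1 boundary
  E <- outer(g, g, bliss_expected)
  expect_equal(E, t(E))                       # symmetric
  expect_true(all(E >= -tol & E <= 1 + tol))  # closed on [0,1]^2
  expect_true(all(diff(E) >= -tol))           # monotone in fa
  expect_true(all(apply(E, 1, diff) >= -tol)) # monotone in fb
  expect_true(all(E + tol >= pmax(outer(g, g, function(a, b) a),
                                  outer(g, g, function(a, b) b))))
})

test_that("excess grid: additive observations give zero summary, sign
          convention, missing-cell policy", {
  fa <- c(0.1, 0.3); fb <- c(0.2, 0.4, 0.6)
  additive <- outer(fa, fb, bliss_expected)
  g <- dose_response_grid("s", "a", "b", c(1e-7, 2e-7),
                          c(1e-7, 2e-7, 3e-7), fa, fb, additive)
  out <- bliss_excess_grid(g)
  expect_equal(out$bliss, 0)
  expect_equal(out$excess, additive * 0)

  # all-zero combined effect with active single agents: antagonism
  g0 <- dose_response_grid("s", "a", "b", c(1e-7, 2e-7),
                           c(1e-7, 2e-7, 3e-7), fa, fb, additive * 0)
  expect_lt(bliss_excess_grid(g0)$bliss, 0)

  withNA <- additive; withNA[1, 1] <- NA
  gna <- dose_response_grid("s", "a", "b", c(1e-7, 2e-7),
                            c(1e-7, 2e-7, 3e-7), fa, fb, withNA)
  expect_warning(outna <- bliss_excess_grid(gna), "missing")
  expect_equal(outna$bliss, 0)
  tooNA <- additive; tooNA[1, ] <- NA
  gbad <- dose_response_grid("s", "a", "b", c(1e-7, 2e-7),
                             c(1e-7, 2e-7, 3e-7), fa, fb, tooNA)
  expect_error(suppressWarnings(bliss_excess_grid(gbad)), "25%")
})

test_that("summary is invariant to transposing the grid with swapped drug
          labels", {
  set.seed(13)
  fa <- sort(runif(3)); fb <- sort(runif(4))
  obs <- matrix(runif(12), 3, 4)
  g1 <- dose_response_grid("s", "a", "b", 1e-7 * (1:3), 1e-7 * (1:4),
                           fa, fb, obs)
  g2 <- dose_response_grid("s", "b", "a", 1e-7 * (1:4), 1e-7 * (1:3),
                           fb, fa, t(obs))
  for (m in c("mean", "max", "topq"))
    expect_equal(bliss_excess_grid(g1, m)$bliss,
                 bliss_excess_grid(g2, m)$bliss, tolerance = 1e-12)
})

test_that("screen round-trips through the long CSV format", {
  co <- simulate_cohort(small_config(seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_combination_screen(co$screen, f)
  back <- read_combination_screen(f)
  expect_equal(length(back$grids), length(co$screen$grids))
  expect_equal(screen_bliss(back)$bliss, screen_bliss(co$screen)$bliss,
               tolerance = 1e-12)
})

test_that("extreme synergy quartiles follow the remainder rule and break
          ties by record order", {
  screen <- data.frame(sample = "s", drug_a = paste0("a", 1:8),
                       drug_b = "x", bliss = c(8:1) / 10)
  q <- synergy_quartiles(screen)
  expect_equal(nrow(q$top), 2L)
  expect_equal(nrow(q$bottom), 2L)
  expect_equal(q$top$drug_a, c("a1", "a2"))
  expect_equal(q$bottom$drug_a, c("a8", "a7"))

  tied <- screen; tied$bliss <- 0.5
  qt <- synergy_quartiles(tied)
  expect_equal(nrow(qt$top), 2L)
  expect_equal(qt$top$drug_a, c("a1", "a2"))

  big <- data.frame(sample = rep(paste0("s", 1:6), each = 42),
                    drug_a = "a", drug_b = "b",
                    bliss = seq_len(252) / 252)
  qb <- synergy_quartiles(big)
  expect_equal(nrow(qb$top), 63L)
  expect_equal(nrow(qb$bottom), 63L)
  expect_error(synergy_quartiles(screen[1:3, ]), "at least 4")
})
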