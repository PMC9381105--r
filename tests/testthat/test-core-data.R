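test_that("panel validation enforces uniqueness, controls and size", {
  p <- analyte_panel(c("GAPDH", "AKT_S473", "ERK1_T202"))
  expect_equal(p$size, 2L)
  expect_error(analyte_panel(c("GAPDH", "A", "A")), "duplicate")
  expect_error(analyte_panel(c("A", "B"), controls = "A"), "GAPDH")
  expect_error(analyte_panel(c("GAPDH", "A"), controls = c("GAPDH", "X")),
               "subset")
})

test_that("plate normalization reproduces the hand-computed toy oracle", {
  # 3 DMSO wells with log2 GAPDH ratios {0, 0.2, 0.4} for analyte A01 and
  # a drugged well at ratio 1.0: change = 1.0 - mean(0, 0.2, 0.4) = 0.8
  g <- 100
  mk <- function(cond, rep, lr_a1)
    well_rows("s1", cond, rep, c(GAPDH = g, A01 = g * 2^lr_a1,
                                 A02 = g))
  plate <- raw_plate(rbind(mk("DMSO", 1, 0), mk("DMSO", 2, 0.2),
                           mk("DMSO", 3, 0.4), mk("gefitinib", 1, 1.0)))
  pm <- normalize_plate(plate, toy_panel(2))
  expect_equal(unname(pm$changes[1, "A01"]), 1.0 - mean(c(0, 0.2, 0.4)))
  expect_equal(unname(pm$changes[1, "A02"]), 0)
})

test_that("constant analyte/GAPDH ratio gives all-zero changes", {
  plate <- raw_plate(rbind(
    well_rows("s1", "DMSO", 1, c(GAPDH = 50, A01 = 50, A02 = 50)),
    well_rows("s1", "drugA", 1, c(GAPDH = 900, A01 = 900, A02 = 900))))
  pm <- normalize_plate(plate, toy_panel(2))
  expect_equal(unname(as.vector(pm$changes)), c(0, 0))
})

test_that("normalization is invariant to per-well scaling and equals the
          direct log2 drug/DMSO ratio with one DMSO well", {
  set.seed(42)
  for (rep in 1:5) {
    base <- stats::setNames(stats::runif(4, 10, 1000),
                            c("GAPDH", "A01", "A02", "A03"))
    drugged <- stats::setNames(stats::runif(4, 10, 1000), names(base))
    plate1 <- raw_plate(rbind(well_rows("s1", "DMSO", 1, base),
                              well_rows("s1", "drugA", 1, drugged)))
    # scale whole wells by arbitrary constants
    plate2 <- raw_plate(rbind(well_rows("s1", "DMSO", 1, base * 7.3),
                              well_rows("s1", "drugA", 1, drugged * 0.21)))
    panel <- toy_panel(3)
    pm1 <- normalize_plate(plate1, panel)
    pm2 <- normalize_plate(plate2, panel)
    expect_equal(pm1$changes, pm2$changes, tolerance = 1e-12)
    direct <- log2((drugged[-1] / drugged[["GAPDH"]]) /
                     (base[-1] / base[["GAPDH"]]))
    expect_equal(unname(pm1$changes[1, ]), unname(direct),
                 tolerance = 1e-12)
  }
})

test_that("normalization rejects bad GAPDH and clamps non-positive MFI", {
  plate <- raw_plate(rbind(
    well_rows("s1", "DMSO", 1, c(GAPDH = 0.0, A01 = 5, A02 = 5)),
    well_rows("s1", "drugA", 1, c(GAPDH = 10, A01 = 5, A02 = 5))))
  expect_error(normalize_plate(plate, toy_panel(2)), "GAPDH")
  plate2 <- raw_plate(rbind(
    well_rows("s1", "DMSO", 1, c(GAPDH = 10, A01 = 0, A02 = 5)),
    well_rows("s1", "drugA", 1, c(GAPDH = 10, A01 = 5, A02 = 5))))
  expect_warning(pm <- normalize_plate(plate2, toy_panel(2)), "clamped")
  expect_true(all(is.finite(pm$changes)))
})

test_that("write/read round trip preserves values to >= 12 digits and
          read validates the table against the panel", {
  set.seed(7)
  panel <- toy_panel(5)
  pm <- perturbation_matrix(
    matrix(rnorm(10), 2, 5, dimnames = list(NULL, panel$phospho)),
    c("H522", "PC9"), c("gefitinib", "gefitinib"), panel,
    sample_type = c(H522 = "cell_line", PC9 = "patient"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_perturbation_matrix(pm, f)
  back <- read_perturbation_matrix(f, panel)
  expect_equal(back$changes, pm$changes, tolerance = 1e-13)
  expect_equal(back$sample_type, pm$sample_type)

  # missing analyte column
  bigger <- analyte_panel(c(panel$analytes, "A99"))
  expect_error(read_perturbation_matrix(f, bigger), "A99")
  # extra column warned and ignored
  smaller <- analyte_panel(panel$analytes[1:4])
  expect_warning(pm2 <- read_perturbation_matrix(f, smaller), "A04|A05")
  expect_equal(ncol(pm2$changes), 3L)
})

test_that("duplicate (sample, drug) rows and non-numeric values error", {
  panel <- toy_panel(2)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,drug,A01,A02",
               "H522,gefitinib,0.1,0.2",
               "H522,gefitinib,0.3,0.4"), f)
  expect_error(read_perturbation_matrix(f, panel), "duplicate")
  writeLines(c("sample,drug,A01,A02",
               "H522,gefitinib,abc,0.2"), f)
  expect_error(read_perturbation_matrix(f, panel), "row 1.*A01")
})

test_that("Cmax protein-binding adjustment and its domain errors", {
  d <- drug_info("gefitinib", "EGFR", cmax_plasma = 1e-6,
                 fu_plasma = 0.1, fu_medium = 0.5)
  expect_equal(d$assay_concentration, 2e-7)
  d$fu_medium <- d$fu_plasma  # equal binding: assay conc = Cmax
  expect_equal(adjust_cmax_for_binding(d), d$cmax_plasma)
  d$fu_medium <- 0
  expect_error(adjust_cmax_for_binding(d), "fu_medium")
  d$fu_medium <- 1.2
  expect_error(adjust_cmax_for_binding(d), "fu_medium")
})

test_that("regulation counting matches inspection and bounds", {
  panel <- toy_panel(4)
  ch <- rbind(c(-0.5, -0.2, 0.3, 0.05), c(0, 0, 0, 0))
  colnames(ch) <- panel$phospho
  pm <- perturbation_matrix(ch, c("s1", "s2"), c("d1", "d1"), panel)
  out <- count_regulated(pm, tau = 0.1)
  expect_equal(out$per_condition$n_down, c(2L, 0L))
  expect_equal(out$per_condition$n_up, c(1L, 0L))
  expect_true(all(out$per_condition$n_down + out$per_condition$n_up <=
                    panel$size))
  expect_equal(out$summary$pct_down[1], 100 * mean(c(2, 0)) / 4)
  expect_error(count_regulated(pm, tau = 0), "positive")
})
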