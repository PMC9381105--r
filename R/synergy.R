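#' Enumerate a combination screen design
#'
#' Crosses every two-drug combination with every sample. The ordered view
#' (anchor, partner) distinguishes which drug is held at its fixed assay
#' concentration; the unordered view collapses the two orientations (the
#' heatmap view of the screen).
#'
#' @param drugs Character vector of drug ids (unique).
#' @param samples Character vector of sample ids.
#' @param ordered If `TRUE` (default), all ordered pairs `(a, b)`, `a != b`;
#'   otherwise unordered pairs.
#' @return Data frame `sample, drug_a, drug_b`.
#' @examples
#' nrow(enumerate_screen(paste0("D", 1:7), paste0("S", 1:6)))  # 252
#' @export
enumerate_screen <- function(drugs, samples, ordered = TRUE) {
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs))
    stop("duplicate drug ids: ",
         paste(unique(drugs[duplicated(drugs)]), collapse = ", "))
  if (length(drugs) < 2L) stop("need at least two drugs")
  if (ordered) {
    g <- expand.grid(drug_b = drugs, drug_a = drugs,
                     stringsAsFactors = FALSE)
    g <- g[g$drug_a != g$drug_b, c("drug_a", "drug_b")]
  } else {
    cmb <- utils::combn(drugs, 2L)
    g <- data.frame(drug_a = cmb[1L, ], drug_b = cmb[2L, ],
                    stringsAsFactors = FALSE)
  }
  out <- merge(data.frame(sample = as.character(samples),
                          stringsAsFactors = FALSE), g)
  rownames(out) <- NULL
  out[order(out$sample, out$drug_a, out$drug_b), ]
}

#' Bliss-independence expected combined effect
#'
#' Under Bliss independence two drugs act as independent probabilistic
#' events, so the expected combined fractional effect is
#' `fa + fb - fa * fb`. Positive excess of the observed combined effect
#' over this expectation indicates synergy.
#'
#' @param fa,fb Single-agent fractional effects in \[0, 1\]
#'   (effect = 1 - fractional viability). Vectorized.
#' @return Expected combined effect, same shape as the inputs.
#' @examples
#' bliss_expected(0.2, 0.4)  # 0.52
#' @export
bliss_expected <- function(fa, fb) {
  if (any(!is.finite(fa)) || any(!is.finite(fb)) ||
      any(fa < 0 | fa > 1) || any(fb < 0 | fb > 1))
    stop("single-agent effects must lie in [0, 1]")
  fa + fb - fa * fb
}

#' Construct a two-drug dose-response grid
#'
#' @param sample_id Sample identifier.
#' @param drug_a,drug_b Drug identifiers (a = anchor rows, b = partner
#'   columns).
#' @param conc_a,conc_b Ascending molar concentration vectors.
#' @param fa,fb Single-agent fractional effects at each concentration.
#' @param f_obs Observed combined-effect matrix, `length(conc_a)` rows by
#'   `length(conc_b)` columns; values outside \[0, 1\] are clamped with a
#'   warning, `NA` cells are allowed (missing wells).
#' @return An object of class `dose_response_grid`.
#' @export
dose_response_grid <- function(sample_id, drug_a, drug_b, conc_a, conc_b,
                               fa, fb, f_obs) {
  f_obs <- as.matrix(f_obs)
  stopifnot(length(fa) == length(conc_a), length(fb) == length(conc_b),
            nrow(f_obs) == length(conc_a), ncol(f_obs) == length(conc_b))
  if (is.unsorted(conc_a) || is.unsorted(conc_b))
    stop("concentrations must be ascending")
  if (any(fa < 0 | fa > 1, na.rm = TRUE) ||
      any(fb < 0 | fb > 1, na.rm = TRUE))
    stop("single-agent effects must lie in [0, 1]")
  out_of_range <- sum(f_obs < 0 | f_obs > 1, na.rm = TRUE)
  if (out_of_range) {
    warning(out_of_range, " observed effect(s) clamped to [0, 1]")
    f_obs[] <- pmin(pmax(f_obs, 0), 1)
  }
  structure(list(sample_id = sample_id, drug_a = drug_a, drug_b = drug_b,
                 conc_a = conc_a, conc_b = conc_b, fa = fa, fb = fb,
                 f_obs = f_obs),
            class = "dose_response_grid")
}

#' Bliss excess over a dose grid and its scalar summary
#'
#' Per grid cell, excess = observed combined effect minus the
#' Bliss-expected effect from the single agents at the corresponding
#' concentrations. The scalar summary reduces the excess matrix by its
#' mean (default), maximum, or mean of the top-quartile cells.
#'
#' @param grid A [dose_response_grid].
#' @param summary One of `"mean"`, `"max"`, `"topq"`.
#' @return List with `excess` (matrix) and `bliss` (scalar summary).
#'   Missing cells are excluded from the summary with a warning; more than
#'   25% missing is an error.
#' @export
bliss_excess_grid <- function(grid, summary = c("mean", "max", "topq")) {
  stopifnot(inherits(grid, "dose_response_grid"))
  summary <- match.arg(summary)
  expected <- outer(grid$fa, grid$fb, bliss_expected)
  excess <- grid$f_obs - expected
  nmiss <- sum(is.na(excess))
  if (nmiss > 0.25 * length(excess))
    stop("more than 25% of grid cells are missing")
  if (nmiss > 0)
    warning(nmiss, " missing grid cell(s) excluded from summary")
  v <- excess[!is.na(excess)]
  bliss <- switch(summary,
    mean = mean(v),
    max = max(v),
    topq = mean(sort(v, decreasing = TRUE)[seq_len(max(1L,
             ceiling(length(v) / 4)))]))
  list(excess = excess, bliss = bliss)
}

#' Summarize a combination screen into per-pair Bliss scores
#'
#' @param screen A `combination_screen` (list with element `grids`, each a
#'   [dose_response_grid]), e.g. from [simulate_combination_screen()] or
#'   [read_combination_screen()].
#' @param summary Summary statistic passed to [bliss_excess_grid()].
#' @return Data frame `sample, drug_a, drug_b, bliss`.
#' @export
screen_bliss <- function(screen, summary = "mean") {
  grids <- if (inherits(screen, "combination_screen")) screen$grids
           else screen
  do.call(rbind, lapply(grids, function(g) {
    data.frame(sample = g$sample_id, drug_a = g$drug_a, drug_b = g$drug_b,
               bliss = bliss_excess_grid(g, summary = summary)$bliss,
               stringsAsFactors = FALSE)
  }))
}

#' Extreme Bliss-synergy quartiles of a screen
#'
#' Sorts screen records by their Bliss summary score and returns the
#' top-25% (most synergistic) and bottom-25% (least synergistic) record
#' sets. Quartile sizes follow the same remainder rule as
#' [assign_quartiles()]; ties are broken deterministically by record order
#' (sample, drug_a, drug_b).
#'
#' @param screen Data frame `sample, drug_a, drug_b, bliss`.
#' @return List with data frames `top` and `bottom`.
#' @export
synergy_quartiles <- function(screen) {
  n <- nrow(screen)
  if (n < 4L) stop("need at least 4 screen records")
  rec_id <- paste(screen$sample, screen$drug_a, screen$drug_b)
  ord <- order(-screen$bliss, rec_id)
  sizes <- .quartile_sizes(n)
  top_n <- sizes[1L]; bottom_n <- sizes[4L]
  list(top = screen[ord[seq_len(top_n)], , drop = FALSE],
       bottom = screen[rev(ord)[seq_len(bottom_n)], , drop = FALSE])
}

#' Read a combination screen from long-format CSV
#'
#' Columns `sample, drug_a, drug_b, conc_a, conc_b, effect`; single-agent
#' rows are encoded with the other drug's concentration equal to 0.
#'
#' @param path CSV file path.
#' @return A `combination_screen` (list of [dose_response_grid]s).
#' @export
read_combination_screen <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$sample, df$drug_a, df$drug_b, sep = "\r")
  grids <- lapply(unique(key), function(k) {
    d <- df[key == k, ]
    ca <- sort(unique(d$conc_a[d$conc_a > 0]))
    cb <- sort(unique(d$conc_b[d$conc_b > 0]))
    fa <- vapply(ca, function(cc)
      d$effect[d$conc_a == cc & d$conc_b == 0][1L], 0)
    fb <- vapply(cb, function(cc)
      d$effect[d$conc_b == cc & d$conc_a == 0][1L], 0)
    m <- matrix(NA_real_, length(ca), length(cb))
    comb <- d[d$conc_a > 0 & d$conc_b > 0, ]
    m[cbind(match(comb$conc_a, ca), match(comb$conc_b, cb))] <- comb$effect
    dose_response_grid(d$sample[1L], d$drug_a[1L], d$drug_b[1L],
                       ca, cb, fa, fb, m)
  })
  structure(list(grids = grids), class = "combination_screen")
}

#' Write a combination screen to long-format CSV
#' @param screen A `combination_screen`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_combination_screen <- function(screen, path) {
  rows <- lapply(screen$grids, function(g) {
    rbind(
      data.frame(sample = g$sample_id, drug_a = g$drug_a, drug_b = g$drug_b,
                 conc_a = g$conc_a, conc_b = 0, effect = g$fa),
      data.frame(sample = g$sample_id, drug_a = g$drug_a, drug_b = g$drug_b,
                 conc_a = 0, conc_b = g$conc_b, effect = g$fb),
      data.frame(sample = g$sample_id, drug_a = g$drug_a, drug_b = g$drug_b,
                 conc_a = rep(g$conc_a, times = length(g$conc_b)),
                 conc_b = rep(g$conc_b, each = length(g$conc_a)),
                 effect = as.vector(g$f_obs)))
  })
  df <- do.call(rbind, rows)
  df$effect <- formatC(df$effect, digits = 17, format = "g")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
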