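#' Construct a raw bead-assay plate
#'
#' Long-format well-level fluorescence intensities: one row per
#' (sample, condition, replicate, analyte) with the measured median
#' fluorescence intensity (MFI). `condition` is a drug identifier or
#' `"DMSO"` for the vehicle controls; the study design exposes every sample
#' to each drug once plus three DMSO control wells.
#'
#' @param wells Data frame with columns `sample`, `condition`, `replicate`,
#'   `analyte`, `mfi`.
#' @return An object of class `raw_plate`.
#' @export
raw_plate <- function(wells) {
  req <- c("sample", "condition", "replicate", "analyte", "mfi")
  if (!all(req %in% names(wells)))
    stop("wells must have columns: ", paste(req, collapse = ", "))
  wells$mfi <- as.numeric(wells$mfi)
  if (any(is.na(wells$mfi))) stop("non-numeric MFI values present")
  if (any(wells$mfi < 0)) stop("negative MFI values present")
  wells$well_id <- paste(wells$sample, wells$condition, wells$replicate,
                         sep = "\r")
  gap <- wells[wells$analyte == "GAPDH", ]
  if (!all(unique(wells$well_id) %in% gap$well_id))
    stop("every well must carry a GAPDH measurement")
  for (s in unique(wells$sample)) {
    conds <- unique(wells$condition[wells$sample == s])
    if (any(conds != "DMSO") && !"DMSO" %in% conds)
      stop("sample ", s, " has drugged wells but no DMSO control well")
  }
  structure(list(wells = wells[, req]), class = "raw_plate")
}

#' Read a raw plate from long-format CSV
#'
#' Columns: `sample, condition, replicate, analyte, mfi`.
#'
#' @param path CSV file path.
#' @return A [raw_plate].
#' @export
read_raw_plate <- function(path) {
  raw_plate(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Normalize a raw plate into a perturbation matrix
#'
#' Implements the loading-control normalization and median-centering used to
#' turn well-level bead intensities into signed perturbation profiles:
#'
#' 1. Within each well, every analyte intensity is divided by that well's
#'    GAPDH intensity and log2-transformed (loading-control normalization;
#'    removes any per-well scale factor).
#' 2. Per analyte, the median of the log2 ratios across all DMSO wells of
#'    the plate is subtracted from every well (median-centering anchored on
#'    the vehicle controls).
#' 3. The change for a (sample, drug, analyte) is the centered value of the
#'    drugged well (mean over replicates if several) minus the mean centered
#'    value of that sample's DMSO replicate wells.
#'
#' Step 2 cancels in step 3 and is retained so that intermediate centered
#' values are interpretable on a plate-anchored scale; the final changes are
#' DMSO-referenced and invariant to per-well scaling.
#'
#' Zero or negative analyte intensities are clamped to a floor (smallest
#' positive intensity on the plate times `floor_factor`) with a warning;
#' a non-positive GAPDH intensity is an error.
#'
#' @param plate A [raw_plate].
#' @param panel An [analyte_panel]; every non-control analyte must be
#'   measured in every well.
#' @param floor_factor Multiplier on the smallest positive plate intensity
#'   used as the clamping floor for non-positive values.
#' @param sample_type Optional named vector passed to
#'   [perturbation_matrix()].
#' @return A [perturbation_matrix] with one row per (sample, drug).
#' @export
normalize_plate <- function(plate, panel, floor_factor = 0.5,
                            sample_type = NULL) {
  stopifnot(inherits(plate, "raw_plate"))
  w <- plate$wells
  w$well_id <- paste(w$sample, w$condition, w$replicate, sep = "\r")

  gap <- w[w$analyte == "GAPDH", c("well_id", "mfi")]
  gapdh <- stats::setNames(gap$mfi, gap$well_id)
  if (any(gapdh <= 0)) stop("non-positive GAPDH intensity in well(s): ",
                            paste(gsub("\r", "/", names(gapdh)[gapdh <= 0]),
                                  collapse = ", "))

  x <- w[w$analyte %in% panel$phospho, ]
  if (any(x$mfi <= 0)) {
    floor <- min(w$mfi[w$mfi > 0]) * floor_factor
    n <- sum(x$mfi <= 0)
    warning(sprintf("%d non-positive intensities clamped to floor %.6g",
                    n, floor))
    x$mfi[x$mfi <= 0] <- floor
  }
  x$lr <- log2(x$mfi / gapdh[x$well_id])

  # per-analyte median over all DMSO wells of the plate
  dmso <- x[x$condition == "DMSO", ]
  med <- tapply(dmso$lr, dmso$analyte, stats::median)
  x$centered <- x$lr - med[x$analyte]

  # mean centered value per (sample, condition, analyte) over replicates
  agg <- stats::aggregate(centered ~ sample + condition + analyte, data = x,
                          FUN = mean)
  base <- agg[agg$condition == "DMSO", ]
  basemap <- stats::setNames(base$centered, paste(base$sample, base$analyte,
                                                  sep = "\r"))
  drugged <- agg[agg$condition != "DMSO", ]
  drugged$change <- drugged$centered -
    basemap[paste(drugged$sample, drugged$analyte, sep = "\r")]

  conds <- unique(drugged[, c("sample", "condition")])
  m <- matrix(NA_real_, nrow(conds), panel$size,
              dimnames = list(NULL, panel$phospho))
  idx_r <- match(paste(drugged$sample, drugged$condition, sep = "\r"),
                 paste(conds$sample, conds$condition, sep = "\r"))
  idx_c <- match(drugged$analyte, panel$phospho)
  if (anyNA(idx_c))
    stop("plate contains analytes outside the panel")
  m[cbind(idx_r, idx_c)] <- drugged$change
  if (anyNA(m)) {
    miss <- colnames(m)[colSums(is.na(m)) > 0]
    stop("panel analyte(s) not measured in every well: ",
         paste(miss, collapse = ", "))
  }
  perturbation_matrix(m, conds$sample, conds$condition, panel,
                      sample_type = sample_type)
}

#' Drug annotation with clinically anchored assay concentration
#'
#' Holds a drug's network target nodes and the pharmacology needed to set
#' the assay concentration from the clinical maximum plasma concentration
#' (Cmax), adjusted for differential protein binding between plasma and the
#' 20%-FBS culture medium.
#'
#' @param drug_id Drug identifier.
#' @param target_node_ids Non-empty character vector of network node
#'   identifiers the drug inhibits.
#' @param cmax_plasma Clinical Cmax, molar.
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @param fu_medium Fraction unbound in 20% FBS medium, in (0, 1].
#' @return An object of class `drug_info`; `assay_concentration` is filled
#'   by [adjust_cmax_for_binding()] when the binding fields are supplied.
#' @export
drug_info <- function(drug_id, target_node_ids, cmax_plasma = NA_real_,
                      fu_plasma = NA_real_, fu_medium = NA_real_) {
  if (length(target_node_ids) == 0L)
    stop("target_node_ids must be non-empty")
  obj <- structure(
    list(drug_id = drug_id,
         target_node_ids = as.character(target_node_ids),
         cmax_plasma = cmax_plasma, fu_plasma = fu_plasma,
         fu_medium = fu_medium, assay_concentration = NA_real_),
    class = "drug_info")
  if (!is.na(cmax_plasma) && !is.na(fu_plasma) && !is.na(fu_medium))
    obj$assay_concentration <- adjust_cmax_for_binding(obj)
  obj
}

#' Adjust Cmax for protein binding in culture medium
#'
#' Returns the medium concentration giving the same unbound drug
#' concentration as the clinical Cmax in plasma:
#' `cmax_plasma * fu_plasma / fu_medium`, where `fu` is the fraction
#' unbound in plasma and in 20%-FBS medium respectively.
#'
#' @param info A [drug_info] with `cmax_plasma`, `fu_plasma` and
#'   `fu_medium` set.
#' @return The assay concentration (molar).
#' @examples
#' d <- drug_info("gefitinib", "EGFR")
#' d$cmax_plasma <- 1e-6; d$fu_plasma <- 0.1; d$fu_medium <- 0.5
#' adjust_cmax_for_binding(d)  # 2e-7
#' @export
adjust_cmax_for_binding <- function(info) {
  stopifnot(inherits(info, "drug_info"))
  for (f in c("fu_plasma", "fu_medium")) {
    v <- info[[f]]
    if (is.na(v) || v <= 0 || v > 1)
      stop(f, " must lie in (0, 1]")
  }
  if (is.na(info$cmax_plasma) || info$cmax_plasma <= 0)
    stop("cmax_plasma must be positive")
  info$cmax_plasma * info$fu_plasma / info$fu_medium
}

#' Count up- and down-regulated analytes per condition
#'
#' For each (sample, drug) condition, counts analytes with change below
#' `-tau` (down-regulated) and above `+tau` (up-regulated) on the log2
#' scale, and summarizes cohort means separately for cell lines and
#' patient-derived samples, both as counts and as percent of the panel.
#'
#' @param x A [perturbation_matrix].
#' @param tau Positive regulation threshold on the log2 change scale.
#' @return A list with `per_condition` (data frame `sample, drug, n_down,
#'   n_up`) and `summary` (data frame per cohort: mean counts and percent
#'   of panel).
#' @export
count_regulated <- function(x, tau = 0.1) {
  stopifnot(inherits(x, "perturbation_matrix"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a positive scalar")
  n_down <- rowSums(x$changes < -tau)
  n_up <- rowSums(x$changes > tau)
  per <- data.frame(sample = x$sample, drug = x$drug,
                    n_down = n_down, n_up = n_up, row.names = NULL)
  cohort <- unname(x$sample_type[x$sample])
  psize <- ncol(x$changes)
  sm <- do.call(rbind, lapply(unique(cohort), function(cc) {
    i <- cohort == cc
    data.frame(cohort = cc,
               mean_down = mean(n_down[i]), mean_up = mean(n_up[i]),
               pct_down = 100 * mean(n_down[i]) / psize,
               pct_up = 100 * mean(n_up[i]) / psize,
               n_conditions = sum(i))
  }))
  list(per_condition = per, summary = sm)
}
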